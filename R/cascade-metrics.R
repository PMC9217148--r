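#' Build the dissemination tree of one root post
#'
#' Assembles the rooted tree containing the original post (level 0) and
#' every resolved repost reachable from it. Nodes carry their forwarding
#' level, timestamp and engagement (forwards, likes); each edge points
#' from the forwarded post to the forwarding repost.
#'
#' @param root_post One-row tibble for the root post (from an
#'   `rc_dataset`'s `posts` table).
#' @param edges Edge tibble from [resolve_parents()] (any roots; only
#'   edges of this root are used).
#' @param parsed Parsed repost tibble from [parse_chains()].
#' @return An object of class `rc_tree`: list with `root_id` and `nodes`,
#'   a tibble (`id`, `parent_id`, `level`, `timestamp`, `forwards`,
#'   `likes`) whose first row is the root (level 0, `parent_id` `NA`).
#' @export
build_tree <- function(root_post, edges, parsed) {
  stopifnot(nrow(root_post) == 1)
  root_id <- root_post$post_id
  edges <- edges[edges$root_post_id == root_id, , drop = FALSE]
  parsed <- parsed[match(edges$child_id, parsed$repost_id), , drop = FALSE]

  nodes <- tibble::tibble(
    id = root_id, parent_id = NA_character_, level = 0L,
    timestamp = root_post$timestamp,
    forwards = root_post$forwards, likes = root_post$likes)

  if (nrow(edges) > 0) {
    if (anyDuplicated(edges$child_id)) {
      abort(sprintf("cycle or multiple parents detected at node(s): %s",
                    paste(unique(edges$child_id[duplicated(edges$child_id)]),
                          collapse = ", ")))
    }
    kids <- tibble::tibble(
      id = edges$child_id, parent_id = edges$parent_id,
      level = parsed$level, timestamp = parsed$timestamp,
      forwards = parsed$forwards, likes = parsed$likes)
    # keep only records reachable from the root, walking level by level
    keep <- character(0); frontier <- root_id; lev <- 1L
    repeat {
      nxt <- kids$id[kids$parent_id %in% frontier & kids$level == lev]
      if (length(nxt) == 0) break
      keep <- c(keep, nxt); frontier <- nxt; lev <- lev + 1L
      if (lev > nrow(kids) + 1L) {
        abort(sprintf("cycle detected while walking tree of root %s", root_id))
      }
    }
    kids <- kids[kids$id %in% keep, , drop = FALSE]
    parent_level <- ifelse(kids$parent_id == root_id, 0L,
                           kids$level[match(kids$parent_id, kids$id)])
    if (any(kids$level != parent_level + 1L)) {
      bad <- kids$id[kids$level != parent_level + 1L]
      abort(sprintf("level inconsistency at node(s): %s",
                    paste(bad, collapse = ", ")))
    }
    nodes <- dplyr::bind_rows(nodes, kids[order(kids$level, kids$id), ])
  }
  structure(list(root_id = root_id, nodes = nodes), class = "rc_tree")
}

#' @export
print.rc_tree <- function(x, ...) {
  cat(sprintf("<rc_tree> root %s: %d repost node(s), depth %d\n",
              x$root_id, nrow(x$nodes) - 1L, max(x$nodes$level)))
  invisible(x)
}

level_widths <- function(tree) {
  lev <- tree$nodes$level[tree$nodes$level >= 1L]
  if (length(lev) == 0) return(integer(0))
  tabulate(lev, nbins = max(lev))
}

#' Dissemination metrics of one cascade tree
#'
#' Computes the five topological attributes of a dissemination network:
#' \describe{
#'   \item{scale}{number of repost nodes (the root is excluded), i.e. the
#'     number of forwards the original post accumulated;}
#'   \item{depth}{highest forwarding level reached (root = level 0);}
#'   \item{max_width}{number of nodes at the widest repost level;}
#'   \item{avg_width}{mean number of nodes per repost level, equal to
#'     scale / depth;}
#'   \item{speed}{reposts per hour over the cascade lifetime (root
#'     timestamp to latest repost), with elapsed time floored at one
#'     minute; `NA` for an undisseminated post.}
#' }
#'
#' @param tree An `rc_tree` from [build_tree()].
#' @return One-row tibble: `post_id`, `scale`, `depth`, `max_width`,
#'   `avg_width`, `speed`.
#' @export
compute_metrics <- function(tree) {
  stopifnot(inherits(tree, "rc_tree"))
  w <- level_widths(tree)
  scale <- sum(w)
  depth <- length(w)
  if (scale == 0) {
    return(tibble::tibble(post_id = tree$root_id, scale = 0L, depth = 0L,
                          max_width = 0L, avg_width = 0, speed = NA_real_))
  }
  elapsed_h <- as.numeric(difftime(max(tree$nodes$timestamp),
                                   tree$nodes$timestamp[1], units = "hours"))
  tibble::tibble(
    post_id = tree$root_id,
    scale = as.integer(scale),
    depth = as.integer(depth),
    max_width = as.integer(max(w)),
    avg_width = scale / depth,
    speed = scale / max(elapsed_h, 1 / 60))
}

#' Classify a cascade as radiation, sector or viral
#'
#' Structural typology of dissemination networks:
#' \itemize{
#'   \item \strong{radiation} — the first forwarding level is at least as
#'     wide as every deeper level (star-dominated spread straight from
#'     the original poster); depth-1 cascades and width ties fall here.
#'   \item Otherwise a deeper level is the widest, meaning secondary hubs
#'     carried the spread. The repost node with the largest engagement
#'     (the larger of its forwards and likes; ties broken by larger
#'     forwards, then earlier timestamp, then id) is the pivot:
#'     \strong{sector} when it drew at least as many forwards as likes,
#'     \strong{viral} when likes dominate.
#'   \item \strong{undisseminated} — no reposts at all.
#' }
#'
#' @param tree An `rc_tree`.
#' @return One-row tibble: `post_id`, `net_type`, `level1_width`,
#'   `max_other_width`, `pivot_node`, `pivot_forwards`, `pivot_likes`.
#' @export
classify_network <- function(tree) {
  stopifnot(inherits(tree, "rc_tree"))
  w <- level_widths(tree)
  empty <- tibble::tibble(
    post_id = tree$root_id, net_type = "undisseminated",
    level1_width = 0L, max_other_width = 0L, pivot_node = NA_character_,
    pivot_forwards = NA_real_, pivot_likes = NA_real_)
  if (length(w) == 0) return(empty)
  w1 <- w[1]
  w_other <- if (length(w) > 1) max(w[-1]) else 0L
  if (w1 >= w_other) {
    return(dplyr::mutate(empty, net_type = "radiation",
                         level1_width = as.integer(w1),
                         max_other_width = as.integer(w_other)))
  }
  reps <- tree$nodes[tree$nodes$level >= 1L, , drop = FALSE]
  score <- pmax(reps$forwards, reps$likes)
  ord <- order(-score, -reps$forwards, reps$timestamp, reps$id)
  pivot <- reps[ord[1], , drop = FALSE]
  tibble::tibble(
    post_id = tree$root_id,
    net_type = if (pivot$forwards >= pivot$likes) "sector" else "viral",
    level1_width = as.integer(w1),
    max_other_width = as.integer(w_other),
    pivot_node = pivot$id,
    pivot_forwards = pivot$forwards,
    pivot_likes = pivot$likes)
}

#' Parse, build and measure every cascade in a dataset
#'
#' Runs the full per-post chain: parse chain texts, resolve forwarding
#' relationships, build each post's dissemination tree, compute metrics
#' and classify structure.
#'
#' @param d An `rc_dataset`.
#' @param separator Chain delimiter.
#' @return List with `metrics` (one row per post: metrics + `net_type` +
#'   typology diagnostics), `trees` (named list of `rc_tree`), `parsed`,
#'   `edges` and `orphans` tibbles.
#' @export
cascade_analysis <- function(d, separator = "//") {
  stopifnot(inherits(d, "rc_dataset"))
  parsed <- parse_chains(d$reposts, separator)
  res <- resolve_parents(parsed)
  trees <- lapply(seq_len(nrow(d$posts)), function(i) {
    build_tree(d$posts[i, ], res$edges, parsed)
  })
  names(trees) <- d$posts$post_id
  metrics <- dplyr::bind_rows(lapply(trees, compute_metrics))
  types <- dplyr::bind_rows(lapply(trees, classify_network))
  metrics <- dplyr::left_join(metrics, types, by = "post_id")
  list(metrics = metrics, trees = trees, parsed = parsed,
       edges = res$edges, orphans = res$orphans)
}

#' A small worked-example cascade
#'
#' A nine-node demonstration cascade: root post A is forwarded by B1, B2
#' and B3; B1 is forwarded by C1, C2 and C3, B3 by C4, and C3 by D1. Its
#' metrics are scale 8, depth 3, maximum width 4 (the second forwarding
#' level). The repost records carry raw `"//"` chain texts, so the
#' example exercises the full parse-resolve-build path.
#'
#' @return An `rc_dataset` with one post, nine users and eight reposts.
#' @export
toy_cascade <- function() {
  t0 <- "2020-02-01T10:00"
  posts <- tibble::tibble(
    post_id = "A", author_id = "uA", timestamp = t0,
    text = "original claim", topic = "medical_information",
    forwards = 8, comments = 2, likes = 10, sentiment = 0.4)
  mk <- function(id, reposter, time, chain, fwd = 0, lik = 0) {
    tibble::tibble(repost_id = id, root_post_id = "A", reposter_id = reposter,
                   timestamp = time, chain_text = chain,
                   forwards = fwd, likes = lik)
  }
  reposts <- dplyr::bind_rows(
    mk("B1", "uB1", "2020-02-01T10:05", "look at this", fwd = 3, lik = 0),
    mk("B2", "uB2", "2020-02-01T10:06", "seen this?"),
    mk("B3", "uB3", "2020-02-01T10:07", "fwd", fwd = 1),
    mk("C1", "uC1", "2020-02-01T10:15", "agree//@uB1: look at this"),
    mk("C2", "uC2", "2020-02-01T10:16", "hm//@uB1: look at this"),
    mk("C3", "uC3", "2020-02-01T10:17", "really?//@uB1: look at this", fwd = 1),
    mk("C4", "uC4", "2020-02-01T10:18", "wow//@uB3: fwd"),
    mk("D1", "uD1", "2020-02-01T10:30",
       "doubt it//@uC3: really?//@uB1: look at this"))
  users <- tibble::tibble(
    user_id = c("uA", "uB1", "uB2", "uB3", "uC1", "uC2", "uC3", "uC4", "uD1"),
    verified = c(TRUE, rep(FALSE, 8)),
    verification_type = c("media", rep("none", 8)),
    mrank = c(5, rep(1, 8)), urank = c(40, rep(10, 8)),
    posts_count = 100, followers_count = c(50000, rep(100, 8)),
    following_count = 50)
  rc_dataset(posts, users, reposts, quiet = TRUE)
}
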