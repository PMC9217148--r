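#' Extract the forwarding level from repost chain text
#'
#' On the platform, a repost's content accumulates the comments of every
#' forward along its path, newest first, separated by `"//"`; each
#' `"@handle: "`-prefixed segment was contributed by one forwarder. The
#' number of segments is therefore the forwarding level: a direct repost
#' of the root carries a single segment (its own comment, possibly
#' empty), a repost of a repost carries two, and so on.
#'
#' @param chain_text Character vector of raw repost contents.
#' @param separator Chain delimiter, `"//"` by convention.
#' @return Integer vector of forwarding levels (root post = level 0, so
#'   every repost has level >= 1).
#' @examples
#' extract_level("nice point")                      # 1
#' extract_level("agree//@userB: nice point")       # 2
#' extract_level("wow//@B: agree//@C: nice point")  # 3
#' @export
extract_level <- function(chain_text, separator = "//") {
  chain_text <- as.character(chain_text)
  chain_text[is.na(chain_text)] <- ""
  n_sep <- vapply(
    gregexpr(separator, chain_text, fixed = TRUE),
    function(m) if (m[1] == -1L) 0L else length(m), integer(1))
  n_sep + 1L
}

chain_segments <- function(chain_text, separator = "//") {
  chain_text <- as.character(chain_text)
  chain_text[is.na(chain_text)] <- ""
  lapply(strsplit(paste0(chain_text, "\x01"), separator, fixed = TRUE),
         function(s) { s[length(s)] <- sub("\x01$", "", s[length(s)]); trimws(s) })
}

# Leading "@handle:" mention of a segment; NA when the segment has none.
segment_handle <- function(segment) {
  m <- regmatches(segment, regexpr("^@[^:]+:", segment))
  out <- rep(NA_character_, length(segment))
  has <- grepl("^@[^:]+:", segment)
  out[has] <- sub("^@([^:]+):.*$", "\\1", segment[has])
  out
}

#' Parse repost chain texts into levels and parent handles
#'
#' Splits each repost's `chain_text` on the separator, derives the
#' forwarding level (= number of segments), and extracts the handle
#' mentioned at the head of the second segment, which names the user
#' whose repost was forwarded (the parent for level >= 2 records).
#'
#' @param reposts Repost tibble (as in an `rc_dataset`).
#' @param separator Chain delimiter.
#' @return Tibble with one row per repost: `repost_id`, `root_post_id`,
#'   `reposter_id`, `timestamp`, `level`, `parent_handle` (`NA` for
#'   level-1 records), `segments` (list column, newest first),
#'   `forwards`, `likes`.
#' @export
parse_chains <- function(reposts, separator = "//") {
  segs <- chain_segments(reposts$chain_text, separator)
  level <- lengths(segs)
  parent_handle <- vapply(segs, function(s) {
    if (length(s) < 2) NA_character_ else segment_handle(s[2])
  }, character(1))
  tibble::tibble(
    repost_id = reposts$repost_id,
    root_post_id = reposts$root_post_id,
    reposter_id = reposts$reposter_id,
    timestamp = reposts$timestamp,
    level = as.integer(level),
    parent_handle = parent_handle,
    segments = segs,
    forwards = reposts$forwards,
    likes = reposts$likes)
}

#' Resolve parent-child forwarding relationships
#'
#' Attaches every level-1 repost to its root post and every level-k
#' repost (k > 1) to the level-(k-1) repost of the same cascade whose
#' reposter handle matches the leading `@handle:` mention of its second
#' chain segment. Handle matching is case-sensitive and exact. When two
#' candidate parents share handle and level, the one with the nearest
#' earlier timestamp wins; remaining ties go to the smallest `repost_id`.
#'
#' Records whose parent cannot be found (the intermediate repost was
#' deleted or blocked before capture) are dropped as orphans and counted,
#' never re-attached to the root: re-attachment would deflate depth and
#' inflate first-level width, biasing the structural classification.
#' Children of orphans are orphans too.
#'
#' @param parsed Output of [parse_chains()]; may span several root posts.
#' @return List with `edges` (tibble `root_post_id`, `parent_id`,
#'   `child_id`, `level` of the child) and `orphans` (tibble `repost_id`,
#'   `root_post_id`, `reason`). `nrow(edges) + nrow(orphans)` equals the
#'   number of input records.
#' @export
resolve_parents <- function(parsed) {
  pieces <- split(seq_len(nrow(parsed)), parsed$root_post_id)
  edges <- list(); orphans <- list()
  for (root in names(pieces)) {
    res <- resolve_one_root(parsed[pieces[[root]], , drop = FALSE], root)
    edges[[root]] <- res$edges
    orphans[[root]] <- res$orphans
  }
  edges <- dplyr::bind_rows(edges)
  orphans <- dplyr::bind_rows(orphans)
  if (nrow(orphans) > 0) {
    warn(sprintf("resolve_parents: dropped %d orphan repost(s) with unresolvable parents",
                 nrow(orphans)))
  }
  list(
    edges = if (nrow(edges) > 0) edges else
      tibble::tibble(root_post_id = character(0), parent_id = character(0),
                     child_id = character(0), level = integer(0)),
    orphans = if (nrow(orphans) > 0) orphans else
      tibble::tibble(repost_id = character(0), root_post_id = character(0),
                     reason = character(0)))
}

resolve_one_root <- function(p, root) {
  p <- p[order(p$level, p$timestamp, p$repost_id), , drop = FALSE]
  resolved <- character(0)           # repost_ids attached so far
  edges <- vector("list", nrow(p)); orphans <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    lev <- p$level[i]
    if (lev == 1L) {
      edges[[i]] <- tibble::tibble(root_post_id = root, parent_id = root,
                                   child_id = p$repost_id[i], level = 1L)
      resolved <- c(resolved, p$repost_id[i])
      next
    }
    cand <- which(p$level == lev - 1L &
                    p$reposter_id == p$parent_handle[i] &
                    p$repost_id %in% resolved)
    if (length(cand) == 0) {
      orphans[[i]] <- tibble::tibble(
        repost_id = p$repost_id[i], root_post_id = root,
        reason = if (is.na(p$parent_handle[i]))
          "no parent mention in chain text" else
          sprintf("no resolved level-%d repost by @%s", lev - 1L, p$parent_handle[i]))
      next
    }
    if (length(cand) > 1) {
      earlier <- cand[p$timestamp[cand] <= p$timestamp[i]]
      pool <- if (length(earlier) > 0) earlier else cand
      best_t <- max(p$timestamp[pool])
      pool <- pool[p$timestamp[pool] == best_t]
      cand <- pool[order(p$repost_id[pool])][1]
    }
    edges[[i]] <- tibble::tibble(root_post_id = root,
                                 parent_id = p$repost_id[cand],
                                 child_id = p$repost_id[i], level = lev)
    resolved <- c(resolved, p$repost_id[i])
  }
  list(edges = dplyr::bind_rows(edges), orphans = dplyr::bind_rows(orphans))
}
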