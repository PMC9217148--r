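# Shared fixtures: build small cascade datasets from an explicit parent map,
# deriving the "//" chain texts independently of the package's generator.

minutes <- function(m) as.difftime(m, units = "mins")

# nodes: tibble(id, parent, reposter, minutes_after_root, forwards, likes);
# parent == "ROOT" attaches to the root post. Chain texts are assembled
# recursively: own comment, then "@<parent reposter>: <parent chain>".
dataset_from_parents <- function(nodes, root_id = "P", root_author = "uROOT",
                                 root_time = "2020-02-01T09:00",
                                 root_forwards = 0, root_likes = 0) {
  comment <- setNames(paste0("c_", nodes$id), nodes$id)
  chain <- function(id) {
    i <- match(id, nodes$id)
    if (nodes$parent[i] == "ROOT") return(comment[[id]])
    p <- nodes$parent[i]
    paste0(comment[[id]], "//@", nodes$reposter[match(p, nodes$id)], ": ",
           chain(p))
  }
  t0 <- as.POSIXct(root_time, format = "%Y-%m-%dT%H:%M", tz = "UTC")
  reposts <- tibble::tibble(
    repost_id = nodes$id,
    root_post_id = root_id,
    reposter_id = nodes$reposter,
    timestamp = t0 + minutes(nodes$minutes_after_root),
    chain_text = vapply(nodes$id, chain, character(1)),
    forwards = nodes$forwards,
    likes = nodes$likes)
  posts <- tibble::tibble(
    post_id = root_id, author_id = root_author, timestamp = root_time,
    text = "root claim", topic = "medical_information",
    forwards = nrow(nodes), comments = 0, likes = root_likes,
    sentiment = 0.5)
  users <- tibble::tibble(
    user_id = unique(c(root_author, nodes$reposter)),
    verified = FALSE, verification_type = "none", mrank = 1, urank = 10,
    posts_count = 10, followers_count = 100, following_count = 10)
  rc_dataset(posts, users, reposts, quiet = TRUE)
}

# The nine-node worked example: root P; B1,B2,B3 forward P; C1,C2,C3
# forward B1; C4 forwards B3; D1 forwards C3.
nine_node_nodes <- function() {
  tibble::tibble(
    id       = c("B1", "B2", "B3", "C1", "C2", "C3", "C4", "D1"),
    parent   = c("ROOT", "ROOT", "ROOT", "B1", "B1", "B1", "B3", "C3"),
    reposter = c("uB1", "uB2", "uB3", "uC1", "uC2", "uC3", "uC4", "uD1"),
    minutes_after_root = c(5, 6, 7, 15, 16, 17, 18, 30),
    forwards = c(3, 0, 1, 0, 0, 1, 0, 0),
    likes    = c(0, 0, 0, 0, 0, 0, 0, 0))
}

# Balanced k-ary cascade of depth d as a parent map.
kary_nodes <- function(k, d) {
  rows <- list(); counter <- 0
  grow <- function(parent, level) {
    if (level > d) return(invisible(NULL))
    for (j in seq_len(k)) {
      counter <<- counter + 1
      id <- sprintf("n%04d", counter)
      rows[[length(rows) + 1]] <<- tibble::tibble(
        id = id, parent = parent, reposter = paste0("u", id),
        minutes_after_root = level * 10 + j, forwards = 0, likes = 0)
      grow(id, level + 1)
    }
  }
  grow("ROOT", 1)
  dplyr::bind_rows(rows)
}

tree_from_dataset <- function(d, ...) {
  cas <- cascade_analysis(d, ...)
  cas$trees[[1]]
}

# Independent Spearman oracle: midranks by explicit counting, then the
# Pearson product-moment formula written out in sums.
brute_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Minimal valid single-post tables for I/O tests.
tiny_tables <- function() {
  list(
    posts = tibble::tibble(
      post_id = "p1", author_id = "u1", timestamp = "2020-03-01T08:30",
      text = "hello, with comma", topic = "epidemic_spread",
      forwards = 2, comments = 1, likes = 5, sentiment = 0.7),
    users = tibble::tibble(
      user_id = "u1", verified = TRUE, verification_type = "media",
      mrank = 3, urank = 20, posts_count = 11, followers_count = 1000,
      following_count = 50),
    reposts = tibble::tibble(
      repost_id = "r1", root_post_id = "p1", reposter_id = "u1",
      timestamp = "2020-03-01T09:00",
      chain_text = "agree, strongly//@u1: hello, with comma",
      forwards = 0, likes = 1))
}

small_cfg <- function(seed = 42, ...) {
  sim_config(seed = seed, n_users = 400, n_posts = 60, ...)
}

# Five equally mixed archetypes at pairwise-equidistant centroids (one-hot
# offsets, >= 5 within-cluster SDs apart), for k-selection recovery tests.
equidistant_cfg <- function(seed, n_users = 1500) {
  base <- c(10, 1, 3, 3, 3)
  delta <- c(15, 5, 4, 4, 4)
  cents <- lapply(1:5, function(j) {
    m <- base; m[j] <- m[j] + delta[j]
    list(mean = m, sd = c(1.5, 0.4, 0.35, 0.35, 0.35))
  })
  names(cents) <- c("general", "platform", "inactive", "influential", "mingler")
  sim_config(seed = seed, n_users = n_users,
             archetype_mix = c(general = 0.2, platform = 0.2, inactive = 0.2,
                               influential = 0.2, mingler = 0.2),
             archetype_centroids = cents)
}
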