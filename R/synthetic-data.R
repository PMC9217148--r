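#' Simulation configuration
#'
#' Parameters of the synthetic microblog corpus generator. Defaults
#' emulate the statistical structure the pipeline assumes on real data:
#' five user archetypes with well-separated authority profiles and
#' heavy-tailed (lognormal) counts, a topic mix dominated by medical
#' misinformation, level-dependent branching cascades in three
#' structural regimes (a radiation-dominated mix), overdispersed
#' negative-binomial engagement with likes far exceeding forwards on
#' average, and exponential inter-repost waiting times.
#'
#' @param seed Integer seed; fully determines the output.
#' @param n_users Number of users.
#' @param n_posts Number of original posts.
#' @param archetype_mix Named proportions over the five archetypes
#'   (general, platform, inactive, influential, mingler); must sum to 1.
#' @param archetype_centroids List per archetype: `mean` and `sd`
#'   vectors over (urank, mrank, log_posts, log_followers,
#'   log_following); count features are on the natural-log scale.
#' @param topic_mix Named proportions over the five topics; sums to 1.
#' @param regime_mix Proportions over the structural regimes
#'   (radiation, sector, viral); sums to 1.
#' @param branching Per-regime vectors of level-dependent mean offspring
#'   counts \eqn{\lambda_1..\lambda_L}; level-k nodes spawn
#'   Poisson(\eqn{\lambda_{k+1}}) children, zero beyond L.
#' @param hub_lambda Mean offspring of the planted secondary hub in the
#'   sector/viral regimes (one level-1 node with inflated branching).
#' @param followers_ref Reference follower count: the root author's
#'   follower count scales the level-1 branching rate by
#'   `log1p(followers)/log1p(followers_ref)`, planting a positive
#'   scale-followers rank correlation.
#' @param engagement Named list of negative-binomial means/sizes for
#'   post-level forwards/comments/likes and repost-level engagement,
#'   plus the planted hub engagement levels.
#' @param wait_mean Mean of the exponential inter-repost waiting time,
#'   in hours.
#' @param start Corpus start time (ISO-8601); root posts spread
#'   uniformly over `n_weeks` ISO weeks from here.
#' @param n_weeks Length of the posting window in weeks.
#' @param max_nodes Cascade size cap; larger cascades are truncated and
#'   flagged.
#' @return A list of class `rc_sim_config`.
#' @export
sim_config <- function(
    seed = 42,
    n_users = 2000,
    n_posts = 300,
    archetype_mix = c(general = 2342, platform = 2980, inactive = 5652,
                      influential = 101, mingler = 226) / 11301,
    archetype_centroids = default_archetype_centroids(),
    topic_mix = c(government_response = 0.0892, epidemic_spread = 0.0558,
                  medical_information = 0.4680, social_livelihood = 0.3609,
                  international_issues = 0.0261),
    regime_mix = c(radiation = 0.97, sector = 0.01, viral = 0.02),
    branching = list(radiation = c(8, 0.2, 0.1),
                     sector = c(2, 0.8, 0.5, 0.3),
                     viral = c(2, 0.8, 0.5, 0.3)),
    hub_lambda = 8,
    followers_ref = 250,
    engagement = list(
      post = list(forwards_mu = 11, comments_mu = 13, likes_mu = 189,
                  size = 0.4),
      repost = list(mu = 1, size = 0.5),
      hub = list(major = 60, minor = 5)),
    wait_mean = 0.5,
    start = "2020-01-06T00:00",
    n_weeks = 10,
    max_nodes = 1e5) {
  stopifnot(abs(sum(archetype_mix) - 1) < 1e-8,
            abs(sum(topic_mix) - 1) < 1e-8,
            abs(sum(regime_mix) - 1) < 1e-8,
            all(unlist(branching) >= 0))
  structure(as.list(environment()), class = "rc_sim_config")
}

#' @rdname sim_config
#' @export
default_archetype_centroids <- function() {
  # (urank, mrank, log_posts, log_followers, log_following)
  list(
    general     = list(mean = c(30, 1, 5.0, 5.5, 5.5),
                       sd   = c(2.0, 0.4, 0.35, 0.35, 0.35)),
    platform    = list(mean = c(30, 6, 5.0, 5.5, 5.5),
                       sd   = c(2.0, 0.4, 0.35, 0.35, 0.35)),
    inactive    = list(mean = c(5, 0.3, 1.5, 2.0, 2.0),
                       sd   = c(1.5, 0.3, 0.35, 0.35, 0.35)),
    influential = list(mean = c(45, 6.8, 9.0, 11.0, 6.0),
                       sd   = c(1.2, 0.2, 0.35, 0.35, 0.35)),
    mingler     = list(mean = c(20, 3, 2.0, 10.0, 7.0),
                       sd   = c(1.5, 0.4, 0.35, 0.35, 0.35)))
}

rtrunc_round <- function(n, mean, sd, lo, hi) {
  pmin(pmax(round(rnorm(n, mean, sd)), lo), hi)
}

simulate_users_impl <- function(cfg) {
  arch <- sample(names(cfg$archetype_mix), cfg$n_users, replace = TRUE,
                 prob = cfg$archetype_mix)
  ids <- sprintf("u%05d", seq_len(cfg$n_users))
  rows <- lapply(seq_len(cfg$n_users), function(i) {
    c0 <- cfg$archetype_centroids[[arch[i]]]
    tibble::tibble(
      user_id = ids[i],
      verified = arch[i] == "influential" || runif(1) < 0.05,
      verification_type = if (arch[i] == "influential")
        sample(c("media", "government"), 1) else
          sample(c("none", "personal", "business"),
                 1, prob = c(0.9, 0.08, 0.02)),
      mrank = rtrunc_round(1, c0$mean[2], c0$sd[2], 0, 7),
      urank = rtrunc_round(1, c0$mean[1], c0$sd[1], 0, 48),
      posts_count = round(rlnorm(1, c0$mean[3], c0$sd[3])),
      followers_count = round(rlnorm(1, c0$mean[4], c0$sd[4])),
      following_count = round(rlnorm(1, c0$mean[5], c0$sd[5])))
  })
  list(users = dplyr::bind_rows(rows),
       truth = tibble::tibble(user_id = ids, archetype = arch))
}

#' Simulate users with planted archetypes
#'
#' Draws `n_users` users from the archetype mixture; authority counts
#' are lognormal around the archetype centroid, levels truncated
#' Gaussian. The true archetype labels are returned separately so that
#' clustering-recovery tests never leak them into the dataset.
#'
#' @param cfg An `rc_sim_config`.
#' @return List: `users` tibble, `truth` tibble (`user_id`, `archetype`).
#' @export
simulate_users <- function(cfg) {
  set.seed(cfg$seed)
  simulate_users_impl(cfg)
}

# One branching-process cascade. Reposter ids are drawn without
# replacement from `pool`, so each user forwards a given post at most
# once and handle-based parent resolution is exact.
simulate_cascade_impl <- function(cfg, regime, root_post_id, root_time,
                                  root_followers, pool, id_prefix) {
  lambda <- cfg$branching[[regime]]
  scale1 <- if (sum(lambda) == 0) 1 else
    log1p(root_followers) / log1p(cfg$followers_ref)
  lam1 <- if (length(lambda) >= 1) lambda[1] * scale1 else 0
  n1 <- rpois(1, lam1)
  if (regime != "radiation" && lam1 > 0) n1 <- max(n1, 1L)
  n1 <- min(n1, length(pool), cfg$max_nodes)
  truncated <- FALSE
  if (n1 == 0) {
    return(list(reposts = NULL, edges = NULL, truncated = FALSE))
  }

  rmu <- cfg$engagement$repost
  new_node <- function(k, idx, reposter, parent_id, parent_time,
                       parent_chain, parent_reposter) {
    ts <- floor_minute(parent_time + rexp(1, 1 / cfg$wait_mean) * 3600)
    comment <- paste0("fwd ", idx)
    chain <- if (k == 1) comment else
      paste0(comment, "//@", parent_reposter, ": ", parent_chain)
    tibble::tibble(
      repost_id = paste0(id_prefix, idx),
      root_post_id = root_post_id, reposter_id = reposter,
      timestamp = ts, chain_text = chain,
      forwards = rnbinom(1, size = rmu$size, mu = rmu$mu),
      likes = rnbinom(1, size = rmu$size, mu = rmu$mu),
      parent_repost_id = if (k == 1) NA_character_ else parent_id,
      level = k)
  }

  idx <- 0L
  used <- 0L
  nodes <- list()
  frontier <- list()  # each: list(id, reposter, time, chain)
  for (j in seq_len(n1)) {
    idx <- idx + 1L; used <- used + 1L
    nd <- new_node(1L, idx, pool[used], NA, root_time, NA, NA)
    nodes[[idx]] <- nd
    frontier[[j]] <- list(id = nd$repost_id, reposter = nd$reposter_id,
                          time = nd$timestamp, chain = nd$chain_text,
                          level = 1L, is_hub = FALSE)
  }
  hub_pos <- NA_integer_
  if (regime != "radiation") {
    hub_pos <- 1L
    frontier[[1]]$is_hub <- TRUE
    hub_id <- frontier[[1]]$id
    eng <- cfg$engagement$hub
    major <- eng$minor + 1 + rpois(1, eng$major)
    minor <- rpois(1, eng$minor)
    i_hub <- which(vapply(nodes, function(n) n$repost_id, "") == hub_id)
    if (regime == "sector") {
      nodes[[i_hub]]$forwards <- major; nodes[[i_hub]]$likes <- minor
    } else {
      nodes[[i_hub]]$likes <- major; nodes[[i_hub]]$forwards <- minor
    }
  }

  while (length(frontier) > 0 && used < length(pool) && idx < cfg$max_nodes) {
    nxt <- list()
    for (f in frontier) {
      k <- f$level + 1L
      lam <- if (k <= length(lambda)) lambda[k] else 0
      if (f$is_hub && k == 2L) lam <- lam + cfg$hub_lambda
      n_kids <- rpois(1, lam)
      if (n_kids == 0) next
      for (j in seq_len(n_kids)) {
        if (used >= length(pool) || idx >= cfg$max_nodes) {
          truncated <- TRUE
          break
        }
        idx <- idx + 1L; used <- used + 1L
        nd <- new_node(k, idx, pool[used], f$id, f$time, f$chain, f$reposter)
        nodes[[idx]] <- nd
        nxt[[length(nxt) + 1L]] <- list(
          id = nd$repost_id, reposter = nd$reposter_id, time = nd$timestamp,
          chain = nd$chain_text, level = k, is_hub = FALSE)
      }
    }
    frontier <- nxt
  }

  reposts <- dplyr::bind_rows(nodes)
  edges <- tibble::tibble(
    root_post_id = root_post_id,
    parent_id = ifelse(is.na(reposts$parent_repost_id), root_post_id,
                       reposts$parent_repost_id),
    child_id = reposts$repost_id,
    level = reposts$level)
  list(reposts = dplyr::select(reposts, -"level"), edges = edges,
       truncated = truncated)
}

#' Simulate one repost cascade
#'
#' Generates a level-dependent Galton-Watson cascade in the requested
#' structural regime, with raw `"//"` chain texts built so that the
#' chain parser recovers the true tree exactly. In the radiation regime
#' the level-1 branching rate dwarfs deeper rates; sector and viral
#' regimes plant a secondary hub — one level-1 node with inflated
#' offspring — whose engagement favours forwards (sector) or likes
#' (viral).
#'
#' @param cfg An `rc_sim_config`.
#' @param regime One of `"radiation"`, `"sector"`, `"viral"`.
#' @param root_post_id Id for the root post.
#' @param root_time Root POSIXct timestamp (minute resolution).
#' @param root_followers Root author's follower count (drives the
#'   level-1 rate).
#' @param pool Character vector of candidate reposter ids (sampled
#'   without replacement).
#' @param id_prefix Prefix for generated repost ids.
#' @return List: `reposts` tibble (with `chain_text` and
#'   `parent_repost_id` ground truth), `edges` (true tree), `truncated`.
#' @export
simulate_cascade <- function(cfg, regime, root_post_id = "p1",
                             root_time = parse_rc_time(cfg$start),
                             root_followers = cfg$followers_ref,
                             pool = sprintf("u%05d", seq_len(cfg$n_users)),
                             id_prefix = paste0(root_post_id, "r")) {
  regime <- match.arg(regime, names(cfg$regime_mix))
  simulate_cascade_impl(cfg, regime, root_post_id, root_time,
                        root_followers, sample(pool), id_prefix)
}

# Archetype-dependent topic propensities: each archetype tilts the base
# topic mix toward one pet topic (renormalised).
topic_propensities <- function(cfg) {
  tilt <- c(general = "social_livelihood", platform = "medical_information",
            inactive = "medical_information",
            influential = "international_issues",
            mingler = "government_response")
  out <- lapply(names(cfg$archetype_mix), function(a) {
    p <- cfg$topic_mix
    p[tilt[[a]]] <- p[tilt[[a]]] * 2
    p / sum(p)
  })
  names(out) <- names(cfg$archetype_mix)
  out
}

#' Simulate a full synthetic corpus
#'
#' Generates users, posts and repost cascades as a validated
#' [rc_dataset()], plus truth tables (planted archetypes, cascade
#' regimes, true forwarding edges) kept separate from the dataset so
#' pipeline code cannot peek. Post authors are drawn from the user pool;
#' topics follow archetype-dependent propensities; each post's cascade
#' regime follows `regime_mix`, and the root author's follower count
#' scales the level-1 branching rate, planting a positive rank
#' correlation between follower count and dissemination scale. The
#' post's recorded `forwards` count equals its cascade's scale.
#'
#' @param cfg An `rc_sim_config`.
#' @return List: `dataset` (an `rc_dataset`), `truth` (list with
#'   `archetypes`, `regimes`, `edges`, `truncated`).
#' @export
simulate_dataset <- function(cfg) {
  set.seed(cfg$seed)
  u <- simulate_users_impl(cfg)
  users <- u$users
  prop <- topic_propensities(cfg)
  t0 <- parse_rc_time(cfg$start)

  authors <- sample(users$user_id, cfg$n_posts, replace = TRUE)
  arch <- u$truth$archetype[match(authors, u$truth$user_id)]
  regimes <- sample(names(cfg$regime_mix), cfg$n_posts, replace = TRUE,
                    prob = cfg$regime_mix)
  eng <- cfg$engagement$post
  posts <- tibble::tibble(
    post_id = sprintf("p%04d", seq_len(cfg$n_posts)),
    author_id = authors,
    timestamp = floor_minute(t0 + runif(cfg$n_posts) * cfg$n_weeks * 7 * 24 * 3600),
    text = paste("claim", seq_len(cfg$n_posts)),
    topic = vapply(arch, function(a)
      sample(names(cfg$topic_mix), 1, prob = prop[[a]]), character(1)),
    forwards = 0,
    comments = rnbinom(cfg$n_posts, size = eng$size, mu = eng$comments_mu),
    likes = rnbinom(cfg$n_posts, size = eng$size, mu = eng$likes_mu),
    sentiment = rbeta(cfg$n_posts, 2, 2))

  reposts <- list(); edges <- list(); truncated <- logical(cfg$n_posts)
  for (i in seq_len(cfg$n_posts)) {
    followers <- users$followers_count[match(authors[i], users$user_id)]
    pool <- sample(setdiff(users$user_id, authors[i]))
    cas <- simulate_cascade_impl(cfg, regimes[i], posts$post_id[i],
                                 posts$timestamp[i], followers, pool,
                                 paste0(posts$post_id[i], "r"))
    truncated[i] <- cas$truncated
    if (!is.null(cas$reposts)) {
      reposts[[i]] <- cas$reposts
      edges[[i]] <- cas$edges
      posts$forwards[i] <- nrow(cas$reposts)
    }
  }
  reposts <- dplyr::bind_rows(reposts)
  dataset <- rc_dataset(posts, users,
                        if (nrow(reposts) > 0) reposts else NULL,
                        quiet = TRUE)
  list(dataset = dataset,
       truth = list(
         archetypes = u$truth,
         regimes = tibble::tibble(post_id = posts$post_id, regime = regimes,
                                  truncated = truncated),
         edges = dplyr::bind_rows(edges)))
}
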