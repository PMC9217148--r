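test_that("spearman matches the brute-force midrank oracle to 1e-12", {
  # hand-picked cases
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$rho, 1)
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  expect_equal(spearman_cor(x, y)$rho, brute_spearman(x, y), tolerance = 1e-12)
  # random inputs, with and without ties
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    xs <- sample(1:8, n, replace = TRUE)   # heavy ties
    ys <- rnorm(n)
    got <- spearman_cor(xs, ys)
    expect_equal(got$rho, brute_spearman(xs, ys), tolerance = 1e-12)
    # agrees with the standard library estimate
    expect_equal(got$rho, unname(cor(xs, ys, method = "spearman")),
                 tolerance = 1e-12)
  }
})

test_that("spearman is invariant under monotone transforms and NA on constants", {
  set.seed(6)
  x <- rnorm(30)
  y <- rnorm(30)
  expect_equal(spearman_cor(x, exp(y))$rho, spearman_cor(x, y)$rho)
  expect_true(is.na(spearman_cor(rep(1, 10), rnorm(10))$rho))
  expect_true(is.na(spearman_cor(c(1, 2), c(3, 4))$rho))  # n < 3
})

test_that("the correlation grid detects the planted scale-followers link", {
  sim <- simulate_dataset(sim_config(seed = 121, n_users = 1500, n_posts = 500))
  cas <- cascade_analysis(sim$dataset)
  grid <- correlation_matrix(cas$metrics, sim$dataset$posts, sim$dataset$users)
  expect_equal(nrow(grid), 25)
  cell <- grid[grid$topology == "scale" & grid$feature == "followers_count", ]
  expect_gt(cell$rho, 0)
  expect_lt(cell$p_value, 0.05)
  # per-cell n is reported and bounded by the number of cascades
  expect_true(all(grid$n <= nrow(cas$metrics)))
})

test_that("cells with fewer than three complete cases are missing", {
  metrics <- tibble::tibble(post_id = c("p1", "p2"), scale = c(1, 2),
                            depth = c(1, 1), max_width = c(1, 2),
                            avg_width = c(1, 2), speed = c(NA_real_, NA_real_))
  posts <- tibble::tibble(post_id = c("p1", "p2"), author_id = c("u1", "u2"))
  users <- tibble::tibble(user_id = c("u1", "u2"), urank = c(1, 2),
                          mrank = c(1, 2), posts_count = c(1, 2),
                          followers_count = c(1, 2), following_count = c(1, 2))
  grid <- correlation_matrix(metrics, posts, users)
  expect_true(all(is.na(grid$rho)))
  expect_true(all(grid$n[grid$topology == "speed"] == 0))
})

test_that("group summaries match the hand-computed t interval", {
  df <- tibble::tibble(g = c("a", "a", "a", "b"), v = c(1, 2, 3, 9))
  out <- group_summary(df, values = "v", group = "g")
  a <- out[out$group == "a", ]
  expect_equal(a$mean, 2)
  expect_equal(a$sd, 1)
  expect_equal(a$ci_upper - a$mean, qt(0.975, 2) * 1 / sqrt(3))
  expect_equal(a$ci_upper - a$mean, 2.484, tolerance = 1e-3)
  # single-row group: no interval; identical values: zero-width interval
  b <- out[out$group == "b", ]
  expect_true(is.na(b$ci_lower))
  same <- group_summary(tibble::tibble(g = "c", v = c(4, 4, 4)), "v", "g")
  expect_equal(same$ci_lower, same$ci_upper)
  expect_equal(same$sd, 0)
})

test_that("t intervals cover the planted branching-process mean scale", {
  # radiation regime with fixed level-1 rate: E[scale] = 5 + 5*0.2 = 6
  cfg <- sim_config(seed = 131, n_users = 4000,
                    branching = list(radiation = c(5, 0.2),
                                     sector = c(2, 0.8), viral = c(2, 0.8)))
  mu <- 5 + 5 * 0.2
  set.seed(131)
  pool <- sprintf("u%05d", seq_len(cfg$n_users))
  covered <- replicate(150, {
    scales <- replicate(60, {
      cas <- simulate_cascade(cfg, "radiation", pool = pool)
      if (is.null(cas$reposts)) 0L else nrow(cas$reposts)
    })
    ci <- group_summary(tibble::tibble(g = "r", v = scales), "v", "g")
    ci$ci_lower <= mu && mu <= ci$ci_upper
  })
  expect_gt(mean(covered), 0.875)
  expect_lt(mean(covered), 1)
})

test_that("weekly bins conserve totals and keep sentiment in range", {
  sim <- simulate_dataset(small_cfg(seed = 141))
  bins <- time_binned_aggregate(sim$dataset$posts)
  expect_equal(sum(bins$n), nrow(sim$dataset$posts))
  expect_true(all(bins$mean_sentiment >= 0 & bins$mean_sentiment <= 1))
  # bins are Monday-anchored
  expect_true(all(lubridate::wday(bins$bin, week_start = 1) == 1))
  # all posts in one week collapse to a single bin
  one_week <- dplyr::mutate(sim$dataset$posts,
                            timestamp = parse_rc_time("2020-03-04T12:00"))
  b1 <- time_binned_aggregate(one_week)
  expect_equal(length(unique(b1$bin)), 1)
  # without sentiment the aggregate is omitted
  no_sent <- dplyr::mutate(sim$dataset$posts, sentiment = NA_real_)
  expect_false("mean_sentiment" %in% names(time_binned_aggregate(no_sent)))
})

test_that("krippendorff alpha matches the coincidence-matrix oracle", {
  # perfect agreement is exactly 1
  perfect <- cbind(rep(c("A", "B"), 5), rep(c("A", "B"), 5))
  expect_equal(krippendorff_alpha(perfect)$alpha, 1)
  # 2 coders, items (A,A),(A,B),(B,B),(B,B): coincidences o_AA=2, o_AB=o_BA=1,
  # o_BB=4; D_o = 2/8, D_e = (8^2 - (3^2+5^2)) / (8*7) = 30/56; alpha = 8/15
  grid <- rbind(c("A", "A"), c("A", "B"), c("B", "B"), c("B", "B"))
  expect_equal(krippendorff_alpha(grid)$alpha, 8 / 15, tolerance = 1e-12)
  # systematic disagreement is negative: (A,B),(B,A) repeated
  swap <- rbind(c("A", "B"), c("B", "A"), c("A", "B"), c("B", "A"))
  expect_equal(krippendorff_alpha(swap)$alpha, 1 - 1 / (32 / 56),
               tolerance = 1e-12)
  expect_lt(krippendorff_alpha(swap)$alpha, 0)
})

test_that("alpha ignores category relabeling and single-coded items", {
  set.seed(7)
  grid <- matrix(sample(c("x", "y", "z"), 60, replace = TRUE), ncol = 3)
  relabeled <- matrix(c(x = "q", y = "r", z = "s")[grid], ncol = 3)
  expect_equal(krippendorff_alpha(grid)$alpha,
               krippendorff_alpha(relabeled)$alpha, tolerance = 1e-12)
  # items carrying one code are unpairable
  grid[1, 2:3] <- NA
  out <- krippendorff_alpha(grid)
  expect_equal(out$n_items, 19L)
  all_single <- cbind(c("A", "B"), c(NA, NA))
  expect_warning(undef <- krippendorff_alpha(all_single), "undefined")
  expect_true(is.na(undef$alpha))
})
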