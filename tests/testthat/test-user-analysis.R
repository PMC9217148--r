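test_that("standardisation z-scores features and log-transforms counts", {
  feats <- tibble::tibble(
    user_id = c("a", "b"), urank = c(10, 30), mrank = c(1, 3),
    posts_count = c(0, 100), followers_count = c(10, 1000),
    following_count = c(5, 500))
  x <- standardize_features(feats)
  expect_equal(colMeans(x), rep(0, 5), ignore_attr = TRUE)
  expect_equal(unname(apply(x, 2, sd)), rep(1, 5))
  # two users symmetric about the mean: z-scores are +/- the same value
  expect_equal(x[1, ], -x[2, ], ignore_attr = TRUE)
  # log1p(0) = 0 enters the transform for zero-count users
  expect_equal(attr(x, "center")[["posts_count"]],
               mean(log1p(c(0, 100))))
})

test_that("zero-variance features are dropped with a warning", {
  feats <- tibble::tibble(
    user_id = letters[1:4], urank = c(1, 2, 3, 4), mrank = 2,
    posts_count = c(1, 5, 9, 2), followers_count = c(1, 2, 3, 4),
    following_count = c(4, 3, 2, 1))
  expect_warning(x <- standardize_features(feats), "mrank")
  expect_false("mrank" %in% colnames(x))
  expect_equal(ncol(x), 4)
})

test_that("k-means is seed-deterministic and k < 2 is refused", {
  sim <- simulate_users(sim_config(seed = 71, n_users = 400))
  x <- standardize_features(authority_features(sim$users))
  f1 <- kmeans_cluster(x, 5, seed = 9)
  f2 <- kmeans_cluster(x, 5, seed = 9)
  expect_identical(f1$cluster, f2$cluster)
  expect_error(kmeans_cluster(x, 1, seed = 9), "at least 2")
})

test_that("the elbow criterion recovers planted cluster counts", {
  # five equally separated archetypes
  sim <- simulate_users(equidistant_cfg(seed = 81))
  x <- standardize_features(authority_features(sim$users))
  k5 <- choose_k(x, 2:8, seed = 3)
  expect_equal(as.integer(k5), 5L)
  diag5 <- attr(k5, "diagnostics")
  expect_true(all(c("wcss", "silhouette") %in% names(diag5)))
  expect_true(all(diff(diag5$wcss) < 1e-8))  # WCSS non-increasing in k

  # two separated blobs
  set.seed(82)
  blob <- rbind(matrix(rnorm(200, 0), ncol = 2),
                matrix(rnorm(200, 8), ncol = 2))
  colnames(blob) <- c("f1", "f2")
  k2 <- choose_k(scale(blob), 2:6, seed = 3)
  expect_equal(as.integer(k2), 2L)

  # identical points are degenerate
  same <- matrix(1, nrow = 10, ncol = 2)
  expect_error(choose_k(same, 2:4, seed = 3), "identical")
})

test_that("planted archetypes are recovered and named correctly", {
  skip_if_not_installed("mclust")
  sim <- simulate_users(sim_config(seed = 91, n_users = 1500))
  cl <- cluster_disseminators(sim$users, k = 5, seed = 7)
  j <- dplyr::inner_join(cl$assignments, sim$truth, by = "user_id")
  ari <- mclust::adjustedRandIndex(j$cluster_index, j$archetype.y)
  expect_gte(ari, 0.9)
  # archetype naming matches the construction for every cluster
  agreement <- mean(j$archetype.x == j$archetype.y)
  expect_gte(agreement, 0.95)
})

test_that("naming is skipped for k != 5 and unresolved on identical centroids", {
  centroids4 <- tibble::tibble(
    cluster_index = 1:4, urank = c(5, 10, 20, 40), mrank = c(0, 2, 4, 6),
    posts_count = c(1, 10, 100, 1000), followers_count = c(1, 10, 100, 1000),
    following_count = c(1, 10, 100, 1000))
  out4 <- suppressMessages(name_clusters(centroids4))
  expect_true(all(is.na(out4$archetype)))

  centroids5 <- dplyr::bind_rows(centroids4[1, ], centroids4)
  centroids5$cluster_index <- 1:5
  expect_warning(out5 <- name_clusters(centroids5), "unresolved")
  expect_true(all(is.na(out5$archetype)))
})

test_that("the archetype-by-topic crosstab conserves counts and shares", {
  sim <- simulate_dataset(small_cfg(seed = 101))
  cl <- cluster_disseminators(sim$dataset$users, k = 5, seed = 7)
  tab <- topic_cluster_crosstab(cl$assignments, sim$dataset$posts)
  expect_equal(sum(tab$n), nrow(sim$dataset$posts))
  shares <- dplyr::summarise(dplyr::group_by(tab, .data$archetype),
                             s = sum(.data$share))
  expect_equal(shares$s, rep(1, nrow(shares)))
  # a one-user one-post dataset puts a single 1 in its cell
  one <- topic_cluster_crosstab(
    tibble::tibble(user_id = "u1", cluster_index = 1L, archetype = "general"),
    tibble::tibble(author_id = "u1", topic = "epidemic_spread"))
  expect_equal(one$n, 1L)
  expect_equal(one$share, 1)
})

test_that("planted topic propensities show through the crosstab", {
  sim <- simulate_dataset(sim_config(seed = 111, n_users = 600, n_posts = 800))
  truth <- sim$truth$archetypes
  assignments <- tibble::tibble(user_id = truth$user_id,
                                cluster_index = as.integer(factor(truth$archetype)),
                                archetype = truth$archetype)
  tab <- topic_cluster_crosstab(assignments, sim$dataset$posts)
  # influential users tilt towards international issues (2x base odds)
  infl <- tab[tab$archetype == "influential", ]
  base <- sim_config()$topic_mix[["international_issues"]]
  tilted <- 2 * base / (1 + base)  # renormalised tilt
  share_intl <- sum(infl$n[infl$topic == "international_issues"]) / sum(infl$n)
  se <- sqrt(tilted * (1 - tilted) / sum(infl$n))
  expect_lt(abs(share_intl - tilted), 3 * se + 0.02)
})
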