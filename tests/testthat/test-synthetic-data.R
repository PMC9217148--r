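test_that("a fixed seed reproduces the corpus bit for bit", {
  cfg <- small_cfg(seed = 151)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$dataset$posts, s2$dataset$posts)
  expect_identical(s1$dataset$users, s2$dataset$users)
  expect_identical(s1$dataset$reposts, s2$dataset$reposts)
  expect_identical(s1$truth, s2$truth)
  # and written files are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(s1$dataset, d1); write_dataset(s2$dataset, d2)
  for (f in c("posts.csv", "users.csv", "reposts.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("the archetype mixture is respected within sampling error", {
  cfg <- sim_config(seed = 161, n_users = 5000)
  sim <- simulate_users(cfg)
  emp <- table(factor(sim$truth$archetype, names(cfg$archetype_mix))) / 5000
  for (a in names(cfg$archetype_mix)) {
    p <- cfg$archetype_mix[[a]]
    se <- sqrt(p * (1 - p) / 5000)
    expect_lt(abs(emp[[a]] - p), 3 * se + 1e-3, label = a)
  }
  # degenerate mix puts everyone in one archetype
  lone <- simulate_users(sim_config(seed = 162, n_users = 50,
    archetype_mix = c(general = 0, platform = 0, inactive = 1,
                      influential = 0, mingler = 0)))
  expect_true(all(lone$truth$archetype == "inactive"))
  # feature invariants hold
  expect_true(all(sim$users$mrank >= 0 & sim$users$mrank <= 7))
  expect_true(all(sim$users$urank >= 0 & sim$users$urank <= 48))
})

test_that("all-zero branching produces no reposts", {
  cfg <- sim_config(seed = 171, n_users = 50,
                    branching = list(radiation = c(0, 0), sector = c(0, 0),
                                     viral = c(0, 0)))
  set.seed(171)
  cas <- simulate_cascade(cfg, "radiation")
  expect_null(cas$reposts)
})

test_that("parsing the generated chain texts reproduces the true trees exactly", {
  sim <- simulate_dataset(small_cfg(seed = 181))
  parsed <- parse_chains(sim$dataset$reposts)
  res <- resolve_parents(parsed)
  expect_equal(nrow(res$orphans), 0)
  truth <- dplyr::arrange(sim$truth$edges, .data$child_id)
  got <- dplyr::arrange(res$edges, .data$child_id)
  expect_equal(got[, c("parent_id", "child_id")],
               truth[, c("parent_id", "child_id")])
})

test_that("metrics agree between parsed chains and the generator's true trees", {
  sim <- simulate_dataset(small_cfg(seed = 191))
  via_parser <- cascade_analysis(sim$dataset)$metrics
  # independent route: metrics straight from the true edge list
  truth_metrics <- lapply(seq_len(nrow(sim$dataset$posts)), function(i) {
    post <- sim$dataset$posts[i, ]
    e <- sim$truth$edges[sim$truth$edges$root_post_id == post$post_id, ]
    parsed <- parse_chains(sim$dataset$reposts)
    build_tree(post, e, parsed) |> compute_metrics()
  })
  truth_metrics <- dplyr::bind_rows(truth_metrics)
  cols <- c("scale", "depth", "max_width", "avg_width", "speed")
  expect_equal(via_parser[, cols], truth_metrics[, cols])
})

test_that("level-1 offspring follow the configured rate, scaled by followers", {
  cfg <- sim_config(seed = 201, n_users = 5000,
                    branching = list(radiation = c(3, 0.5),
                                     sector = c(2, 0.8), viral = c(2, 0.8)))
  set.seed(201)
  pool <- sprintf("u%05d", seq_len(cfg$n_users))
  n1 <- replicate(800, {
    cas <- simulate_cascade(cfg, "radiation", root_followers = cfg$followers_ref,
                            pool = pool)
    if (is.null(cas$reposts)) 0L else sum(cas$edges$level == 1)
  })
  # reference followers: scaling factor 1, so E[n1] = lambda_1 = 3
  expect_lt(abs(mean(n1) - 3), 3 * sd(n1) / sqrt(800))
  # two-level branching expectation: E[scale] = l1 + l1*l2
  scales <- replicate(800, {
    cas <- simulate_cascade(cfg, "radiation", root_followers = cfg$followers_ref,
                            pool = pool)
    if (is.null(cas$reposts)) 0L else nrow(cas$reposts)
  })
  expect_lt(abs(mean(scales) - (3 + 3 * 0.5)), 3 * sd(scales) / sqrt(800))
})

test_that("the planted scale-followers dependence is detectable", {
  sim <- simulate_dataset(sim_config(seed = 211, n_users = 2000, n_posts = 400))
  cas <- cascade_analysis(sim$dataset)
  followers <- sim$dataset$users$followers_count[
    match(sim$dataset$posts$author_id, sim$dataset$users$user_id)]
  out <- spearman_cor(cas$metrics$scale, followers)
  expect_gt(out$rho, 0)
  expect_lt(out$p_value, 0.05)
})

test_that("truth tables stay separate from the dataset", {
  sim <- simulate_dataset(small_cfg(seed = 221))
  expect_false("archetype" %in% names(sim$dataset$users))
  expect_false("regime" %in% names(sim$dataset$posts))
  expect_setequal(names(sim$truth), c("archetypes", "regimes", "edges"))
  expect_equal(nrow(sim$truth$regimes), nrow(sim$dataset$posts))
})
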