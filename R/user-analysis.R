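#' Authority feature matrix for clustering
#'
#' Extracts the five user-authority features used to segment the users
#' who post misinformation: user level (`urank`), membership level
#' (`mrank`), and posts / followers / following counts. Rows with any
#' missing feature are excluded (and counted), since k-means requires
#' complete cases.
#'
#' @param users User tibble from an `rc_dataset`.
#' @return Tibble `user_id` + the five features, complete cases only.
#' @export
authority_features <- function(users) {
  feats <- dplyr::select(users, "user_id", dplyr::all_of(rc_authority_features))
  keep <- complete.cases(feats)
  if (any(!keep)) {
    inform(sprintf("authority_features: excluded %d user(s) with missing features",
                   sum(!keep)))
  }
  feats[keep, , drop = FALSE]
}

#' Standardise authority features
#'
#' The three count features (posts, followers, following) are heavy
#' tailed — raw follower counts span several orders of magnitude and
#' would dominate Euclidean distance — so they are `log1p`-transformed
#' before z-scoring; the bounded levels (`urank`, `mrank`) are z-scored
#' directly. Zero-variance features are dropped with a warning.
#'
#' @param feats Output of [authority_features()].
#' @return Numeric matrix (rows = users) with attributes `user_id`,
#'   `center`, `scale`, `log_features` and `dropped`.
#' @export
standardize_features <- function(feats) {
  if (nrow(feats) < 2) abort("standardize_features: need at least 2 users")
  x <- as.matrix(feats[, rc_authority_features, drop = FALSE])
  log_cols <- c("posts_count", "followers_count", "following_count")
  x[, log_cols] <- log1p(x[, log_cols])
  sds <- apply(x, 2, sd)
  drop <- names(sds)[sds == 0]
  if (length(drop) > 0) {
    warn(sprintf("standardize_features: dropped zero-variance feature(s): %s",
                 paste(drop, collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) == 0) abort("standardize_features: all features have zero variance")
  z <- scale(x)
  out <- z[, , drop = FALSE]
  attr(out, "user_id") <- feats$user_id
  attr(out, "center") <- attr(z, "scaled:center")
  attr(out, "scale") <- attr(z, "scaled:scale")
  attr(out, "log_features") <- log_cols
  attr(out, "dropped") <- drop
  out
}

# Deterministic farthest-point seeding: first centre drawn under the seed,
# each next centre the point farthest from all chosen centres.
farthest_point_centers <- function(x, k, seed) {
  set.seed(seed)
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    idx[j + 1] <- which.max(d2)
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[j + 1], ], n, ncol(x), byrow = TRUE))^2))
  }
  x[idx, , drop = FALSE]
}

#' K-means clustering of standardised users
#'
#' Lloyd's algorithm started from deterministic farthest-point seeding,
#' so a fixed seed yields identical assignments on identical input.
#'
#' @param x Standardised matrix from [standardize_features()].
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed controlling the initial centre.
#' @param iter_max Lloyd iteration cap.
#' @return `stats::kmeans` fit augmented with `user_id`.
#' @export
kmeans_cluster <- function(x, k, seed = 42, iter_max = 300) {
  if (k < 2) abort("kmeans_cluster: k must be at least 2")
  if (nrow(unique(x)) < k) abort("kmeans_cluster: fewer distinct points than clusters")
  centers <- farthest_point_centers(x, k, seed)
  fit <- tryCatch(
    kmeans(x, centers = centers, iter.max = iter_max, algorithm = "Lloyd"),
    error = function(e) {
      set.seed(seed)  # empty-cluster fallback: seeded random restarts
      kmeans(x, centers = k, iter.max = iter_max, nstart = 10,
             algorithm = "Lloyd")
    })
  fit$user_id <- attr(x, "user_id")
  fit
}

#' Choose k by the elbow of the within-cluster sum of squares
#'
#' Runs [kmeans_cluster()] over `k_range`, records total within-cluster
#' sum of squares (WCSS) and mean silhouette width, and returns the k
#' maximising the second difference of WCSS
#' \eqn{W(k-1) - 2W(k) + W(k+1)} — the sharpest bend of the elbow
#' curve. So that the ends of `k_range` are eligible too, the WCSS
#' curve is extended by one k on either side: downwards to k = 1
#' (where WCSS is the total sum of squares, no clustering needed) and
#' upwards by one extra k-means run when n allows.
#'
#' @param x Standardised feature matrix.
#' @param k_range Candidate k values (contiguous, within \[2, n-1\]).
#' @param seed Seed passed to each k-means run.
#' @return The selected k (integer) with attribute `diagnostics`, a
#'   tibble of `k`, `wcss`, `silhouette`, `d2` (second difference) over
#'   the extended curve.
#' @export
choose_k <- function(x, k_range = 2:8, seed = 42) {
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > nrow(x) - 1) {
    abort("choose_k: k_range must lie within [2, n - 1]")
  }
  if (nrow(unique(x)) == 1) abort("choose_k: all points are identical")
  ks <- seq(min(k_range) - 1L, min(max(k_range) + 1L, nrow(x) - 1L))
  fits <- lapply(ks, function(k) {
    if (k == 1) NULL else kmeans_cluster(x, k, seed = seed)
  })
  wcss <- vapply(seq_along(ks), function(i) {
    if (ks[i] == 1) sum(scale(x, scale = FALSE)^2) else
      fits[[i]]$tot.withinss
  }, numeric(1))
  dx <- stats::dist(x)
  sil <- vapply(seq_along(ks), function(i) {
    if (ks[i] == 1) return(NA_real_)
    mean(cluster::silhouette(fits[[i]]$cluster, dx)[, "sil_width"])
  }, numeric(1))
  d2 <- rep(NA_real_, length(ks))
  inner <- which(ks %in% k_range & ks > min(ks) & ks < max(ks))
  d2[inner] <- wcss[inner - 1] - 2 * wcss[inner] + wcss[inner + 1]
  diagnostics <- tibble::tibble(k = ks, wcss = wcss, silhouette = sil,
                                d2 = d2)
  k_best <- if (all(is.na(d2))) k_range[which.max(sil[ks %in% k_range])] else
    ks[which.max(d2)]
  structure(as.integer(k_best), diagnostics = diagnostics)
}

#' Name five clusters by their centroid profiles
#'
#' Maps cluster indices to the five disseminator archetypes by comparing
#' centroids (on the original feature scale; counts compared on the log
#' scale) across clusters:
#' \enumerate{
#'   \item \strong{influential} — largest combined posts + followers
#'     profile (ties broken by user + membership level);
#'   \item \strong{mingler} — of the rest, most followers but few posts;
#'   \item \strong{inactive} — of the rest, lowest on all five features
#'     combined;
#'   \item the remaining two split on membership level:
#'     \strong{platform} (higher) vs \strong{general}.
#' }
#' These rules are heuristics reverse-engineered from the verbal cluster
#' descriptions of the five archetypes; with k != 5 naming is skipped.
#'
#' @param centroids Tibble with `cluster_index` and the five authority
#'   features on their original scale.
#' @return Tibble `cluster_index`, `archetype` (`NA` with a warning on
#'   collisions or k != 5).
#' @export
name_clusters <- function(centroids) {
  k <- nrow(centroids)
  out <- tibble::tibble(cluster_index = centroids$cluster_index,
                        archetype = NA_character_)
  if (k != 5) {
    inform("name_clusters: archetype naming requires k = 5; returning indices only")
    return(out)
  }
  m <- as.matrix(centroids[, rc_authority_features])
  m[, c("posts_count", "followers_count", "following_count")] <-
    log1p(m[, c("posts_count", "followers_count", "following_count")])
  if (anyDuplicated(m)) {
    warn("name_clusters: identical centroids; archetype naming unresolved")
    return(out)
  }
  z <- scale(m)
  z[is.nan(z)] <- 0  # zero-variance feature across centroids
  take <- function(pool, score) {
    s <- score[pool]
    cand <- pool[s == max(s)]
    if (length(cand) > 1) {
      warn("name_clusters: tied centroids; archetype naming unresolved")
      return(NA_integer_)
    }
    cand
  }
  pool <- seq_len(5)
  infl <- take(pool, z[, "posts_count"] + z[, "followers_count"] +
                 1e-6 * (z[, "urank"] + z[, "mrank"]))
  if (is.na(infl)) return(out)
  pool <- setdiff(pool, infl)
  ming <- take(pool, z[, "followers_count"] - z[, "posts_count"])
  if (is.na(ming)) return(out)
  pool <- setdiff(pool, ming)
  inact <- take(pool, -rowSums(z))
  if (is.na(inact)) return(out)
  pool <- setdiff(pool, inact)
  plat <- take(pool, z[, "mrank"])
  if (is.na(plat)) return(out)
  gen <- setdiff(pool, plat)
  out$archetype[c(infl, ming, inact, plat, gen)] <-
    c("influential", "mingler", "inactive", "platform", "general")
  out
}

#' Cluster the users who post misinformation
#'
#' End-to-end user segmentation: assemble authority features,
#' standardise, select k by the elbow criterion (unless given), run
#' seeded k-means, and (for k = 5) name the archetypes.
#'
#' @param users User tibble from an `rc_dataset`.
#' @param k Number of clusters, or `NULL` to select via [choose_k()].
#' @param k_range Candidate range when `k` is `NULL`.
#' @param seed Integer seed.
#' @return List: `assignments` (`user_id`, `cluster_index`, `archetype`),
#'   `centroids` (original scale), `k`, `fit`, `k_diagnostics`.
#' @export
cluster_disseminators <- function(users, k = NULL, k_range = 2:8, seed = 42) {
  feats <- authority_features(users)
  x <- standardize_features(feats)
  k_diag <- NULL
  if (is.null(k)) {
    k <- choose_k(x, k_range, seed = seed)
    k_diag <- attr(k, "diagnostics")
  }
  fit <- kmeans_cluster(x, k, seed = seed)
  centroids <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(feats, cluster_index = fit$cluster), .data$cluster_index),
    dplyr::across(dplyr::all_of(rc_authority_features), mean),
    n = dplyr::n(), .groups = "drop")
  names_tbl <- name_clusters(centroids)
  assignments <- tibble::tibble(
    user_id = feats$user_id,
    cluster_index = fit$cluster,
    archetype = names_tbl$archetype[match(fit$cluster, names_tbl$cluster_index)])
  list(assignments = assignments, centroids = centroids,
       k = as.integer(k), fit = fit, k_diagnostics = k_diag)
}

#' Cross-tabulate user archetypes against misinformation topics
#'
#' Counts, for each user archetype (or cluster index when unnamed), how
#' many posts its members contributed to each misinformation topic, with
#' row-normalised shares. Users without posts simply contribute no rows;
#' posts by unclustered authors are excluded and counted.
#'
#' @param assignments Assignment tibble from [cluster_disseminators()].
#' @param posts Post tibble with `author_id` and `topic`.
#' @return Tibble `archetype`, `topic`, `n`, `share` (share within
#'   archetype).
#' @export
topic_cluster_crosstab <- function(assignments, posts) {
  lab <- if (all(is.na(assignments$archetype)))
    as.character(assignments$cluster_index) else assignments$archetype
  key <- tibble::tibble(author_id = assignments$user_id, archetype = lab)
  joined <- dplyr::inner_join(posts, key, by = "author_id")
  n_excluded <- nrow(posts) - nrow(joined)
  if (n_excluded > 0) {
    inform(sprintf("topic_cluster_crosstab: %d post(s) by unclustered authors excluded",
                   n_excluded))
  }
  tab <- dplyr::count(joined, .data$archetype, .data$topic, name = "n")
  dplyr::mutate(dplyr::group_by(tab, .data$archetype),
                share = .data$n / sum(.data$n)) |> dplyr::ungroup()
}
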