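#' Spearman rank correlation with tie midranks
#'
#' Computes Spearman's rho as the Pearson correlation of midranks and a
#' two-sided p-value from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of
#' freedom. Incomplete pairs are dropped; a constant vector leaves rho
#' undefined (`NA`).
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row tibble: `rho`, `p_value`, `n` (complete pairs used).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, n = n)
}

#' Correlation grid: cascade topology vs creator authority
#'
#' Joins each cascade's topological attributes (scale, depth, maximum
#' width, average width, speed) to the authority features of the user
#' who created the root post, and fills a 5 x 5 grid of Spearman
#' correlations, one per (topology, authority) pair, with pairwise
#' complete cases. Cells with fewer than 3 complete cases are left
#' missing. Raw two-sided p-values are reported, plus a
#' Benjamini-Hochberg adjusted column across the grid.
#'
#' @param metrics Cascade metrics tibble (from [cascade_analysis()]).
#' @param posts Post tibble (`post_id`, `author_id`).
#' @param users User tibble with authority features.
#' @return Tibble `topology`, `feature`, `rho`, `p_value`, `p_bh`, `n`.
#' @export
correlation_matrix <- function(metrics, posts, users) {
  topo_cols <- c("scale", "depth", "max_width", "avg_width", "speed")
  joined <- dplyr::left_join(
    dplyr::left_join(metrics, dplyr::select(posts, "post_id", "author_id"),
                     by = "post_id"),
    dplyr::select(users, "user_id", dplyr::all_of(rc_authority_features)),
    by = c(author_id = "user_id"))
  grid <- tidyr::expand_grid(topology = topo_cols,
                             feature = rc_authority_features)
  cells <- purrr::pmap(grid, function(topology, feature) {
    spearman_cor(joined[[topology]], joined[[feature]])
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(cells))
  out$p_bh <- p.adjust(out$p_value, method = "BH")
  out
}

#' Per-group descriptive summary with 95% CI of the mean
#'
#' For each group (e.g. misinformation topic) and each requested value
#' column, reports n, mean, SD, maximum and the t-based 95% confidence
#' interval of the mean, \eqn{\bar x \pm t_{0.975, n-1} s/\sqrt n}.
#' Single-row groups report no interval.
#'
#' @param df Data frame.
#' @param values Character vector of value columns to summarise.
#' @param group Grouping column name.
#' @param conf Confidence level (default 0.95).
#' @return Tibble `group`, `variable`, `n`, `mean`, `sd`, `max`,
#'   `ci_lower`, `ci_upper`.
#' @export
group_summary <- function(df, values, group, conf = 0.95) {
  long <- tidyr::pivot_longer(
    dplyr::select(df, dplyr::all_of(c(group, values))),
    dplyr::all_of(values), names_to = "variable", values_to = "value")
  long <- long[is.finite(long$value), , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(long, .data[[group]], .data$variable),
    n = dplyr::n(), mean = mean(.data$value), sd = sd(.data$value),
    max = max(.data$value), .groups = "drop")
  half <- rep(NA_real_, nrow(out))
  ok <- out$n >= 2
  half[ok] <- qt(1 - (1 - conf) / 2, out$n[ok] - 1) * out$sd[ok] / sqrt(out$n[ok])
  out$ci_lower <- out$mean - half
  out$ci_upper <- out$mean + half
  dplyr::rename(out, group = 1)
}

#' Time-binned topic counts and mean sentiment
#'
#' Bins posts into ISO calendar weeks (Monday-anchored by default) and
#' reports per-bin, per-topic post counts, plus the mean of the supplied
#' sentiment scores when any are present. Counts conserve the total
#' number of posts.
#'
#' @param posts Post tibble with `timestamp`, `topic` and optionally
#'   `sentiment`.
#' @param unit Bin width understood by [lubridate::floor_date()].
#' @param week_start Week anchor day (1 = Monday).
#' @return Tibble `bin`, `topic`, `n` and, when sentiment is available,
#'   `mean_sentiment`.
#' @export
time_binned_aggregate <- function(posts, unit = "week", week_start = 1) {
  binned <- dplyr::mutate(posts,
    bin = lubridate::floor_date(.data$timestamp, unit = unit,
                                week_start = week_start))
  has_sent <- "sentiment" %in% names(posts) && any(!is.na(posts$sentiment))
  if (has_sent) {
    dplyr::summarise(dplyr::group_by(binned, .data$bin, .data$topic),
                     n = dplyr::n(),
                     mean_sentiment = mean(.data$sentiment, na.rm = TRUE),
                     .groups = "drop")
  } else {
    dplyr::summarise(dplyr::group_by(binned, .data$bin, .data$topic),
                     n = dplyr::n(), .groups = "drop")
  }
}

#' Krippendorff's alpha for nominal inter-coder reliability
#'
#' Chance-corrected agreement over an items x coders grid of categorical
#' labels, computed from the coincidence matrix: within each item every
#' ordered pair of codes contributes \eqn{1/(m_u - 1)} (with \eqn{m_u}
#' the number of codes on that item), and
#' \eqn{\alpha = 1 - D_o / D_e} with observed disagreement
#' \eqn{D_o = \sum_{c \ne k} o_{ck} / n} and expected disagreement
#' \eqn{D_e = \sum_{c \ne k} n_c n_k / (n(n-1))} under the nominal
#' (0/1) distance. Items carrying fewer than two codes are unpairable
#' and dropped; perfect agreement gives exactly 1.
#'
#' @param labels Matrix or data frame, rows = items, columns = coders;
#'   `NA` marks a missing code.
#' @param metric Distance metric; only `"nominal"` is implemented.
#' @return One-row tibble: `alpha`, `n_items` (pairable), `n_coders`,
#'   `metric`.
#' @export
krippendorff_alpha <- function(labels, metric = "nominal") {
  metric <- match.arg(metric, "nominal")
  m <- as.matrix(labels)
  if (ncol(m) < 2) abort("krippendorff_alpha: need at least 2 coders")
  mode(m) <- "character"
  pairable <- rowSums(!is.na(m)) >= 2
  if (!any(pairable)) {
    warn("krippendorff_alpha: no item carries two or more codes; alpha undefined")
    return(tibble::tibble(alpha = NA_real_, n_items = 0L,
                          n_coders = ncol(m), metric = metric))
  }
  mp <- m[pairable, , drop = FALSE]
  cats <- sort(unique(stats::na.omit(as.vector(mp))))
  o <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (i in seq_len(nrow(mp))) {
    vals <- mp[i, !is.na(mp[i, ])]
    mu <- length(vals)
    for (a in seq_len(mu)) for (b in seq_len(mu)) {
      if (a != b) o[vals[a], vals[b]] <- o[vals[a], vals[b]] + 1 / (mu - 1)
    }
  }
  n_c <- rowSums(o)
  n_tot <- sum(n_c)
  d_o <- (n_tot - sum(diag(o))) / n_tot
  d_e <- (sum(outer(n_c, n_c)) - sum(n_c^2)) / (n_tot * (n_tot - 1))
  alpha <- if (d_e == 0) 1 else 1 - d_o / d_e
  tibble::tibble(alpha = alpha, n_items = as.integer(sum(pairable)),
                 n_coders = ncol(m), metric = metric)
}
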