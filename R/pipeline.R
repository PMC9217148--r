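#' Percentage with half-up rounding
#'
#' Formats `100 * num / den` with half-up rounding to `digits` decimals
#' (so 46.795 prints as "46.80", never banker's-rounded down), the
#' convention used throughout the report tables.
#'
#' @param num,den Numerator and denominator.
#' @param digits Decimal places.
#' @return Character vector like `"46.80"`.
#' @export
pct_half_up <- function(num, den, digits = 2) {
  x <- 100 * num / den
  f <- 10^digits
  sprintf(paste0("%.", digits, "f"), floor(x * f + 0.5 + 1e-9) / f)
}

stage_log <- function(stage, ...) {
  inform(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full misinformation-cascade pipeline
#'
#' Orchestrates every stage over one dataset: chain parsing and parent
#' resolution, tree construction, dissemination metrics and structural
#' typology, user clustering, topology-authority correlations, per-topic
#' summaries and weekly time bins, and the final report. Each stage logs
#' its input/output row counts; all result tables are written to
#' `out_dir` as CSV, plus `report.md`.
#'
#' @param input An `rc_dataset`, or a path accepted by [read_dataset()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param separator Chain delimiter.
#' @param seed Integer seed for the clustering stage.
#' @param k Number of user clusters, or `NULL` for elbow selection.
#' @param format Input format when `input` is a path.
#' @param week_start Week anchor for time bins (1 = Monday).
#' @return Invisibly, a list: `dataset`, `cascades` (metrics + trees +
#'   orphans), `clusters`, `crosstab`, `correlations`, `summaries`,
#'   `timebins`, `report` (character lines), `files`.
#' @export
run_pipeline <- function(input, out_dir = NULL, separator = "//", seed = 42,
                         k = NULL, format = c("csv", "jsonl"),
                         week_start = 1) {
  format <- match.arg(format)
  d <- if (inherits(input, "rc_dataset")) input else
    read_dataset(input, format = format)
  stage_log("read", "%d posts, %d users, %d reposts",
            nrow(d$posts), nrow(d$users), nrow(d$reposts))

  cas <- cascade_analysis(d, separator = separator)
  stage_log("cascade", "%d trees built, %d edges resolved, %d orphans dropped",
            length(cas$trees), nrow(cas$edges), nrow(cas$orphans))

  clus <- cluster_disseminators(d$users, k = k, seed = seed)
  stage_log("cluster", "k = %d over %d users", clus$k,
            nrow(clus$assignments))
  crosstab <- topic_cluster_crosstab(clus$assignments, d$posts)

  corr <- correlation_matrix(cas$metrics, d$posts, d$users)
  summaries <- group_summary(
    dplyr::left_join(cas$metrics,
                     dplyr::select(d$posts, "post_id", "topic"),
                     by = "post_id"),
    values = c("scale", "depth", "max_width", "avg_width", "speed"),
    group = "topic")
  timebins <- time_binned_aggregate(d$posts, week_start = week_start)
  stage_log("associate", "%d correlation cells, %d summary rows, %d time bins",
            nrow(corr), nrow(summaries), nrow(timebins))

  report <- make_report(d, cas$metrics, clus, crosstab, corr)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(tbl, name) {
      tbl <- dplyr::select(tbl, -dplyr::any_of("segments"))
      if ("timestamp" %in% names(tbl)) tbl$timestamp <- format_rc_time(tbl$timestamp)
      f <- file.path(out_dir, name)
      readr::write_csv(tbl, f, na = "", progress = FALSE)
      f
    }
    files <- c(
      wr(dplyr::select(cas$parsed, "repost_id", "root_post_id", "level"),
         "parsed_reposts.csv"),
      wr(cas$orphans, "orphans.csv"),
      wr(cas$edges, "edges.csv"),
      wr(cas$metrics, "cascade_metrics.csv"),
      wr(clus$assignments, "clusters.csv"),
      wr(clus$centroids, "centroids.csv"),
      wr(crosstab, "crosstab.csv"),
      wr(corr, "correlations.csv"),
      wr(summaries, "group_summary.csv"),
      wr(timebins, "timebins.csv"))
    report_file <- file.path(out_dir, "report.md")
    writeLines(report, report_file)
    files <- c(files, report_file)
    stage_log("write", "%d file(s) written to %s", length(files), out_dir)
  }

  invisible(list(dataset = d, cascades = cas, clusters = clus,
                 crosstab = crosstab, correlations = corr,
                 summaries = summaries, timebins = timebins,
                 report = report, files = files))
}

md_table <- function(df, digits = 3) {
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "", format(round(v, digits))) else
      ifelse(is.na(v), "", as.character(v))
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Assemble the summary report
#'
#' Builds a markdown report: descriptive Mean (SD) / Maximum grid for the
#' five dissemination metrics, topic share table (counts and two-decimal
#' percentages), network-type shares, cluster summary and the
#' topology-authority correlation grid. Every printed percentage
#' recomputes exactly from its printed numerator and denominator.
#'
#' @param d The `rc_dataset`.
#' @param metrics Cascade metrics tibble.
#' @param clusters Result of [cluster_disseminators()].
#' @param crosstab Result of [topic_cluster_crosstab()].
#' @param correlations Result of [correlation_matrix()].
#' @return Character vector of markdown lines.
#' @export
make_report <- function(d, metrics, clusters = NULL, crosstab = NULL,
                        correlations = NULL) {
  lines <- c("# Misinformation dissemination report", "")

  lines <- c(lines, "## Topic shares", "")
  if (nrow(d$posts) == 0) {
    lines <- c(lines, "No posts.", "")
  } else {
    tt <- dplyr::count(d$posts, .data$topic, name = "n")
    tt <- tt[order(-tt$n), ]
    tt$share <- paste0(pct_half_up(tt$n, nrow(d$posts)), "%")
    lines <- c(lines, md_table(tt), "",
               sprintf("Total posts: %d.", nrow(d$posts)), "")
  }

  lines <- c(lines, "## Dissemination patterns", "")
  disseminated <- metrics[metrics$scale > 0, , drop = FALSE]
  if (nrow(disseminated) == 0) {
    lines <- c(lines, "No cascades (no post was forwarded).", "")
  } else {
    grid <- dplyr::bind_rows(lapply(
      c("scale", "depth", "max_width", "avg_width", "speed"), function(v) {
        x <- disseminated[[v]]
        x <- x[is.finite(x)]
        tibble::tibble(metric = v,
                       `mean (SD)` = sprintf("%.1f (%.2f)", mean(x), sd(x)),
                       maximum = format(round(max(x), 2)))
      }))
    lines <- c(lines, md_table(grid), "",
               sprintf("Cascades with at least one repost: %d of %d posts.",
                       nrow(disseminated), nrow(metrics)), "")
    nt <- dplyr::count(disseminated, .data$net_type, name = "n")
    nt$share <- paste0(pct_half_up(nt$n, nrow(disseminated)), "%")
    lines <- c(lines, "### Network types", "", md_table(nt), "")
  }

  if (!is.null(clusters)) {
    lines <- c(lines, "## Disseminator clusters", "")
    cs <- dplyr::count(clusters$assignments, .data$cluster_index,
                       .data$archetype, name = "n")
    cs$share <- paste0(pct_half_up(cs$n, sum(cs$n)), "%")
    lines <- c(lines, md_table(cs), "")
    if (!is.null(crosstab) && nrow(crosstab) > 0) {
      wide <- tidyr::pivot_wider(
        dplyr::select(crosstab, -"share"),
        names_from = "topic", values_from = "n", values_fill = 0)
      lines <- c(lines, "### Posts per archetype and topic", "",
                 md_table(wide), "")
    }
  }

  if (!is.null(correlations)) {
    lines <- c(lines, "## Topology vs authority (Spearman rho)", "")
    if (all(is.na(correlations$rho))) {
      lines <- c(lines, "No cells with enough complete cases.", "")
    } else {
      wide <- tidyr::pivot_wider(
        dplyr::mutate(correlations,
                      cell = sprintf("%.2f%s", .data$rho,
                                     ifelse(!is.na(.data$p_value) & .data$p_value < 0.01, "**",
                                            ifelse(!is.na(.data$p_value) & .data$p_value < 0.05, "*", "")))),
        id_cols = "feature", names_from = "topology", values_from = "cell")
      lines <- c(lines, md_table(wide), "",
                 "`*` p < .05, `**` p < .01 (two-sided, unadjusted).", "")
    }
  }
  lines
}
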