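#' Assemble a validated cascade dataset
#'
#' Bundles the three input tables of the pipeline — original posts, the
#' users who wrote or forwarded them, and raw repost records carrying
#' `"//"`-delimited forward chains — into a single validated object.
#'
#' Rows that violate a type invariant (negative engagement counts,
#' sentiment outside \[0, 1\], membership level outside \[0, 7\], user level
#' outside \[0, 48\], a repost time-stamped before its root post, or a
#' repost pointing at a root post that does not exist) are rejected, never
#' silently dropped: the rejected rows and the reason for each are kept in
#' the `rejected` attribute and their count is reported. Authors and
#' reposters that are absent from the user table are allowed and flagged
#' (`missing_user`), mirroring accounts that were blocked or deleted
#' between posting and data capture.
#'
#' @param posts Tibble of original posts. Columns: `post_id`, `author_id`,
#'   `timestamp` (ISO-8601, minute resolution), `text`, `topic` (one of
#'   government_response, epidemic_spread, medical_information,
#'   social_livelihood, international_issues, or `NA`), `forwards`,
#'   `comments`, `likes` (non-negative integers), `sentiment` (in
#'   \[0, 1\] or `NA`).
#' @param users Tibble of users. Columns: `user_id`, `verified` (logical),
#'   `verification_type` (personal/government/media/business/none),
#'   `mrank` (membership level, 0-7), `urank` (user level, 0-48),
#'   `posts_count`, `followers_count`, `following_count`.
#' @param reposts Tibble of repost records. Columns: `repost_id`,
#'   `root_post_id`, `reposter_id`, `timestamp`, `chain_text` (raw repost
#'   content with `"//"`-delimited forward chain), `forwards`, `likes`,
#'   and optionally `parent_repost_id` (left `NA` until resolved).
#' @param quiet Suppress the per-table rejection report.
#'
#' @return An object of class `rc_dataset`: a list with elements `posts`,
#'   `users`, `reposts` (validated tibbles) and attribute `rejected`
#'   (named list of tibbles with a `reason` column).
#' @export
rc_dataset <- function(posts = NULL, users = NULL, reposts = NULL,
                       quiet = FALSE) {
  posts <- coerce_posts(posts)
  users <- coerce_users(users)
  reposts <- coerce_reposts(reposts)

  vp <- validate_posts(posts)
  vu <- validate_users(users)
  vr <- validate_reposts(reposts, vp$valid)

  rejected <- list(posts = vp$rejected, users = vu$rejected,
                   reposts = vr$rejected)
  n_rej <- sum(vapply(rejected, nrow, integer(1)))
  if (!quiet && n_rej > 0) {
    inform(sprintf(
      "rc_dataset: rejected %d row(s) violating invariants (%d posts, %d users, %d reposts); see attr(d, \"rejected\")",
      n_rej, nrow(vp$rejected), nrow(vu$rejected), nrow(vr$rejected)))
  }

  missing_users <- setdiff(
    c(vp$valid$author_id, vr$valid$reposter_id), users$user_id)
  missing_users <- missing_users[!is.na(missing_users)]
  if (!quiet && length(missing_users) > 0) {
    inform(sprintf(
      "rc_dataset: %d referenced user id(s) absent from the user table (blocked/deleted accounts); kept and flagged",
      length(missing_users)))
  }

  structure(
    list(posts = vp$valid, users = vu$valid, reposts = vr$valid),
    rejected = rejected,
    missing_users = missing_users,
    class = "rc_dataset")
}

#' @export
print.rc_dataset <- function(x, ...) {
  cat("<rc_dataset>\n")
  cat(sprintf("  posts:   %d\n", nrow(x$posts)))
  cat(sprintf("  users:   %d\n", nrow(x$users)))
  cat(sprintf("  reposts: %d\n", nrow(x$reposts)))
  rej <- attr(x, "rejected")
  n_rej <- sum(vapply(rej, nrow, integer(1)))
  if (n_rej > 0) cat(sprintf("  rejected rows: %d\n", n_rej))
  invisible(x)
}

# ---- timestamp handling ----------------------------------------------------

# The platform exposes repost times at minute resolution; all timestamps are
# ISO-8601 strings "YYYY-MM-DDTHH:MM" on disk and POSIXct (UTC) in memory.

parse_rc_time <- function(x) {
  if (inherits(x, "POSIXct")) return(floor_minute(x))
  out <- as.POSIXct(as.character(x), format = "%Y-%m-%dT%H:%M", tz = "UTC")
  fallback <- is.na(out) & !is.na(x)
  if (any(fallback)) {
    out[fallback] <- as.POSIXct(as.character(x[fallback]), tz = "UTC")
  }
  floor_minute(out)
}

format_rc_time <- function(x) {
  ifelse(is.na(x), NA_character_, format(x, "%Y-%m-%dT%H:%M", tz = "UTC"))
}

floor_minute <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

# ---- coercion to canonical column types ------------------------------------

posts_schema <- c("post_id", "author_id", "timestamp", "text", "topic",
                  "forwards", "comments", "likes", "sentiment")
users_schema <- c("user_id", "verified", "verification_type", "mrank",
                  "urank", "posts_count", "followers_count", "following_count")
reposts_schema <- c("repost_id", "root_post_id", "reposter_id", "timestamp",
                    "chain_text", "forwards", "likes", "parent_repost_id")

empty_tbl <- function(schema) {
  tibble::as_tibble(setNames(rep(list(character(0)), length(schema)), schema))
}

check_schema <- function(df, schema, what) {
  missing <- setdiff(schema, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s table is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  df
}

coerce_posts <- function(posts) {
  if (is.null(posts)) posts <- empty_tbl(posts_schema)
  posts <- tibble::as_tibble(posts)
  if (!"sentiment" %in% names(posts)) posts$sentiment <- NA_real_
  if (!"topic" %in% names(posts)) posts$topic <- NA_character_
  posts <- check_schema(posts, setdiff(posts_schema, c("topic", "sentiment")),
                        "posts")
  dplyr::mutate(posts,
    post_id = as.character(.data$post_id),
    author_id = as.character(.data$author_id),
    timestamp = parse_rc_time(.data$timestamp),
    text = as.character(.data$text),
    topic = as.character(.data$topic),
    forwards = as.numeric(.data$forwards),
    comments = as.numeric(.data$comments),
    likes = as.numeric(.data$likes),
    sentiment = as.numeric(.data$sentiment))
}

coerce_users <- function(users) {
  if (is.null(users)) users <- empty_tbl(users_schema)
  users <- tibble::as_tibble(users)
  users <- check_schema(users, users_schema, "users")
  dplyr::mutate(users,
    user_id = as.character(.data$user_id),
    verified = as.logical(.data$verified),
    verification_type = as.character(.data$verification_type),
    mrank = as.numeric(.data$mrank),
    urank = as.numeric(.data$urank),
    posts_count = as.numeric(.data$posts_count),
    followers_count = as.numeric(.data$followers_count),
    following_count = as.numeric(.data$following_count))
}

coerce_reposts <- function(reposts) {
  if (is.null(reposts)) reposts <- empty_tbl(reposts_schema)
  reposts <- tibble::as_tibble(reposts)
  if (!"parent_repost_id" %in% names(reposts)) {
    reposts$parent_repost_id <- NA_character_
  }
  reposts <- check_schema(reposts, setdiff(reposts_schema, "parent_repost_id"),
                          "reposts")
  dplyr::mutate(reposts,
    repost_id = as.character(.data$repost_id),
    root_post_id = as.character(.data$root_post_id),
    reposter_id = as.character(.data$reposter_id),
    timestamp = parse_rc_time(.data$timestamp),
    chain_text = as.character(.data$chain_text),
    forwards = as.numeric(.data$forwards),
    likes = as.numeric(.data$likes),
    parent_repost_id = as.character(.data$parent_repost_id))
}

# ---- row-level validation ---------------------------------------------------

split_valid <- function(df, reasons) {
  bad <- !is.na(reasons)
  list(valid = df[!bad, , drop = FALSE],
       rejected = dplyr::mutate(df[bad, , drop = FALSE],
                                reason = reasons[bad]))
}

first_reason <- function(...) {
  conds <- list(...)
  out <- rep(NA_character_, length(conds[[1]]$test))
  for (cond in conds) {
    hit <- cond$test & is.na(out)
    out[hit] <- cond$reason
  }
  out
}

validate_posts <- function(posts) {
  if (nrow(posts) == 0) return(list(valid = posts, rejected = dplyr::mutate(posts, reason = character(0))))
  if (anyDuplicated(posts$post_id)) {
    abort(sprintf("duplicate post_id value(s): %s",
                  paste(unique(posts$post_id[duplicated(posts$post_id)]), collapse = ", ")))
  }
  reasons <- first_reason(
    list(test = is.na(posts$post_id), reason = "missing post_id"),
    list(test = is.na(posts$timestamp), reason = "unparseable timestamp"),
    list(test = !is.na(posts$forwards) & posts$forwards < 0, reason = "forwards < 0"),
    list(test = !is.na(posts$comments) & posts$comments < 0, reason = "comments < 0"),
    list(test = !is.na(posts$likes) & posts$likes < 0, reason = "likes < 0"),
    list(test = !is.na(posts$sentiment) & (posts$sentiment < 0 | posts$sentiment > 1),
         reason = "sentiment outside [0, 1]"),
    list(test = !is.na(posts$topic) & !posts$topic %in% rc_topics,
         reason = "unknown topic label"))
  split_valid(posts, reasons)
}

validate_users <- function(users) {
  if (nrow(users) == 0) return(list(valid = users, rejected = dplyr::mutate(users, reason = character(0))))
  if (anyDuplicated(users$user_id)) {
    abort(sprintf("duplicate user_id value(s): %s",
                  paste(unique(users$user_id[duplicated(users$user_id)]), collapse = ", ")))
  }
  reasons <- first_reason(
    list(test = is.na(users$user_id), reason = "missing user_id"),
    list(test = !is.na(users$mrank) & (users$mrank < 0 | users$mrank > 7),
         reason = "mrank outside [0, 7]"),
    list(test = !is.na(users$urank) & (users$urank < 0 | users$urank > 48),
         reason = "urank outside [0, 48]"),
    list(test = !is.na(users$posts_count) & users$posts_count < 0,
         reason = "posts_count < 0"),
    list(test = !is.na(users$followers_count) & users$followers_count < 0,
         reason = "followers_count < 0"),
    list(test = !is.na(users$following_count) & users$following_count < 0,
         reason = "following_count < 0"),
    list(test = !is.na(users$verification_type) &
           !users$verification_type %in% rc_verification_types,
         reason = "unknown verification_type"))
  split_valid(users, reasons)
}

validate_reposts <- function(reposts, posts) {
  if (nrow(reposts) == 0) return(list(valid = reposts, rejected = dplyr::mutate(reposts, reason = character(0))))
  if (anyDuplicated(reposts$repost_id)) {
    abort(sprintf("duplicate repost_id value(s): %s",
                  paste(unique(reposts$repost_id[duplicated(reposts$repost_id)]), collapse = ", ")))
  }
  root_time <- posts$timestamp[match(reposts$root_post_id, posts$post_id)]
  reasons <- first_reason(
    list(test = is.na(reposts$repost_id), reason = "missing repost_id"),
    list(test = is.na(reposts$timestamp), reason = "unparseable timestamp"),
    list(test = !reposts$root_post_id %in% posts$post_id,
         reason = "root_post_id not in posts table"),
    list(test = !is.na(reposts$forwards) & reposts$forwards < 0, reason = "forwards < 0"),
    list(test = !is.na(reposts$likes) & reposts$likes < 0, reason = "likes < 0"),
    list(test = !is.na(root_time) & reposts$timestamp < root_time,
         reason = "repost timestamped before its root post"))
  split_valid(reposts, reasons)
}

# ---- reading and writing ----------------------------------------------------

#' Read a cascade dataset from disk
#'
#' Reads the three input tables (`posts`, `users`, `reposts`) from a
#' directory written by [write_dataset()], or from three explicitly named
#' files, and validates them into an [rc_dataset()].
#'
#' @param path Directory containing `posts.<ext>`, `users.<ext>`,
#'   `reposts.<ext>`, or a named character vector/list with elements
#'   `posts`, `users`, `reposts` giving the three file paths.
#' @param format `"csv"` (UTF-8, quoted free-text fields) or `"jsonl"`
#'   (one JSON record per line).
#' @param quiet Suppress the rejection report.
#' @return A validated `rc_dataset`.
#' @export
read_dataset <- function(path, format = c("csv", "jsonl"), quiet = FALSE) {
  format <- match.arg(format)
  ext <- if (format == "csv") "csv" else "jsonl"
  if (length(path) == 1 && is.character(path) && is.null(names(path))) {
    paths <- file.path(path, paste0(c("posts", "users", "reposts"), ".", ext))
    names(paths) <- c("posts", "users", "reposts")
  } else {
    paths <- unlist(path)
    if (!all(c("posts", "users", "reposts") %in% names(paths))) {
      abort("path must be a directory or a named vector with elements posts, users, reposts")
    }
  }
  for (p in paths) {
    if (!file.exists(p)) abort(sprintf("input file does not exist: %s", p))
  }
  reader <- if (format == "csv") read_rc_csv else read_rc_jsonl
  rc_dataset(posts = reader(paths[["posts"]]),
             users = reader(paths[["users"]]),
             reposts = reader(paths[["reposts"]]),
             quiet = quiet)
}

read_rc_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

read_rc_jsonl <- function(path) {
  if (file.size(path) == 0) return(NULL)
  tibble::as_tibble(jsonlite::stream_in(file(path), verbose = FALSE))
}

#' Write a cascade dataset to disk
#'
#' Writes the three tables of an `rc_dataset` as `posts`, `users` and
#' `reposts` files. Timestamps are serialised as ISO-8601 strings at
#' minute resolution, so a write followed by [read_dataset()] is the
#' identity on every field.
#'
#' @param d An `rc_dataset`.
#' @param dir Output directory (created if absent).
#' @param format `"csv"` or `"jsonl"`.
#' @return Invisibly, a manifest tibble with columns `table`, `file`, `n`.
#' @export
write_dataset <- function(d, dir, format = c("csv", "jsonl")) {
  stopifnot(inherits(d, "rc_dataset"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "csv") "csv" else "jsonl"
  tables <- list(posts = d$posts, users = d$users, reposts = d$reposts)
  files <- character(0)
  for (nm in names(tables)) {
    tbl <- tables[[nm]]
    if ("timestamp" %in% names(tbl)) {
      tbl$timestamp <- format_rc_time(tbl$timestamp)
    }
    f <- file.path(dir, paste0(nm, ".", ext))
    if (format == "csv") {
      readr::write_csv(tbl, f, na = "", progress = FALSE)
    } else {
      con <- file(f, open = "w")
      if (nrow(tbl) > 0) {
        jsonlite::stream_out(as.data.frame(tbl), con, verbose = FALSE,
                             digits = NA)
      }
      close(con)
    }
    files[nm] <- f
  }
  invisible(tibble::tibble(
    table = names(tables), file = unname(files),
    n = unname(vapply(tables, nrow, integer(1)))))
}
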