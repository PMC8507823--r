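#' Calendar weeks of a study year
#'
#' Weeks are aligned to the Unix epoch week (a 7-day grid anchored at
#' Thursday 1 January 1970, 00:00 UTC). Only weeks lying entirely
#' within the year are "complete"; the partial weeks containing 1
#' January and 31 December are excluded. For 2020 (1 January falls on
#' a Wednesday) the two partial weeks hold exactly one in-year day
#' each, leaving exactly 52 complete weeks — the only 7-day alignment
#' with that property in a 366-day year.
#'
#' @param year Calendar year.
#' @return `week_bounds()`: data.frame with `week` (1..K), `start`,
#'   `end` (UTC epoch seconds, half-open interval).
#'   `n_complete_weeks()`: the count K of complete weeks.
#' @name weeks
NULL

WEEK_SECONDS <- 604800

year_epoch <- function(year) {
  as.numeric(ISOdatetime(year, 1, 1, 0, 0, 0, tz = "UTC"))
}

#' @rdname weeks
#' @export
week_bounds <- function(year) {
  e0 <- year_epoch(year)
  e1 <- year_epoch(year + 1)
  w_first <- floor(e0 / WEEK_SECONDS)   # epoch week containing Jan 1
  first_complete <- if (w_first * WEEK_SECONDS >= e0) w_first else w_first + 1
  w <- first_complete
  starts <- numeric(0)
  while ((w + 1) * WEEK_SECONDS <= e1) {
    starts <- c(starts, w * WEEK_SECONDS)
    w <- w + 1
  }
  data.frame(week = seq_along(starts), start = starts,
             end = starts + WEEK_SECONDS)
}

#' @rdname weeks
#' @export
n_complete_weeks <- function(year) nrow(week_bounds(year))

#' Assign timestamps to complete analysis weeks
#'
#' @param timestamp UTC epoch seconds (vectorized).
#' @param year Study year; timestamps outside it are an error.
#' @return Integer week index (1..K) per timestamp, `NA` for
#'   timestamps in an excluded partial week.
#' @examples
#' assign_week(as.numeric(as.POSIXct("2020-01-01", tz = "UTC")), 2020)  # NA
#' @export
assign_week <- function(timestamp, year) {
  timestamp <- as.numeric(timestamp)
  e0 <- year_epoch(year)
  e1 <- year_epoch(year + 1)
  if (any(timestamp < e0 | timestamp >= e1, na.rm = TRUE))
    stop("timestamp outside year ", year)
  wb <- week_bounds(year)
  idx <- floor(timestamp / WEEK_SECONDS) - floor(wb$start[1] / WEEK_SECONDS) + 1
  idx[idx < 1 | idx > nrow(wb)] <- NA_integer_
  as.integer(idx)
}

#' Ingest post/comment records
#'
#' Reads NDJSON or CSV event records, validates the schema, drops
#' records whose author is the deleted-account marker (with a logged
#' count), and counts malformed lines.
#'
#' @param path Input file.
#' @param format `"ndjson"` or `"csv"` (default guessed from the file
#'   extension).
#' @param max_malformed_fraction Abort if more than this fraction of
#'   lines fail to parse.
#' @return data.table of valid records with attributes `n_deleted`
#'   (dropped deleted-author records) and `n_malformed`.
#' @export
ingest_records <- function(path, format = NULL,
                           max_malformed_fraction = 0.05) {
  if (!file.exists(path)) stop("unreadable input file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "ndjson"
  format <- match.arg(format, c("ndjson", "csv"))
  required <- c("id", "author", "community", "created_utc", "title",
                "body", "kind")
  n_malformed <- 0L
  warned_empty <- FALSE
  if (format == "csv") {
    rec <- data.table::fread(path, colClasses = list(character = c(
      "id", "author", "community", "title", "body", "kind")))
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      warning("empty input file: ", path)
      warned_empty <- TRUE
      rec <- data.table::as.data.table(
        setNames(rep(list(character(0)), length(required)), required))
      rec[, created_utc := numeric(0)]
    } else {
      parsed <- tryCatch(
        jsonlite::fromJSON(paste0("[", paste(lines, collapse = ","), "]"),
                           simplifyDataFrame = TRUE),
        error = function(e) NULL)
      if (is.null(parsed)) {   # fall back line-wise, counting failures
        one <- lapply(lines, function(l)
          tryCatch(jsonlite::fromJSON(l), error = function(e) NULL))
        n_malformed <- sum(vapply(one, is.null, logical(1)))
        if (n_malformed / length(lines) > max_malformed_fraction)
          stop(n_malformed, " of ", length(lines),
               " lines malformed (exceeds max_malformed_fraction)")
        parsed <- data.table::rbindlist(Filter(Negate(is.null), one),
                                        fill = TRUE)
      }
      rec <- data.table::as.data.table(parsed)
    }
  }
  missing <- setdiff(required, names(rec))
  if (length(missing))
    stop("input lacks required fields: ", paste(missing, collapse = ", "))
  rec <- rec[, required, with = FALSE]
  rec[, created_utc := as.numeric(created_utc)]
  bad <- is.na(rec$created_utc) | is.na(rec$author) | !nzchar(rec$author)
  n_malformed <- n_malformed + sum(bad)
  if (nrow(rec) && n_malformed / (nrow(rec) + n_malformed) >
        max_malformed_fraction)
    stop(n_malformed, " malformed records exceed max_malformed_fraction")
  rec <- rec[!bad]
  n_deleted <- sum(rec$author == DELETED_MARKER)
  if (n_deleted > 0L) {
    message("dropping ", n_deleted, " deleted-account records")
    rec <- rec[author != DELETED_MARKER]
  }
  if (!nrow(rec) && !warned_empty)
    warning("no valid records after filtering")
  data.table::setattr(rec, "n_deleted", n_deleted)
  data.table::setattr(rec, "n_malformed", n_malformed)
  rec[]
}

#' Identify MH/NMH cohorts by username matching
#'
#' The MH cohort consists of teen-community authors with at least one
#' item in any mental-health community within the year; remaining
#' teen-community authors form the NMH cohort. Authors seen only in
#' mental-health communities are excluded from all analyses (no
#' username match in the teen community).
#'
#' @param records Record table (post-filtering; deleted-account rows
#'   must already be removed).
#' @return Object of class `cohort_assignment`: list with `assignment`
#'   (data.table author -> cohort), `n_mh`, `n_nmh`, `mh_fraction`,
#'   `n_unmatched` (MH-community-only authors).
#' @export
identify_cohort <- function(records) {
  records <- data.table::as.data.table(records)
  teen_authors <- unique(records[community == "teen", author])
  teen_authors <- setdiff(teen_authors, DELETED_MARKER)
  mh_authors <- unique(records[community %in% MH_COMMUNITIES, author])
  mh_authors <- setdiff(mh_authors, DELETED_MARKER)
  mh <- intersect(teen_authors, mh_authors)
  assignment <- data.table::data.table(author = teen_authors)
  assignment[, cohort := data.table::fifelse(author %in% mh, "MH", "NMH")]
  data.table::setorder(assignment, author)
  structure(list(assignment = assignment[],
                 n_mh = length(mh),
                 n_nmh = length(teen_authors) - length(mh),
                 mh_fraction = if (length(teen_authors))
                   length(mh) / length(teen_authors) else NA_real_,
                 n_unmatched = length(setdiff(mh_authors, teen_authors))),
            class = "cohort_assignment")
}

#' @export
print.cohort_assignment <- function(x, ...) {
  cat("cohorts:", x$n_mh, "MH /", x$n_nmh, "NMH teen-community authors",
      sprintf("(mh_fraction %.4f); %d MH-community-only authors excluded\n",
              x$mh_fraction, x$n_unmatched))
  invisible(x)
}

#' Build weekly engagement/emotion series
#'
#' Aggregates records into one row per key and week: distinct active
#' participants, item counts, posts/comments per participant, and the
#' mean per-item compound emotion. Weekly emotion means average over
#' items (not authors). Weeks with no items keep `n_participants = 0`
#' and `NA` frequency/emotion.
#'
#' @param records Record table; a `week` column is used if present,
#'   otherwise weeks are assigned from `created_utc` (items in excluded
#'   partial weeks are dropped).
#' @param by `"community"` (series per subreddit; mental-health
#'   communities restricted to username-matched authors when
#'   `assignment` is given) or `"cohort"` (teen-community records
#'   split MH vs NMH; requires `assignment`).
#' @param scores Optional [score_records()] output row-aligned with
#'   `records` (or a `compound` column already present in `records`).
#' @param assignment A [identify_cohort()] result.
#' @param year Study year used when assigning weeks.
#' @param n_weeks Number of analysis weeks in the output grid.
#' @return data.table: `key`, `week`, `n_participants`, `n_items`,
#'   `posts_per_participant`, `mean_compound`.
#' @export
weekly_series <- function(records, by = c("community", "cohort"),
                          scores = NULL, assignment = NULL, year = 2020,
                          n_weeks = n_complete_weeks(year)) {
  by <- match.arg(by)
  rec <- data.table::as.data.table(records)
  if (!is.null(scores)) {
    stopifnot(nrow(scores) == nrow(rec))
    rec[, compound := scores$compound]
  }
  if (!"compound" %in% names(rec)) rec[, compound := NA_real_]
  if (!"week" %in% names(rec)) rec[, week := assign_week(created_utc, year)]
  rec <- rec[!is.na(week) & week <= n_weeks]
  if (by == "cohort") {
    if (is.null(assignment))
      stop("cohort series require a cohort assignment")
    rec <- rec[community == "teen"]
    amap <- assignment$assignment
    rec[, key := amap$cohort[match(author, amap$author)]]
    rec <- rec[!is.na(key)]
    keys <- c("NMH", "MH")
  } else {
    if (!is.null(assignment)) {
      matched <- assignment$assignment$author
      rec <- rec[community == "teen" | author %in% matched]
    }
    rec[, key := community]
    keys <- intersect(COMMUNITIES, unique(rec$key))
  }
  agg <- rec[, .(n_participants = data.table::uniqueN(author),
                 n_items = .N,
                 mean_compound = mean(compound)),
             by = .(key, week)]
  grid <- data.table::CJ(key = keys, week = seq_len(n_weeks))
  out <- agg[grid, on = c("key", "week")]
  out[is.na(n_items), `:=`(n_items = 0L, n_participants = 0L)]
  out[, posts_per_participant :=
        data.table::fifelse(n_participants > 0L,
                            n_items / n_participants, NA_real_)]
  data.table::setcolorder(out, c("key", "week", "n_participants", "n_items",
                                 "posts_per_participant", "mean_compound"))
  data.table::setorder(out, key, week)
  out[]
}

#' Percent change between two values
#'
#' Reports the rounded percent change in the reporting style used for
#' week-to-week engagement comparisons: increases as positive percent
#' increases, declines as positive percent declines, with
#' round-half-away-from-zero integer rounding.
#'
#' @param v1 Baseline value (> 0).
#' @param v2 Comparison value.
#' @return List of class `percent_change`: `value` (non-negative
#'   integer magnitude), `direction` (`"increase"`, `"decline"` or
#'   `"no change"`), and `signed` (signed integer percent).
#' @examples
#' percent_change(4.56, 6.15)   # 35% increase
#' percent_change(5.49, 3.14)   # 43% decline
#' @export
percent_change <- function(v1, v2) {
  if (!is.finite(v1) || v1 <= 0) stop("baseline v1 must be positive")
  round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  signed <- round_half_away(100 * (v2 - v1) / v1)
  structure(list(value = abs(signed),
                 direction = if (signed > 0) "increase"
                             else if (signed < 0) "decline"
                             else "no change",
                 signed = signed),
            class = "percent_change")
}

#' @export
print.percent_change <- function(x, ...) {
  cat(x$value, "% ", x$direction, "\n", sep = "")
  invisible(x)
}

#' Scale a series for figure display
#'
#' Multiplies values by a display factor (e.g. 30 for small
#' mental-health community participant counts plotted against a much
#' larger general community) and records the factor as metadata.
#' Display scaling is presentation-only: analysis paths never consume
#' scaled series.
#'
#' @param x Numeric vector (or a [weekly_series()] table, in which case
#'   `columns` are scaled).
#' @param factor Positive multiplier.
#' @param columns Columns to scale when `x` is a table.
#' @return Scaled copy of `x` with attribute `display_scale = factor`.
#' @export
scale_for_display <- function(x, factor, columns = "n_participants") {
  if (!is.finite(factor) || factor <= 0) stop("factor must be positive")
  if (is.data.frame(x)) {
    out <- data.table::copy(data.table::as.data.table(x))
    for (cl in columns) out[[cl]] <- out[[cl]] * factor
    data.table::setattr(out, "display_scale", factor)
    return(out[])
  }
  structure(x * factor, display_scale = factor)
}
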