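#' Pipeline configuration
#'
#' Bundles and validates everything [run_pipeline()] needs. Analysis
#' constants default to the study profile: interruption at week 11,
#' Newey-West lag 12, 52 analysis weeks, display scale factor 30 and a
#' 3.5% MH cohort in the simulated corpus.
#'
#' @param out_dir Run directory (created if needed).
#' @param sim A [sim_config()] used when simulating, or `NULL` to read
#'   `input`.
#' @param input Path of an NDJSON/CSV corpus (used when `sim` is
#'   `NULL`).
#' @param lexicon_path Optional lexicon TSV overriding the bundled one.
#' @param year,n_weeks Week grid of the analysis.
#' @param t0 Interruption week.
#' @param lag Newey-West lag.
#' @param display_factor Display scaling for MH-community participant
#'   curves in figures.
#' @param write_corpus Also write the simulated corpus (NDJSON) and
#'   ground-truth ledger into the run directory.
#' @param make_plots Render the five standard figures.
#' @param annotations Optional data.frame (week, label) of event
#'   markers; defaults to the bundled pandemic timeline when `TRUE`.
#' @param seed Overrides the simulation seed when not `NULL`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            input = NULL,
                            lexicon_path = NULL,
                            year = 2020,
                            n_weeks = 52,
                            t0 = 11,
                            lag = 12,
                            display_factor = 30,
                            write_corpus = FALSE,
                            make_plots = TRUE,
                            annotations = TRUE,
                            seed = NULL) {
  if (is.null(sim) && is.null(input))
    stop("either a simulation config or an input path is required")
  if (!is.null(input) && !file.exists(input))
    stop("input path does not exist: ", input)
  if (!is.null(lexicon_path) && !file.exists(lexicon_path))
    stop("lexicon path does not exist: ", lexicon_path)
  if (n_weeks > n_complete_weeks(year))
    stop("year ", year, " has fewer than ", n_weeks, " complete weeks")
  if (t0 < 1 || t0 > n_weeks)
    stop("interruption week t0 must lie in 1..n_weeks")
  if (lag < 0 || lag >= n_weeks)
    stop("lag must lie in 0..(n_weeks - 1)")
  if (!is.null(sim)) {
    if (!is.null(seed)) sim$seed <- as.integer(seed)
    sim$n_weeks <- as.integer(n_weeks)
    sim$interruption_week <- as.integer(t0)
    sim$year <- as.integer(year)
    validate_sim_config(sim)
  }
  structure(list(out_dir = out_dir, sim = sim, input = input,
                 lexicon_path = lexicon_path, year = year,
                 n_weeks = as.integer(n_weeks), t0 = as.integer(t0),
                 lag = as.integer(lag), display_factor = display_factor,
                 write_corpus = isTRUE(write_corpus),
                 make_plots = isTRUE(make_plots),
                 annotations = annotations,
                 seed = if (is.null(seed)) sim$seed else as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(manifest, name, expr) {
  res <- tryCatch(force(expr), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  res
}

#' Run the full simulate-score-aggregate-fit pipeline
#'
#' Executes the stages in order (simulate or ingest, score, aggregate,
#' itsa, report), writing weekly-series CSVs, two ITSA JSON summaries
#' (posting frequency and emotion by cohort), figures, tables and a
#' manifest into the run directory. Outputs are a deterministic
#' function of the configuration.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with `manifest`, `series`, `fits`, `cohorts`
#'   and output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  lexicon <- if (is.null(config$lexicon_path)) load_lexicon()
             else load_lexicon(config$lexicon_path)
  manifest <- list(package = "teenits",
                   version = as.character(packageVersion("teenits")),
                   seed = config$seed, t0 = config$t0, lag = config$lag,
                   year = config$year, n_weeks = config$n_weeks,
                   decisions = c(
                     "weeks are epoch-aligned; partial first/last weeks excluded",
                     "emotion denominators use post-preprocessing token counts",
                     "weekly emotion means average over items",
                     "cohort membership is year-global"),
                   stages = list())
  paths <- list()

  # stage 1: obtain records
  n_deleted <- 0L
  if (!is.null(config$sim)) {
    corpus <- run_stage(manifest, "simulate", generate_corpus(config$sim,
                                                              lexicon = lexicon))
    records <- corpus$records
    if (config$write_corpus) {
      paths$corpus <- file.path(config$out_dir, "corpus.ndjson")
      write_corpus_ndjson(records, paths$corpus)
      paths$ledger <- file.path(config$out_dir, "ledger.json")
      write_ledger(corpus, paths$ledger)
    }
    n_input <- nrow(records)
    if (any(records$author == DELETED_MARKER)) {
      n_deleted <- sum(records$author == DELETED_MARKER)
      records <- records[author != DELETED_MARKER]
    }
    manifest$stages$simulate <- list(status = "complete", rows = n_input)
  } else {
    records <- run_stage(manifest, "ingest", ingest_records(config$input))
    n_deleted <- attr(records, "n_deleted")
    n_input <- nrow(records) + n_deleted
    manifest$stages$ingest <- list(status = "complete", rows = n_input,
                                   malformed = attr(records, "n_malformed"))
  }

  # stage 2: emotion scoring
  scores <- run_stage(manifest, "score", score_records(records, lexicon))
  manifest$stages$score <- list(status = "complete", rows = nrow(scores))

  # stage 3: aggregation
  cohorts <- run_stage(manifest, "aggregate", identify_cohort(records))
  series_comm <- weekly_series(records, by = "community", scores = scores,
                               assignment = cohorts, year = config$year,
                               n_weeks = config$n_weeks)
  series_coh <- weekly_series(records, by = "cohort", scores = scores,
                              assignment = cohorts, year = config$year,
                              n_weeks = config$n_weeks)
  paths$series_community <- file.path(config$out_dir,
                                      "weekly_series_community.csv")
  paths$series_cohort <- file.path(config$out_dir,
                                   "weekly_series_cohort.csv")
  data.table::fwrite(series_comm, paths$series_community)
  data.table::fwrite(series_coh, paths$series_cohort)
  paths$cohorts <- file.path(config$out_dir, "cohort_assignment.csv")
  data.table::fwrite(cohorts$assignment, paths$cohorts)
  manifest$stages$aggregate <- list(status = "complete",
                                    rows = nrow(series_comm) + nrow(series_coh),
                                    mh_fraction = cohorts$mh_fraction)

  # stage 4: interrupted time series fits by cohort
  fits <- list()
  for (outcome in c("frequency", "emotion")) {
    col <- if (outcome == "frequency") "posts_per_participant"
           else "mean_compound"
    sg <- data.table::data.table(group = series_coh$key,
                                 week = series_coh$week,
                                 value = series_coh[[col]])
    fits[[outcome]] <- run_stage(manifest, paste0("itsa_", outcome),
                                 fit_itsa(sg, t0 = config$t0, L = config$lag))
    paths[[paste0("itsa_", outcome)]] <-
      file.path(config$out_dir, paste0("itsa_", outcome, ".json"))
    write_itsa_json(fits[[outcome]], paths[[paste0("itsa_", outcome)]])
  }
  manifest$stages$itsa <- list(status = "complete",
                               r_square = vapply(fits, `[[`, numeric(1),
                                                 "r_square"))

  # stage 5: report (tables + figures)
  tables <- export_tables(fits$frequency, series_comm,
                          cohort_series = series_coh)
  paths$table_fit <- file.path(config$out_dir, "itsa_frequency_table.csv")
  data.table::fwrite(tables$fit_table, paths$table_fit)
  paths$table_summary <- file.path(config$out_dir, "series_summary.csv")
  data.table::fwrite(tables$summary, paths$table_summary)
  if (config$make_plots) {
    ann <- config$annotations
    if (isTRUE(ann)) ann <- load_event_annotations()
    if (isFALSE(ann)) ann <- NULL
    paths$figures <- plot_series(series_comm, series_coh,
                                 out_dir = file.path(config$out_dir, "figures"),
                                 annotations = ann,
                                 display_factor = config$display_factor)
  }
  manifest$stages$report <- list(status = "complete")

  manifest$counts <- list(items_in = n_input, items_dropped = n_deleted,
                          items_scored = nrow(scores))
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, series = list(community = series_comm,
                                                    cohort = series_coh),
                 fits = fits, cohorts = cohorts, paths = paths))
}

write_itsa_json <- function(fit, path) {
  obj <- list(groups = fit$group_levels, n = fit$n, t0 = fit$t0,
              lag = fit$L, r_square = fit$r_square,
              coefficients = fit$coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Export fit and summary tables
#'
#' Renders the standard eight-parameter fit table (parameter, b,
#' approximate SE, t value, p value, plus an R-square row) and a
#' per-key summary of the weekly series (mean and range), mirroring
#' the usual reporting style.
#'
#' @param fit An [fit_itsa()] result.
#' @param series A community [weekly_series()] table.
#' @param cohort_series Optional cohort series appended to the
#'   summary.
#' @return List with `fit_table` and `summary` data.tables.
#' @export
export_tables <- function(fit, series, cohort_series = NULL) {
  ft <- data.table::copy(fit$coefficients)
  ft[, term := NULL]
  data.table::setnames(ft, c("Parameter", "b", "Approx. SE", "t Value",
                             "Pr > |t|"))
  ft <- rbind(ft, data.table::data.table(
    Parameter = "R-square", b = fit$r_square, `Approx. SE` = NA_real_,
    `t Value` = NA_real_, `Pr > |t|` = NA_real_))
  summarize <- function(d, label) {
    d[, .(series = label,
          mean_participants = mean(n_participants),
          mean_frequency = mean(posts_per_participant, na.rm = TRUE),
          min_frequency = suppressWarnings(min(posts_per_participant,
                                               na.rm = TRUE)),
          max_frequency = suppressWarnings(max(posts_per_participant,
                                               na.rm = TRUE)),
          mean_emotion = mean(mean_compound, na.rm = TRUE)),
      by = .(key)]
  }
  s <- summarize(data.table::as.data.table(series), "community")
  if (!is.null(cohort_series))
    s <- rbind(s, summarize(data.table::as.data.table(cohort_series),
                            "cohort"))
  list(fit_table = ft[], summary = s[])
}
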