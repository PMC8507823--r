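#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic Reddit-like
#' corpus generator. The defaults describe the world the downstream
#' analysis targets: a year of activity (52 complete weeks) across one
#' general teen community and three mental-health (MH) communities,
#' with 3.5% of teen-community users belonging to the latent MH cohort,
#' weekly posting intensities following a segmented linear trend broken
#' at week 11, gamma-distributed per-user activity multipliers
#' (negative-binomial weekly counts marginally), and post texts drawn
#' from emotion-word mixtures.
#'
#' @param n_users Number of rostered teen-community users.
#' @param fraction_mh Probability that a user belongs to the MH cohort.
#' @param n_weeks Number of complete analysis weeks.
#' @param interruption_week Week index T0 of the trend break; the
#'   level/slope change applies from T0 onward.
#' @param year Calendar year providing the week grid (see
#'   [assign_week()]).
#' @param rate_params Named list of segmented-trend parameter vectors
#'   `c(level, slope, level_change, slope_change)` on the weekly
#'   expected-posts-per-user scale, for streams `nmh_teen` (NMH users
#'   in the teen community), `mh_teen` (MH users in the teen community)
#'   and `mh_forum` (MH users in their MH community).
#' @param user_heterogeneity Variance of the mean-1 gamma activity
#'   multiplier (0 = homogeneous users).
#' @param emotion_mix Named list of mixture proportions over
#'   `c(anger, fear, happiness, sadness, surprise, neutral)` for
#'   streams `teen_nmh`, `teen_mh`, `depression`, `anxiety`,
#'   `suicidewatch`; each must sum to 1.
#' @param text_length_range Integer range of body token counts
#'   (uniform).
#' @param comment_fraction Probability an item is a comment (comments
#'   carry empty titles).
#' @param deleted_fraction Fraction of records whose author is replaced
#'   by the deleted-account marker, to exercise ingest filtering.
#' @param mh_community_probs Probabilities with which an MH user's home
#'   forum is each of the three MH communities.
#' @param seed Integer RNG seed; the corpus is a deterministic function
#'   of the configuration.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_users = 5000,
                       fraction_mh = 0.035,
                       n_weeks = 52,
                       interruption_week = 11,
                       year = 2020,
                       rate_params = list(
                         nmh_teen = c(level = 4.948, slope = -0.028,
                                      level_change = 0.741, slope_change = 0.032),
                         mh_teen  = c(level = 9.832, slope = -0.160,
                                      level_change = 2.253, slope_change = 0.146),
                         mh_forum = c(level = 3.0, slope = 0,
                                      level_change = 0.3, slope_change = 0.01)),
                       user_heterogeneity = 0.125,
                       emotion_mix = list(
                         teen_nmh     = c(anger = 0.048, fear = 0.07,
                                          happiness = 0.03, sadness = 0.143,
                                          surprise = 0.02, neutral = 0.689),
                         teen_mh      = c(anger = 0.06, fear = 0.08,
                                          happiness = 0.025, sadness = 0.15,
                                          surprise = 0.02, neutral = 0.665),
                         depression   = c(anger = 0.06, fear = 0.12,
                                          happiness = 0.01, sadness = 0.28,
                                          surprise = 0.01, neutral = 0.52),
                         anxiety      = c(anger = 0.05, fear = 0.22,
                                          happiness = 0.01, sadness = 0.22,
                                          surprise = 0.02, neutral = 0.48),
                         suicidewatch = c(anger = 0.05, fear = 0.12,
                                          happiness = 0.01, sadness = 0.31,
                                          surprise = 0.01, neutral = 0.50)),
                       text_length_range = c(5L, 30L),
                       comment_fraction = 0.9,
                       deleted_fraction = 0,
                       mh_community_probs = c(depression = 0.45, anxiety = 0.20,
                                              suicidewatch = 0.35),
                       seed = 1L) {
  cfg <- list(n_users = as.integer(n_users), fraction_mh = fraction_mh,
              n_weeks = as.integer(n_weeks),
              interruption_week = as.integer(interruption_week),
              year = as.integer(year), rate_params = rate_params,
              user_heterogeneity = user_heterogeneity,
              emotion_mix = emotion_mix,
              text_length_range = as.integer(text_length_range),
              comment_fraction = comment_fraction,
              deleted_fraction = deleted_fraction,
              mh_community_probs = mh_community_probs,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_users < 1L) stop("n_users must be positive")
  if (is.na(cfg$fraction_mh) || cfg$fraction_mh < 0 || cfg$fraction_mh > 1)
    stop("fraction_mh must lie in [0, 1]")
  if (cfg$n_weeks < 1L) stop("n_weeks must be positive")
  if (cfg$interruption_week < 1L || cfg$interruption_week > cfg$n_weeks)
    stop("interruption_week must lie in 1..n_weeks")
  if (n_complete_weeks(cfg$year) < cfg$n_weeks)
    stop("year ", cfg$year, " has fewer than ", cfg$n_weeks, " complete weeks")
  need <- c("nmh_teen", "mh_teen", "mh_forum")
  if (!all(need %in% names(cfg$rate_params)))
    stop("rate_params must name streams: ", paste(need, collapse = ", "))
  for (nm in need) {
    lam <- segmented_intensity(seq_len(cfg$n_weeks), cfg$rate_params[[nm]],
                               cfg$interruption_week, floor_at = -Inf)
    if (any(lam <= 0))
      stop("non-positive expected weekly posts for stream '", nm,
           "' (configuration error)")
  }
  for (nm in names(cfg$emotion_mix)) {
    p <- cfg$emotion_mix[[nm]]
    if (length(p) != 6L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("emotion_mix[['", nm,
           "']] must be 6 non-negative proportions summing to 1")
  }
  if (cfg$user_heterogeneity < 0) stop("user_heterogeneity must be >= 0")
  if (length(cfg$text_length_range) != 2L ||
      cfg$text_length_range[1] < 1L ||
      cfg$text_length_range[2] < cfg$text_length_range[1])
    stop("text_length_range must be an increasing positive integer pair")
  if (cfg$deleted_fraction < 0 || cfg$deleted_fraction >= 1)
    stop("deleted_fraction must lie in [0, 1)")
  if (cfg$comment_fraction < 0 || cfg$comment_fraction > 1)
    stop("comment_fraction must lie in [0, 1]")
  if (abs(sum(cfg$mh_community_probs) - 1) > 1e-8)
    stop("mh_community_probs must sum to 1")
  invisible(cfg)
}

#' Segmented linear weekly intensity
#'
#' The planted expected-posts curve: `level + slope * t` before the
#' interruption, plus `level_change + slope_change * (t - t0)` from
#' week `t0` onward (so at `t = t0` only the level change applies).
#'
#' @param t Integer week index (vectorized).
#' @param params Numeric `c(level, slope, level_change, slope_change)`.
#' @param t0 Interruption week.
#' @param floor_at Small positive floor applied to the result.
#' @return Numeric intensity per week.
#' @export
segmented_intensity <- function(t, params, t0, floor_at = 0.01) {
  params <- as.numeric(params)
  post <- as.numeric(t >= t0)
  pmax(params[1] + params[2] * t + post * (params[3] + params[4] * (t - t0)),
       floor_at)
}

#' Simulate one user's weekly item counts
#'
#' Weekly counts are Poisson with mean
#' `multiplier * segmented_intensity(t)`; with gamma-distributed
#' multipliers across users the marginal weekly count is negative
#' binomial, which matches overdispersed posting behaviour while
#' keeping closed-form means for tests.
#'
#' @param config A [sim_config()].
#' @param multiplier Per-user activity multiplier (mean 1 across the
#'   roster).
#' @param stream One of `"nmh_teen"`, `"mh_teen"`, `"mh_forum"`.
#' @return Integer vector of `config$n_weeks` counts.
#' @export
simulate_weekly_counts <- function(config, multiplier = 1,
                                   stream = "nmh_teen") {
  validate_sim_config(config)
  stopifnot(multiplier > 0, stream %in% names(config$rate_params))
  lam <- multiplier * segmented_intensity(seq_len(config$n_weeks),
                                          config$rate_params[[stream]],
                                          config$interruption_week)
  rpois(config$n_weeks, lam)
}

# fast concatenation of a token vector into per-text strings
concat_groups <- function(words, lengths) {
  stopifnot(sum(lengths) == length(words))
  out <- character(length(lengths))
  if (!length(words)) return(out)
  big <- paste(words, collapse = " ")
  pos_end <- cumsum(nchar(words) + 1L) - 1L   # last char of word i in big
  last <- cumsum(lengths)
  nonzero <- lengths > 0L
  stop_at <- pos_end[last[nonzero]]
  first <- c(1L, head(last, -1L) + 1L)
  prev <- first[nonzero] - 1L              # index of word before the group
  start_at <- rep(1L, sum(nonzero))
  start_at[prev > 0L] <- pos_end[prev[prev > 0L]] + 2L
  out[nonzero] <- substring(big, start_at, stop_at)
  out
}

# vectorized text rendering for one mixture
render_texts <- function(mixture, lengths, pools) {
  classes <- c(EMOTIONS, "neutral")
  stopifnot(length(mixture) == 6L)
  mixture <- as.numeric(mixture)
  active <- which(mixture > 0)
  for (k in active)
    if (!length(pools[[classes[k]]]))
      stop("empty lexicon class with positive weight: ", classes[k])
  total <- sum(lengths)
  cls <- sample.int(6L, total, replace = TRUE, prob = mixture)
  words <- character(total)
  for (k in unique(cls)) {
    pool <- pools[[classes[k]]]
    idx <- cls == k
    words[idx] <- pool[sample.int(length(pool), sum(idx), replace = TRUE)]
  }
  concat_groups(words, lengths)
}

#' Render a bag-of-words text from an emotion mixture
#'
#' Draws each token independently: first an emotion class (or neutral)
#' from `mixture`, then a word uniformly from that class's vocabulary.
#' No stopwords are emitted, so the lexicon scorer recovers the mixture
#' proportions in expectation exactly.
#'
#' @param mixture Numeric length-6 proportions over
#'   `c(anger, fear, happiness, sadness, surprise, neutral)`, summing
#'   to 1.
#' @param length Token count.
#' @param lexicon Word -> emotion map ([load_lexicon()]).
#' @param neutral_words Neutral vocabulary ([load_neutral_words()]).
#' @return A single space-separated token string.
#' @export
render_text <- function(mixture, length, lexicon = load_lexicon(),
                        neutral_words = load_neutral_words()) {
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture must sum to 1")
  pools <- c(split(names(lexicon), lexicon[])[EMOTIONS],
             list(neutral = neutral_words))
  render_texts(mixture, as.integer(length), pools)
}

#' Generate a synthetic corpus with ground truth
#'
#' Produces a full year of post/comment events plus a ledger of every
#' planted parameter. MH-cohort users post in the teen community (at
#' `mh_teen` rates) and in one home MH community (at `mh_forum` rates,
#' guaranteed at least one forum item so the cohort is identifiable);
#' NMH users post only in the teen community. Timestamps are uniform
#' within complete analysis weeks, so no item falls in the excluded
#' partial first/last calendar weeks. Identical configurations
#' (including seed) give identical corpora.
#'
#' @param config A [sim_config()].
#' @param lexicon,neutral_words Vocabularies used by the text renderer.
#' @param render_text Render title/body token strings (the expensive
#'   part). Set `FALSE` for count-only studies (e.g. posting-dynamics
#'   replicates); bodies are then empty strings.
#' @return List of class `sim_corpus` with elements `records`
#'   (data.table: id, author, community, created_utc, title, body,
#'   kind) sorted by timestamp, and `ledger` (planted ground truth:
#'   config, per-user roster with cohort labels and multipliers,
#'   planted rates, expected compound emotion per stream, counts).
#' @export
generate_corpus <- function(config, lexicon = load_lexicon(),
                            neutral_words = load_neutral_words(),
                            render_text = TRUE) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_users
  t0 <- config$interruption_week
  wk <- seq_len(config$n_weeks)
  week_start <- week_bounds(config$year)$start[wk]

  pools <- c(split(names(lexicon), lexicon[])[EMOTIONS],
             list(neutral = neutral_words))

  author <- sprintf("user%06d", seq_len(n))
  is_mh <- runif(n) < config$fraction_mh
  mult <- if (config$user_heterogeneity > 0) {
    shape <- 1 / config$user_heterogeneity
    rgamma(n, shape = shape, rate = shape)
  } else rep(1, n)
  home <- rep(NA_character_, n)
  if (any(is_mh))
    home[is_mh] <- sample(names(config$mh_community_probs), sum(is_mh),
                          replace = TRUE, prob = config$mh_community_probs)

  # weekly counts per stream, users x weeks
  draw_counts <- function(users, stream) {
    lam <- outer(mult[users],
                 segmented_intensity(wk, config$rate_params[[stream]], t0))
    matrix(rpois(length(lam), lam), nrow = length(users))
  }

  blocks <- list()
  nmh_idx <- which(!is_mh)
  if (length(nmh_idx)) {
    cnt <- draw_counts(nmh_idx, "nmh_teen")
    blocks$nmh_teen <- expand_counts(cnt, author[nmh_idx], "teen", wk)
  }
  mh_idx <- which(is_mh)
  if (length(mh_idx)) {
    cnt <- draw_counts(mh_idx, "mh_teen")
    blocks$mh_teen <- expand_counts(cnt, author[mh_idx], "teen", wk)
    fcnt <- draw_counts(mh_idx, "mh_forum")
    silent <- rowSums(fcnt) == 0L
    if (any(silent)) {   # cohort must be identifiable: plant one item
      j <- sample.int(config$n_weeks, sum(silent), replace = TRUE)
      fcnt[cbind(which(silent), j)] <- 1L
    }
    blocks$mh_forum <- expand_counts(fcnt, author[mh_idx], home[mh_idx], wk)
  }
  rec <- data.table::rbindlist(blocks, idcol = "stream")

  # emotion mixture stream per record
  rec[, mix_key := data.table::fifelse(
        community == "teen",
        data.table::fifelse(stream == "mh_teen", "teen_mh", "teen_nmh"),
        community)]

  # timestamps uniform within the item's (complete) week
  rec[, created_utc := week_start[week] + floor(runif(.N) * 604800)]

  # kind, ids, deleted markers
  rec[, kind := data.table::fifelse(runif(.N) < config$comment_fraction,
                                    "comment", "post")]
  rec[, id := make_ids(.N)]
  n_deleted <- 0L
  if (config$deleted_fraction > 0) {
    del <- runif(nrow(rec)) < config$deleted_fraction
    n_deleted <- sum(del)
    rec[del, author := DELETED_MARKER]
  }

  # texts per mixture stream
  rec[, body := ""]
  rec[, title := ""]
  len_lo <- config$text_length_range[1]
  len_span <- config$text_length_range[2] - len_lo + 1L
  for (mk in if (render_text) unique(rec$mix_key) else character(0)) {
    ridx <- which(rec$mix_key == mk)
    lens <- len_lo + sample.int(len_span, length(ridx), replace = TRUE) - 1L
    data.table::set(rec, ridx, "body",
                    render_texts(config$emotion_mix[[mk]], lens, pools))
    pidx <- ridx[rec$kind[ridx] == "post"]
    if (length(pidx)) {
      tl <- 2L + sample.int(4L, length(pidx), replace = TRUE) - 1L
      data.table::set(rec, pidx, "title",
                      render_texts(config$emotion_mix[[mk]], tl, pools))
    }
  }

  data.table::setorder(rec, created_utc, id)
  ledger <- list(
    config = unclass(config),
    roster = data.frame(author = author,
                        cohort = ifelse(is_mh, "MH", "NMH"),
                        multiplier = mult, home_community = home,
                        stringsAsFactors = FALSE),
    n_mh = sum(is_mh), n_nmh = sum(!is_mh),
    mh_fraction = mean(is_mh),
    planted_rates = config$rate_params,
    planted_compound = vapply(config$emotion_mix, function(p)
      unname(p[1] + p[2] - p[3] + p[4]), numeric(1)),
    n_records = nrow(rec), n_deleted = n_deleted)
  rec[, c("stream", "mix_key", "week") := NULL]
  data.table::setcolorder(rec, c("id", "author", "community", "created_utc",
                                 "title", "body", "kind"))
  structure(list(records = rec[], ledger = ledger), class = "sim_corpus")
}

expand_counts <- function(cnt, authors, community, weeks) {
  pos <- which(cnt > 0L, arr.ind = TRUE)
  k <- cnt[pos]
  comm <- if (length(community) == 1L) community
          else rep.int(community[pos[, 1L]], k)
  data.table::data.table(
    author = rep.int(authors[pos[, 1L]], k),
    community = comm,
    week = rep.int(weeks[pos[, 2L]], k))
}

make_ids <- function(n) {
  alphabet <- c(letters, 0:9)
  m <- matrix(alphabet[sample.int(36L, 8L * n, replace = TRUE)], nrow = n)
  paste0("t_", do.call(paste0, data.table::as.data.table(m)))
}

#' Closed-form expected posting-frequency path of a corpus
#'
#' Conditional on the generated roster (cohort labels and activity
#' multipliers recorded in the ledger), the expected weekly
#' posts-per-participant of cohort c is
#' `lambda_w * sum(m_i) / sum(1 - exp(-m_i * lambda_w))`: Poisson
#' expected items over expected active participants. This is the
#' ground-truth curve that the aggregate-then-fit pipeline should
#' recover; regressing it on the segmented design gives the effective
#' planted coefficients (the participant denominator makes the path
#' slightly super-linear relative to the raw intensity).
#'
#' @param ledger A `sim_corpus` ledger (or a `sim_corpus`).
#' @return data.table with columns `group` ("NMH"/"MH"), `week`,
#'   `value`.
#' @export
planted_frequency_path <- function(ledger) {
  if (inherits(ledger, "sim_corpus")) ledger <- ledger$ledger
  cfg <- ledger$config
  roster <- ledger$roster
  wk <- seq_len(cfg$n_weeks)
  out <- list()
  for (coh in c("NMH", "MH")) {
    m <- roster$multiplier[roster$cohort == coh]
    if (!length(m)) next
    stream <- if (coh == "MH") "mh_teen" else "nmh_teen"
    lam <- segmented_intensity(wk, cfg$rate_params[[stream]],
                               cfg$interruption_week)
    ei <- lam * sum(m)
    ep <- vapply(lam, function(l) sum(1 - exp(-m * l)), numeric(1))
    out[[coh]] <- data.table::data.table(group = coh, week = wk,
                                         value = ei / ep)
  }
  data.table::rbindlist(out)
}

#' @export
print.sim_corpus <- function(x, ...) {
  cat("synthetic corpus:", nrow(x$records), "records,",
      x$ledger$n_mh, "MH /", x$ledger$n_nmh, "NMH users",
      sprintf("(mh_fraction %.4f)\n", x$ledger$mh_fraction))
  invisible(x)
}

json_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

#' Write a corpus as newline-delimited JSON
#'
#' One UTF-8 JSON object per line with fields id, author, community,
#' created_utc, title, body, kind. Output is byte-identical across runs
#' for identical record tables.
#'
#' @param records Record data.frame/data.table (or a `sim_corpus`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_corpus_ndjson <- function(records, path) {
  if (inherits(records, "sim_corpus")) records <- records$records
  lines <- sprintf(
    '{"id":"%s","author":"%s","community":"%s","created_utc":%d,"title":"%s","body":"%s","kind":"%s"}',
    json_escape(records$id), json_escape(records$author),
    json_escape(records$community), as.integer(records$created_utc),
    json_escape(records$title), json_escape(records$body),
    json_escape(records$kind))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Write a corpus as CSV
#'
#' @inheritParams write_corpus_ndjson
#' @return `path`, invisibly.
#' @export
write_corpus_csv <- function(records, path) {
  if (inherits(records, "sim_corpus")) records <- records$records
  data.table::fwrite(data.table::as.data.table(records), path)
  invisible(path)
}

#' Write the ground-truth ledger as JSON
#'
#' The ledger is kept separate from the record stream: PostRecords
#' never embed ground truth.
#'
#' @param corpus A `sim_corpus` (or a ledger list).
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(corpus, path) {
  ledger <- if (inherits(corpus, "sim_corpus")) corpus$ledger else corpus
  jsonlite::write_json(ledger, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
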