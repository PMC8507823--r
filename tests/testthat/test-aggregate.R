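test_that("2020 has exactly 52 complete epoch-aligned weeks", {
  wb <- week_bounds(2020)
  expect_equal(nrow(wb), 52L)
  expect_equal(n_complete_weeks(2020), 52L)
  # every complete week lies fully inside the year
  e0 <- as.numeric(as.POSIXct("2020-01-01", tz = "UTC"))
  e1 <- as.numeric(as.POSIXct("2021-01-01", tz = "UTC"))
  expect_true(all(wb$start >= e0 & wb$end <= e1))
  expect_true(all(diff(wb$start) == 604800))
})

test_that("partial boundary weeks are excluded, in-year weeks indexed", {
  jan1 <- as.numeric(as.POSIXct("2020-01-01 12:00:00", tz = "UTC"))
  dec31 <- as.numeric(as.POSIXct("2020-12-31 12:00:00", tz = "UTC"))
  expect_true(is.na(assign_week(jan1, 2020)))
  expect_true(is.na(assign_week(dec31, 2020)))
  expect_equal(assign_week(as.numeric(as.POSIXct("2020-01-02", tz = "UTC")),
                           2020), 1L)
  expect_error(assign_week(as.numeric(as.POSIXct("2021-03-01", tz = "UTC")),
                           2020), "outside year")
  # a uniform full-year grid touches every one of the 52 weeks
  ts <- seq(jan1, dec31, by = 3600)
  expect_equal(sort(unique(na.omit(assign_week(ts, 2020)))), 1:52)
})

test_that("ingest validates, drops deleted authors, counts malformed", {
  f <- tempfile(fileext = ".ndjson")
  rec <- tiny_records()[1:3]
  del <- data.table::copy(rec[1])
  del[, `:=`(id = "t_99", author = "[deleted]")]
  write_corpus_ndjson(rbind(rec, del), f)
  expect_message(out <- ingest_records(f), "1 deleted-account")
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "n_deleted"), 1L)

  # empty file warns and returns an empty stream
  fe <- tempfile(); writeLines(character(0), fe)
  expect_warning(empty <- ingest_records(fe, format = "ndjson"), "empty")
  expect_equal(nrow(empty), 0L)

  # malformed lines beyond the tolerance are fatal
  fm <- tempfile()
  writeLines(c('{"bad json', "{}"), fm)
  expect_error(ingest_records(fm, format = "ndjson"), "malformed")
})

test_that("planted deleted-account fraction is recovered at ingest", {
  cfg <- sim_config(n_users = 150, seed = 31, deleted_fraction = 0.02,
                    text_length_range = c(3L, 5L))
  corp <- generate_corpus(cfg, render_text = FALSE)
  f <- tempfile(fileext = ".ndjson")
  write_corpus_ndjson(corp, f)
  out <- suppressMessages(ingest_records(f))
  expect_equal(attr(out, "n_deleted"), corp$ledger$n_deleted)
  n <- corp$ledger$n_records
  ci <- qbinom(c(0.005, 0.995), n, 0.02)
  expect_gte(attr(out, "n_deleted"), ci[1])
  expect_lte(attr(out, "n_deleted"), ci[2])
})

test_that("cohorts partition teen authors by username matching", {
  coh <- identify_cohort(tiny_records())
  a <- coh$assignment
  # bob posted in teen + anxiety -> MH; dan only in depression -> excluded
  expect_equal(a$cohort[a$author == "bob"], "MH")
  expect_false("dan" %in% a$author)
  expect_equal(coh$n_unmatched, 1L)
  expect_setequal(a$author, c("ann", "bob", "cat", "eve"))
  expect_setequal(a$cohort[a$author != "bob"], "NMH")
  # partition: MH and NMH are disjoint and cover all teen authors
  expect_equal(coh$n_mh + coh$n_nmh, nrow(a))
  expect_equal(coh$mh_fraction, 1 / 4)
})

test_that("weekly series count participants, items and emotion", {
  rec <- tiny_records()
  sc <- score_records(rec)
  coh <- identify_cohort(rec)
  ws <- weekly_series(rec, "community", scores = sc, assignment = coh)
  teen1 <- ws[ws$key == "teen" & ws$week == 1]
  # week 1 teen: ann twice, bob once, cat once -> 3 participants 4 items
  expect_equal(teen1$n_participants, 3L)
  expect_equal(teen1$n_items, 4L)
  expect_equal(teen1$posts_per_participant, 4 / 3)
  # zero-activity weeks flagged as missing, zero participants
  teen9 <- ws[ws$key == "teen" & ws$week == 9]
  expect_equal(teen9$n_participants, 0L)
  expect_true(is.na(teen9$posts_per_participant))
  expect_equal(nrow(ws[ws$key == "teen"]), 52L)
  # direct arithmetic example: 2 authors, 3 items, mean of compounds
  one <- data.table::data.table(
    id = c("a", "b", "c"), author = c("u1", "u1", "u2"),
    community = "teen", created_utc = week_bounds(2020)$start[5] + 10,
    title = "", body = "x", kind = "post",
    compound = c(0.2, 0.4, 0.6))
  w5 <- weekly_series(one, "community")[week == 5]
  expect_equal(w5$n_participants, 2L)
  expect_equal(w5$posts_per_participant, 1.5)
  expect_equal(w5$mean_compound, 0.4)
})

test_that("weekly counting matches a brute-force set construction", {
  cfg <- sim_config(n_users = 60, seed = 17, text_length_range = c(3L, 5L))
  rec <- generate_corpus(cfg, render_text = FALSE)$records
  rec[, week := assign_week(created_utc, 2020)]
  ws <- weekly_series(rec, "community")
  for (w in c(1L, 11L, 30L, 52L)) {
    sub <- rec[community == "teen" & week == w]
    expect_equal(ws[key == "teen" & week == w, n_participants],
                 length(unique(sub$author)))
    expect_equal(ws[key == "teen" & week == w, n_items], nrow(sub))
  }
  # frequency is at least 1 whenever anyone is active
  act <- ws[n_participants > 0]
  expect_true(all(act$posts_per_participant >= 1))
})

test_that("cohort series split teen activity and track planted rates", {
  cfg <- sim_config(n_users = 400, seed = 19, text_length_range = c(3L, 5L))
  corp <- generate_corpus(cfg, render_text = FALSE)
  rec <- corp$records
  coh <- identify_cohort(rec)
  ws <- weekly_series(rec, "cohort", assignment = coh)
  expect_setequal(unique(ws$key), c("MH", "NMH"))
  # weekly frequency tracks the ledger-conditional expected path
  oracle <- planted_frequency_path(corp)
  obs <- ws[key == "NMH"][order(week)]
  exp_v <- oracle[group == "NMH"][order(week), value]
  n_nmh <- corp$ledger$n_nmh
  se <- sqrt(exp_v / n_nmh)   # Poisson-scale approximation
  expect_true(mean(abs(obs$posts_per_participant - exp_v) <= 3 * se) > 0.9)
})

test_that("dropping deleted authors changes exactly their contributions", {
  rec <- tiny_records()
  del <- data.table::copy(rec)
  del[author == "cat", author := "[deleted]"]
  kept <- del[author != "[deleted]"]
  ws_all <- weekly_series(rec, "community")
  ws_kept <- weekly_series(kept, "community")
  # cat had 1 teen item in week 1 and 1 in week 2
  expect_equal(ws_all[key == "teen" & week == 1, n_items] -
                 ws_kept[key == "teen" & week == 1, n_items], 1L)
  expect_equal(ws_all[key == "teen" & week == 1, n_participants] -
                 ws_kept[key == "teen" & week == 1, n_participants], 1L)
  expect_equal(ws_all[key == "anxiety", n_items],
               ws_kept[key == "anxiety", n_items])
})

test_that("percent change reports signed integer magnitudes", {
  expect_equal(percent_change(5, 5)$value, 0)
  expect_equal(percent_change(5, 5)$direction, "no change")
  expect_error(percent_change(0, 5), "positive")
  expect_error(percent_change(-1, 5), "positive")
  # round-half-away-from-zero at the .5 boundary
  expect_equal(percent_change(100, 100.5)$signed, 1)
  expect_equal(percent_change(100, 99.5)$signed, -1)
  pc <- percent_change(4, 3)
  expect_equal(pc$value, 25)
  expect_equal(pc$direction, "decline")
})

test_that("display scaling is metadata-tagged and reversible", {
  expect_equal(as.numeric(scale_for_display(c(1, 2, 3), 30)), c(30, 60, 90))
  expect_equal(as.numeric(scale_for_display(c(1, 2, 3), 1)), c(1, 2, 3))
  x <- c(0.3, 1.7, 2.9)
  sc <- scale_for_display(x, 30)
  expect_equal(attr(sc, "display_scale"), 30)
  expect_equal(as.numeric(scale_for_display(as.numeric(sc), 1 / 30)), x,
               tolerance = 1e-12)
  expect_error(scale_for_display(x, 0), "positive")
  ws <- weekly_series(tiny_records(), "community")
  wsc <- scale_for_display(ws, 30)
  expect_equal(wsc$n_participants, ws$n_participants * 30)
})
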