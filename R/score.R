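#' Score a token sequence against an emotion lexicon
#'
#' For each of the five emotions, the score is the number of tokens the
#' lexicon maps to that emotion divided by the total number of tokens
#' (the post-preprocessing token count). Tokens absent from the lexicon
#' contribute only to the denominator. An empty token sequence scores
#' zero on all five emotions with `n_tokens = 0`.
#'
#' @param tokens Character vector of preprocessed tokens.
#' @param lexicon Named character vector word -> emotion
#'   (see [load_lexicon()]).
#' @return A named list of class `emotion_scores`: `anger`, `fear`,
#'   `happiness`, `sadness`, `surprise` (proportions in `[0, 1]`),
#'   `compound` (anger + fear - happiness + sadness, in `[-1, 3]`) and
#'   `n_tokens`.
#' @seealso [score_text()] for the raw-text convenience wrapper,
#'   [compound_scale()] for the compound formula.
#' @export
score_tokens <- function(tokens, lexicon = load_lexicon()) {
  n <- length(tokens)
  if (n == 0L) {
    s <- as.list(setNames(numeric(5), EMOTIONS))
  } else {
    emo <- lexicon[match(tokens, names(lexicon))]
    cnt <- table(factor(emo, levels = EMOTIONS))
    s <- as.list(as.numeric(cnt) / n)
    names(s) <- EMOTIONS
  }
  s$compound <- s$anger + s$fear - s$happiness + s$sadness
  s$n_tokens <- n
  class(s) <- "emotion_scores"
  s
}

#' Score raw text
#'
#' Convenience composition of [preprocess_text()] and [score_tokens()]
#' for a single text.
#'
#' @param text A single character string.
#' @inheritParams score_tokens
#' @param ... Passed to [preprocess_text()].
#' @return An `emotion_scores` object.
#' @export
score_text <- function(text, lexicon = load_lexicon(), ...) {
  score_tokens(preprocess_text(text, ...)[[1L]], lexicon)
}

#' Compound negative-emotion scale
#'
#' Combines four of the five emotion proportions into one signed scale:
#' happiness is reverse-coded and the surprise emotion is dropped
#' (it can mark both positive and negative affect), giving
#' `anger + fear - happiness + sadness`. The attainable range is
#' `[-1, 3]`; in practice the five proportions jointly sum to at most 1
#' so observed values fall in `[-1, 1]`.
#'
#' @param anger,fear,happiness,sadness Emotion proportions in `[0, 1]`.
#'   Alternatively pass an `emotion_scores` object as the single first
#'   argument.
#' @return Numeric compound score(s).
#' @examples
#' compound_scale(0.1, 0.6, 0.1, 0.1)  # 0.7
#' @export
compound_scale <- function(anger, fear, happiness, sadness) {
  if (inherits(anger, "emotion_scores")) {
    s <- anger
    return(compound_scale(s$anger, s$fear, s$happiness, s$sadness))
  }
  v <- cbind(anger, fear, happiness, sadness)
  if (anyNA(v) || any(v < 0) || any(v > 1))
    stop("emotion scores must lie in [0, 1]")
  unname(v[, 1L] + v[, 2L] - v[, 3L] + v[, 4L])
}

#' @export
print.emotion_scores <- function(x, ...) {
  cat("emotion scores (", x$n_tokens, " tokens)\n", sep = "")
  v <- unlist(x[EMOTIONS])
  print(round(c(v, compound = x$compound), 4))
  invisible(x)
}

#' Score a batch of records
#'
#' Vectorized scoring of a record table: titles and bodies are
#' concatenated with a single space (comments carry empty titles),
#' preprocessed, and scored. Texts that are empty after preprocessing
#' are scored all-zero and flagged, and remain part of any weekly mean.
#'
#' @param records data.frame/data.table with columns `title` and `body`
#'   (a `text` column is used as-is if present instead).
#' @param lexicon Named word -> emotion vector.
#' @param stopwords,contractions,emoji_map Preprocessing resources
#'   (see [preprocess_text()]).
#' @return A data.table with columns `anger`, `fear`, `happiness`,
#'   `sadness`, `surprise`, `compound`, `n_tokens`, `empty_text`
#'   (row-aligned with `records`). Metadata attribute
#'   `scoring_decisions` records the denominator convention.
#' @export
score_records <- function(records, lexicon = load_lexicon(),
                          stopwords = load_stopwords(),
                          contractions = load_contractions(),
                          emoji_map = load_emoji_map()) {
  stopifnot(is.data.frame(records))
  if ("text" %in% names(records)) {
    txt <- records[["text"]]
  } else {
    stopifnot(all(c("title", "body") %in% names(records)))
    ti <- records[["title"]]
    ti[is.na(ti)] <- ""
    txt <- paste(ti, records[["body"]])
    txt[!nzchar(ti)] <- records[["body"]][!nzchar(ti)]
  }
  core <- preprocess_core(txt, stopwords = stopwords,
                          contractions = contractions,
                          emoji_map = emoji_map)
  flat <- core$tokens
  grp <- core$grp
  n <- tabulate(grp, nbins = core$n_texts)
  out <- data.table::data.table(row = seq_len(core$n_texts), n_tokens = n)
  emo <- lexicon[match(flat, names(lexicon))]
  for (e in EMOTIONS) {
    cnt <- tabulate(grp[!is.na(emo) & emo == e], nbins = core$n_texts)
    data.table::set(out, j = e, value = cnt / pmax(n, 1L))
  }
  data.table::set(out, j = "compound",
                  value = out$anger + out$fear - out$happiness + out$sadness)
  data.table::set(out, j = "empty_text", value = n == 0L)
  data.table::set(out, j = "row", value = NULL)
  data.table::setcolorder(out, c(EMOTIONS, "compound", "n_tokens", "empty_text"))
  attr(out, "scoring_decisions") <-
    "denominator = token count after preprocessing; unlisted tokens count only in the denominator"
  out[]
}
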