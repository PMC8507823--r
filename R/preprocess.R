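#' Preprocess free text into scoring tokens
#'
#' Normalizes raw post/comment text into the lowercase alphabetic token
#' sequence consumed by [score_tokens()]. Steps, in order: strip URLs;
#' replace emojis with their word names; lowercase; normalize curly
#' apostrophes; split on non-letter characters (keeping in-word
#' apostrophes); expand contractions and common shortcuts token-wise
#' ("i'm" to "i am", "thx" to "thanks"); drop remaining apostrophes;
#' remove stopwords and non-alphabetic leftovers. A total function on
#' character input: empty or `NA` text yields an empty token vector.
#'
#' @param text Character vector of raw texts (title and body are
#'   concatenated with a single space upstream).
#' @param stopwords,contractions,emoji_map Resource objects as returned
#'   by [load_stopwords()], [load_contractions()], [load_emoji_map()].
#' @return A list of character vectors, one per input text (a single
#'   unnamed text may be passed; the result is still a length-1 list).
#' @examples
#' preprocess_text("I'm scared!!")[[1]]   # "scared"
#' @export
preprocess_text <- function(text,
                            stopwords = load_stopwords(),
                            contractions = load_contractions(),
                            emoji_map = load_emoji_map()) {
  flat <- preprocess_core(text, stopwords, contractions, emoji_map)
  unname(split(flat$tokens,
               factor(flat$grp, levels = seq_len(flat$n_texts))))
}

# shared vectorized core: returns the flattened token vector plus the
# text index of each token, avoiding a per-text split when the caller
# (score_records) only needs grouped counts
preprocess_core <- function(text, stopwords, contractions, emoji_map) {
  if (length(text) == 0L)
    return(list(tokens = character(0), grp = integer(0), n_texts = 0L))
  x <- as.character(text)
  x[is.na(x)] <- ""

  # URLs: only touch strings that can contain one
  has_url <- grepl("http|www\\.", x)
  if (any(has_url))
    x[has_url] <- gsub("(https?://|www\\.)[^[:space:]]+", " ", x[has_url])

  # emojis: restrict the per-emoji pass to non-ASCII strings
  has_wide <- grepl("[^\001-\177]", x, useBytes = TRUE)
  if (any(has_wide) && length(emoji_map)) {
    xi <- x[has_wide]
    for (i in seq_along(emoji_map)) {
      xi <- gsub(names(emoji_map)[i], paste0(" ", emoji_map[[i]], " "),
                 xi, fixed = TRUE)
    }
    x[has_wide] <- xi
  }

  x <- tolower(x)
  x <- gsub("’", "'", x, fixed = TRUE)

  toks <- strsplit(x, "[^a-z']+")

  n_per <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  if (length(flat)) {
    # token-wise contraction/shortcut expansion, then re-split multiword
    # expansions so "i'm" contributes tokens "i" and "am"
    hit <- match(flat, names(contractions))
    repl <- which(!is.na(hit))
    if (length(repl)) {
      exp_toks <- strsplit(contractions[hit[repl]], " ", fixed = TRUE)
      pieces <- rep(list(NULL), length(flat))
      pieces[seq_along(flat)] <- as.list(flat)
      pieces[repl] <- exp_toks
      grp <- rep.int(seq_along(n_per), n_per)
      grp <- rep.int(grp, lengths(pieces))
      flat <- unlist(pieces, use.names = FALSE)
      n_per <- tabulate(grp, nbins = length(n_per))
    }
    flat <- gsub("'", "", flat, fixed = TRUE)
    keep <- nzchar(flat) & !grepl("[^a-z]", flat) & !(flat %in% stopwords)
    grp <- rep.int(seq_along(n_per), n_per)
    list(tokens = flat[keep], grp = grp[keep], n_texts = length(x))
  } else {
    list(tokens = character(0), grp = integer(0), n_texts = length(x))
  }
}
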