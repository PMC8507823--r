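#' Bundled text resources
#'
#' The package ships small plain-text resources used by the scoring and
#' simulation modules:
#' \describe{
#'   \item{emotion lexicon}{`emotion_lexicon.tsv`, two tab-separated
#'     columns `word`, `emotion`; each lowercase word maps to exactly
#'     one of anger, fear, happiness, sadness, surprise. This is a
#'     small curated list assembled for this package (the dictionary of
#'     the original third-party emotion tool is not redistributable);
#'     absolute emotion levels therefore depend on the lexicon chosen.}
#'   \item{stopwords}{`stopwords_en.txt`, one lowercase word per line.}
#'   \item{contractions / shortcuts}{`contractions.tsv`, columns
#'     `form`, `expansion`; applied token-wise after lowercasing.}
#'   \item{emoji map}{`emoji_map.tsv`, columns `emoji`, `word`.}
#'   \item{neutral vocabulary}{`neutral_words.txt`, words carrying no
#'     lexicon emotion, used by the corpus generator.}
#' }
#'
#' @param path Path to a resource file; defaults to the bundled one.
#' @return `load_lexicon()`: a named character vector mapping word to
#'   emotion label, with attribute `provenance`. `load_stopwords()` and
#'   `load_neutral_words()`: character vectors. `load_contractions()`
#'   and `load_emoji_map()`: named character vectors (name = form,
#'   value = expansion).
#' @name resources
NULL

res_file <- function(name) {
  p <- system.file("extdata", name, package = "teenits")
  if (!nzchar(p)) stop("bundled resource not found: ", name)
  p
}

#' @rdname resources
#' @export
load_lexicon <- function(path = res_file("emotion_lexicon.tsv")) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                  quote = "", comment.char = "")
  if (!all(c("word", "emotion") %in% names(d)))
    stop("lexicon must have columns 'word' and 'emotion'")
  w <- tolower(trimws(d$word))
  e <- tolower(trimws(d$emotion))
  bad <- setdiff(unique(e), EMOTIONS)
  if (length(bad)) stop("unknown emotion labels: ", paste(bad, collapse = ", "))
  if (anyDuplicated(w))
    stop("lexicon words must map to exactly one emotion; duplicated: ",
         paste(unique(w[duplicated(w)]), collapse = ", "))
  missing <- setdiff(EMOTIONS, unique(e))
  if (length(missing))
    stop("lexicon has no words for: ", paste(missing, collapse = ", "))
  lex <- setNames(e, w)
  attr(lex, "provenance") <- paste0("teenits curated lexicon (", basename(path), ")")
  lex
}

#' @rdname resources
#' @export
load_stopwords <- function(path = res_file("stopwords_en.txt")) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- tolower(trimws(x))
  x[nzchar(x)]
}

#' @rdname resources
#' @export
load_contractions <- function(path = res_file("contractions.tsv")) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                  quote = "", comment.char = "")
  setNames(tolower(trimws(d$expansion)), tolower(trimws(d$form)))
}

#' @rdname resources
#' @export
load_emoji_map <- function(path = res_file("emoji_map.tsv")) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                  quote = "", comment.char = "", fileEncoding = "UTF-8")
  setNames(tolower(trimws(d$word)), trimws(d$emoji))
}

#' @rdname resources
#' @export
load_neutral_words <- function(path = res_file("neutral_words.txt")) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- tolower(trimws(x))
  x[nzchar(x)]
}

#' Load the bundled pandemic-timeline annotation table
#'
#' A static (week, label) table of notable 2020 events used only to
#' annotate plots; it plays no analytic role.
#'
#' @param path CSV path; defaults to the bundled file.
#' @return data.frame with columns `week` (integer) and `label`.
#' @export
load_event_annotations <- function(path = res_file("pandemic_events_2020.csv")) {
  read.csv(path, stringsAsFactors = FALSE)
}

# emotion label order used everywhere
EMOTIONS <- c("anger", "fear", "happiness", "sadness", "surprise")

# author placeholder for removed accounts
DELETED_MARKER <- "[deleted]"

# community identifiers: one general teen community, three MH communities
COMMUNITIES <- c("teen", "depression", "anxiety", "suicidewatch")
MH_COMMUNITIES <- c("depression", "anxiety", "suicidewatch")
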