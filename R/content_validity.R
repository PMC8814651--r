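#' @title Content validity indices and readability
#' @description Expert content-validity indices on a 4-point relevance scale
#'   and the Flesch reading-ease formula.
#' @name content-validity
NULL

#' Item content validity index (I-CVI)
#'
#' Proportion of experts rating the item 3 or 4 on the 4-point relevance
#' scale (1 = not relevant, 4 = very relevant).
#'
#' @param ratings Integer vector of ratings in 1-4, one per expert.
#' @return Fraction in 0-1 (always a multiple of `1/length(ratings)`).
#' @export
item_cvi <- function(ratings) {
  ratings <- as.numeric(ratings)
  if (length(ratings) < 1L) stop("at least one expert rating is required")
  if (anyNA(ratings) || any(ratings < 1 | ratings > 4 | ratings != round(ratings)))
    stop("ratings must be integers in 1-4")
  mean(ratings >= 3)
}

#' Scale content validity index (S-CVI)
#'
#' Arithmetic mean of the item content validity indices.
#'
#' @param item_cvis Numeric vector of I-CVI values in 0-1.
#' @return Fraction in 0-1.
#' @export
scale_cvi <- function(item_cvis) {
  item_cvis <- as.numeric(item_cvis)
  if (length(item_cvis) < 1L) stop("at least one item I-CVI is required")
  if (anyNA(item_cvis) || any(item_cvis < 0 | item_cvis > 1))
    stop("I-CVI values must lie in [0, 1]")
  mean(item_cvis)
}

#' Relevance flags against the published CVI thresholds
#'
#' An item counts as relevant when its I-CVI is at least 0.78; the scale
#' counts as relevant when the S-CVI is at least 0.9.
#'
#' @param icvis Numeric vector of item CVIs.
#' @param scvi Scale CVI; defaults to the mean of `icvis`.
#' @return List with `item_relevant` (logical vector), `scale_relevant`
#'   (logical), and the thresholds used.
#' @export
cvi_flags <- function(icvis, scvi = scale_cvi(icvis)) {
  if (any(icvis < 0 | icvis > 1) || scvi < 0 || scvi > 1)
    stop("CVI values must lie in [0, 1]")
  list(item_relevant = icvis >= 0.78,
       scale_relevant = scvi >= 0.9,
       item_threshold = 0.78,
       scale_threshold = 0.9)
}

#' CVI summary of an expert rating matrix
#'
#' @param ratings Matrix or data.frame, rows = experts, columns = items,
#'   entries in 1-4.
#' @return List with per-item `icvi` (named, rounded copies in `icvi_2dp`),
#'   `scvi`, and the [cvi_flags()] output.
#' @export
expert_cvi <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("expert rating matrix has missing cells")
  icvi <- apply(m, 2L, item_cvi)
  scvi <- scale_cvi(icvi)
  list(icvi = icvi, icvi_2dp = round(icvi, 2L),
       scvi = scvi, scvi_2dp = round(scvi, 2L),
       flags = cvi_flags(icvi, scvi),
       n_experts = nrow(m))
}

#' Read an expert rating matrix from CSV (rows = experts, columns = items)
#' @param path CSV file path.
#' @return Integer matrix.
#' @export
read_expert_ratings <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, encoding = "UTF-8")
  if ("expert_id" %in% names(df)) df$expert_id <- NULL
  as.matrix(df)
}

#' Published per-item I-CVI values of an instrument
#'
#' Extracts the expert-panel tallies carried in the instrument metadata and
#' returns exact I-CVI fractions per item.
#'
#' @param inst An `iflt_instrument` whose items carry `icvi` tallies.
#' @return Named numeric vector of I-CVI fractions.
#' @export
instrument_icvi <- function(inst) {
  tallies <- lapply(inst$items, `[[`, "icvi")
  if (any(vapply(tallies, is.null, logical(1))))
    stop("instrument does not carry expert content-validity tallies")
  vapply(tallies, function(t) t[["relevant"]] / t[["total"]], numeric(1))
}

#' Flesch reading ease
#'
#' `206.835 - 1.015 * (words / sentences) - 84.6 * (syllables / words)`.
#' Higher is easier; 70-80 is considered fairly easy for the average adult.
#' The score depends only on the two ratios (words per sentence and
#' syllables per word).
#'
#' @param total_words,total_sentences,total_syllables Counts; alternatively
#'   pass `text` and the counts are derived with the approximate
#'   [count_syllables()] heuristic.
#' @param text Optional raw text.
#' @return List with `score` and an interpretation `band` (`"fairly easy"`
#'   when the score lies in \[70, 80\]).
#' @export
flesch_reading_ease <- function(total_words = NULL, total_sentences = NULL,
                                total_syllables = NULL, text = NULL) {
  if (!is.null(text)) {
    counts <- readability_counts(text)
    total_words <- counts$total_words
    total_sentences <- counts$total_sentences
    total_syllables <- counts$total_syllables
  }
  if (is.null(total_words) || is.null(total_sentences) || is.null(total_syllables))
    stop("provide either text or all three counts")
  if (total_sentences < 1) stop("total_sentences must be at least 1")
  if (total_words < total_sentences) stop("total_words must be >= total_sentences")
  if (total_syllables < total_words) stop("total_syllables must be >= total_words")
  score <- 206.835 - 1.015 * (total_words / total_sentences) -
    84.6 * (total_syllables / total_words)
  band <- if (score >= 70 && score <= 80) "fairly easy"
  else if (score > 80) "easy" else "difficult"
  list(score = score, band = band,
       words_per_sentence = total_words / total_sentences,
       syllables_per_word = total_syllables / total_words)
}

#' Approximate syllable and word counts for raw text
#'
#' Vowel-group heuristic: a syllable is a maximal run of vowel characters
#' (aeiouy, including common accented forms); every word counts at least one
#' syllable. Sentences are split on `.`, `!` and `?`. Clearly approximate --
#' language-specific hyphenation rules are out of scope.
#'
#' @param text Character vector (concatenated).
#' @return List with `total_words`, `total_sentences`, `total_syllables`.
#' @export
readability_counts <- function(text) {
  text <- paste(text, collapse = " ")
  sentences <- strsplit(text, "[.!?]+")[[1]]
  sentences <- sentences[grepl("[[:alnum:]]", sentences)]
  words <- regmatches(text, gregexpr("[[:alpha:]']+", text))[[1]]
  if (length(words) == 0L) stop("text contains no words")
  syll <- vapply(words, count_syllables, numeric(1), USE.NAMES = FALSE)
  list(total_words = length(words),
       total_sentences = max(1L, length(sentences)),
       total_syllables = sum(syll))
}

#' @rdname readability_counts
#' @param word A single word.
#' @export
count_syllables <- function(word) {
  groups <- gregexpr("[aeiouy\u00e0-\u00e6\u00e8-\u00ef\u00f2-\u00f6\u00f9-\u00fc]+",
                     tolower(word))[[1]]
  max(1L, sum(groups > 0L))
}
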