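# Readability scoring for parliamentary speeches: tokenisation, syllable
# counting, Flesch / Flesch-Kincaid / RIX, and the sample filters (chair
# exclusion, <25-word drop).

# Fixed abbreviation list whose trailing period never terminates a sentence.
.ABBREVIATIONS <- c("Dr.", "Mr.", "Mrs.", "St.", "No.", "etc.")

stop_unscorable <- function(msg) {
  stop(errorCondition(paste0("unscorable speech: ", msg),
                      class = c("parlheat_unscorable", "error", "condition")))
}

#' Split a speech into sentences
#'
#' Sentences end at `.`, `!`, `?` or `;` followed by whitespace and a
#' capital letter, or at end of text. The trailing period of a small fixed
#' abbreviation list (`Dr.`, `Mr.`, `Mrs.`, `St.`, `No.`, `etc.`) never
#' terminates a sentence. The rule set is deliberately deterministic so
#' that token counts are reproducible.
#'
#' @param text A single character string.
#' @return Character vector of sentences, in order, length >= 1.
#' @examples
#' segment_sentences("I agree. We must act.")
#' @export
segment_sentences <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("`text` must be a single non-NA character string")
  }
  squished <- gsub("\\s+", " ", trimws(text))
  if (!nzchar(squished)) stop_unscorable("empty text")
  protected <- squished
  for (ab in .ABBREVIATIONS) {
    protected <- gsub(ab, sub("\\.$", "\x01", ab), protected, fixed = TRUE)
  }
  parts <- strsplit(protected, "(?<=[.!?;])\\s+(?=[A-Z])", perl = TRUE)[[1]]
  parts <- gsub("\x01", ".", parts, fixed = TRUE)
  parts <- parts[nzchar(trimws(parts))]
  if (!length(parts)) stop_unscorable("no sentences")
  parts
}

#' Count syllables in words
#'
#' Heuristic, English-oriented counter: maximal vowel groups (`aeiouy`)
#' are counted, one is subtracted for a terminal silent `e` (unless the
#' word ends in `le` preceded by a consonant), and the result is floored
#' at 1. Tokens without alphabetic characters (numerals) count as one
#' syllable. The counter is the single source of syllable truth in the
#' package: the synthetic text generator annotates its lexicon with it,
#' which makes scorer round trips exact by construction.
#'
#' @param word Character vector of tokens.
#' @return Integer vector of syllable counts, all >= 1.
#' @examples
#' count_syllables(c("act", "temperature", "a"))
#' @export
count_syllables <- function(word) {
  if (!length(word)) return(integer(0))
  letters_only <- gsub("[^a-z]", "", tolower(as.character(word)))
  vapply(letters_only, function(x) {
    if (!nzchar(x)) return(1L)
    groups <- gregexpr("[aeiouy]+", x)[[1]]
    k <- if (groups[1L] == -1L) 0L else length(groups)
    if (grepl("[^aeiouy]e$", x) && !grepl("[^aeiou]le$", x)) k <- k - 1L
    max(k, 1L)
  }, integer(1), USE.NAMES = FALSE)
}

# Word tokens: alphanumeric runs, internal apostrophes/hyphens kept.
tokenize_words <- function(text) {
  m <- gregexpr("[[:alnum:]]+(?:['\u2019-][[:alnum:]]+)*", text, perl = TRUE)
  regmatches(text, m)[[1]]
}

# "Long word" = strictly more than 6 letters, counting letters only.
.is_long_word <- function(tokens) {
  nchar(gsub("[^[:alpha:]]", "", tokens)) > 6L
}

#' Token counts for one speech
#'
#' Container holding the four counts all complexity scores are built
#' from. Invariants are validated: `long_words <= total_words`, and
#' every word has at least one syllable.
#'
#' @param total_words Nonnegative integer.
#' @param total_sentences Positive integer.
#' @param total_syllables Nonnegative integer.
#' @param long_words Nonnegative integer, words with more than 6 letters.
#' @return An object of class `token_counts`.
#' @export
token_counts <- function(total_words, total_sentences, total_syllables,
                         long_words) {
  stopifnot(total_words >= 0, total_sentences >= 1,
            total_syllables >= 0, long_words >= 0,
            long_words <= total_words)
  if (total_words > 0 && total_syllables < total_words) {
    stop("total_syllables must be >= total_words (every word has >= 1 syllable)")
  }
  structure(list(total_words = as.integer(total_words),
                 total_sentences = as.integer(total_sentences),
                 total_syllables = as.integer(total_syllables),
                 long_words = as.integer(long_words)),
            class = "token_counts")
}

#' @export
print.token_counts <- function(x, ...) {
  cat(sprintf("<token_counts> words=%d sentences=%d syllables=%d long_words=%d\n",
              x$total_words, x$total_sentences, x$total_syllables, x$long_words))
  invisible(x)
}

#' Tokenise a speech and count words, sentences, syllables, long words
#'
#' @param text A single character string.
#' @return A [token_counts()] object.
#' @examples
#' tokenize_and_count("I agree. We must act.")
#' @export
tokenize_and_count <- function(text) {
  sentences <- segment_sentences(text)
  tokens <- tokenize_words(paste(sentences, collapse = " "))
  if (!length(tokens)) stop_unscorable("no word tokens")
  token_counts(total_words = length(tokens),
               total_sentences = length(sentences),
               total_syllables = sum(count_syllables(tokens)),
               long_words = sum(.is_long_word(tokens)))
}

# Accept a token_counts object, a list, or a data.frame of count columns.
.as_count_frame <- function(counts, need_long = FALSE) {
  if (inherits(counts, "token_counts")) counts <- unclass(counts)
  if (!is.data.frame(counts)) counts <- as.data.frame(counts)
  req <- c("total_words", "total_sentences", "total_syllables")
  if (need_long) req <- c(req, "long_words")
  missing <- setdiff(req, names(counts))
  if (length(missing)) {
    stop("missing count fields: ", paste(missing, collapse = ", "))
  }
  counts
}

#' Flesch reading-ease score
#'
#' `206.835 - 1.015 * (words/sentences) - 84.6 * (syllables/words)`.
#' Higher values mean easier text; typical range roughly 0-100.
#'
#' @param counts A [token_counts()] object, or a list/data.frame with
#'   columns `total_words`, `total_sentences`, `total_syllables`
#'   (vectorised).
#' @return Numeric vector of scores.
#' @examples
#' flesch_score(token_counts(100, 5, 150, 20))  # 59.635
#' @export
flesch_score <- function(counts) {
  cf <- .as_count_frame(counts)
  if (any(cf$total_words <= 0) || any(cf$total_sentences <= 0)) {
    stop_unscorable("zero words or sentences")
  }
  206.835 - 1.015 * (cf$total_words / cf$total_sentences) -
    84.6 * (cf$total_syllables / cf$total_words)
}

#' Flesch-Kincaid grade level
#'
#' `0.39 * (words/sentences) + 11.8 * (syllables/words) - 15.59`,
#' expressing complexity as US school-grade years; higher = more complex.
#'
#' @inheritParams flesch_score
#' @return Numeric vector of grade levels.
#' @examples
#' flesch_kincaid_score(token_counts(100, 5, 150, 20))  # 9.91
#' @export
flesch_kincaid_score <- function(counts) {
  cf <- .as_count_frame(counts)
  if (any(cf$total_words <= 0) || any(cf$total_sentences <= 0)) {
    stop_unscorable("zero words or sentences")
  }
  0.39 * (cf$total_words / cf$total_sentences) +
    11.8 * (cf$total_syllables / cf$total_words) - 15.59
}

#' RIX readability index
#'
#' Long words (more than 6 letters) per sentence. Robust to
#' syllabification and hence comparable across languages.
#'
#' @param counts A [token_counts()] object, or a list/data.frame with
#'   columns `long_words` and `total_sentences` (vectorised).
#' @return Numeric vector of scores.
#' @examples
#' rix_score(token_counts(100, 4, 150, 12))  # 3
#' @export
rix_score <- function(counts) {
  cf <- .as_count_frame(counts, need_long = TRUE)
  if (any(cf$total_sentences <= 0)) stop_unscorable("zero sentences")
  cf$long_words / cf$total_sentences
}

#' All complexity scores for a set of counts
#'
#' @inheritParams rix_score
#' @return A data.frame with columns `flesch`, `flesch_kincaid`, `rix`,
#'   `avg_sentence_length`, `avg_word_syllables`.
#' @export
complexity_scores <- function(counts) {
  cf <- .as_count_frame(counts, need_long = TRUE)
  data.frame(flesch = flesch_score(cf),
             flesch_kincaid = flesch_kincaid_score(cf),
             rix = rix_score(cf),
             avg_sentence_length = cf$total_words / cf$total_sentences,
             avg_word_syllables = cf$total_syllables / cf$total_words)
}

# Word count per speech row, from count columns when present, else text.
.speech_word_counts <- function(speeches) {
  if ("total_words" %in% names(speeches)) {
    return(speeches$total_words)
  }
  if (!"text" %in% names(speeches)) {
    stop("speeches need either a `total_words` column or a `text` column")
  }
  vapply(speeches$text, function(tx) {
    if (is.na(tx)) return(NA_integer_)
    length(tokenize_words(tx))
  }, integer(1), USE.NAMES = FALSE)
}

#' Apply the sample filters: drop chairs and speeches shorter than 25 words
#'
#' Speeches by parliamentary chairs are interjection-heavy and are
#' excluded; speeches shorter than 25 words (strictly) are dropped to
#' filter out interjections and short questions. Each dropped speech is
#' logged with a reason.
#'
#' @param speeches data.frame with columns `speech_id`, `is_chair`, and
#'   either `total_words` or `text`.
#' @param min_words Word threshold; retained speeches have at least this
#'   many words (default 25).
#' @return List with `retained` (the surviving rows) and `exclusions`
#'   (data.frame of `speech_id`, `reason`).
#' @export
filter_speeches <- function(speeches, min_words = 25L) {
  stopifnot(is.data.frame(speeches))
  if (!nrow(speeches)) {
    return(list(retained = speeches,
                exclusions = data.frame(speech_id = character(0),
                                        reason = character(0))))
  }
  if (!"is_chair" %in% names(speeches)) {
    stop("speeches need an `is_chair` column")
  }
  wc <- .speech_word_counts(speeches)
  chair <- as.logical(speeches$is_chair)
  short <- !chair & (is.na(wc) | wc < min_words)
  reason <- rep(NA_character_, nrow(speeches))
  reason[chair] <- "chair"
  reason[short] <- "short"
  keep <- !chair & !short
  list(retained = speeches[keep, , drop = FALSE],
       exclusions = data.frame(
         speech_id = as.character(speeches$speech_id[!keep]),
         reason = reason[!keep],
         stringsAsFactors = FALSE))
}

#' Score a table of speeches
#'
#' Adds token counts and complexity scores to a speech table. Rows whose
#' text is unscorable (empty after tokenisation) are excluded and logged
#' rather than scored zero, so that the outcome distribution is not
#' polluted. Rows already carrying count columns (`total_words`,
#' `total_sentences`, `total_syllables`, `long_words`) are scored from
#' those; otherwise `text` is tokenised.
#'
#' @param speeches data.frame with a `speech_id` column plus either
#'   precomputed count columns or `text`.
#' @return List with `scored` (input augmented with counts and the five
#'   score columns) and `exclusions` (data.frame `speech_id`, `reason`).
#' @export
score_speeches <- function(speeches) {
  stopifnot(is.data.frame(speeches), nrow(speeches) >= 0)
  count_cols <- c("total_words", "total_sentences", "total_syllables",
                  "long_words")
  if (all(count_cols %in% names(speeches))) {
    cf <- speeches[count_cols]
    bad <- cf$total_words <= 0 | cf$total_sentences <= 0 |
      is.na(cf$total_words) | is.na(cf$total_sentences)
  } else {
    if (!"text" %in% names(speeches)) {
      stop("speeches need count columns or a `text` column")
    }
    counted <- lapply(speeches$text, function(tx) {
      tryCatch(unclass(tokenize_and_count(tx)),
               parlheat_unscorable = function(e) NULL)
    })
    bad <- vapply(counted, is.null, logical(1))
    cf <- data.frame(total_words = NA_integer_,
                     total_sentences = NA_integer_,
                     total_syllables = NA_integer_,
                     long_words = NA_integer_)[rep(1L, nrow(speeches)), ,
                                               drop = FALSE]
    if (any(!bad)) {
      cf[!bad, ] <- do.call(rbind, lapply(counted[!bad], as.data.frame))
    }
    speeches <- cbind(speeches, cf)
  }
  scored <- speeches[!bad, , drop = FALSE]
  if (nrow(scored)) {
    scored <- cbind(scored, complexity_scores(scored[count_cols]))
  } else {
    scored <- cbind(scored,
                    data.frame(flesch = numeric(0), flesch_kincaid = numeric(0),
                               rix = numeric(0), avg_sentence_length = numeric(0),
                               avg_word_syllables = numeric(0)))
  }
  rownames(scored) <- NULL
  list(scored = scored,
       exclusions = data.frame(
         speech_id = as.character(speeches$speech_id[bad]),
         reason = rep("unscorable", sum(bad)),
         stringsAsFactors = FALSE))
}
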