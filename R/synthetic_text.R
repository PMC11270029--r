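# Synthetic speech text at controlled complexity. Words are drawn from
# a lexicon annotated with the package's own syllable counter, so that
# re-scoring generated text reproduces the targets exactly (sentence
# length) or to rounding (syllables per word).

# Candidate vocabulary; grouped by syllable count at first use, using
# count_syllables() itself as the annotator.
.LEXICON_WORDS <- c(
  "act", "vote", "law", "tax", "plan", "day", "speech", "point", "bill",
  "house", "state", "trade", "debt", "fund", "school", "road", "court",
  "first", "strong", "clear", "fair", "raise", "spend", "work", "claim",
  "budget", "member", "order", "reform", "public", "question", "reason",
  "data", "ruling", "party", "leader", "motion", "taxes", "housing",
  "voters", "senate", "chamber", "justice", "payment", "measure",
  "policy", "economy", "minister", "committee", "agreement", "amendment",
  "parliament", "industry", "citizens", "families", "energy", "pension",
  "education", "employment", "community", "majority", "authority",
  "development", "agriculture", "infrastructure", "responsibility",
  "administration", "representative", "constitutional", "environmental",
  "democracy", "referendum", "delivery", "security", "emergency",
  "obligatory", "population", "legislation", "opposition")

.lexicon_env <- new.env(parent = emptyenv())

#' Lexicon for the synthetic text generator
#'
#' Words grouped by syllable count (1 through 5), annotated by
#' [count_syllables()] so that generator and scorer agree by
#' construction. Non-alphabetic candidates are excluded.
#'
#' @return Named list `"1"` ... `"5"` of character vectors.
#' @export
default_lexicon <- function() {
  if (!is.null(.lexicon_env$lex)) return(.lexicon_env$lex)
  words <- .LEXICON_WORDS[grepl("^[a-z]+$", .LEXICON_WORDS)]
  syl <- count_syllables(words)
  keep <- syl >= 1 & syl <= 5
  lex <- split(words[keep], syl[keep])
  if (!all(as.character(1:5) %in% names(lex))) {
    stop("lexicon must span 1-5 syllables")  # guards vocabulary edits
  }
  .lexicon_env$lex <- lex
  lex
}

#' Generate text with target sentence length and syllable density
#'
#' Emits `n_words` words arranged in sentences so that the re-scored
#' average sentence length is within 0.1 of `target_asl` (exact when
#' `n_words` is a multiple of the implied sentence count) and the
#' average syllables per word within 0.05 of `target_asw`. Sentences
#' start with a capital and end with a period, matching the package's
#' segmentation rules.
#'
#' @param target_asl Target words per sentence, >= 1.
#' @param target_asw Target syllables per word, in `[1, 5]`.
#' @param n_words Number of words to emit.
#' @param lexicon A syllable-grouped lexicon, see [default_lexicon()].
#' @param seed Integer seed, or `NULL` for the current RNG stream.
#' @return A single character string.
#' @examples
#' txt <- generate_text(20, 1.5, 100, seed = 7)
#' flesch_kincaid_score(tokenize_and_count(txt))  # ~9.91
#' @export
generate_text <- function(target_asl, target_asw, n_words,
                          lexicon = default_lexicon(), seed = NULL) {
  stopifnot(target_asl >= 1, target_asw >= 1, n_words >= 1)
  if (!is.null(seed)) .set_fixed_rng(seed)
  n_sent <- max(1L, as.integer(round(n_words / target_asl)))
  if (abs(n_words / n_sent - target_asl) > 0.1) {
    stop(sprintf(
      "target ASL %.3f unreachable with %d words (closest achievable %.3f)",
      target_asl, n_words, n_words / n_sent))
  }
  max_syl <- max(as.integer(names(lexicon)))
  total_syl <- as.integer(round(target_asw * n_words))
  if (total_syl < n_words || total_syl > max_syl * n_words) {
    stop("target ASW unreachable with this lexicon")
  }
  # distribute words across sentences as evenly as possible
  base_len <- n_words %/% n_sent
  lens <- rep(base_len, n_sent)
  extra <- n_words - base_len * n_sent
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  # distribute syllables: start at 1 per word, sprinkle the surplus
  syl <- rep(1L, n_words)
  surplus <- total_syl - n_words
  while (surplus > 0L) {
    room <- which(syl < max_syl)
    pick <- room[sample.int(length(room), min(surplus, length(room)))]
    add <- pmin(max_syl - syl[pick], 1L)
    syl[pick] <- syl[pick] + add
    surplus <- surplus - sum(add)
  }
  words <- vapply(syl, function(s) {
    pool <- lexicon[[as.character(s)]]
    pool[sample.int(length(pool), 1L)]
  }, character(1))
  stops <- cumsum(lens)
  starts <- c(1L, head(stops, -1L) + 1L)
  sentences <- vapply(seq_len(n_sent), function(i) {
    w <- words[starts[i]:stops[i]]
    w[1L] <- paste0(toupper(substr(w[1L], 1L, 1L)),
                    substr(w[1L], 2L, nchar(w[1L])))
    paste0(paste(w, collapse = " "), ".")
  }, character(1))
  paste(sentences, collapse = " ")
}

#' Attach generated text matching each speech's numeric outcome
#'
#' For pipelines exercised end to end on synthetic data: converts each
#' speech's numeric Flesch-Kincaid outcome into achievable integer
#' sentence/syllable targets (at a fixed syllables-per-word density) and
#' generates matching text. The re-scored outcome reproduces the numeric
#' one up to integer rounding of the targets.
#'
#' @param speeches Speech table with a `flesch_kincaid` column.
#' @param target_asw Syllables-per-word density used for all speeches.
#' @param sentences_range Range of sentence counts to draw per speech.
#' @param seed Integer seed.
#' @return `speeches` with a `text` column added.
#' @export
attach_speech_text <- function(speeches, target_asw = 1.5,
                               sentences_range = c(3L, 6L), seed = 1L) {
  stopifnot("flesch_kincaid" %in% names(speeches))
  if (!is.null(seed)) .set_fixed_rng(seed)
  lex <- default_lexicon()
  n <- nrow(speeches)
  n_sent <- sample(seq(sentences_range[1L], sentences_range[2L]), n,
                   replace = TRUE)
  # invert the FK formula for the sentence-length target at fixed ASW
  asl <- (speeches$flesch_kincaid + 15.59 - 11.8 * target_asw) / 0.39
  asl <- pmax(asl, 25)  # keep speeches above the 25-word filter
  wps <- pmax(1L, as.integer(round(asl)))
  speeches$text <- vapply(seq_len(n), function(i) {
    nw <- wps[i] * n_sent[i]
    generate_text(target_asl = nw / n_sent[i],
                  target_asw = target_asw, n_words = nw,
                  lexicon = lex, seed = NULL)
  }, character(1))
  speeches
}
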