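# Harmonicity-peak candidate transcription: each harmonicity peak in a
# trial recording is taken to mark one vowel, so the peak count estimates
# how many of the prompted words the speaker actually produced.

#' Transcription rule for peak-count mapping
#'
#' @param syllables_per_word Syllables (vowels, hence harmonicity peaks)
#'   per word; 2 for disyllabic word lists.
#' @param max_words Number of prompted words per trial.
#' @return A `transcription_rule` list.
#' @export
transcription_rule <- function(syllables_per_word = 2, max_words = 8) {
  if (syllables_per_word < 1 || max_words < 1) {
    abort("transcription_rule: both fields must be >= 1")
  }
  structure(list(syllables_per_word = as.integer(syllables_per_word),
                 max_words = as.integer(max_words)),
            class = "transcription_rule")
}

#' Estimated word count from a harmonicity peak count
#'
#' `min(max_words, ceiling(n_peaks / syllables_per_word))`: with
#' disyllabic words and 8 prompted words, 13 or 14 peaks give 7 words and
#' 15 or 16 peaks give all 8. Monotone non-decreasing in the peak count
#' and clamped at the prompted-word maximum.
#'
#' @param n_peaks Non-negative integer vector of harmonicity peak counts
#'   (one per trial).
#' @param rule A [transcription_rule()].
#' @return Integer vector of estimated word counts.
#' @export
peaks_to_word_count <- function(n_peaks, rule = transcription_rule()) {
  if (any(n_peaks < 0)) abort("peaks_to_word_count: n_peaks must be >= 0")
  as.integer(pmin(rule$max_words,
                  ceiling(n_peaks / rule$syllables_per_word)))
}

#' Candidate transcription: the produced word prefix
#'
#' Speakers who drop words overwhelmingly drop them from the end of the
#' prompted sequence, so the candidate transcription for a trial with an
#' estimated `n_words` produced words is simply the first `n_words`
#' prompted words, in order.
#'
#' @param prompted_words Ordered character vector of prompted words.
#' @param n_words How many words to keep (`0 <= n_words <=
#'   length(prompted_words)`).
#' @return Character vector of the first `n_words` prompted words.
#' @export
candidate_transcription <- function(prompted_words, n_words) {
  if (n_words < 0 || n_words > length(prompted_words)) {
    abort(sprintf("n_words = %d outside [0, %d]", n_words,
                  length(prompted_words)))
  }
  head(prompted_words, n_words)
}
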