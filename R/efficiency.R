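# Per-word time aggregation and the rejection-aware bootstrap of
# annotator-hours needed to obtain a target number of well-segmented
# words per modality.

#' Per-word times for the baseline modality
#'
#' The baseline workflow is timed per trial (the Praat script records when
#' a trial was opened and saved), so per-word cost is the trial duration
#' divided by the number of good words the annotator segmented in that
#' trial: each good word of the trial receives an equal share. Trials
#' with zero good words contribute no records (their time is excluded);
#' the number of such dropped trials is attached as attribute
#' `n_zero_word_trials`.
#'
#' @param timing Timing tibble (see [read_timing_csv()]); only
#'   `task == "baseline_trial"` events are used, one event per annotator
#'   per trial.
#' @param good_words_per_trial Named integer vector or two-column data
#'   frame (`unit_id`, `n_good`) giving the number of good words per
#'   trial.
#' @return Tibble of word-time records: `word_id`, `modality`,
#'   `total_seconds`, `accepted` (always `TRUE` here).
#' @export
baseline_word_times <- function(timing, good_words_per_trial) {
  validate_timing(timing)
  trials <- timing |> filter(.data$task == "baseline_trial")
  if (is.data.frame(good_words_per_trial)) {
    n_good <- setNames(as.integer(good_words_per_trial$n_good),
                       good_words_per_trial$unit_id)
  } else {
    n_good <- as.integer(good_words_per_trial) |>
      setNames(names(good_words_per_trial))
  }
  dur <- trials$t_end_s - trials$t_start_s
  if (any(dur < 0)) abort("baseline trial with negative duration")
  ng <- n_good[trials$unit_id]
  if (anyNA(ng)) {
    abort(sprintf("no good-word count for trial '%s'",
                  trials$unit_id[which(is.na(ng))[1]]))
  }
  keep <- ng > 0
  n_dropped <- sum(!keep)
  recs <- purrr::pmap(list(trials$unit_id[keep], trials$annotator_id[keep],
                           dur[keep], ng[keep]),
                      function(uid, ann, d, k) {
    tibble(word_id = sprintf("%s@%s_w%d", uid, ann, seq_len(k)),
           modality = "baseline", total_seconds = d / k, accepted = TRUE)
  })
  out <- dplyr::bind_rows(recs)
  attr(out, "n_zero_word_trials") <- n_dropped
  out
}

#' Per-word times for the POnSS modality
#'
#' Sums every interaction with a word candidate -- all triage passes and
#' all retrim passes, across annotators -- into one record per word, and
#' attaches whether the word was ultimately accepted into the finished
#' dataset. Rejected words keep their time: that cost is real and is what
#' the rejection-aware bootstrap accounts for.
#'
#' @param timing Timing tibble; `triage` and `retrim` events are used.
#' @param final_status Named character/logical vector or data frame
#'   (`word_id`/`unit_id`, `accepted`) mapping each word to its final
#'   accepted/rejected status.
#' @return Tibble of word-time records: `word_id`, `modality`,
#'   `total_seconds`, `accepted`.
#' @export
ponss_word_times <- function(timing, final_status) {
  validate_timing(timing)
  events <- timing |> filter(.data$task %in% c("triage", "retrim"))
  if (is.data.frame(final_status)) {
    id_col <- intersect(c("word_id", "unit_id"), names(final_status))[1]
    status <- setNames(final_status$accepted, final_status[[id_col]])
  } else {
    status <- final_status
  }
  if (is.character(status)) status <- status == "accepted"
  agg <- events |>
    group_by(word_id = .data$unit_id) |>
    summarise(total_seconds = sum(.data$t_end_s - .data$t_start_s),
              .groups = "drop")
  acc <- status[agg$word_id]
  if (anyNA(acc)) {
    abort(sprintf("word '%s' has timing events but no final status",
                  agg$word_id[which(is.na(acc))[1]]))
  }
  if (any(agg$total_seconds == 0)) {
    warn(sprintf("%d word(s) with zero total interaction time",
                 sum(agg$total_seconds == 0)))
  }
  agg |> mutate(modality = "ponss", accepted = unname(acc)) |>
    select("word_id", "modality", "total_seconds", "accepted")
}

#' Bootstrap the annotator-hours to reach a target of good words
#'
#' Repeatedly estimates the total time needed to end up with `n_good`
#' accepted words. Each replicate samples words without replacement from
#' the pool (fresh across replicates): for a pool without rejections this
#' is simply the sum over `n_good` sampled words; when the pool contains
#' rejected words (the POnSS case) the replicate starts at `n_good`
#' sampled words and keeps adding random words until it contains `n_good`
#' accepted ones, counting the time of *every* sampled word, rejected
#' ones included. With rejection fraction r the expected replicate total
#' is inflated by roughly 1/(1-r).
#'
#' @param records Word-time tibble from [baseline_word_times()] or
#'   [ponss_word_times()].
#' @param n_good Target number of accepted words per replicate.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return A `bootstrap_hours` tibble: one row per replicate with
#'   `replicate`, `modality`, `n_words_sampled`, `hours`.
#' @export
bootstrap_hours <- function(records, n_good = 5000, n_reps = 1000,
                            seed = NULL) {
  assert_cols(records, c("modality", "total_seconds", "accepted"),
              "word-time records")
  n_pool <- nrow(records)
  n_accepted <- sum(records$accepted)
  if (n_accepted < n_good) {
    abort(sprintf("insufficient accepted pool: %d accepted, %d required",
                  n_accepted, n_good))
  }
  secs <- records$total_seconds
  acc <- records$accepted
  modality <- records$modality[1]
  reps <- with_seed_or_not(seed, {
    purrr::map(seq_len(n_reps), function(r) {
      perm <- sample.int(n_pool)
      # smallest k with n_good accepted among the first k sampled words;
      # k == n_good exactly when no rejected word was drawn early
      k <- which(cumsum(acc[perm]) == n_good)[1]
      idx <- perm[seq_len(k)]
      tibble(replicate = r, modality = modality,
             n_words_sampled = k, hours = sum(secs[idx]) / 3600)
    }) |> dplyr::bind_rows()
  })
  class(reps) <- c("bootstrap_hours", class(reps))
  attr(reps, "n_good") <- as.integer(n_good)
  reps
}

#' Compare two bootstrap hour distributions
#'
#' @param a,b `bootstrap_hours` tibbles for the two modalities with the
#'   same `n_good` target.
#' @return One-row tibble: `mean_diff_hours` (mean of `a` minus mean of
#'   `b`), `pct_reduction` (absolute difference over the larger mean,
#'   in percent), and `cohens_d` (difference over the pooled SD).
#' @export
compare_modalities <- function(a, b) {
  if (!identical(attr(a, "n_good"), attr(b, "n_good")) &&
      !is.null(attr(a, "n_good")) && !is.null(attr(b, "n_good"))) {
    abort("compare_modalities: the two distributions target different n_good")
  }
  ma <- mean(a$hours); mb <- mean(b$hours)
  diff <- ma - mb
  pooled_sd <- sqrt(((nrow(a) - 1) * sd(a$hours)^2 +
                     (nrow(b) - 1) * sd(b$hours)^2) /
                    (nrow(a) + nrow(b) - 2))
  d <- if (pooled_sd == 0) {
    if (diff == 0) 0 else {
      warn("zero pooled SD with nonzero difference; Cohen's d is infinite")
      sign(diff) * Inf
    }
  } else {
    diff / pooled_sd
  }
  tibble(mean_diff_hours = diff,
         pct_reduction = if (max(ma, mb) == 0) 0 else
           100 * abs(diff) / max(ma, mb),
         cohens_d = d)
}

#' Violin plot of bootstrap hour distributions
#'
#' @param object A `bootstrap_hours` tibble (or several row-bound
#'   together, distinguished by `modality`).
#' @param ... Unused.
#' @return A ggplot violin plot of hours by modality.
#' @export
autoplot.bootstrap_hours <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$modality, y = .data$hours,
                                       fill = .data$modality)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = NULL,
                  y = sprintf("annotator-hours to %d good words",
                              attr(object, "n_good") %||% NA_integer_))
}
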