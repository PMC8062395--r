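# Synthetic study generator: complete multi-annotator segmentation
# studies (tokens, true boundaries, two-modality annotations, timing
# logs, harmonicity peak counts) with the statistical structure the
# analyses assume, so every pipeline stage can be exercised without
# corpus data.

WORD_POOL <- c("snavel", "wortel", "vogel", "lepel", "spiegel", "ketel",
               "mossel", "gevel", "tafel", "sleutel", "hamer", "vijzel")

default_error_model <- function() {
  base <- list(
    fast = mixture_spec(sigma = c(1.2, 5, 20), theta = c(0.5, 0.35, 0.15)),
    medium = mixture_spec(sigma = c(1, 4, 15), theta = c(0.5, 0.35, 0.15)),
    slow = mixture_spec(sigma = c(1, 4, 16), theta = c(0.5, 0.35, 0.15)))
  list(ponss = base, baseline = base)
}

#' Configuration for the synthetic study generator
#'
#' Defaults emulate an elicited word-list corpus: trials of 8 prompted
#' disyllabic words spoken at three trained rates, segmented independently
#' in two modalities by small annotator teams. Segmentation error is
#' mixture-distributed per modality x rate cell (identical across
#' modalities by default, i.e. a null modality effect, with wider error
#' for fast speech); word omission grows towards the end of the prompted
#' sequence; a fraction of POnSS words get a second triage pass and a
#' retrim pass, retrim boundary adjustments are partly quantized to the
#' 20-ms keyboard step, and about 5 percent of candidates end up
#' rejected. Interaction durations are log-normal (positive,
#' right-skewed, as human handling times are).
#'
#' @param n_speakers,trials_per_speaker,words_per_trial Study layout;
#'   trials cycle through the three rates.
#' @param rate_word_ms,rate_gap_ms Named mean word durations / inter-word
#'   gaps (ms) per rate.
#' @param omission_probs Per-position omission probabilities, monotone
#'   non-decreasing, length `words_per_trial`.
#' @param annotators Named list with character vectors `ponss` and
#'   `baseline` of annotator ids.
#' @param error_model Nested list `modality -> rate -> [mixture_spec()]`
#'   of deviation distributions.
#' @param quantization_prob,quantization_step Probability that a
#'   retrim-derived POnSS deviation snaps to the nearest multiple of
#'   `quantization_step` ms.
#' @param retrim_fraction Fraction of POnSS words receiving a retrim
#'   pass.
#' @param rejection_prob Probability a POnSS word candidate is rejected.
#' @param double_triage_fraction Fraction of POnSS words triaged twice.
#' @param timing Log-normal duration parameters (`meanlog`/`sdlog`) for
#'   triage and retrim interactions and for per-word baseline trial time.
#' @param seed Integer master seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_speakers = 4, trials_per_speaker = 15,
                             words_per_trial = 8,
                             rate_word_ms = c(fast = 250, medium = 400,
                                              slow = 600),
                             rate_gap_ms = c(fast = 60, medium = 120,
                                             slow = 200),
                             omission_probs = c(0, 0, 0, 0, 0.02, 0.05,
                                                0.1, 0.2),
                             annotators = list(
                               ponss = c("p1", "p2", "p3"),
                               baseline = c("b1", "b2", "b3")),
                             error_model = default_error_model(),
                             quantization_prob = 0.1,
                             quantization_step = 20,
                             retrim_fraction = 0.3,
                             rejection_prob = 0.05,
                             double_triage_fraction = 0.2,
                             timing = list(triage_meanlog = log(3),
                                           triage_sdlog = 0.4,
                                           retrim_meanlog = log(10),
                                           retrim_sdlog = 0.4,
                                           baseline_word_meanlog = log(20),
                                           baseline_word_sdlog = 0.3),
                             seed = 1L) {
  if (length(omission_probs) != words_per_trial) {
    abort("omission_probs must have one entry per prompted word position")
  }
  if (any(omission_probs < 0 | omission_probs > 1) ||
      any(diff(omission_probs) < 0)) {
    abort("omission_probs must lie in [0,1] and be non-decreasing with position")
  }
  for (p in c(quantization_prob, retrim_fraction, rejection_prob,
              double_triage_fraction)) {
    if (p < 0 || p > 1) abort("probabilities must lie in [0, 1]")
  }
  if (quantization_step <= 0) abort("quantization_step must be > 0")
  if (!setequal(names(annotators), MODALITY_LEVELS) ||
      !setequal(names(error_model), MODALITY_LEVELS) ||
      !all(vapply(error_model,
                  function(m) setequal(names(m), RATE_LEVELS), logical(1)))) {
    abort("annotators and error_model must be keyed by modality (and rate)")
  }
  structure(list(n_speakers = n_speakers,
                 trials_per_speaker = trials_per_speaker,
                 words_per_trial = words_per_trial,
                 rate_word_ms = rate_word_ms, rate_gap_ms = rate_gap_ms,
                 omission_probs = omission_probs, annotators = annotators,
                 error_model = error_model,
                 quantization_prob = quantization_prob,
                 quantization_step = quantization_step,
                 retrim_fraction = retrim_fraction,
                 rejection_prob = rejection_prob,
                 double_triage_fraction = double_triage_fraction,
                 timing = timing, seed = as.integer(seed)),
            class = "generator_config")
}

#' Produced word positions for one trial draw
#'
#' Draws which of the prompted positions a (synthetic) speaker actually
#' produced, by independent per-position omission with the configured
#' monotone probabilities. Uses the current RNG stream, so the caller
#' controls seeding.
#'
#' @param config A [generator_config()].
#' @return Integer vector of produced positions (possibly empty).
#' @export
omission_positions <- function(config) {
  n <- config$words_per_trial
  which(runif(n) >= config$omission_probs)
}

#' Generate a complete synthetic segmentation study
#'
#' Lays out words sequentially per trial with rate-dependent durations
#' and gaps, omits later words more often, annotates every produced word
#' in both modalities with mixture-distributed boundary errors
#' (retrim-derived POnSS deviations partly quantized to the keyboard
#' step), builds the POnSS triage/retrim and baseline per-trial timing
#' logs, and counts two harmonicity peaks per produced disyllabic word
#' plus small integer noise. Fully reproducible under `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A list of tibbles: `tokens` (with true boundaries and
#'   produced/retrimmed/rejected flags), `true_boundaries`, `annotations`
#'   (the [read_annotations_csv()] schema), `timing` (the
#'   [read_timing_csv()] schema), `peak_counts`, `final_status` (word
#'   acceptance for [ponss_word_times()]) and `good_words_per_trial`
#'   (for [baseline_word_times()]), plus the `config` echoed back.
#' @examples
#' study <- generate_study(generator_config(n_speakers = 1,
#'                                          trials_per_speaker = 3))
#' dplyr::count(study$annotations, modality, boundary)
#' @export
generate_study <- function(config = generator_config()) {
  with_seed_or_not(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(config) {
  n_trials <- config$n_speakers * config$trials_per_speaker
  trials <- tibble(
    trial_id = sprintf("sp%02d_t%03d",
                       rep(seq_len(config$n_speakers),
                           each = config$trials_per_speaker),
                       seq_len(n_trials)),
    speaker_id = sprintf("sp%02d", rep(seq_len(config$n_speakers),
                                       each = config$trials_per_speaker)),
    rate = RATE_LEVELS[(seq_len(n_trials) - 1L) %% 3L + 1L])

  # prompted words and produced/omitted draw per trial
  tokens <- purrr::pmap(trials, function(trial_id, speaker_id, rate) {
    labels <- sample(WORD_POOL, config$words_per_trial)
    produced_pos <- omission_positions(config)
    tibble(trial_id = trial_id, speaker_id = speaker_id, rate = rate,
           position = seq_len(config$words_per_trial), label = labels,
           produced = seq_len(config$words_per_trial) %in% produced_pos)
  }) |> dplyr::bind_rows() |>
    mutate(token_id = sprintf("%s_w%d", .data$trial_id, .data$position))

  # sequential time layout: produced words only occupy time; each word
  # gets a jittered duration and is preceded by a jittered gap
  tokens <- tokens |>
    mutate(dur = config$rate_word_ms[.data$rate] * runif(dplyr::n(), 0.85, 1.15),
           gap = config$rate_gap_ms[.data$rate] * runif(dplyr::n(), 0.7, 1.3)) |>
    group_by(.data$trial_id) |>
    mutate(onset_true = cumsum(.data$gap + dplyr::lag(.data$dur, default = 0) *
                                 as.integer(dplyr::lag(.data$produced,
                                                       default = FALSE))),
           offset_true = .data$onset_true + .data$dur) |>
    ungroup()

  produced <- tokens |> filter(.data$produced)

  # POnSS word-level workflow flags
  produced <- produced |>
    mutate(retrimmed = runif(dplyr::n()) < config$retrim_fraction,
           rejected = runif(dplyr::n()) < config$rejection_prob,
           double_triaged = runif(dplyr::n()) < config$double_triage_fraction)

  true_boundaries <- produced |>
    select("token_id", "onset_true", "offset_true") |>
    tidyr::pivot_longer(cols = c("onset_true", "offset_true"),
                        names_to = "boundary", values_to = "time_ms") |>
    mutate(boundary = sub("_true", "", .data$boundary))

  # annotation units: produced token x modality x annotator
  units <- purrr::map(MODALITY_LEVELS, function(mod) {
    tidyr::expand_grid(produced,
                       annotator_id = config$annotators[[mod]]) |>
      mutate(modality = mod)
  }) |> dplyr::bind_rows()

  # per-cell mixture deviations for onset and offset independently
  units <- units |>
    group_by(.data$modality, .data$rate) |>
    group_modify(function(df, key) {
      spec <- config$error_model[[key$modality]][[key$rate]]
      df |> mutate(dev_onset = rmixture(nrow(df), spec),
                   dev_offset = rmixture(nrow(df), spec))
    }) |>
    ungroup()

  # keyboard-step quantization: only retrim-derived ponss boundaries
  quantize <- function(dev, eligible) {
    snap <- eligible & runif(length(dev)) < config$quantization_prob
    dev[snap] <- round(dev[snap] / config$quantization_step) *
      config$quantization_step
    dev
  }
  eligible <- units$modality == "ponss" & units$retrimmed
  units$dev_onset <- quantize(units$dev_onset, eligible)
  units$dev_offset <- quantize(units$dev_offset, eligible)

  annotations <- units |>
    mutate(onset = pmax(0, .data$onset_true + .data$dev_onset),
           offset = pmax(.data$offset_true + .data$dev_offset,
                         .data$onset + 1)) |>
    select("token_id", "trial_id", "position", "label", "speaker_id",
           "rate", "modality", "annotator_id", "onset", "offset") |>
    tidyr::pivot_longer(cols = c("onset", "offset"),
                        names_to = "boundary", values_to = "time_ms")

  # --- timing logs -------------------------------------------------------
  tl <- config$timing
  ponss_events <- produced |>
    mutate(n_triage = 1L + as.integer(.data$double_triaged)) |>
    (\(df) tibble(
      unit_id = rep(df$token_id, df$n_triage + df$retrimmed),
      task = unlist(purrr::pmap(list(df$n_triage, df$retrimmed),
                                function(nt, rt) c(rep("triage", nt),
                                                   if (rt) "retrim"))),
      rejected = rep(df$rejected, df$n_triage + df$retrimmed)))() |>
    mutate(
      annotator_id = sample(config$annotators$ponss, dplyr::n(),
                            replace = TRUE),
      modality = "ponss",
      duration = ifelse(.data$task == "triage",
                        rlnorm(dplyr::n(), tl$triage_meanlog, tl$triage_sdlog),
                        rlnorm(dplyr::n(), tl$retrim_meanlog, tl$retrim_sdlog)),
      outcome = dplyr::case_when(
        .data$task == "retrim" ~ "saved",
        .data$rejected ~ "rejected",
        .default = "accepted"))

  n_good <- produced |> count(.data$trial_id, name = "n_good")
  baseline_events <- tidyr::expand_grid(
    n_good, annotator_id = config$annotators$baseline) |>
    mutate(unit_id = .data$trial_id, task = "baseline_trial",
           modality = "baseline",
           duration = vapply(.data$n_good, function(k) {
             sum(rlnorm(k, tl$baseline_word_meanlog, tl$baseline_word_sdlog))
           }, double(1)),
           outcome = "saved") |>
    select(-"trial_id", -"n_good")

  timing <- dplyr::bind_rows(
    ponss_events |> select("unit_id", "annotator_id", "modality", "task",
                           "duration", "outcome"),
    baseline_events) |>
    group_by(.data$annotator_id) |>
    mutate(t_end_s = cumsum(.data$duration),
           t_start_s = .data$t_end_s - .data$duration) |>
    ungroup() |>
    select("unit_id", "annotator_id", "modality", "task", "t_start_s",
           "t_end_s", "outcome")

  peak_counts <- tokens |>
    group_by(.data$trial_id) |>
    summarise(n_produced = sum(.data$produced), .groups = "drop") |>
    mutate(n_peaks = pmax(0L, 2L * .data$n_produced +
                            sample(c(-1L, 0L, 1L), dplyr::n(),
                                   replace = TRUE,
                                   prob = c(0.1, 0.8, 0.1))))

  list(tokens = tokens |> left_join(
         produced |> select("token_id", "retrimmed", "rejected",
                            "double_triaged"),
         by = "token_id"),
       true_boundaries = true_boundaries,
       annotations = validate_annotations(annotations),
       timing = validate_timing(timing),
       peak_counts = peak_counts,
       final_status = produced |>
         transmute(word_id = .data$token_id, accepted = !.data$rejected),
       good_words_per_trial = n_good |> rename(unit_id = "trial_id"),
       config = config)
}
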