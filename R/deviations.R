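#' Median reference times per token and boundary
#'
#' For each word token and boundary (onset/offset) present in the input,
#' computes the median annotated time pooled across *all* annotators and
#' *both* modalities. This pooled median is the reference against which
#' every individual segmentation is scored; pooling both modalities means
#' neither modality's systematic placement defines "truth".
#'
#' Even numbers of contributing annotations use the mean of the two
#' central values. Singleton tokens are retained (their deviation is
#' necessarily zero).
#'
#' @param annotations Annotation tibble (see [read_annotations_csv()]).
#' @return A tibble with columns `token_id`, `boundary`, `median_ms`,
#'   `n_contributing`.
#' @examples
#' ann <- tibble::tibble(
#'   token_id = "w1", annotator_id = c("a", "b", "c"),
#'   modality = c("baseline", "baseline", "ponss"),
#'   boundary = "onset", time_ms = c(100, 102, 104))
#' reference_medians(ann)
#' @export
reference_medians <- function(annotations) {
  assert_cols(annotations, c("token_id", "boundary", "time_ms"),
              "annotation table")
  annotations |>
    group_by(.data$token_id, .data$boundary) |>
    summarise(median_ms = median(.data$time_ms),
              n_contributing = dplyr::n(), .groups = "drop")
}

#' Signed deviations from the median reference
#'
#' One record per annotation: `deviation_ms = time_ms - median_ms` of the
#' matching reference entry, so positive deviations are placements later
#' than the cross-annotator median. The deviation distribution is the
#' object all reliability analyses consume.
#'
#' @param annotations Annotation tibble.
#' @param references Output of [reference_medians()]; computed from
#'   `annotations` when omitted. Every `(token_id, boundary)` in
#'   `annotations` must have a reference entry.
#' @return A tibble with columns `token_id`, `boundary`, `modality`,
#'   `rate` (if present in the input), `annotator_id`, `deviation_ms`.
#' @export
compute_deviations <- function(annotations, references = NULL) {
  assert_cols(annotations,
              c("token_id", "boundary", "modality", "annotator_id", "time_ms"),
              "annotation table")
  if (is.null(references)) references <- reference_medians(annotations)
  joined <- left_join(annotations, references,
                      by = c("token_id", "boundary"))
  if (anyNA(joined$median_ms)) {
    miss <- joined$token_id[which(is.na(joined$median_ms))[1]]
    abort(sprintf("no reference median for token '%s'", miss))
  }
  keep <- intersect(c("token_id", "boundary", "modality", "rate",
                      "annotator_id"), names(joined))
  joined |>
    mutate(deviation_ms = .data$time_ms - .data$median_ms) |>
    select(dplyr::all_of(keep), "deviation_ms")
}

#' Draw a balanced evaluation sample of deviations
#'
#' Samples exactly `per_cell_n` deviation records, without replacement,
#' from every cell of the modality x rate x boundary design (the default
#' cells). With the study's design of 2 modalities, 3 speaking rates, 2
#' boundaries and 300 records per cell this yields the 3600-record
#' evaluation sample used for distribution fitting.
#'
#' @param deviations Deviation tibble from [compute_deviations()].
#' @param per_cell_n Records to draw per cell.
#' @param cells Character vector of stratification columns.
#' @param seed Integer seed; identical seeds reproduce the sample exactly.
#' @return A tibble of sampled deviation records with the cell columns
#'   retained.
#' @export
balanced_sample <- function(deviations, per_cell_n = 300,
                            cells = c("modality", "rate", "boundary"),
                            seed = NULL) {
  assert_cols(deviations, c(cells, "deviation_ms"), "deviation table")
  counts <- deviations |> count(across(dplyr::all_of(cells)))
  too_small <- counts |> filter(.data$n < per_cell_n)
  if (nrow(too_small) > 0) {
    cell_desc <- paste(
      apply(too_small[cells], 1, paste, collapse = "/"),
      sprintf("(%d available, %d requested)", too_small$n, per_cell_n),
      collapse = "; ")
    abort(paste0("undersized cell(s): ", cell_desc))
  }
  with_seed_or_not(seed, {
    deviations |>
      group_by(across(dplyr::all_of(cells))) |>
      slice_sample(n = per_cell_n) |>
      ungroup()
  })
}

#' Histogram of a deviation sample
#'
#' @param deviations Deviation tibble; a `modality` column, when present,
#'   is mapped to fill so the two modalities can be compared.
#' @param binwidth Histogram bin width in ms.
#' @param xlim Plotting range in ms.
#' @return A ggplot object.
#' @export
plot_deviations <- function(deviations, binwidth = 1, xlim = c(-50, 50)) {
  p <- ggplot2::ggplot(deviations,
                       ggplot2::aes(x = .data$deviation_ms)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      binwidth = binwidth, boundary = 0, alpha = 0.6,
      position = "identity") +
    ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::labs(x = "deviation from median reference (ms)", y = "density")
  if ("modality" %in% names(deviations)) {
    p <- p + ggplot2::aes(fill = .data$modality)
  }
  p
}
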