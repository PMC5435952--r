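#' Fuzzy-entropy feature extraction
#'
#' Turns cleaned epochs into the feature representation used for fatigue
#' classification: one row per (subject, epoch time), one fuzzy-entropy value
#' per channel, plus a binary state label (0 = normal, 1 = fatigue).
#' Channels are joined side by side, so an epoch time missing on any channel
#' (e.g. after asymmetric artifact rejection) is dropped entirely rather than
#' imputed; the number of dropped rows is reported.
#'
#' @param epochs Epoch tibble from [segment_epochs()] /
#'   [reject_artifacts()].
#' @param params A [fuzzyen_params()] object governing the entropy.
#' @return A tibble with columns `subject_id`, `epoch_index`,
#'   `fuzzyen_<channel>` (one per channel), `label`. The parameter set is
#'   attached as attribute `params`.
#' @examples
#' rec <- eeg_recording(cbind(FP1 = rnorm(3000), FP2 = rnorm(3000)))
#' rec |> segment_epochs() |> extract_features()
#' @export
extract_features <- function(epochs, params = fuzzyen_params()) {
  stopifnot(inherits(params, "fuzzyen_params"))
  if (nrow(epochs) == 0) {
    warn("no epochs supplied: returning an empty feature table")
    return(structure(
      tibble::tibble(subject_id = character(), epoch_index = integer(),
                     label = integer()),
      params = params))
  }
  if (dplyr::n_distinct(epochs$fs) != 1) {
    abort("epochs mix sampling rates; extract features per rate")
  }
  channels <- sort(unique(epochs$channel))

  long <- epochs |>
    dplyr::mutate(
      fuzzyen = purrr::map_dbl(.data$samples, fuzzy_entropy, params = params),
      label = as.integer(.data$state == "fatigue")
    )

  wide <- long |>
    dplyr::select("subject_id", "state", "label", "epoch_index", "channel",
                  "fuzzyen") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "fuzzyen",
                       names_prefix = "fuzzyen_")

  feat_cols <- paste0("fuzzyen_", channels)
  complete <- stats::complete.cases(wide[feat_cols])
  if (any(!complete)) {
    inform(sprintf("dropped %d epoch time(s) missing on some channel",
                   sum(!complete)))
  }
  out <- wide[complete, , drop = FALSE] |>
    dplyr::select("subject_id", "epoch_index", dplyr::all_of(feat_cols),
                  "label") |>
    dplyr::arrange(.data$subject_id, .data$label, .data$epoch_index)
  structure(out, params = params)
}

feature_cols <- function(features) {
  grep("^fuzzyen_", names(features), value = TRUE)
}

#' Entropy-by-state plot
#'
#' Boxplots of per-epoch fuzzy entropy for the normal and fatigue states,
#' one panel per channel — the visual check that fatigue epochs carry higher
#' entropy than alert epochs.
#'
#' @param features A feature table from [extract_features()].
#' @return A ggplot object.
#' @export
plot_entropy_by_state <- function(features) {
  long <- features |>
    tidyr::pivot_longer(dplyr::all_of(feature_cols(features)),
                        names_to = "channel", values_to = "fuzzyen") |>
    dplyr::mutate(channel = sub("^fuzzyen_", "", .data$channel),
                  state = factor(.data$label, c(0, 1),
                                 c("normal", "fatigue")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$state, y = .data$fuzzyen,
                                     fill = .data$state)) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = NULL, y = "fuzzy entropy") +
    ggplot2::theme_minimal()
}
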