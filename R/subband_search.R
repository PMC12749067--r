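#' Standard sub-band mask set
#'
#' The 19 sub-band combinations routinely screened when selecting frequency
#' bands: the eight single bands, alternating and contiguous groups, and the
#' full sweep.
#'
#' @return A character vector of canonical mask strings.
#' @export
standard_mask_set <- function() {
  c("1000 0000", "0100 0000", "0010 0000", "0001 0000",
    "0000 1000", "0000 0100", "0000 0010", "0000 0001",
    "1010 1010", "0101 0101", "0011 1100", "1100 0000",
    "0000 0011", "1100 0011", "1111 0000", "0000 1111",
    "1001 1100", "1011 1100", "1111 1111")
}

#' Search sub-band combinations for the best classification performance
#'
#' Extracts per-band features for every scan once, then evaluates the given
#' classifier on each candidate sub-band mask using identical Monte-Carlo +
#' k-fold splits (the same plan seed), so rows are directly comparable.
#' Results are ranked by held-out balance rate, ties broken by total
#' accuracy.
#'
#' @param scans A list of labelled [s21_scan()] objects.
#' @param masks Candidate masks (strings or [subband_mask()] objects);
#'   duplicates are removed with a warning. Defaults to
#'   [standard_mask_set()].
#' @param response Label column to classify (default `"density"`).
#' @param classifier A [classifier_spec()].
#' @param plan A [split_plan()]; reused verbatim for every mask.
#' @param n_components FFT components per domain (see [feature_config()]).
#' @return A tibble of class `mw_subband_search`: one row per unique mask
#'   and phase, with `<metric>_mean` / `<metric>_sd` columns, ranked by test
#'   balance rate. The underlying `mw_eval` objects are kept in the
#'   `reports` attribute.
#' @export
subband_search <- function(scans, masks = standard_mask_set(),
                           response = "density",
                           classifier = classifier_spec("svm_rbf"),
                           plan = split_plan(),
                           n_components = 40L) {
  mask_strs <- vapply(masks, function(m) format(subband_mask(m)), character(1))
  if (anyDuplicated(mask_strs)) {
    warning("duplicate masks removed: ",
            paste(unique(mask_strs[duplicated(mask_strs)]), collapse = ", "))
    masks <- masks[!duplicated(mask_strs)]
    mask_strs <- mask_strs[!duplicated(mask_strs)]
  }
  # Per-band features are computed independently per band, so the all-band
  # table is extracted once and each mask just selects its band's columns.
  all_cfg <- feature_config(n_components = n_components,
                            mask = subband_mask("1111 1111"),
                            mode = "per_band")
  full <- feature_table(scans, all_cfg)
  meta_cols <- c("sample_id", "density", "health")
  reports <- list()
  rows <- list()
  for (i in seq_along(masks)) {
    bands <- subband_bands(subband_mask(masks[[i]]))
    keep <- grepl(paste0("_sb(", paste(bands, collapse = "|"), ")_"),
                  names(full))
    sub <- full[c(meta_cols, names(full)[keep])]
    rep <- evaluate_classifier(sub, response, classifier, plan)
    reports[[mask_strs[i]]] <- rep
    agg <- summary_eval(rep)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(mask = mask_strs[i], n_bands = length(bands),
                     phase = agg$phase),
      agg[setdiff(names(agg), "phase")]
    )
  }
  out <- dplyr::bind_rows(rows)
  test_rank <- out |>
    dplyr::filter(.data$phase == "test") |>
    dplyr::arrange(.data$balance_rate_mean, dplyr::desc(.data$total_accuracy_mean))
  out <- out |>
    dplyr::mutate(mask = factor(.data$mask, levels = test_rank$mask)) |>
    dplyr::arrange(.data$mask, dplyr::desc(.data$phase)) |>
    dplyr::mutate(mask = as.character(.data$mask))
  attr(out, "reports") <- reports
  class(out) <- c("mw_subband_search", class(out))
  out
}
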