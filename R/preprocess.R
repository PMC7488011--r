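#' Impute undetected qPCR reactions at the sentinel Ct
#'
#' Assays that never crossed the amplification threshold carry no Ct
#' value; following standard qPCR panel practice they are assigned the
#' sentinel cycle number 45 (the last cycle of the run, i.e. "at or below
#' the detection limit"). Detected entries are untouched.
#'
#' @param ct Long tibble with columns `sample_id`, `mirna_id`, `ct`,
#'   `detected`.
#' @param sentinel Ct value assigned to undetected entries (default 45).
#' @return The same tibble with undetected `ct` set to `sentinel`.
#' @export
#' @examples
#' ct <- tibble::tibble(sample_id = "s1", mirna_id = c("a", "b"),
#'                      ct = c(25, NA), detected = c(TRUE, FALSE))
#' impute_undetected(ct)
impute_undetected <- function(ct, sentinel = 45) {
  stopifnot_cols(ct, c("sample_id", "mirna_id", "ct", "detected"), "ct")
  dplyr::mutate(ct, ct = ifelse(.data$detected, .data$ct, sentinel))
}

#' Filter assays by detection rate
#'
#' Retains assays detected in at least `threshold` of the samples. The
#' default pools all samples across exposure groups; `by_group = TRUE`
#' instead requires the threshold within every group separately.
#'
#' @param ct Long Ct tibble (`sample_id`, `mirna_id`, `detected`).
#' @param threshold Minimum detected fraction, in (0, 1]; the boundary is
#'   inclusive (exactly 80% detected is retained at the default 0.8).
#' @param meta Sample metadata (required for `by_group = TRUE`).
#' @param by_group Apply the threshold within each exposure group.
#' @return A tibble with columns `mirna_id`, `frac_detected`, `retained`,
#'   in the input assay order.
#' @export
filter_expressed <- function(ct, threshold = 0.8, meta = NULL,
                             by_group = FALSE) {
  stopifnot_cols(ct, c("sample_id", "mirna_id", "detected"), "ct")
  if (nrow(ct) == 0) abort("Empty Ct table.")
  if (!(threshold > 0 && threshold <= 1)) {
    abort("`threshold` must be in (0, 1].")
  }
  if (by_group) {
    if (is.null(meta)) abort("`meta` is required when `by_group = TRUE`.")
    tab <- ct |>
      dplyr::left_join(dplyr::select(meta, "sample_id", "group"),
                       by = "sample_id") |>
      dplyr::summarise(frac = mean(.data$detected),
                       .by = c("mirna_id", "group")) |>
      dplyr::summarise(frac_detected = min(.data$frac), .by = "mirna_id")
  } else {
    tab <- dplyr::summarise(ct, frac_detected = mean(.data$detected),
                            .by = "mirna_id")
  }
  order_ids <- unique(ct$mirna_id)
  tab <- tab[match(order_ids, tab$mirna_id), ]
  dplyr::mutate(tab, retained = .data$frac_detected >= threshold)
}

#' Global-mean delta-Ct normalization
#'
#' Normalizes each retained assay's Ct to the average Ct of all retained
#' assays in the same sample: `dct_ij = ct_ij - mean_j(ct_ij)`. This
#' removes per-sample additive technical offsets exactly; each sample's
#' delta-Ct values sum to zero. Lower delta-Ct means more abundant.
#'
#' @param ct Long Ct tibble; imputation must already have been applied
#'   (no missing Ct among retained assays).
#' @param retained Output of [filter_expressed()], or a character vector
#'   of assay ids to keep. `NULL` keeps every assay.
#' @return Long tibble `sample_id`, `mirna_id`, `dct`.
#' @export
#' @examples
#' ct <- tibble::tibble(sample_id = "s1", mirna_id = c("a", "b", "c"),
#'                      ct = c(20, 30, 40), detected = TRUE)
#' global_mean_normalize(ct)
global_mean_normalize <- function(ct, retained = NULL) {
  stopifnot_cols(ct, c("sample_id", "mirna_id", "ct"), "ct")
  keep <- if (is.null(retained)) {
    unique(ct$mirna_id)
  } else if (is.data.frame(retained)) {
    retained$mirna_id[retained$retained]
  } else {
    retained
  }
  if (length(keep) == 0) abort("Retained assay set is empty.")
  sub <- dplyr::filter(ct, .data$mirna_id %in% keep)
  if (anyNA(sub$ct)) {
    abort("Missing Ct among retained assays; run impute_undetected() first.")
  }
  sub |>
    dplyr::mutate(dct = .data$ct - mean(.data$ct), .by = "sample_id") |>
    dplyr::select("sample_id", "mirna_id", "dct")
}
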