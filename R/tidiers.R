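# broom-style methods for the tibble-backed result classes.

#' @export
tidy.mb_stability <- function(x, ...) {
  tibble::as_tibble(unclass_mb(x))
}

#' @export
glance.mb_stability <- function(x, ...) {
  x |>
    dplyr::summarise(
      n_mirnas = dplyr::n_distinct(.data$mirna_id),
      n_iterations = .data$n_iterations[1],
      mean_prop = mean(.data$prop_significant),
      prop_above_half = mean(.data$prop_significant > 0.5),
      .by = c("stratum", "model")
    ) |>
    tibble::as_tibble()
}

#' @export
tidy.mb_effect <- function(x, ...) {
  tibble::as_tibble(unclass_mb(x))
}

#' @export
glance.mb_effect <- function(x, ...) {
  est <- if (!"significant" %in% names(x)) {
    classify_significant_effect(x)
  } else {
    x
  }
  tibble::tibble(
    n_mirnas = dplyr::n_distinct(est$mirna_id),
    n_iterations = est$n_iterations[1],
    n_significant = sum(est$significant),
    median_abs_g = median(abs(est$median_g)),
    median_ci_width = median(est$ci_high - est$ci_low)
  )
}

#' @export
tidy.mb_counts <- function(x, ...) {
  tibble::as_tibble(unclass_mb(x))
}

#' @export
tidy.mb_enrichment <- function(x, ...) {
  tibble::as_tibble(unclass_mb(x))
}

#' @export
glance.mb_enrichment <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_defined = sum(!is.na(x$percent_change)),
    total_exposed = sum(x$count_exposed),
    total_control = sum(x$count_control)
  )
}

unclass_mb <- function(x) {
  class(x) <- setdiff(class(x), c("mb_stability", "mb_effect",
                                  "mb_counts", "mb_enrichment"))
  x
}
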