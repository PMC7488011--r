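#' Hedges' g standardized mean difference
#'
#' `g = J * (mean(x) - mean(y)) / s_p` with the pooled SD
#' `s_p = sqrt(((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2))` and
#' the small-sample bias correction `J = 1 - 3 / (4 (n_x + n_y) - 9)`.
#' By convention `x` is the exposed group and `y` the unexposed
#' reference, and the values are normalized delta-Ct, so positive g means
#' higher Ct, i.e. lower abundance, in the exposed group.
#'
#' @param x,y Numeric vectors with at least 2 observations each.
#' @return Hedges' g. If the pooled SD is zero with equal means, 0; with
#'   unequal means an error is raised.
#' @export
#' @examples
#' hedges_g(c(1, 2, 3), c(2, 3, 4))  # -0.8
hedges_g <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 2 || ny < 2) abort("Both groups need >= 2 observations.")
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  md <- mean(x) - mean(y)
  if (sp2 <= 0) {
    if (md == 0) return(0)
    abort("Zero pooled SD with unequal means: g is undefined.")
  }
  j <- 1 - 3 / (4 * (nx + ny) - 9)
  j * md / sqrt(sp2)
}

# Vectorized Hedges' g across panel columns for one bootstrap draw.
# Zero pooled-SD columns contribute g = 0 (keeps B fixed).
panel_hedges_g <- function(x, ix, iy) {
  nx <- length(ix)
  ny <- length(iy)
  xs <- x[ix, , drop = FALSE]
  ys <- x[iy, , drop = FALSE]
  sx <- colSums(xs)
  sy <- colSums(ys)
  vx <- (colSums(xs^2) - sx^2 / nx) / (nx - 1)
  vy <- (colSums(ys^2) - sy^2 / ny) / (ny - 1)
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
  md <- sx / nx - sy / ny
  j <- 1 - 3 / (4 * (nx + ny) - 9)
  g <- j * md / sqrt(pmax(sp2, 0))
  g[sp2 <= 0 | !is.finite(g)] <- 0
  g
}

#' Bootstrap median effect size with percentile confidence interval
#'
#' For every miRNA, resamples the exposed and reference groups with
#' replacement (each to its own size) for `config$n_iterations`
#' iterations, computes Hedges' g per iteration, and reports the median
#' and the 2.5/97.5 bootstrap percentiles (linear interpolation between
#' order statistics). Iterations with zero pooled SD contribute g = 0.
#'
#' @param dct Normalized expression (long tibble).
#' @param meta Sample metadata.
#' @param group Exposed group (`"HEa"` or `"HEua"`), compared against
#'   `reference`.
#' @param reference Reference group (default `"UE"`).
#' @param time_point Time point to analyze.
#' @param sex `NULL` for the aggregated (composite) sample, or `"M"`/`"F"`.
#' @param config A [bootstrap_config()] (uses the `"effect"` stream).
#' @return Tibble of class `"mb_effect"`: `mirna_id`, `comparison`,
#'   `stratum`, `median_g`, `ci_low`, `ci_high`, `n_iterations`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_mirnas = 10, seed = 2))
#' dct <- global_mean_normalize(impute_undetected(sim$ct))
#' bootstrap_effect_size(dct, sim$meta, "HEa", time_point = 2,
#'                       config = bootstrap_config(100, seed = 1))
bootstrap_effect_size <- function(dct, meta, group, reference = "UE",
                                  time_point, sex = NULL,
                                  config = bootstrap_config()) {
  sub <- filter_stratum(meta, time_point = time_point, sex = sex)
  boot_g_ci(dct, sub,
            x_ids = sort(sub$sample_id[sub$group == group]),
            y_ids = sort(sub$sample_id[sub$group == reference]),
            comparison = paste(group, "vs", reference),
            stratum = stratum_label(sex),
            config = config,
            tag = paste("effect", group, reference,
                        stratum_label(sex), time_point, sep = "|"))
}

# Shared bootstrap-g engine over two explicit sample-id sets.
boot_g_ci <- function(dct, sub, x_ids, y_ids, comparison, stratum, config,
                      tag) {
  if (length(x_ids) < 2 || length(y_ids) < 2) {
    abort(sprintf("Comparison '%s' (%s): both groups need >= 2 samples.",
                  comparison, stratum))
  }
  ids <- c(x_ids, y_ids)
  x <- values_matrix(dplyr::filter(dct, .data$sample_id %in% ids), "dct")
  x <- x[ids, , drop = FALSE]
  px <- seq_along(x_ids)
  py <- length(x_ids) + seq_along(y_ids)
  seed <- stream_seed(config$seed, "effect")
  b <- config$n_iterations
  gmat <- matrix(NA_real_, nrow = b, ncol = ncol(x))
  for (it in seq_len(b)) {
    ix <- px[resample_positions(length(px), seed, it, paste(tag, "x",
                                                            sep = "|"))]
    iy <- py[resample_positions(length(py), seed, it, paste(tag, "y",
                                                            sep = "|"))]
    gmat[it, ] <- panel_hedges_g(x, ix, iy)
  }
  ci <- apply(gmat, 2, quantile, probs = c(0.025, 0.975), names = FALSE,
              type = 7)
  res <- tibble::tibble(
    mirna_id = colnames(x), comparison = comparison, stratum = stratum,
    median_g = apply(gmat, 2, median), ci_low = ci[1, ], ci_high = ci[2, ],
    n_iterations = b
  )
  new_mb_tbl(res, "mb_effect")
}

#' Flag significant bootstrap effect sizes
#'
#' An effect is significant when the 95% bootstrap percentile interval
#' excludes zero; an endpoint exactly at zero is not significant.
#'
#' @param est An effect-size tibble (`ci_low`, `ci_high`).
#' @return The tibble with a logical `significant` column added.
#' @export
classify_significant_effect <- function(est) {
  stopifnot_cols(est, c("ci_low", "ci_high"), "est")
  dplyr::mutate(est, significant = .data$ci_low > 0 | .data$ci_high < 0)
}

#' Flag sex-stratified medians outside the composite interval
#'
#' A sex-stratified median effect size "falls outside" when it is
#' strictly below the composite sample's 95% CI lower bound or strictly
#' above its upper bound for the same miRNA and comparison.
#'
#' @param sex_est Sex-stratified effect-size tibble.
#' @param composite Composite (aggregated) effect-size tibble for the
#'   same comparison.
#' @return `sex_est` with a logical `outside_composite` column.
#' @export
classify_outside_composite <- function(sex_est, composite) {
  stopifnot_cols(sex_est, c("mirna_id", "comparison", "median_g"),
                 "sex_est")
  comp <- dplyr::select(composite, "mirna_id", "comparison",
                        comp_low = "ci_low", comp_high = "ci_high")
  joined <- dplyr::inner_join(sex_est, comp,
                              by = c("mirna_id", "comparison"))
  if (nrow(joined) != nrow(sex_est)) {
    abort("Composite estimates do not cover every miRNA/comparison.")
  }
  joined |>
    dplyr::mutate(outside_composite = .data$median_g < .data$comp_low |
                    .data$median_g > .data$comp_high) |>
    dplyr::select(-"comp_low", -"comp_high")
}

#' Baseline sexual dimorphism in the unexposed group
#'
#' Within unexposed (reference-group) pregnancies only, bootstraps the
#' male-minus-female Hedges' g per miRNA and flags miRNAs whose 95%
#' percentile interval excludes zero. Negative direction means lower
#' delta-Ct (higher abundance is lower Ct, so interpret with the panel's
#' sign convention: negative median = lower values in mothers of males).
#'
#' @param dct Normalized expression.
#' @param meta Sample metadata.
#' @param time_point Time point to analyze.
#' @param group Reference population (default `"UE"`).
#' @param config A [bootstrap_config()].
#' @return Tibble `mirna_id`, `median_g`, `ci_low`, `ci_high`,
#'   `significant`, `direction` (-1/0/+1), class `"mb_effect"`.
#' @export
baseline_dimorphism <- function(dct, meta, time_point, group = "UE",
                                config = bootstrap_config()) {
  sub <- filter_stratum(meta, time_point = time_point, group = group)
  males <- sort(sub$sample_id[sub$sex == "M"])
  females <- sort(sub$sample_id[sub$sex == "F"])
  if (length(males) < 2 || length(females) < 2) {
    abort(sprintf("Group %s needs >= 2 samples of each sex.", group))
  }
  est <- boot_g_ci(dct, sub, males, females,
                   comparison = paste0(group, "-male vs ", group,
                                       "-female"),
                   stratum = "baseline", config = config,
                   tag = paste("dimorphism", group, time_point, sep = "|"))
  est |>
    classify_significant_effect() |>
    dplyr::mutate(direction = sign(.data$median_g) *
                    as.integer(.data$significant))
}
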