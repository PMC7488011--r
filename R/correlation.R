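# Two-sided p-values for Pearson r via the t transform.  Perfect |r| = 1
# is clamped to the smallest positive double; undefined r (constant
# column) is recorded as r = 0, p = 1 so the pair universe stays fixed.
pearson_p <- function(r, n) {
  df <- n - 2
  p <- matrix(1, nrow = nrow(r), ncol = ncol(r),
              dimnames = dimnames(r))
  ok <- is.finite(r) & abs(r) < 1
  t <- abs(r[ok]) * sqrt(df / (1 - r[ok]^2))
  p[ok] <- 2 * pt(t, df, lower.tail = FALSE)
  p[is.finite(r) & abs(r) >= 1] <- .Machine$double.xmin
  diag(p) <- 0
  p
}

# Critical |r| above which the two-sided Pearson p is strictly < alpha.
critical_r <- function(alpha, n) {
  tcrit <- qt(1 - alpha / 2, n - 2)
  sqrt(tcrit^2 / (tcrit^2 + n - 2))
}

#' Pearson correlation matrix with significance
#'
#' Builds the full pairwise Pearson product-moment correlation matrix of
#' a set of samples (e.g. one exposure group at one time point), with
#' two-sided p-values from the t transform (`t = r sqrt((n-2)/(1-r^2))`).
#' Constant columns yield r = 0, p = 1 for all their pairs.
#'
#' @param dct Normalized expression (long tibble), already restricted to
#'   the samples of interest.
#' @param alpha Significance level used to count significant pairs.
#' @return An object of class `"mb_cor"`: a list with the `r` and `p`
#'   matrices, `n` (samples), `alpha` and `n_significant` (unordered
#'   off-diagonal pairs with p < alpha).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_mirnas = 8, seed = 5))
#' dct <- global_mean_normalize(impute_undetected(sim$ct))
#' ids <- sim$meta$sample_id[sim$meta$group == "UE" &
#'                           sim$meta$time_point == 2]
#' cm <- pearson_matrix(dplyr::filter(dct, sample_id %in% ids))
#' count_significant(cm)
pearson_matrix <- function(dct, alpha = 0.05) {
  x <- values_matrix(dct, if ("dct" %in% names(dct)) "dct" else "ct")
  n <- nrow(x)
  if (n < 3) abort("Need at least 3 samples for correlation p-values.")
  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  p <- pearson_p(r, n)
  out <- list(r = r, p = p, n = n, alpha = alpha,
              mirna_ids = colnames(x))
  out$n_significant <- count_significant(out, alpha)
  class(out) <- "mb_cor"
  out
}

#' @export
print.mb_cor <- function(x, ...) {
  cat(sprintf(
    "<mb_cor> %d miRNAs, %d samples, %d significant pairs (alpha = %g)\n",
    length(x$mirna_ids), x$n, x$n_significant, x$alpha))
  invisible(x)
}

#' Count significant correlation pairs
#'
#' Number of unordered off-diagonal miRNA pairs with p strictly below
#' `alpha`.
#'
#' @param summary An `"mb_cor"` object.
#' @param alpha Significance level.
#' @return Integer count.
#' @export
count_significant <- function(summary, alpha = summary$alpha) {
  ut <- upper.tri(summary$p)
  sum(summary$p[ut] < alpha)
}

#' Significant correlation edges
#'
#' @param summary An `"mb_cor"` object.
#' @param alpha Significance level.
#' @return Tibble `mirna_a`, `mirna_b`, `r`, `p` for pairs with p < alpha.
#' @export
significant_edges <- function(summary, alpha = summary$alpha) {
  dplyr::filter(tidy(summary), .data$p < alpha)
}

#' @export
tidy.mb_cor <- function(x, ...) {
  ut <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    mirna_a = x$mirna_ids[ut[, 1]],
    mirna_b = x$mirna_ids[ut[, 2]],
    r = x$r[ut],
    p = x$p[ut]
  )
}

#' @export
glance.mb_cor <- function(x, ...) {
  tibble::tibble(n_mirnas = length(x$mirna_ids), n_samples = x$n,
                 alpha = x$alpha, n_significant = x$n_significant)
}

#' Partial correlation matrix controlling for covariates
#'
#' Pearson correlations of the least-squares residuals of each miRNA on
#' the covariates (with intercept) - the standard residual method for
#' partial correlation, used here to control for gestational age at
#' blood draw.
#'
#' @param dct Normalized expression (long tibble), restricted to the
#'   samples of interest.
#' @param covariates Numeric vector or matrix aligned with the samples
#'   (sorted by `sample_id` as in the pivoted matrix), or a data frame
#'   with a `sample_id` column plus covariate columns.
#' @return The partial correlation matrix.
#' @export
partial_correlation_matrix <- function(dct, covariates) {
  x <- values_matrix(dct, if ("dct" %in% names(dct)) "dct" else "ct")
  if (is.data.frame(covariates) && "sample_id" %in% names(covariates)) {
    covariates <- as.matrix(
      covariates[match(rownames(x), covariates$sample_id),
                 setdiff(names(covariates), "sample_id"), drop = FALSE])
  }
  cv <- as.matrix(covariates)
  if (nrow(cv) != nrow(x)) abort("Covariates not aligned with samples.")
  if (any(apply(cv, 2, var) == 0)) abort("Constant covariate.")
  if (nrow(x) <= ncol(cv) + 2) {
    abort("Need n > (number of covariates + 2) samples.")
  }
  z <- cbind(1, cv)
  q <- qr(z)
  if (q$rank < ncol(z)) abort("Collinear covariates.")
  res <- qr.resid(q, x)
  r <- suppressWarnings(stats::cor(res))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}

#' Concordance between full and partial correlation matrices
#'
#' Squared Pearson correlation between the vectorized upper triangles of
#' two correlation matrices of matching dimension.
#'
#' @param full,partial Correlation matrices (or `"mb_cor"` objects).
#' @return R-squared.
#' @export
correlation_concordance <- function(full, partial) {
  if (inherits(full, "mb_cor")) full <- full$r
  if (inherits(partial, "mb_cor")) partial <- partial$r
  if (!all(dim(full) == dim(partial))) abort("Dimension mismatch.")
  ut <- upper.tri(full)
  concordance_r2(full[ut], partial[ut])
}

#' Bootstrap distribution of significant-correlation counts
#'
#' Resamples one stratum (exposure group, optionally restricted to one
#' fetal sex, at one time point) with replacement to its own size for
#' `config$n_iterations` iterations; in each iteration recomputes the
#' full Pearson correlation matrix and records the number of significant
#' pairs (p < alpha). Internally significance is evaluated as
#' `|r| > r_crit(alpha, n)`, which is exactly equivalent to the
#' two-sided t-transform p < alpha; undefined correlations from
#' duplicated-sample degeneracies count as non-significant.
#'
#' @param dct Normalized expression (long tibble).
#' @param meta Sample metadata.
#' @param group Exposure group to resample.
#' @param time_point Time point.
#' @param sex `NULL` (aggregated) or `"M"`/`"F"`.
#' @param config A [bootstrap_config()] (uses the `"corr"` stream).
#' @param stream Name of the RNG child stream (override for independent
#'   calibration runs).
#' @return Tibble of class `"mb_counts"`: `iteration`, `n_significant`;
#'   attributes carry the stratum descriptors and `mean_count`.
#' @export
bootstrap_correlation_counts <- function(dct, meta, group, time_point,
                                         sex = NULL,
                                         config = bootstrap_config(),
                                         stream = "corr") {
  sub <- filter_stratum(meta, time_point = time_point, sex = sex,
                        group = group)
  sub <- sub[order(sub$sample_id), , drop = FALSE]  # row-order invariance
  n <- nrow(sub)
  if (n < 4) {
    abort(sprintf("Stratum %s/%s/tp%s has %d samples; need >= 4.",
                  group, stratum_label(sex), time_point, n))
  }
  x <- values_matrix(dplyr::semi_join(dct, sub, by = "sample_id"), "dct")
  x <- x[sub$sample_id, , drop = FALSE]
  seed <- stream_seed(config$seed, stream)
  tag <- paste("corr", group, stratum_label(sex), time_point, sep = "|")
  rcrit <- critical_r(config$alpha, n)
  ut <- upper.tri(matrix(0, ncol(x), ncol(x)))
  b <- config$n_iterations
  counts <- integer(b)
  for (it in seq_len(b)) {
    idx <- resample_positions(n, seed, it, tag)
    r <- suppressWarnings(stats::cor(x[idx, , drop = FALSE]))
    counts[it] <- sum(abs(r[ut]) > rcrit, na.rm = TRUE)
  }
  res <- tibble::tibble(iteration = seq_len(b), n_significant = counts)
  new_mb_tbl(res, "mb_counts", group = group,
             stratum = stratum_label(sex), time_point = time_point,
             alpha = config$alpha, n_samples = n,
             mean_count = mean(counts))
}

#' @export
glance.mb_counts <- function(x, ...) {
  tibble::tibble(
    group = attr(x, "group"), stratum = attr(x, "stratum"),
    time_point = attr(x, "time_point"), n_samples = attr(x, "n_samples"),
    n_iterations = nrow(x), mean_count = attr(x, "mean_count"),
    sd_count = sd(x$n_significant)
  )
}

#' Count-exceedance test for co-secretion differences
#'
#' Tests the null hypothesis that the mean number of significant miRNA
#' cross-correlations is not different between an alcohol-exposed group
#' and the unexposed reference: counts the exposed bootstrap iterations
#' whose significant-correlation count strictly exceeds the mean
#' reference count, divides by the number of iterations, and subtracts
#' the ratio from 1. The null is rejected when p < 0.05.
#'
#' @param exposed,reference `"mb_counts"` distributions from the same
#'   number of iterations.
#' @return One-row tibble: `group`, `stratum`, `time_point`,
#'   `mean_exposed`, `mean_reference`, `p_value`.
#' @export
correlation_count_test <- function(exposed, reference) {
  if (nrow(exposed) != nrow(reference)) {
    abort("Count distributions must come from the same number of iterations.")
  }
  ref_mean <- mean(reference$n_significant)
  p <- 1 - mean(exposed$n_significant > ref_mean)
  tibble::tibble(
    group = attr(exposed, "group") %||% NA_character_,
    stratum = attr(exposed, "stratum") %||% NA_character_,
    time_point = attr(exposed, "time_point") %||% NA_integer_,
    mean_exposed = mean(exposed$n_significant),
    mean_reference = ref_mean,
    p_value = p
  )
}

#' Iteration-count calibration study
#'
#' For each candidate iteration count B and each of `n_runs` independent
#' RNG streams, runs [bootstrap_correlation_counts()] and records the
#' mean significant-correlation count. The across-run variance of the
#' mean shrinks as B grows, which is how a production iteration count is
#' chosen.
#'
#' @param dct,meta,group,time_point,sex As in
#'   [bootstrap_correlation_counts()].
#' @param iteration_grid Candidate values of B (default 50-3000).
#' @param n_runs Independent runs per grid point (default 20).
#' @param alpha,seed Test level and master seed.
#' @return Tibble `n_iterations`, `run`, `mean_count`.
#' @export
iteration_calibration <- function(dct, meta, group, time_point, sex = NULL,
                                  iteration_grid = c(50, 100, 250, 500,
                                                     1000, 2000, 3000),
                                  n_runs = 20, alpha = 0.05, seed = 1L) {
  if (length(iteration_grid) == 0) abort("Empty iteration grid.")
  if (any(iteration_grid < 1)) abort("Invalid iteration count in grid.")
  purrr::map_dfr(iteration_grid, function(b) {
    purrr::map_dfr(seq_len(n_runs), function(run) {
      cfg <- bootstrap_config(n_iterations = b, alpha = alpha,
                              seed = mix_seed(seed, "calibration", run))
      cd <- bootstrap_correlation_counts(dct, meta, group, time_point,
                                         sex = sex, config = cfg,
                                         stream = "calibration")
      tibble::tibble(n_iterations = b, run = run,
                     mean_count = attr(cd, "mean_count"))
    })
  })
}
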