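#' One-way ANOVA p-value
#'
#' Classical one-way fixed-effects ANOVA: `F = (SSB/df_b) / (SSW/df_w)`
#' with the two-sided p from the F distribution. Completely degenerate
#' input (all values identical) returns p = 1.
#'
#' @param values Numeric response vector, or a list of per-group vectors
#'   (in which case `groups` is ignored).
#' @param groups Grouping vector aligned with `values`.
#' @param strict Error if any group has fewer than 2 observations.
#' @return The p-value.
#' @export
#' @examples
#' anova_pvalue(list(c(0, 1), c(0, 1), c(4, 5)))
anova_pvalue <- function(values, groups = NULL, strict = TRUE) {
  if (is.list(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  g <- factor(groups)
  k <- nlevels(g)
  if (k < 2) abort("Need at least 2 groups.")
  ns <- tabulate(g)
  if (strict && any(ns < 2)) abort("Every group needs >= 2 observations.")
  n <- length(values)
  gm <- tapply(values, g, mean)
  ssb <- sum(ns * (gm - mean(values))^2)
  ssw <- sum((values - gm[as.integer(g)])^2)
  scale <- max(sum(values^2), 1)
  if (ssw <= 1e-12 * scale) {
    return(if (ssb <= 1e-12 * scale) 1 else 0)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  pf(f, k - 1, n - k, lower.tail = FALSE)
}

#' ANCOVA group-effect p-value
#'
#' p-value for the group factor from the F drop test comparing
#' `value ~ covariates + group` against `value ~ covariates`
#' (type-II style, covariates always retained).
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector.
#' @param covariates Numeric vector or matrix of covariates (e.g. the
#'   gestational age at blood draw), aligned with `values`.
#' @return The p-value for the group factor.
#' @export
ancova_pvalue <- function(values, groups, covariates) {
  g <- factor(groups)
  if (nlevels(g) < 2) abort("Need at least 2 groups.")
  covariates <- as.matrix(covariates)
  if (anyNA(covariates)) abort("Missing covariate values.")
  if (nrow(covariates) != length(values)) {
    abort("Covariates not aligned with `values`.")
  }
  if (any(apply(covariates, 2, function(x) var(x) == 0))) {
    abort("Zero-variance covariate.")
  }
  z1 <- cbind(1, covariates)
  z2 <- cbind(z1, stats::model.matrix(~g)[, -1, drop = FALSE])
  q1 <- qr(z1)
  q2 <- qr(z2)
  if (q2$rank < ncol(z2)) abort("Rank-deficient design.")
  rss1 <- sum(qr.resid(q1, values)^2)
  rss2 <- sum(qr.resid(q2, values)^2)
  df1 <- q2$rank - q1$rank
  df2 <- length(values) - q2$rank
  if (df2 <= 0) abort("Not enough residual degrees of freedom.")
  scale <- max(sum(values^2), 1)
  if (rss2 <= 1e-12 * scale) {
    return(if (rss1 - rss2 <= 1e-12 * scale) 1 else 0)
  }
  f <- ((rss1 - rss2) / df1) / (rss2 / df2)
  pf(f, df1, df2, lower.tail = FALSE)
}

# Vectorized per-iteration ANOVA across a panel: X is the resampled
# samples x miRNAs matrix, `gidx` the group index (1..k), `ns` the group
# sizes.  Degenerate columns (zero within-group variance) return p = 1,
# i.e. score as non-significant.
panel_anova_p <- function(x, gidx, ns) {
  n <- nrow(x)
  k <- length(ns)
  gsum <- rowsum(x, gidx, reorder = TRUE)
  gsumsq <- rowsum(x * x, gidx, reorder = TRUE)
  tot <- colSums(gsum)
  ssb <- colSums(gsum^2 / ns) - tot^2 / n
  ssw <- colSums(gsumsq) - colSums(gsum^2 / ns)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  scale <- pmax(colSums(gsumsq), 1)
  p[ssw <= 1e-10 * scale] <- 1
  p
}

# Vectorized per-iteration ANCOVA drop test across a panel.
panel_ancova_p <- function(x, gdummies, cov, ns) {
  n <- nrow(x)
  k <- length(ns)
  z1 <- cbind(1, cov)
  z2 <- cbind(z1, gdummies)
  q1 <- qr(z1)
  q2 <- qr(z2)
  df1 <- q2$rank - q1$rank
  df2 <- n - q2$rank
  if (df1 <= 0 || df2 <= 0) return(rep(1, ncol(x)))
  rss1 <- colSums(qr.resid(q1, x)^2)
  rss2 <- colSums(qr.resid(q2, x)^2)
  f <- ((rss1 - rss2) / df1) / (rss2 / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  scale <- pmax(colSums(x^2), 1)
  p[rss2 <= 1e-10 * scale] <- 1
  p
}

#' Bootstrap significance-stability profile
#'
#' For each miRNA and each requested stratum, computes the proportion of
#' bootstrap iterations in which the group test (one-way ANOVA, or ANCOVA
#' adjusting for gestational age at blood draw) reaches `p < alpha`. In
#' every iteration each exposure group is resampled with replacement to
#' its own size; iterations in which a resampled panel column has zero
#' within-group variance score as non-significant for that miRNA.
#'
#' @param dct Normalized expression (long tibble `sample_id`, `mirna_id`,
#'   `dct`), e.g. from [global_mean_normalize()].
#' @param meta Sample metadata (`sample_id`, `group`, `sex`,
#'   `time_point`, `ga`, `ga_bd1`, `ga_bd2`).
#' @param time_point Time point to analyze (2 or 3).
#' @param model `"anova"` or `"ancova"`.
#' @param strata Which strata to profile; any of `"aggregated"`,
#'   `"male"`, `"female"`.
#' @param covariates For ANCOVA: `"matched"` uses the gestational age at
#'   the analyzed blood draw (`ga`); `"both"` uses `ga_bd1` and `ga_bd2`.
#' @param config A [bootstrap_config()]; its `seed` feeds the `"anova"`
#'   stream so profiles are independent of other analyses.
#' @param per_mirna Audit mode: draw an independent resample stream per
#'   miRNA instead of sharing one draw across the panel (identical
#'   marginal distributions, much slower).
#' @return A tibble of class `"mb_stability"` with columns `mirna_id`,
#'   `stratum`, `model`, `prop_significant`, `n_iterations`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_mirnas = 12, seed = 1))
#' dct <- global_mean_normalize(impute_undetected(sim$ct))
#' stability_profile(dct, sim$meta, time_point = 2,
#'                   config = bootstrap_config(50, seed = 1))
stability_profile <- function(dct, meta, time_point,
                              model = c("anova", "ancova"),
                              strata = c("aggregated", "male", "female"),
                              covariates = c("matched", "both"),
                              config = bootstrap_config(),
                              per_mirna = FALSE) {
  model <- match.arg(model)
  covariates <- match.arg(covariates)
  strata <- match.arg(strata, several.ok = TRUE)
  seed <- stream_seed(config$seed, "anova")
  res <- purrr::map_dfr(strata, function(s) {
    sex <- switch(s, aggregated = NULL, male = "M", female = "F")
    sub <- filter_stratum(meta, time_point = time_point, sex = sex)
    sub <- sub[order(sub$sample_id), , drop = FALSE]  # row-order invariance
    if (nrow(sub) < 3) {
      abort(sprintf("Stratum '%s' at time point %s has < 3 samples.",
                    s, time_point))
    }
    x <- values_matrix(dplyr::semi_join(dct, sub, by = "sample_id"), "dct")
    x <- x[sub$sample_id, , drop = FALSE]
    cov <- switch(covariates, matched = cbind(sub$ga),
                  both = cbind(sub$ga_bd1, sub$ga_bd2))
    prop <- boot_stability(x, sub$group, cov, model, config, seed,
                           tag = paste(model, s, time_point, sep = "|"),
                           per_mirna = per_mirna)
    tibble::tibble(mirna_id = colnames(x), stratum = s,
                   model = toupper(model), prop_significant = unname(prop),
                   n_iterations = config$n_iterations)
  })
  new_mb_tbl(res, "mb_stability", time_point = time_point,
             alpha = config$alpha)
}

boot_stability <- function(x, groups, cov, model, config, seed, tag,
                           per_mirna = FALSE) {
  g <- factor(groups)
  pos_by_group <- split(seq_len(nrow(x)), g)
  small <- names(pos_by_group)[lengths(pos_by_group) < 2]
  if (length(small) > 0) {
    abort(sprintf("Group(s) %s too small to resample a model fit.",
                  paste(small, collapse = ", ")))
  }
  ns <- lengths(pos_by_group)
  gidx <- rep(seq_along(pos_by_group), ns)
  gdum <- stats::model.matrix(~factor(gidx))[, -1, drop = FALSE]
  b <- config$n_iterations
  alpha <- config$alpha
  m <- ncol(x)
  count <- numeric(m)
  if (!per_mirna) {
    for (it in seq_len(b)) {
      idx <- resample_groups(pos_by_group, seed, it, tag)
      p <- if (model == "anova") {
        panel_anova_p(x[idx, , drop = FALSE], gidx, ns)
      } else {
        panel_ancova_p(x[idx, , drop = FALSE], gdum,
                       cov[idx, , drop = FALSE], ns)
      }
      count <- count + (p < alpha)
    }
  } else {
    for (j in seq_len(m)) {
      for (it in seq_len(b)) {
        idx <- unlist(lapply(names(pos_by_group), function(gr) {
          pos <- pos_by_group[[gr]]
          pos[resample_positions(length(pos), seed, it,
                                 paste(tag, gr, sep = "|"), unit = j)]
        }), use.names = FALSE)
        p <- if (model == "anova") {
          panel_anova_p(x[idx, j, drop = FALSE], gidx, ns)
        } else {
          panel_ancova_p(x[idx, j, drop = FALSE], gdum,
                         cov[idx, , drop = FALSE], ns)
        }
        count[j] <- count[j] + (p < alpha)
      }
    }
  }
  count / b
}

#' Classify fetal sex-specific stability gains
#'
#' A miRNA is "likely alcohol-sensitive, fetal sex-specific" for a sex
#' when disaggregating by that sex strictly increases its proportion of
#' significant bootstrap iterations relative to the aggregated analysis
#' AND that proportion strictly exceeds `threshold` (default 0.5, i.e.
#' significance is more likely than not).
#'
#' @param profile A stability tibble containing the `aggregated` stratum
#'   and at least one of `male`/`female` (one model).
#' @param threshold Absolute stability bar (default 0.5).
#' @return Tibble `mirna_id`, `label` with
#'   `label` in `none`/`male`/`female`/`both`.
#' @export
#' @examples
#' prof <- tibble::tibble(
#'   mirna_id = rep("a", 3), stratum = c("aggregated", "male", "female"),
#'   model = "ANOVA", prop_significant = c(0.3, 0.2, 0.7),
#'   n_iterations = 100)
#' classify_sex_specific(prof)
classify_sex_specific <- function(profile, threshold = 0.5) {
  stopifnot_cols(profile, c("mirna_id", "stratum", "prop_significant"),
                 "profile")
  wide <- tidyr::pivot_wider(
    dplyr::select(profile, "mirna_id", "stratum", "prop_significant"),
    names_from = "stratum", values_from = "prop_significant"
  )
  if (!"aggregated" %in% names(wide)) {
    abort("Profile must include the 'aggregated' stratum.")
  }
  hit <- function(sexcol) {
    if (!sexcol %in% names(wide)) return(rep(FALSE, nrow(wide)))
    !is.na(wide[[sexcol]]) &
      wide[[sexcol]] > wide$aggregated & wide[[sexcol]] > threshold
  }
  m <- hit("male")
  f <- hit("female")
  tibble::tibble(
    mirna_id = wide$mirna_id,
    label = dplyr::case_when(m & f ~ "both", m ~ "male",
                             f ~ "female", TRUE ~ "none")
  )
}

#' Concordance between two stability (or correlation) profiles
#'
#' Squared Pearson correlation between two aligned numeric vectors, used
#' to compare ANOVA vs ANCOVA stability profiles or full vs partial
#' correlation coefficients. Sign-blind by construction.
#'
#' @param a,b Numeric vectors of equal length (>= 3).
#' @return R-squared.
#' @export
concordance_r2 <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    abort("Need two aligned vectors of length >= 3.")
  }
  if (sd(a) == 0 || sd(b) == 0) abort("Zero variance in a profile.")
  stats::cor(a, b)^2
}
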