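test_that("one-way ANOVA matches hand computation and the lm oracle", {
  # equal group means -> F = 0, p = 1
  expect_equal(anova_pvalue(list(1:3, 1:3, 1:3)), 1)
  # hand-computed sums of squares: F = 64/3 on (2, 3) df
  vals <- c(0, 1, 0, 1, 4, 5)
  grp <- rep(1:3, each = 2)
  p <- anova_pvalue(vals, grp)
  expect_equal(p, pf(64 / 3, 2, 3, lower.tail = FALSE), tolerance = 1e-12)
  oracle <- anova(lm(vals ~ factor(grp)))$`Pr(>F)`[1]
  expect_equal(p, oracle, tolerance = 1e-10)
  # fully degenerate data
  expect_equal(anova_pvalue(rep(2, 6), grp), 1)
  expect_error(anova_pvalue(list(1, 1:2, 1:2)), "observations")
})

test_that("ANCOVA drop test matches the nested-lm oracle", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(9:25, 1)
    vals <- rnorm(n)
    grp <- sample(rep(1:3, length.out = n))
    cov <- cbind(rnorm(n), rnorm(n))
    p <- ancova_pvalue(vals, grp, cov)
    oracle <- anova(lm(vals ~ cov), lm(vals ~ cov + factor(grp)))$`Pr(>F)`[2]
    expect_equal(p, oracle, tolerance = 1e-10)
  }
  # response driven by the covariate -> group carries (almost) nothing
  ga <- seq(10, 40, length.out = 12)
  grp <- sample(rep(1:3, 4))
  vals <- 2 * ga + rnorm(12, sd = 1e-3)
  p <- ancova_pvalue(vals, grp, ga)
  oracle <- anova(lm(vals ~ ga), lm(vals ~ ga + factor(grp)))$`Pr(>F)`[2]
  expect_equal(p, oracle, tolerance = 1e-10)
  # exactly collinear response: zero residual -> degenerate convention
  expect_equal(ancova_pvalue(2 * ga, grp, ga), 1)
  expect_error(ancova_pvalue(rnorm(9), rep(1:3, 3), rep(1, 9)),
               "Zero-variance covariate")
})

test_that("vectorized panel tests agree with the scalar primitives", {
  set.seed(9)
  n <- 18
  x <- matrix(rnorm(n * 5), n, 5)
  gidx <- rep(1:3, each = 6)
  pv <- mirboot:::panel_anova_p(x, gidx, c(6, 6, 6))
  for (j in 1:5) {
    expect_equal(pv[j], anova_pvalue(x[, j], gidx), tolerance = 1e-12)
  }
  cov <- cbind(rnorm(n))
  gdum <- stats::model.matrix(~factor(gidx))[, -1]
  pva <- mirboot:::panel_ancova_p(x, gdum, cov, c(6, 6, 6))
  for (j in 1:5) {
    expect_equal(pva[j], ancova_pvalue(x[, j], gidx, cov),
                 tolerance = 1e-12)
  }
})

test_that("stability profiles behave at the extremes", {
  fx <- null_cohort(n_per_group = 8, m = 3, seed = 13)
  # make one miRNA constant and one strongly separated by group
  fx$dct$dct[fx$dct$mirna_id == "m01"] <- 7
  fx$dct$dct[fx$dct$mirna_id == "m02"] <-
    fx$dct$dct[fx$dct$mirna_id == "m02"] +
    ifelse(fx$meta$group[match(fx$dct$sample_id[fx$dct$mirna_id == "m02"],
                               fx$meta$sample_id)] == "HEa", 4.5, 0)
  prof <- stability_profile(fx$dct, fx$meta, time_point = 2,
                            strata = "aggregated",
                            config = bootstrap_config(200, seed = 3))
  expect_equal(prof$prop_significant[prof$mirna_id == "m01"], 0)
  expect_gt(prof$prop_significant[prof$mirna_id == "m02"], 0.9)
  # null miRNA: stability safely below the 0.5 classification bar
  expect_lt(prof$prop_significant[prof$mirna_id == "m03"], 0.5)
})

test_that("profiles are invariant to row and column order", {
  fx <- null_cohort(n_per_group = 6, m = 4, seed = 17)
  cfg <- bootstrap_config(60, seed = 5)
  base <- stability_profile(fx$dct, fx$meta, 2, config = cfg)
  perm <- stability_profile(
    dplyr::arrange(fx$dct, dplyr::desc(sample_id), dplyr::desc(mirna_id)),
    fx$meta[sample(nrow(fx$meta)), ], 2, config = cfg)
  expect_equal(dplyr::arrange(tidy(base), mirna_id, stratum),
               dplyr::arrange(tidy(perm), mirna_id, stratum))
})

test_that("audit per-miRNA streams give comparable proportions", {
  fx <- null_cohort(n_per_group = 6, m = 2, seed = 19)
  cfg <- bootstrap_config(150, seed = 2)
  shared <- stability_profile(fx$dct, fx$meta, 2, strata = "aggregated",
                              config = cfg)
  audit <- stability_profile(fx$dct, fx$meta, 2, strata = "aggregated",
                             config = cfg, per_mirna = TRUE)
  expect_lt(max(abs(shared$prop_significant - audit$prop_significant)),
            0.15)
})

test_that("sex-specific classification applies both strict conditions", {
  prof <- tibble::tibble(
    mirna_id = rep(c("a", "b", "c"), each = 3),
    stratum = rep(c("aggregated", "male", "female"), 3),
    model = "ANOVA",
    prop_significant = c(0.30, 0.20, 0.70,   # a: female
                         0.30, 0.40, 0.40,   # b: fails the 0.5 bar
                         0.55, 0.52, 0.52),  # c: not increased enough? 0.52<0.55
    n_iterations = 100)
  cls <- classify_sex_specific(prof)
  expect_equal(cls$label[cls$mirna_id == "a"], "female")
  expect_equal(cls$label[cls$mirna_id == "b"], "none")
  expect_equal(cls$label[cls$mirna_id == "c"], "none")
  # ties are not increases
  tie <- tibble::tibble(mirna_id = "t",
                        stratum = c("aggregated", "male"),
                        model = "ANOVA",
                        prop_significant = c(0.6, 0.6),
                        n_iterations = 10)
  expect_equal(classify_sex_specific(tie)$label, "none")
  expect_error(classify_sex_specific(dplyr::filter(prof,
                                                   stratum == "male")),
               "aggregated")
})

test_that("profile concordance is the squared Pearson correlation", {
  v <- c(0.1, 0.5, 0.9)
  expect_equal(concordance_r2(v, v), 1)
  expect_equal(concordance_r2(v, rev(v)), 1)  # sign-blind
  expect_error(concordance_r2(v, rep(0.2, 3)), "variance")
  expect_error(concordance_r2(v, v[1:2]), "length")
})

test_that("ANOVA and ANCOVA profiles agree when GA carries no signal", {
  sim <- simulate_cohort(sim_config(n_mirnas = 40, detect_dropout = 0,
                                    seed = 23))
  dct <- global_mean_normalize(impute_undetected(sim$ct))
  cfg <- bootstrap_config(150, seed = 4)
  pa <- stability_profile(dct, sim$meta, 3, model = "anova",
                          strata = "aggregated", config = cfg)
  pc <- stability_profile(dct, sim$meta, 3, model = "ancova",
                          strata = "aggregated", config = cfg)
  expect_gt(concordance_r2(pa$prop_significant, pc$prop_significant), 0.9)
})
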