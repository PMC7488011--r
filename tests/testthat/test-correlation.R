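make_dct <- function(m) {
  ct_from_matrix(m) |>
    dplyr::rename(dct = "ct") |>
    dplyr::select(-"detected")
}

test_that("Pearson matrix p-values match the t-transform and cor.test", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  cm <- pearson_matrix(make_dct(m))
  expect_equal(cm$r["a", "b"], 0.8, tolerance = 1e-12)
  expect_equal(cm$p["a", "b"],
               2 * pt(1.886, 2, lower.tail = FALSE), tolerance = 1e-3)
  expect_equal(cm$p["a", "b"], cor.test(m[, 1], m[, 2])$p.value,
               tolerance = 1e-10)

  # collinear pair: r = 1, p clamped to the smallest positive double
  mc <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  cmc <- pearson_matrix(make_dct(mc))
  expect_equal(cmc$r["a", "b"], 1)
  expect_equal(cmc$p["a", "b"], .Machine$double.xmin)
  expect_equal(count_significant(cmc), 1)

  # constant column: all its pairs non-significant
  mk <- cbind(a = c(1, 2, 3, 4), b = rep(5, 4), c = c(2, 1, 4, 3))
  cmk <- pearson_matrix(make_dct(mk))
  expect_equal(cmk$r["a", "b"], 0)
  expect_equal(cmk$p["a", "b"], 1)
  expect_error(pearson_matrix(make_dct(m[1:2, ])), "3 samples")
})

test_that("significant-pair counting respects alpha and ordering", {
  set.seed(41)
  m <- matrix(rnorm(25 * 150), 25, 150)
  cm <- pearson_matrix(make_dct(m))
  expect_lt(abs(cm$n_significant - 0.05 * choose(150, 2)), 70)
  expect_equal(count_significant(cm, alpha = 0), 0)
  # invariance under sample and miRNA permutations
  perm <- m[sample(25), sample(150)]
  colnames(perm) <- sprintf("p%03d", seq_len(150))
  expect_equal(pearson_matrix(make_dct(perm))$n_significant,
               cm$n_significant)
})

test_that("critical-|r| thresholding is exactly the p < alpha rule", {
  for (n in c(5, 8, 13, 25)) {
    rcrit <- mirboot:::critical_r(0.05, n)
    for (r in c(0.01, rcrit - 1e-6, rcrit + 1e-6, 0.9, 0.9999)) {
      rm <- matrix(c(1, r, r, 1), 2)
      p <- mirboot:::pearson_p(rm, n)[1, 2]
      expect_equal(p < 0.05, abs(r) > rcrit)
    }
  }
})

test_that("partial correlation is the residual-method correlation", {
  set.seed(43)
  n <- 20
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("s%02d", 1:n), letters[1:4]))
  # covariate orthogonalized against every column: partial == full
  cov_raw <- rnorm(n)
  cov_orth <- qr.resid(qr(cbind(1, x)), cov_raw)
  full <- pearson_matrix(make_dct(x))$r
  part <- partial_correlation_matrix(make_dct(x), cov_orth)
  expect_equal(part, full, tolerance = 1e-10)
  expect_equal(diag(part), rep(1, 4), ignore_attr = TRUE)

  # shared GA driver: full r high, partial r near zero
  ga <- rnorm(30, 20, 5)
  y <- cbind(a = 2 * ga + rnorm(30, sd = 1.5),
             b = 2 * ga + rnorm(30, sd = 1.5))
  rownames(y) <- sprintf("t%02d", 1:30)
  fully <- pearson_matrix(make_dct(y))$r["a", "b"]
  party <- partial_correlation_matrix(make_dct(y), ga)["a", "b"]
  expect_gt(fully, 0.9)
  expect_lt(abs(party), 0.3)

  expect_error(partial_correlation_matrix(make_dct(x), rep(1, n)),
               "Constant covariate")
})

test_that("full/partial concordance orders GA-driven vs GA-free data", {
  set.seed(47)
  n <- 30
  ga <- rnorm(n, 20, 5)
  free <- matrix(rnorm(n * 10), n, 10,
                 dimnames = list(sprintf("s%02d", 1:n), NULL))
  colnames(free) <- sprintf("f%02d", 1:10)
  driven <- free + outer(ga - mean(ga), runif(10, 0.1, 0.3))
  colnames(driven) <- sprintf("d%02d", 1:10)
  r2_free <- correlation_concordance(
    pearson_matrix(make_dct(free))$r,
    partial_correlation_matrix(make_dct(free), ga))
  r2_driven <- correlation_concordance(
    pearson_matrix(make_dct(driven))$r,
    partial_correlation_matrix(make_dct(driven), ga))
  expect_gt(r2_free, 0.95)
  expect_lt(r2_driven, r2_free)
  expect_equal(correlation_concordance(pearson_matrix(make_dct(free)),
                                       pearson_matrix(make_dct(free))), 1)
})

test_that("bootstrap count distributions behave at the extremes", {
  ids <- sprintf("s%02d", 1:6)
  const <- tibble::tibble(
    sample_id = rep(ids, 3),
    mirna_id = rep(c("a", "b", "c"), each = 6), dct = 4)
  meta <- tibble::tibble(sample_id = ids, group = "UE", sex = "F",
                         time_point = 2L)
  cd <- bootstrap_correlation_counts(const, meta, "UE", 2,
                                     config = bootstrap_config(25,
                                                               seed = 1))
  expect_equal(cd$n_significant, rep(0L, 25))

  one <- bootstrap_correlation_counts(const, meta, "UE", 2,
                                      config = bootstrap_config(1,
                                                                seed = 1))
  expect_equal(nrow(one), 1)
  expect_error(
    bootstrap_correlation_counts(const, meta[1:3, ], "UE", 2,
                                 config = bootstrap_config(5, seed = 1)),
    ">= 4")
})

test_that("a planted factor block inflates the bootstrap mean count", {
  wins <- purrr::map_lgl(1:5, function(seed) {
    cs <- cosecretion_spec(n_members = 20, loading = 0.9,
                           active_strata = tibble::tibble(
                             group = "HEa", sex = "F", time_point = 2L,
                             scale = 1))
    sim <- simulate_cohort(sim_config(n_mirnas = 60, detect_dropout = 0,
                                      cosecretion = cs, seed = seed))
    dct <- global_mean_normalize(impute_undetected(sim$ct))
    cfg <- bootstrap_config(60, seed = seed)
    planted <- bootstrap_correlation_counts(dct, sim$meta, "HEa", 2,
                                            sex = "F", config = cfg)
    null <- bootstrap_correlation_counts(dct, sim$meta, "HEua", 2,
                                         sex = "F", config = cfg)
    attr(planted, "mean_count") > attr(null, "mean_count")
  })
  expect_gte(mean(wins), 0.8)
})

test_that("the count-exceedance test follows its counting definition", {
  mk <- function(counts, group = "HEa") {
    structure(tibble::tibble(iteration = seq_along(counts),
                             n_significant = counts),
              group = group, stratum = "female", time_point = 2L)
  }
  expect_equal(correlation_count_test(mk(rep(100, 8)),
                                      mk(rep(50, 8)))$p_value, 0)
  expect_equal(correlation_count_test(mk(rep(10, 8)),
                                      mk(rep(50, 8)))$p_value, 1)
  expect_equal(correlation_count_test(mk(c(60, 60, 40, 40)),
                                      mk(rep(50, 4)))$p_value, 0.5)
  # ties with the reference mean do not exceed
  expect_equal(correlation_count_test(mk(rep(50, 4)),
                                      mk(rep(50, 4)))$p_value, 1)
  # shifting every exposed count up never increases p
  base <- mk(c(30, 45, 50, 55, 70))
  ref <- mk(c(40, 50, 45, 55, 60))
  p0 <- correlation_count_test(base, ref)$p_value
  p1 <- correlation_count_test(mk(base$n_significant + 10), ref)$p_value
  expect_lte(p1, p0)
  expect_error(correlation_count_test(mk(1:4), mk(1:5)),
               "same number of iterations")
})

test_that("under the null the exceedance p is not degenerate", {
  ps <- purrr::map_dbl(1:10, function(seed) {
    fx <- null_cohort(n_per_group = 12, m = 30, seed = seed)
    cfg <- bootstrap_config(80, seed = seed)
    ex <- bootstrap_correlation_counts(fx$dct, fx$meta, "HEa", 2,
                                       config = cfg)
    ue <- bootstrap_correlation_counts(fx$dct, fx$meta, "UE", 2,
                                       config = cfg)
    correlation_count_test(ex, ue)$p_value
  })
  # empirical calibration is loose by construction; document the median
  expect_gt(median(ps), 0.1)
  expect_lt(median(ps), 0.9)
})

test_that("iteration calibration reduces the Monte Carlo error", {
  fx <- null_cohort(n_per_group = 10, m = 25, seed = 53)
  cal <- iteration_calibration(fx$dct, fx$meta, "UE", 2,
                               iteration_grid = c(30, 300), n_runs = 8,
                               seed = 11)
  expect_equal(nrow(cal), 16)
  v <- tapply(cal$mean_count, cal$n_iterations, var)
  expect_lt(v[["300"]], v[["30"]])

  small <- iteration_calibration(fx$dct, fx$meta, "UE", 2,
                                 iteration_grid = 50, n_runs = 2,
                                 seed = 1)
  expect_equal(nrow(small), 2)
  expect_error(iteration_calibration(fx$dct, fx$meta, "UE", 2,
                                     iteration_grid = numeric(0)),
               "Empty")
})
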