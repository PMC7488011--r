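test_that("annotation respects chromosome weights and determinism", {
  cfg <- sim_config(n_mirnas = 5, chrom_weights = c(X = 1), seed = 11)
  ann <- simulate_annotation(cfg)
  expect_equal(ann$chromosome, rep("X", 5))

  cfg2 <- sim_config(n_mirnas = 50, seed = 4)
  expect_identical(simulate_annotation(cfg2), simulate_annotation(cfg2))

  big <- sim_config(n_mirnas = 10000, chrom_weights = c(`1` = 0.5, X = 0.5),
                    seed = 9)
  frac_x <- mean(simulate_annotation(big)$chromosome == "X")
  expect_lt(abs(frac_x - 0.5), 0.02)

  expect_error(simulate_annotation(sim_config(n_mirnas = 1, seed = 1)),
               NA)
})

test_that("cohort generation matches the configured design", {
  cfg <- sim_config(n_mirnas = 15, detect_dropout = 0, seed = 21)
  sim <- simulate_cohort(cfg)
  sizes <- dplyr::count(sim$meta, time_point, group, sex, name = "n")
  expect_equal(
    dplyr::arrange(sizes, time_point, group, sex),
    dplyr::arrange(default_group_sizes(), time_point, group, sex),
    ignore_attr = TRUE
  )
  expect_false(anyNA(sim$ct$ct))
  expect_true(all(sim$ct$detected))
  expect_true(all(sim$meta$ga >= 10 & sim$meta$ga <= 42))
  # identical config -> identical draw
  expect_identical(simulate_cohort(cfg)$ct, sim$ct)
})

test_that("null cohorts carry no spurious group effects", {
  cfg <- sim_config(n_mirnas = 60, detect_dropout = 0, seed = 31)
  sim <- simulate_cohort(cfg)
  dct <- global_mean_normalize(impute_undetected(sim$ct))
  meta3 <- dplyr::filter(sim$meta, time_point == 3)
  x <- dplyr::filter(dct, sample_id %in%
                       meta3$sample_id[meta3$group == "HEa"])
  y <- dplyr::filter(dct, sample_id %in%
                       meta3$sample_id[meta3$group == "UE"])
  gs <- purrr::map_dbl(unique(dct$mirna_id), function(id) {
    hedges_g(x$dct[x$mirna_id == id], y$dct[y$mirna_id == id])
  })
  expect_lt(median(abs(gs)), 0.2)
})

test_that("planted effects are recovered at the expected magnitude", {
  cfg <- sim_config(
    n_mirnas = 30, detect_dropout = 0, seed = 41,
    planted_effects = list(planted_effect(3, "HEa", "both", shift = 2)))
  sim <- simulate_cohort(cfg)
  dct <- global_mean_normalize(impute_undetected(sim$ct))
  meta2 <- dplyr::filter(sim$meta, time_point == 2)
  id <- sim$annotation$mirna_id[3]
  gx <- dct$dct[dct$mirna_id == id &
                  dct$sample_id %in%
                    meta2$sample_id[meta2$group == "HEa"]]
  gy <- dct$dct[dct$mirna_id == id &
                  dct$sample_id %in%
                    meta2$sample_id[meta2$group == "UE"]]
  expect_gt(hedges_g(gx, gy), 1.2)
  expect_lt(hedges_g(gx, gy), 2.8)
})

test_that("planted-effect recovery is monotone in the shift", {
  shifts <- c(0.5, 1, 2)
  mean_g <- purrr::map_dbl(shifts, function(s) {
    mean(purrr::map_dbl(1:40, function(seed) {
      cfg <- sim_config(
        n_mirnas = 8, detect_dropout = 0, seed = seed,
        planted_effects = list(planted_effect(1, "HEa", "both", s)))
      sim <- simulate_cohort(cfg)
      dct <- global_mean_normalize(impute_undetected(sim$ct))
      meta2 <- dplyr::filter(sim$meta, time_point == 2)
      id <- sim$annotation$mirna_id[1]
      hedges_g(
        dct$dct[dct$mirna_id == id &
                  dct$sample_id %in%
                    meta2$sample_id[meta2$group == "HEa"]],
        dct$dct[dct$mirna_id == id &
                  dct$sample_id %in%
                    meta2$sample_id[meta2$group == "UE"]])
    }))
  })
  expect_true(all(diff(mean_g) > 0))
})

test_that("null significant-correlation count matches the binomial rate", {
  cfg <- sim_config(n_mirnas = 150, detect_dropout = 0, seed = 51)
  sim <- simulate_cohort(cfg)
  dct <- global_mean_normalize(impute_undetected(sim$ct))
  meta <- dplyr::filter(sim$meta, group == "UE", time_point == 3)
  cm <- pearson_matrix(dplyr::semi_join(dct, meta, by = "sample_id"))
  n_pairs <- choose(150, 2)
  expected <- 0.05 * n_pairs
  tol <- 4 * sqrt(n_pairs * 0.05 * 0.95)
  expect_lt(abs(cm$n_significant - expected), tol)
})

test_that("cohort tables round-trip through TSV", {
  sim <- simulate_cohort(sim_config(n_mirnas = 8, seed = 61))
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  back <- read_cohort(dir)
  expect_equal(back$meta$group, sim$meta$group)
  expect_equal(
    dplyr::arrange(back$ct, sample_id, mirna_id)$ct,
    dplyr::arrange(sim$ct, sample_id, mirna_id)$ct,
    tolerance = 1e-8)
  expect_error(read_cohort(file.path(dir, "nope")), "Missing cohort file")
})
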