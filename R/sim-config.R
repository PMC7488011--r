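#' Default per-stratum cohort sizes
#'
#' Sample counts per (time point, exposure group, fetal sex) cell for the
#' default synthetic cohort: 25/19/24 UE/HEua/HEa samples in trimester 2
#' and 36/23/34 in trimester 3, with the corresponding male/female splits.
#'
#' @return A tibble with columns `time_point`, `group`, `sex`, `n`.
#' @export
default_group_sizes <- function() {
  tibble::tribble(
    ~time_point, ~group, ~sex, ~n,
    2L, "UE",   "M", 17L,
    2L, "UE",   "F",  8L,
    2L, "HEua", "M",  7L,
    2L, "HEua", "F", 12L,
    2L, "HEa",  "M", 11L,
    2L, "HEa",  "F", 13L,
    3L, "UE",   "M", 22L,
    3L, "UE",   "F", 14L,
    3L, "HEua", "M",  9L,
    3L, "HEua", "F", 14L,
    3L, "HEa",  "M", 16L,
    3L, "HEa",  "F", 18L
  )
}

#' Default chromosome weights for synthetic annotation
#'
#' Probabilities of assigning a synthetic miRNA to each human chromosome,
#' proportional to the approximate number of annotated mature miRNAs per
#' chromosome (chromosomes 1, 14, 19 and X are relatively miRNA-rich).
#'
#' @return A named numeric vector over `"1"`..`"22"`, `"X"`, `"Y"` summing
#'   to 1.
#' @export
default_chrom_weights <- function() {
  counts <- c(
    `1` = 134, `2` = 101, `3` = 80, `4` = 57, `5` = 75, `6` = 63,
    `7` = 74, `8` = 79, `9` = 69, `10` = 64, `11` = 85, `12` = 72,
    `13` = 47, `14` = 92, `15` = 68, `16` = 66, `17` = 80, `18` = 29,
    `19` = 110, `20` = 51, `21` = 17, `22` = 46, X = 118, Y = 4
  )
  counts / sum(counts)
}

#' Planted group/sex effect for the synthetic cohort
#'
#' Ground-truth mean shift for one miRNA, expressed on the standardized
#' (Hedges' g) scale and converted to Ct units via the simulation noise SD.
#'
#' @param mirna_index Index of the target miRNA in the panel.
#' @param target_group `"HEa"` or `"HEua"`.
#' @param target_sex `"M"`, `"F"` or `"both"`.
#' @param shift Standardized shift (positive = higher Ct = lower abundance
#'   in the target group).
#' @return A list with class `"planted_effect"`.
#' @export
planted_effect <- function(mirna_index, target_group = c("HEa", "HEua"),
                           target_sex = c("both", "M", "F"), shift) {
  target_group <- match.arg(target_group)
  target_sex <- match.arg(target_sex)
  if (!is.finite(shift)) abort("`shift` must be finite.")
  structure(list(mirna_index = as.integer(mirna_index),
                 target_group = target_group, target_sex = target_sex,
                 shift = shift),
            class = "planted_effect")
}

#' Latent co-secretion factor specification
#'
#' One latent Gaussian factor shared by a block of miRNAs, active only in
#' selected (group, sex, time point) strata. Within an active stratum a
#' member miRNA's noise is `noise_sd * (loading * f + sqrt(1 - loading^2) * z)`
#' with `f` a per-sample standard normal, so the marginal variance is
#' unchanged and the induced pairwise correlation between members is
#' `loading^2`. A configurable fraction of members is drawn from
#' X-chromosome-annotated miRNAs.
#'
#' @param n_members Number of member miRNAs.
#' @param loading Factor loading in `[0, 1)` applied in fully active strata.
#' @param x_fraction Fraction of members annotated to chromosome X.
#' @param active_strata Tibble with columns `group`, `sex`, `time_point` and
#'   optionally `scale` (per-stratum multiplier on the shared-variance
#'   fraction `loading^2`; `scale = 0.5` halves the member-pair correlation).
#' @param member_indices Optional explicit member indices (overrides
#'   `n_members`/`x_fraction` selection).
#' @return A list with class `"cosecretion_spec"`.
#' @export
cosecretion_spec <- function(n_members = 100, loading = 0.95,
                             x_fraction = 0.5,
                             active_strata = default_active_strata(),
                             member_indices = NULL) {
  if (!(loading >= 0 && loading < 1)) abort("`loading` must be in [0, 1).")
  if (n_members < 1 && is.null(member_indices)) {
    abort("Co-secretion member set must be non-empty.")
  }
  if (!("scale" %in% names(active_strata))) active_strata$scale <- 1
  structure(list(n_members = as.integer(n_members), loading = loading,
                 x_fraction = x_fraction,
                 active_strata = tibble::as_tibble(active_strata),
                 member_indices = member_indices),
            class = "cosecretion_spec")
}

#' Default activity pattern of the co-secretion factor
#'
#' The factor is fully active in exposed-affected pregnancies with female
#' fetuses at both time points, active at reduced shared variance
#' (`scale = 0.8`, an intermediate member-pair correlation) in
#' exposed-unaffected female pregnancies at mid-pregnancy only, and active
#' in exposed-affected male pregnancies only late in pregnancy.
#'
#' @return A tibble with columns `group`, `sex`, `time_point`, `scale`.
#' @export
default_active_strata <- function() {
  tibble::tribble(
    ~group, ~sex, ~time_point, ~scale,
    "HEa",  "F",  2L, 1.0,
    "HEa",  "F",  3L, 1.0,
    "HEua", "F",  2L, 0.8,
    "HEa",  "M",  3L, 1.0
  )
}

#' Synthetic cohort configuration
#'
#' Collects every knob of the synthetic qPCR cohort generator. Defaults
#' mirror the structure the analysis assumes: per-stratum sample counts
#' from [default_group_sizes()], a 200-assay candidate panel with
#' detection dropout so the expression filter has work to do, per-sample
#' global Ct shifts, gestational-age draws for both blood draws, and
#' optional planted effects and a latent co-secretion factor.
#'
#' @param group_sizes Tibble `(time_point, group, sex, n)`; see
#'   [default_group_sizes()].
#' @param n_mirnas Candidate panel size (default 200).
#' @param chrom_weights Named chromosome probabilities summing to 1.
#' @param base_ct_range Per-miRNA baseline Ct drawn uniformly from this
#'   interval (default 22-35 cycles).
#' @param sample_shift_sd SD of the per-sample global technical Ct shift
#'   (cycles; removed exactly by global-mean normalization).
#' @param noise_sd Residual within-group SD in cycles (default 1.5).
#' @param detect_dropout Per-miRNA probability of non-detection: a scalar,
#'   a vector of length `n_mirnas`, or `NULL` for the default mixture
#'   (75% of assays robustly expressed with dropout U(0, 0.02), 25%
#'   poorly detected with U(0.3, 0.9), giving roughly three quarters of
#'   the panel past the 80% filter).
#' @param planted_effects List of [planted_effect()] objects.
#' @param cosecretion A [cosecretion_spec()] or `NULL`.
#' @param ga_means_sds List with elements `ga_bd1` and `ga_bd2`, each
#'   `c(mean, sd)` in weeks (defaults 18.88 +/- 4.93 and 33.08 +/- 2.42);
#'   draws are clipped to 10-42 weeks.
#' @param ga_slopes Optional per-miRNA Ct-per-week slopes on the (centred)
#'   gestational age at the analyzed draw.
#' @param seed Integer master seed.
#' @return A list with class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, planted_effects = list(
#'   planted_effect(1, "HEa", "F", shift = 1.5)))
sim_config <- function(group_sizes = default_group_sizes(),
                       n_mirnas = 200,
                       chrom_weights = default_chrom_weights(),
                       base_ct_range = c(22, 35),
                       sample_shift_sd = 1.0,
                       noise_sd = 1.5,
                       detect_dropout = NULL,
                       planted_effects = list(),
                       cosecretion = NULL,
                       ga_means_sds = list(ga_bd1 = c(18.88, 4.93),
                                           ga_bd2 = c(33.08, 2.42)),
                       ga_slopes = NULL,
                       seed = 1L) {
  group_sizes <- tibble::as_tibble(group_sizes)
  stopifnot_cols(group_sizes, c("time_point", "group", "sex", "n"),
                 "group_sizes")
  if (any(group_sizes$n < 0)) abort("Group sizes must be >= 0.")
  if (n_mirnas < 1) abort("`n_mirnas` must be >= 1.")
  if (abs(sum(chrom_weights) - 1) > 1e-8 || any(chrom_weights < 0)) {
    abort("`chrom_weights` must be non-negative and sum to 1.")
  }
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  if (!is.null(detect_dropout)) {
    if (any(detect_dropout < 0 | detect_dropout > 1)) {
      abort("`detect_dropout` probabilities must be in [0, 1].")
    }
    if (!length(detect_dropout) %in% c(1L, n_mirnas)) {
      abort("`detect_dropout` must be scalar or length `n_mirnas`.")
    }
  }
  for (pe in planted_effects) {
    if (pe$mirna_index < 1 || pe$mirna_index > n_mirnas) {
      abort("Planted effect `mirna_index` outside the panel.")
    }
  }
  structure(
    list(group_sizes = group_sizes, n_mirnas = as.integer(n_mirnas),
         chrom_weights = chrom_weights, base_ct_range = base_ct_range,
         sample_shift_sd = sample_shift_sd, noise_sd = noise_sd,
         detect_dropout = detect_dropout, planted_effects = planted_effects,
         cosecretion = cosecretion, ga_means_sds = ga_means_sds,
         ga_slopes = ga_slopes, seed = as.integer(seed)),
    class = "sim_config"
  )
}
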