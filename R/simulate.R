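#' Simulate a synthetic miRNA annotation table
#'
#' Draws a chromosome label for each panel miRNA from the configured
#' chromosome weights and assigns synthetic MIMAT-style accessions and
#' names. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `mirna_id` (synthetic MIMAT accession),
#'   `name`, `chromosome` (character, `"1"`..`"22"`, `"X"`, `"Y"`).
#' @export
simulate_annotation <- function(config) {
  m <- config$n_mirnas
  if (m < 1) abort("Zero miRNAs requested.")
  w <- config$chrom_weights
  chrom <- with_seed(mix_seed(config$seed, "annotation"),
                     sample(names(w), m, replace = TRUE, prob = w))
  tibble::tibble(
    mirna_id = sprintf("MIMAT9%06d", seq_len(m)),
    name = sprintf("sim-miR-%04d", seq_len(m)),
    chromosome = chrom
  )
}

# Per-miRNA dropout probabilities (default mixture, deterministic).
dropout_probs <- function(config) {
  m <- config$n_mirnas
  if (!is.null(config$detect_dropout)) {
    return(rep_len(config$detect_dropout, m))
  }
  with_seed(mix_seed(config$seed, "dropout"), {
    hi <- runif(m) < 0.25
    ifelse(hi, runif(m, 0.3, 0.9), runif(m, 0, 0.02))
  })
}

#' Simulate a synthetic qPCR cohort
#'
#' Generates a full cohort under the generative model
#' `Ct_ij = base_i + shift_j + slope_i * (GA_j - mean GA) + planted shift +
#' factor contribution + N(0, noise_sd)`:
#' per-miRNA baseline Ct, per-sample global technical shift, optional
#' gestational-age trends, planted group/sex mean shifts on the
#' standardized scale, and an optional latent co-secretion factor confined
#' to its active strata. Entries are flagged undetected with the per-miRNA
#' dropout probability; undetected Ct values are recorded as missing (the
#' sentinel substitution is left to [impute_undetected()]).
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `ct`: long tibble `sample_id`, `mirna_id`, `ct`, `detected`;
#'   * `meta`: tibble `sample_id`, `subject_id`, `group`, `sex`,
#'     `time_point`, `ga_bd1`, `ga_bd2`, `ga` (the draw matching
#'     `time_point`);
#'   * `annotation`: as [simulate_annotation()];
#'   * `truth`: ground-truth list (planted effects, factor members,
#'     dropout probabilities).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_mirnas = 20, seed = 3))
#' dplyr::count(sim$meta, time_point, group, sex)
simulate_cohort <- function(config) {
  gs <- config$group_sizes
  n <- sum(gs$n)
  if (n < 1) abort("Configuration yields zero samples.")
  m <- config$n_mirnas
  annotation <- simulate_annotation(config)

  meta <- tidyr::uncount(gs, weights = .data$n)
  meta$sample_id <- sprintf("S%04d", seq_len(n))
  meta$subject_id <- sprintf("P%04d", seq_len(n))
  meta <- dplyr::select(meta, "sample_id", "subject_id", "group", "sex",
                        "time_point")

  ga1 <- config$ga_means_sds$ga_bd1
  ga2 <- config$ga_means_sds$ga_bd2
  meta$ga_bd1 <- with_seed(mix_seed(config$seed, "ga1"),
                           pmin(pmax(rnorm(n, ga1[1], ga1[2]), 10), 42))
  meta$ga_bd2 <- with_seed(mix_seed(config$seed, "ga2"),
                           pmin(pmax(rnorm(n, ga2[1], ga2[2]), 10), 42))
  meta$ga <- ifelse(meta$time_point == 2L, meta$ga_bd1, meta$ga_bd2)

  base <- with_seed(mix_seed(config$seed, "base"),
                    runif(m, config$base_ct_range[1], config$base_ct_range[2]))
  shift <- with_seed(mix_seed(config$seed, "shift"),
                     rnorm(n, 0, config$sample_shift_sd))
  z <- with_seed(mix_seed(config$seed, "noise"),
                 matrix(rnorm(n * m), nrow = n, ncol = m))

  # Latent co-secretion factor: replace member noise by a correlated
  # mixture in active strata, keeping the marginal variance at noise_sd^2.
  members <- integer(0)
  if (!is.null(config$cosecretion)) {
    cs <- config$cosecretion
    members <- cs$member_indices %||% select_members(cs, annotation,
                                                     config$seed)
    # Sign-balanced loadings: alternating member signs keep the factor
    # orthogonal to the per-sample mean, so global-mean normalization
    # (which can only see relative contrasts) preserves the planted
    # member-pair correlation |r| = loading^2 * scale.
    signs <- rep_len(c(1, -1), length(members))
    f <- with_seed(mix_seed(config$seed, "factor"), rnorm(n))
    strata_key <- paste(meta$group, meta$sex, meta$time_point, sep = "|")
    for (i in seq_len(nrow(cs$active_strata))) {
      st <- cs$active_strata[i, ]
      lam2 <- cs$loading^2 * st$scale
      lam <- sqrt(lam2)
      rows <- which(strata_key ==
                      paste(st$group, st$sex, st$time_point, sep = "|"))
      if (length(rows) == 0) next
      z[rows, members] <- outer(lam * f[rows], signs) +
        sqrt(1 - lam2) * z[rows, members, drop = FALSE]
    }
  }

  ct <- sweep(z * config$noise_sd, 2, base, "+") + shift
  if (!is.null(config$ga_slopes)) {
    slopes <- rep_len(config$ga_slopes, m)
    ct <- ct + outer(meta$ga - mean(meta$ga), slopes)
  }
  for (pe in config$planted_effects) {
    rows <- meta$group == pe$target_group
    if (pe$target_sex != "both") rows <- rows & meta$sex == pe$target_sex
    ct[rows, pe$mirna_index] <- ct[rows, pe$mirna_index] +
      pe$shift * config$noise_sd
  }

  p_drop <- dropout_probs(config)
  undetected <- with_seed(
    mix_seed(config$seed, "detect"),
    matrix(runif(n * m), nrow = n, ncol = m) <
      matrix(p_drop, nrow = n, ncol = m, byrow = TRUE)
  )
  ct[undetected] <- NA_real_
  rownames(ct) <- meta$sample_id
  colnames(ct) <- annotation$mirna_id
  rownames(undetected) <- meta$sample_id
  colnames(undetected) <- annotation$mirna_id

  ct_long <- matrix_to_long(ct, "ct")
  ct_long$detected <- !as.vector(undetected)

  list(
    ct = ct_long,
    meta = tibble::as_tibble(meta),
    annotation = annotation,
    truth = list(
      planted_effects = config$planted_effects,
      factor_members = annotation$mirna_id[members],
      dropout = p_drop,
      sample_shift = stats::setNames(shift, meta$sample_id)
    )
  )
}

# Pick factor members: the requested fraction from X-annotated miRNAs
# (as available), the rest from the autosomes; deterministic.
select_members <- function(cs, annotation, seed) {
  k <- cs$n_members
  x_pool <- which(annotation$chromosome == "X")
  other_pool <- which(annotation$chromosome != "X")
  kx <- min(round(cs$x_fraction * k), length(x_pool))
  with_seed(mix_seed(seed, "members"), {
    mem_x <- if (kx > 0) sample(x_pool, kx) else integer(0)
    mem_o <- sample(other_pool, k - kx)
    sort(c(mem_x, mem_o))
  })
}

#' Write synthetic cohort tables to disk
#'
#' Writes the Ct matrix (samples x assays, missing as empty cells), the
#' parallel detection flag table, metadata and annotation as TSV, and the
#' ground-truth tables as JSON.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ct_wide <- tidyr::pivot_wider(
    dplyr::select(sim$ct, "sample_id", "mirna_id", "ct"),
    names_from = "mirna_id", values_from = "ct"
  )
  det_wide <- tidyr::pivot_wider(
    dplyr::select(sim$ct, "sample_id", "mirna_id", "detected"),
    names_from = "mirna_id", values_from = "detected"
  )
  files <- file.path(dir, c("ct.tsv", "detected.tsv", "meta.tsv",
                            "annotation.tsv", "truth.json"))
  readr::write_tsv(ct_wide, files[1], na = "")
  readr::write_tsv(det_wide, files[2])
  readr::write_tsv(sim$meta, files[3])
  readr::write_tsv(sim$annotation, files[4])
  jsonlite::write_json(
    list(planted_effects = lapply(sim$truth$planted_effects, unclass),
         factor_members = sim$truth$factor_members),
    files[5], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(files)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `ct.tsv`, `detected.tsv`, `meta.tsv`
#'   and `annotation.tsv`.
#' @return A list with `ct` (long tibble), `meta` and `annotation`.
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("ct.tsv", "detected.tsv", "meta.tsv",
                           "annotation.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    abort(paste0("Missing cohort file(s): ",
                 paste(missing, collapse = ", ")))
  }
  ct_wide <- readr::read_tsv(need[1], show_col_types = FALSE)
  det_wide <- readr::read_tsv(need[2], show_col_types = FALSE)
  ct <- tidyr::pivot_longer(ct_wide, -"sample_id",
                            names_to = "mirna_id", values_to = "ct")
  det <- tidyr::pivot_longer(det_wide, -"sample_id",
                             names_to = "mirna_id", values_to = "detected")
  ct <- dplyr::left_join(ct, det, by = c("sample_id", "mirna_id"))
  list(ct = ct,
       meta = readr::read_tsv(need[3], show_col_types = FALSE),
       annotation = readr::read_tsv(need[4], show_col_types = FALSE,
                                    col_types = readr::cols(
                                      chromosome = readr::col_character())))
}
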