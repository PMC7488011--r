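#' Bootstrap configuration
#'
#' Bundles the resampling parameters shared by every bootstrap analysis:
#' the number of iterations, the per-test significance level, the master
#' seed, and whether strata are formed by exposure group alone or by
#' group crossed with fetal sex.
#'
#' @param n_iterations Number of bootstrap iterations (default 2000).
#' @param alpha Per-test significance level (default 0.05).
#' @param seed Master integer seed. Every random draw in the package is a
#'   deterministic function of this seed, a named analysis stream, the
#'   iteration number and the stratum, so results are reproducible
#'   regardless of evaluation order.
#' @param strata Either `"group"` or `"group_sex"`.
#' @return A list with class `"bootstrap_config"`.
#' @export
#' @examples
#' bootstrap_config(n_iterations = 500, seed = 42)
bootstrap_config <- function(n_iterations = 2000, alpha = 0.05, seed = 1L,
                             strata = c("group", "group_sex")) {
  strata <- match.arg(strata)
  if (n_iterations < 1) abort("`n_iterations` must be >= 1.")
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1).")
  structure(
    list(n_iterations = as.integer(n_iterations), alpha = alpha,
         seed = as.integer(seed), strata = strata),
    class = "bootstrap_config"
  )
}

# Deterministic within-stratum draw: positions 1..n with replacement.
# (seed, iteration, stratum, unit) fully determine the result.  `unit`
# supports the strict per-miRNA audit mode; the default shares one draw
# across the whole panel.
resample_positions <- function(n, seed, iteration, stratum, unit = NULL) {
  if (n < 1) abort(sprintf("Empty stratum '%s': cannot resample.", stratum))
  s <- if (is.null(unit)) {
    mix_seed(seed, iteration, stratum)
  } else {
    mix_seed(seed, iteration, stratum, unit)
  }
  with_seed(s, sample.int(n, n, replace = TRUE))
}

#' Resample all strata for one bootstrap iteration
#'
#' Draws, independently within each stratum, a with-replacement sample of
#' positions whose size equals the stratum size. The draw for a given
#' (seed, iteration, stratum) is reproducible and independent of any other
#' stratum or iteration.
#'
#' @param meta Sample metadata with columns `sample_id`, `group` and
#'   (for `strata = "group_sex"`) `sex`.
#' @param config A [bootstrap_config()].
#' @param iteration Iteration number (1-based).
#' @return A named list of integer vectors of row positions into `meta`,
#'   one per stratum, each of length equal to the stratum size.
#' @export
resample_strata <- function(meta, config, iteration) {
  stopifnot_cols(meta, "group", "meta")
  key <- if (config$strata == "group_sex") {
    stopifnot_cols(meta, "sex", "meta")
    paste(meta$group, meta$sex, sep = "|")
  } else {
    as.character(meta$group)
  }
  pos_by_stratum <- split(seq_len(nrow(meta)), key)
  lapply(stats::setNames(names(pos_by_stratum), names(pos_by_stratum)),
         function(s) {
    pos <- pos_by_stratum[[s]]
    pos[resample_positions(length(pos), config$seed, iteration, s)]
  })
}

# Fast path used inside bootstrap loops: positions already split by group.
# Returns one concatenated index vector (group blocks in `names(groups)`
# order) so group labels can be precomputed once.
resample_groups <- function(pos_by_group, seed, iteration, tag) {
  unlist(lapply(names(pos_by_group), function(g) {
    pos <- pos_by_group[[g]]
    pos[resample_positions(length(pos), seed, iteration,
                           paste(tag, g, sep = "|"))]
  }), use.names = FALSE)
}
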