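#' Pipeline configuration
#'
#' Assembles everything [run_pipeline()] needs: where the input tables
#' come from (a [sim_config()] for synthetic cohorts, or a directory of
#' TSV files written by [write_cohort()]), which analyses to run, the
#' bootstrap settings and the output directory.
#'
#' @param out_dir Output directory for all TSV/JSON artifacts.
#' @param sim A [sim_config()] to generate the cohort, or `NULL`.
#' @param input_dir Directory with `ct.tsv`, `detected.tsv`, `meta.tsv`,
#'   `annotation.tsv` (used when `sim` is `NULL`).
#' @param analyses Subset of
#'   `c("stability", "effect", "correlation", "chromosome", "cohort")`.
#' @param n_iterations,alpha,seed Bootstrap settings (defaults 2000,
#'   0.05, 1).
#' @param threshold Detection-rate filter threshold (default 0.8).
#' @param by_group Apply the filter per exposure group instead of pooled.
#' @param time_points Time points to analyze (default `c(2, 3)`).
#' @param top_k Number of top chromosome pairs to report (default 10).
#' @return A list with class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, sim = NULL, input_dir = NULL,
                            analyses = c("stability", "effect",
                                         "correlation", "chromosome",
                                         "cohort"),
                            n_iterations = 2000, alpha = 0.05, seed = 1L,
                            threshold = 0.8, by_group = FALSE,
                            time_points = c(2L, 3L), top_k = 10) {
  known <- c("stability", "effect", "correlation", "chromosome", "cohort")
  bad <- setdiff(analyses, known)
  if (length(bad) > 0) {
    abort(paste0("Unknown analyses: ", paste(bad, collapse = ", ")))
  }
  if (is.null(sim) && is.null(input_dir)) {
    abort("Provide either `sim` or `input_dir`.")
  }
  structure(
    list(out_dir = out_dir, sim = sim, input_dir = input_dir,
         analyses = analyses,
         boot = bootstrap_config(n_iterations, alpha, seed),
         threshold = threshold, by_group = by_group,
         time_points = as.integer(time_points), top_k = top_k),
    class = "pipeline_config"
  )
}

#' Run the full bootstrap-stability pipeline
#'
#' Executes, in order: preprocessing (sentinel imputation, detection
#' filter, global-mean normalization), ANOVA/ANCOVA stability profiles
#' with sex-specific classification, bootstrap effect sizes with the
#' significant / outside-composite / baseline-dimorphism rules,
#' correlation-network count distributions with the count-exceedance
#' test, chromosome-pair enrichment, and cohort statistics. All outputs
#' are plain TSV/JSON under `config$out_dir`, plus a `manifest.json`
#' recording the seed, configuration hash and file list; identical
#' configurations produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list with the in-memory results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config().")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  files <- character(0)
  emit_tsv <- function(df, name) {
    readr::write_tsv(df, out(name))
    files <<- c(files, name)
  }
  emit_json <- function(x, name) {
    jsonlite::write_json(x, out(name), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <<- c(files, name)
  }

  # --- inputs -------------------------------------------------------
  cohort <- if (!is.null(config$sim)) {
    simulate_cohort(config$sim)
  } else {
    read_cohort(config$input_dir)
  }
  meta <- cohort$meta
  annot <- cohort$annotation
  boot <- config$boot
  results <- list()

  # --- preprocess ---------------------------------------------------
  ct_imp <- impute_undetected(cohort$ct)
  retained <- filter_expressed(cohort$ct, threshold = config$threshold,
                               meta = meta, by_group = config$by_group)
  dct <- global_mean_normalize(ct_imp, retained)
  emit_tsv(retained, "retained.tsv")
  emit_tsv(dct, "dct.tsv")
  results$retained <- retained
  results$dct <- dct
  message(sprintf("preprocess: %d samples, %d of %d assays retained",
                  dplyr::n_distinct(dct$sample_id),
                  sum(retained$retained), nrow(retained)))

  exposed_groups <- intersect(c("HEa", "HEua"), unique(meta$group))

  # --- stability ----------------------------------------------------
  if ("stability" %in% config$analyses) {
    prof <- purrr::map_dfr(config$time_points, function(tp) {
      purrr::map_dfr(c("anova", "ancova"), function(mod) {
        dplyr::mutate(
          stability_profile(dct, meta, time_point = tp, model = mod,
                            config = boot),
          time_point = tp)
      })
    })
    emit_tsv(prof, "stability_profiles.tsv")
    cls <- prof |>
      dplyr::group_by(.data$model, .data$time_point) |>
      dplyr::group_modify(~classify_sex_specific(.x)) |>
      dplyr::ungroup()
    cls_hits <- dplyr::filter(cls, .data$label != "none")
    emit_json(
      purrr::map(split(cls_hits, paste0(cls_hits$model, "_tp",
                                        cls_hits$time_point)),
                 ~purrr::map2(.x$mirna_id, .x$label,
                              function(id, lab) list(mirna_id = id,
                                                     label = lab))),
      "sex_specific.json")
    results$stability <- prof
    results$sex_specific <- cls
    message(sprintf("stability: %d profiles, %d sex-specific calls",
                    nrow(prof), sum(cls$label != "none")))
  }

  # --- effect sizes -------------------------------------------------
  if ("effect" %in% config$analyses) {
    eff <- purrr::map_dfr(config$time_points, function(tp) {
      composite <- purrr::map_dfr(exposed_groups, function(g) {
        classify_significant_effect(
          bootstrap_effect_size(dct, meta, g, time_point = tp,
                                config = boot))
      })
      sexed <- purrr::map_dfr(exposed_groups, function(g) {
        purrr::map_dfr(c("M", "F"), function(s) {
          est <- classify_significant_effect(
            bootstrap_effect_size(dct, meta, g, time_point = tp, sex = s,
                                  config = boot))
          classify_outside_composite(est, composite)
        })
      })
      dplyr::bind_rows(
        dplyr::mutate(composite, outside_composite = NA),
        sexed
      ) |>
        dplyr::mutate(time_point = tp)
    })
    emit_tsv(eff, "effect_sizes.tsv")
    base_dim <- purrr::map_dfr(config$time_points, function(tp) {
      dplyr::mutate(
        baseline_dimorphism(dct, meta, time_point = tp, config = boot),
        time_point = tp)
    })
    emit_tsv(base_dim, "baseline_dimorphism.tsv")
    results$effect <- eff
    results$baseline_dimorphism <- base_dim
    message(sprintf("effect: %d estimates, %d significant",
                    nrow(eff), sum(eff$significant)))
  }

  # --- correlation network -----------------------------------------
  if (any(c("correlation", "chromosome") %in% config$analyses)) {
    strata <- list(aggregated = NULL, male = "M", female = "F")
    corr_tests <- list()
    count_rows <- list()
    edges_store <- list()
    for (tp in config$time_points) {
      for (sname in names(strata)) {
        s <- strata[[sname]]
        dists <- lapply(
          stats::setNames(GROUP_LEVELS, GROUP_LEVELS),
          function(g) bootstrap_correlation_counts(
            dct, meta, g, time_point = tp, sex = s, config = boot))
        for (g in GROUP_LEVELS) {
          count_rows[[paste(g, sname, tp)]] <-
            dplyr::mutate(dists[[g]], group = g, stratum = sname,
                          time_point = tp)
        }
        for (g in exposed_groups) {
          corr_tests[[paste(g, sname, tp)]] <-
            correlation_count_test(dists[[g]], dists[["UE"]])
        }
        # primary (non-bootstrap) edges, for the chromosome analysis
        for (g in GROUP_LEVELS) {
          sub <- filter_stratum(meta, time_point = tp, sex = s, group = g)
          cm <- pearson_matrix(
            dplyr::semi_join(dct, sub, by = "sample_id"),
            alpha = boot$alpha)
          edges_store[[paste(g, sname, tp)]] <- significant_edges(cm)
        }
      }
    }
    if ("correlation" %in% config$analyses) {
      emit_tsv(dplyr::bind_rows(count_rows), "correlation_counts.tsv")
      tests <- dplyr::bind_rows(corr_tests)
      emit_tsv(tests, "correlation_tests.tsv")
      emit_json(purrr::pmap(tests, function(group, stratum, time_point,
                                            mean_exposed, mean_reference,
                                            p_value) {
        list(group = group, stratum = stratum, time_point = time_point,
             p = p_value)
      }), "correlation_tests.json")
      edges_out <- purrr::imap_dfr(edges_store, function(e, key) {
        parts <- strsplit(key, " ")[[1]]
        dplyr::mutate(e, group = parts[1], stratum = parts[2],
                      time_point = as.integer(parts[3]))
      })
      emit_tsv(edges_out, "significant_edges.tsv")
      results$correlation_counts <- dplyr::bind_rows(count_rows)
      results$correlation_tests <- tests
      results$edges <- edges_out
      message(sprintf("correlation: %d count tests, %d rejected at 0.05",
                      nrow(tests), sum(tests$p_value < 0.05)))
    }
    if ("chromosome" %in% config$analyses) {
      enr <- purrr::map_dfr(config$time_points, function(tp) {
        purrr::map_dfr(names(strata), function(sname) {
          purrr::map_dfr(exposed_groups, function(g) {
            e <- enrich_chromosome_pairs(
              edges_store[[paste(g, sname, tp)]],
              edges_store[[paste("UE", sname, tp)]], annot)
            ranked <- top_pairs(e, k = config$top_k)
            dplyr::mutate(
              dplyr::left_join(e, dplyr::select(ranked, "chrom_a",
                                                "chrom_b", "rank"),
                               by = c("chrom_a", "chrom_b")),
              group = g, stratum = sname, time_point = tp)
          })
        })
      })
      emit_tsv(enr, "chromosome_enrichment.tsv")
      results$enrichment <- enr
      message(sprintf("chromosome: %d pair buckets", nrow(enr)))
    }
  }

  # --- cohort statistics -------------------------------------------
  if ("cohort" %in% config$analyses) {
    demo <- meta |>
      dplyr::distinct(.data$subject_id, .keep_all = TRUE) |>
      dplyr::select("group", "sex", "ga_bd1", "ga_bd2")
    stats_tbl <- cohort_table(demo)
    emit_tsv(stats_tbl, "cohort_stats.tsv")
    results$cohort_stats <- stats_tbl
  }

  # --- manifest -----------------------------------------------------
  manifest <- list(
    package = "mirboot",
    version = as.character(utils::packageVersion("mirboot")),
    seed = boot$seed,
    n_iterations = boot$n_iterations,
    alpha = boot$alpha,
    threshold = config$threshold,
    analyses = config$analyses,
    time_points = config$time_points,
    config_hash = rlang::hash(config),
    files = sort(files)
  )
  emit_json(manifest, "manifest.json")
  results$manifest <- manifest
  invisible(results)
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys are the arguments of
#' [pipeline_config()]; an optional `sim` mapping holds [sim_config()]
#' arguments (planted effects and co-secretion specs are constructed in
#' R, not YAML).
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}
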