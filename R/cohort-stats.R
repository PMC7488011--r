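#' Fisher's exact test for r x c contingency tables
#'
#' Two-sided Freeman-Halton Fisher exact test: conditional on the
#' margins, the p-value is the total multivariate hypergeometric
#' probability of all tables at most as probable as the observed one.
#' `method = "exact"` enumerates (via [stats::fisher.test()]'s network
#' algorithm); `method = "montecarlo"` estimates the same tail from
#' margin-fixed random tables and also reports a standard error.
#'
#' @param counts Non-negative integer matrix (at least 2 x 2) with
#'   positive row and column margins.
#' @param method `"exact"` or `"montecarlo"`.
#' @param n_draws Monte Carlo draws (default 1e6).
#' @param seed Seed for the Monte Carlo draw.
#' @param workspace Workspace for the exact network algorithm (raise for
#'   large sparse tables).
#' @return The p-value, with attributes `method` and, for Monte Carlo,
#'   `n_draws` and `se`.
#' @export
#' @examples
#' fisher_exact_rxc(matrix(c(5, 0, 0, 5), 2))  # 2/252
fisher_exact_rxc <- function(counts, method = c("exact", "montecarlo"),
                             n_draws = 1e6, seed = 1L, workspace = 2e5) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort("Need at least a 2 x 2 table.")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative integers.")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("Zero row or column margin.")
  }
  if (method == "exact") {
    p <- stats::fisher.test(counts, workspace = workspace)$p.value
    structure(min(p, 1), method = "exact")
  } else {
    ft <- with_seed(seed,
                    stats::fisher.test(counts, simulate.p.value = TRUE,
                                       B = as.integer(n_draws)))
    p <- ft$p.value
    structure(p, method = "montecarlo", n_draws = as.integer(n_draws),
              se = sqrt(p * (1 - p) / n_draws))
  }
}

#' Kruskal-Wallis rank sum test p-value
#'
#' Tie-corrected Kruskal-Wallis H with the chi-squared reference
#' (k - 1 degrees of freedom). Fully degenerate data (every value
#' identical) return H = 0, p = 1.
#'
#' @param values Numeric vector, or a list of per-group vectors.
#' @param groups Grouping vector aligned with `values` (ignored when
#'   `values` is a list).
#' @return The p-value, with attribute `statistic` (H).
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  g <- factor(groups)
  if (nlevels(g) < 2) abort("Need at least 2 non-empty groups.")
  if (length(unique(values)) == 1) {
    return(structure(1, statistic = 0))
  }
  kt <- stats::kruskal.test(values, g)
  structure(unname(kt$p.value), statistic = unname(kt$statistic))
}

#' Demographic contingency tables of the reference cohort
#'
#' The packaged r x c count tables of the categorical demographic
#' variables of the 93-subject reference cohort (two heavily exposed
#' groups and one unexposed group), with group column order HEa, HEua,
#' UE. All tables total 93 subjects except smoking status (92; one
#' missing response).
#'
#' @return Named list of integer matrices with dimnames.
#' @export
#' @examples
#' demographic_tables()$child_sex
demographic_tables <- function() {
  grp <- c("HEa", "HEua", "UE")
  tbl <- function(rows, counts) {
    matrix(counts, nrow = length(rows), byrow = TRUE,
           dimnames = list(rows, grp))
  }
  list(
    recruitment_site = tbl(
      c("Khmelnytsky", "Rivne"),
      c(20, 6, 13,
        14, 17, 23)),
    marital_status = tbl(
      c("Married or co-habiting", "Single/separated"),
      c(30, 20, 34,
        4, 3, 2)),
    education = tbl(
      c("Less than high school", "High school or equivalent",
        "Some college or higher"),
      c(4, 1, 0,
        18, 13, 13,
        12, 9, 23)),
    socioeconomic = tbl(
      c("8-19", "20-29", "30-39", "40-54", "55-66"),
      c(8, 1, 2,
        4, 5, 6,
        12, 10, 8,
        8, 5, 13,
        2, 2, 7)),
    gravidity = tbl(
      c("> 1", "1"),
      c(16, 12, 20,
        18, 11, 16)),
    parity = tbl(
      c("> 0", "0"),
      c(14, 10, 16,
        20, 13, 20)),
    smoking = tbl(
      c("Current smoker", "Never", "Past smoker (quit after pregnancy)",
        "Past smoker (quit before pregnancy)"),
      c(10, 5, 3,
        9, 6, 31,
        11, 7, 1,
        3, 5, 1)),
    multivitamin_after = tbl(
      c("No", "Yes"),
      c(12, 3, 8,
        22, 20, 28)),
    multivitamin_prior = tbl(
      c("No", "Yes"),
      c(14, 7, 15,
        20, 16, 21)),
    child_sex = tbl(
      c("Females", "Males"),
      c(18, 14, 14,
        16, 9, 22))
  )
}

#' Write the demographic fixture tables as TSV
#'
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_demographic_tables <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- demographic_tables()
  files <- purrr::imap_chr(tabs, function(tab, nm) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    df <- tibble::as_tibble(tab, rownames = "level")
    readr::write_tsv(df, f)
    f
  })
  invisible(unname(files))
}

#' Demographic summary table with group tests
#'
#' Per-subject demographic data frame in, tidy test table out:
#' continuous variables get a Kruskal-Wallis rank sum p-value,
#' categorical variables a Fisher's exact r x c p-value. Exact
#' enumeration is used for tables up to 3 x 3; larger tables default to
#' the Monte Carlo tail estimate.
#'
#' @param demo Data frame with one row per subject, a `group` column and
#'   any number of demographic columns.
#' @param group_col Name of the grouping column.
#' @param n_draws,seed Monte Carlo settings for large tables.
#' @return Tibble `variable`, `type`, `method`, `p_value`.
#' @export
cohort_table <- function(demo, group_col = "group", n_draws = 1e6,
                         seed = 1L) {
  stopifnot_cols(demo, group_col, "demo")
  grp <- demo[[group_col]]
  vars <- setdiff(names(demo), group_col)
  purrr::map_dfr(vars, function(v) {
    x <- demo[[v]]
    if (is.numeric(x)) {
      keep <- !is.na(x)
      p <- kruskal_wallis(x[keep], grp[keep])
      tibble::tibble(variable = v, type = "continuous",
                     method = "kruskal-wallis", p_value = as.numeric(p))
    } else {
      tab <- table(x, grp)
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (length(unique(as.vector(tab))) == 1 && nrow(tab) == 1) {
        return(tibble::tibble(variable = v, type = "categorical",
                              method = "fisher-exact", p_value = 1))
      }
      if (nrow(tab) < 2 || ncol(tab) < 2) {
        return(tibble::tibble(variable = v, type = "categorical",
                              method = "fisher-exact", p_value = 1))
      }
      method <- if (nrow(tab) <= 3 && ncol(tab) <= 3) "exact"
                else "montecarlo"
      p <- fisher_exact_rxc(unclass(tab), method = method,
                            n_draws = n_draws, seed = seed)
      tibble::tibble(variable = v, type = "categorical",
                     method = paste0("fisher-", attr(p, "method")),
                     p_value = as.numeric(p))
    }
  })
}
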