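# Canonical unordered chromosome-pair labels: "6|X" with the two labels
# ordered 1..22, X, Y.  Intra-chromosome pairs ("21|21") are legal.
canonical_pair <- function(ca, cb) {
  ia <- match(ca, CHROM_LEVELS)
  ib <- match(cb, CHROM_LEVELS)
  if (anyNA(ia) || anyNA(ib)) abort("Unknown chromosome label.")
  swap <- ia > ib
  a <- ifelse(swap, cb, ca)
  b <- ifelse(swap, ca, cb)
  list(chrom_a = a, chrom_b = b)
}

#' Map significant miRNA pairs to chromosome-pair counts
#'
#' Each significantly correlated miRNA pair increments exactly one
#' unordered chromosome-pair bucket ((6, X) and (X, 6) are the same
#' bucket; pairs of miRNAs on the same chromosome count toward the
#' intra-chromosome bucket).
#'
#' @param edges Edge tibble with columns `mirna_a`, `mirna_b` (e.g. from
#'   [significant_edges()]).
#' @param annot Annotation tibble `mirna_id`, `chromosome`.
#' @return Tibble `chrom_a`, `chrom_b`, `n`, summed over edges.
#' @export
#' @examples
#' annot <- tibble::tibble(mirna_id = c("a", "b", "c", "d"),
#'                         chromosome = c("X", "6", "6", "X"))
#' edges <- tibble::tibble(mirna_a = c("a", "c"), mirna_b = c("b", "d"))
#' map_pairs_to_chromosomes(edges, annot)
map_pairs_to_chromosomes <- function(edges, annot) {
  stopifnot_cols(edges, c("mirna_a", "mirna_b"), "edges")
  stopifnot_cols(annot, c("mirna_id", "chromosome"), "annot")
  if (nrow(edges) == 0) {
    return(tibble::tibble(chrom_a = character(0), chrom_b = character(0),
                          n = integer(0)))
  }
  ca <- annot$chromosome[match(edges$mirna_a, annot$mirna_id)]
  cb <- annot$chromosome[match(edges$mirna_b, annot$mirna_id)]
  if (anyNA(ca) || anyNA(cb)) {
    bad <- unique(c(edges$mirna_a[is.na(ca)], edges$mirna_b[is.na(cb)]))
    abort(paste0("Unannotated miRNA(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  pair <- canonical_pair(ca, cb)
  tibble::tibble(chrom_a = pair$chrom_a, chrom_b = pair$chrom_b) |>
    dplyr::count(.data$chrom_a, .data$chrom_b, name = "n") |>
    dplyr::arrange(match(.data$chrom_a, CHROM_LEVELS),
                   match(.data$chrom_b, CHROM_LEVELS))
}

#' Percent change in chromosome-pair correlation counts
#'
#' `100 * (count_exposed - count_control) / count_control`. Pairs absent
#' from the control group have no defined change and are returned as
#' `NA` (flagged "undefined" downstream, excluded from ranking).
#'
#' @param count_exposed,count_control Non-negative counts (vectorized).
#' @return Percent change, `NA` where `count_control` is 0.
#' @export
#' @examples
#' percent_change(c(15, 0, 7), c(10, 10, 0))  # 50, -100, NA
percent_change <- function(count_exposed, count_control) {
  ifelse(count_control > 0,
         100 * (count_exposed - count_control) / count_control,
         NA_real_)
}

#' Chromosome-pair enrichment between exposed and control groups
#'
#' Joins the chromosome-pair counts of significantly correlated miRNA
#' pairs in an exposed and a control group (missing buckets count 0) and
#' computes the percent change per pair.
#'
#' @param edges_exposed,edges_control Significant-edge tibbles.
#' @param annot Annotation tibble.
#' @param min_control Minimum control count for a defined enrichment
#'   (default 1; pairs below it get `percent_change = NA`).
#' @return Tibble of class `"mb_enrichment"`: `chrom_a`, `chrom_b`,
#'   `count_exposed`, `count_control`, `percent_change`.
#' @export
enrich_chromosome_pairs <- function(edges_exposed, edges_control, annot,
                                    min_control = 1) {
  ex <- dplyr::rename(map_pairs_to_chromosomes(edges_exposed, annot),
                      count_exposed = "n")
  ct <- dplyr::rename(map_pairs_to_chromosomes(edges_control, annot),
                      count_control = "n")
  res <- dplyr::full_join(ex, ct, by = c("chrom_a", "chrom_b")) |>
    dplyr::mutate(
      count_exposed = dplyr::coalesce(.data$count_exposed, 0L),
      count_control = dplyr::coalesce(.data$count_control, 0L),
      percent_change = ifelse(
        .data$count_control >= min_control,
        percent_change(.data$count_exposed, .data$count_control),
        NA_real_)
    ) |>
    dplyr::arrange(match(.data$chrom_a, CHROM_LEVELS),
                   match(.data$chrom_b, CHROM_LEVELS))
  new_mb_tbl(res, "mb_enrichment", min_control = min_control)
}

#' Top enriched chromosome pairs
#'
#' The `k` chromosome pairs with the highest percent change in
#' significant correlations (undefined enrichments excluded). Ties are
#' broken by exposed count (descending) and then by the lexicographic
#' pair label, so the ranking is deterministic.
#'
#' @param enrichment Output of [enrich_chromosome_pairs()] (or any tibble
#'   with `chrom_a`, `chrom_b`, `count_exposed`, `percent_change`).
#' @param k Number of pairs to return (default 10).
#' @return The ranked tibble with a `rank` column.
#' @export
top_pairs <- function(enrichment, k = 10) {
  defined <- dplyr::filter(enrichment, !is.na(.data$percent_change))
  ranked <- defined |>
    dplyr::arrange(dplyr::desc(.data$percent_change),
                   dplyr::desc(.data$count_exposed),
                   paste(.data$chrom_a, .data$chrom_b)) |>
    head(k)
  dplyr::mutate(ranked, rank = dplyr::row_number())
}
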