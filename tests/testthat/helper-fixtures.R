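# Shared fixture builders (all data generated in code).

# Minimal long Ct tibble from a samples x assays matrix.
ct_from_matrix <- function(m, detected = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("m%02d", seq_len(ncol(m)))
  if (is.null(detected)) detected <- !is.na(m)
  tibble::tibble(
    sample_id = rep(rownames(m), times = ncol(m)),
    mirna_id = rep(colnames(m), each = nrow(m)),
    ct = as.vector(m),
    detected = as.vector(detected)
  )
}

# Two-group expression fixture for effect-size tests: one miRNA, direct
# dct values.
two_group_dct <- function(x, y, groups = c("HEa", "UE")) {
  n <- length(x) + length(y)
  ids <- sprintf("s%03d", seq_len(n))
  list(
    dct = tibble::tibble(sample_id = ids, mirna_id = "m01",
                         dct = c(x, y)),
    meta = tibble::tibble(sample_id = ids,
                          group = rep(groups, c(length(x), length(y))),
                          sex = "F", time_point = 2L, ga = 20,
                          ga_bd1 = 19, ga_bd2 = 33)
  )
}

# Small three-group cohort with iid normal expression, m miRNAs.
null_cohort <- function(n_per_group = 10, m = 6, seed = 1, sd = 1) {
  groups <- rep(c("UE", "HEua", "HEa"), each = n_per_group)
  n <- length(groups)
  ids <- sprintf("s%03d", seq_len(n))
  set.seed(seed)
  mat <- matrix(rnorm(n * m, sd = sd), n, m,
                dimnames = list(ids, sprintf("m%02d", seq_len(m))))
  list(
    dct = ct_from_matrix(mat) |>
      dplyr::rename(dct = "ct") |>
      dplyr::select(-"detected"),
    meta = tibble::tibble(sample_id = ids, group = groups,
                          sex = rep_len(c("M", "F"), n),
                          time_point = 2L,
                          ga = rnorm(n, 19, 4), ga_bd1 = rnorm(n, 19, 4),
                          ga_bd2 = rnorm(n, 33, 2))
  )
}
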