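# Internal helpers: deterministic seed derivation and long/wide pivots.

# Deterministic 31-bit hash of arbitrary scalars/strings.  Used to derive
# independent, order-insensitive RNG streams: the draw for a given
# (master seed, stream, iteration, stratum) is the same no matter how many
# other analyses ran before it.  Arithmetic stays below 2^53 so the modular
# reduction is exact in doubles.
mix_seed <- function(...) {
  h <- 5381
  for (part in list(...)) {
    vals <- if (is.character(part)) {
      unlist(lapply(part, utf8ToInt), use.names = FALSE)
    } else {
      as.numeric(part)
    }
    for (v in vals) {
      h <- (h * 33 + abs(v) %% 2147483647) %% 2147483647
    }
  }
  as.integer(h)
}

# Named child stream of a master seed ("anova", "effect", "corr", ...).
# Adding a new analysis stream never perturbs draws in existing ones.
stream_seed <- function(seed, stream) {
  mix_seed(seed, stream)
}

# Evaluate `expr` with a local RNG state seeded deterministically.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
}

# Long Ct/expression tibble -> samples x miRNAs matrix.
values_matrix <- function(tbl, value_col) {
  stopifnot_cols(tbl, c("sample_id", "mirna_id", value_col), "data")
  wide <- tidyr::pivot_wider(
    dplyr::select(tbl, dplyr::all_of(c("sample_id", "mirna_id", value_col))),
    names_from = "mirna_id", values_from = dplyr::all_of(value_col)
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  storage.mode(m) <- "double"
  m
}

matrix_to_long <- function(m, value_col) {
  tibble::tibble(
    sample_id = rep(rownames(m), times = ncol(m)),
    mirna_id = rep(colnames(m), each = nrow(m)),
    !!value_col := as.vector(m)
  )
}

# Subset metadata to one time point and optional sex; keeps group levels.
filter_stratum <- function(meta, time_point = NULL, sex = NULL,
                           group = NULL) {
  out <- meta
  if (!is.null(time_point)) {
    out <- dplyr::filter(out, .data$time_point %in% !!time_point)
  }
  if (!is.null(sex)) out <- dplyr::filter(out, .data$sex %in% !!sex)
  if (!is.null(group)) out <- dplyr::filter(out, .data$group %in% !!group)
  out
}

stratum_label <- function(sex) {
  if (is.null(sex)) "aggregated" else if (sex == "M") "male" else "female"
}

new_mb_tbl <- function(tbl, class, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(tbl, nm) <- attrs[[nm]]
  class(tbl) <- c(class, class(tbl))
  tbl
}
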