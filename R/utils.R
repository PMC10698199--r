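# Internal helpers shared across modules.

#' Convert a wide uptake tibble to a numeric matrix
#'
#' Wide uptake tables carry one row per subject, an identifier column and
#' one numeric column per voxel or parcel.  This strips the identifier and
#' returns the numeric matrix with subject ids as rownames, preserving
#' column order.
#'
#' @param data data frame with one row per subject.
#' @param id_col name of the identifier column (default `"subject_id"`).
#' @return numeric matrix, subjects in rows.
#' @keywords internal
#' @noRd
uptake_matrix <- function(data, id_col = "subject_id") {
  stopifnot(is.data.frame(data))
  if (!id_col %in% names(data)) {
    abort(sprintf("column '%s' not found", id_col))
  }
  ids <- as.character(data[[id_col]])
  m <- as.matrix(data[setdiff(names(data), id_col)])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

# Deterministic modal value; ties broken by the smallest value.
mode_label <- function(x) {
  tab <- tabulate(x)
  which.max(tab)
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG. A NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Derive a stream of child seeds from one seed, all below 2^31.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
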