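# Seed-voxel by parcel co-metabolism profiles: Fisher-z transformed
# Pearson correlations across subjects, with a subject-level bootstrap.

#' Fisher z transform of a correlation coefficient
#'
#' `atanh(r)` after clipping `r` to +/-(1 - 1e-7); the clip keeps perfect
#' correlations finite so downstream Euclidean clustering stays defined.
#'
#' @param r correlations in `[-1, 1]`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) abort("|r| > 1")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Seed-voxel by parcel covariance profile matrix
#'
#' For every seed voxel v and parcel p, the Pearson correlation across
#' subjects between voxel uptake and parcel mean uptake, Fisher-z
#' transformed.  Rows and columns follow the input column order exactly.
#'
#' @param seed_uptake data frame: `subject_id` plus one column per seed
#'   voxel.
#' @param parcel_uptake data frame: `subject_id` plus one column per
#'   parcel; same subjects, same order.
#' @return object of class `cov_profile` with elements `z` (V x P
#'   matrix), `voxel_ids`, `parcel_ids`, `n_subjects`.
#' @export
voxel_parcel_covariance <- function(seed_uptake, parcel_uptake,
                                    id_col = "subject_id") {
  X <- uptake_matrix(seed_uptake, id_col)
  Y <- uptake_matrix(parcel_uptake, id_col)
  if (!identical(rownames(X), rownames(Y))) {
    abort("subject ids/order differ between seed and parcel tables")
  }
  if (nrow(X) < 3) abort("need at least 3 subjects")
  check_variance(X, "seed voxel")
  check_variance(Y, "parcel")
  z <- fisher_z(cor(X, Y))
  structure(list(z = z, voxel_ids = colnames(X), parcel_ids = colnames(Y),
                 n_subjects = nrow(X)),
            class = "cov_profile")
}

check_variance <- function(M, what) {
  v <- matrixStats_colVars(M)
  bad <- which(v == 0)
  if (length(bad) > 0) {
    abort(sprintf("zero-variance %s column(s): %s", what,
                  paste(colnames(M)[bad], collapse = ", ")))
  }
}

matrixStats_colVars <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  (colSums(M^2) - n * mu^2) / (n - 1)
}

#' @export
tidy.cov_profile <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$z, responseName = "z",
                                        stringsAsFactors = FALSE)) |>
    stats::setNames(c("voxel_id", "parcel_id", "z"))
}

#' Subject-level bootstrap of the covariance profile matrix
#'
#' Draws `n_boot` bootstrap samples of subjects (with replacement, full
#' cohort size) and recomputes the profile matrix for each.  Columns that
#' become degenerate (zero variance) within a replicate are dropped from
#' that replicate with a warning.
#'
#' @inheritParams voxel_parcel_covariance
#' @param n_boot number of bootstrap replicates (the original analysis
#'   used 500).
#' @param seed RNG seed; fixed seed gives a bit-identical ensemble.
#' @param .draws optional list of index vectors overriding the random
#'   draws (testing hook).
#' @return object of class `boot_ensemble`: `matrices` (list of
#'   `cov_profile`), `subject_draws`, `n_boot`, `seed`.
#' @export
bootstrap_covariance <- function(seed_uptake, parcel_uptake, n_boot = 500,
                                 seed = 1L, id_col = "subject_id",
                                 .draws = NULL) {
  stopifnot(n_boot >= 1)
  X <- uptake_matrix(seed_uptake, id_col)
  Y <- uptake_matrix(parcel_uptake, id_col)
  n <- nrow(X)
  draws <- .draws %||% with_seed(seed, {
    lapply(seq_len(n_boot), function(i) sample.int(n, n, replace = TRUE))
  })
  mats <- lapply(draws, function(idx) boot_profile(X[idx, , drop = FALSE],
                                                   Y[idx, , drop = FALSE]))
  structure(list(matrices = mats, subject_draws = draws,
                 n_boot = length(draws), seed = seed),
            class = "boot_ensemble")
}

# covariance for one bootstrap draw; degenerate columns dropped, not fatal
boot_profile <- function(X, Y) {
  vx <- matrixStats_colVars(X); vy <- matrixStats_colVars(Y)
  if (any(vx == 0)) {
    warn(sprintf("dropping %d degenerate seed voxel(s) in replicate",
                 sum(vx == 0)))
    X <- X[, vx > 0, drop = FALSE]
  }
  if (any(vy == 0)) {
    warn(sprintf("dropping %d degenerate parcel(s) in replicate",
                 sum(vy == 0)))
    Y <- Y[, vy > 0, drop = FALSE]
  }
  z <- fisher_z(cor(X, Y))
  structure(list(z = z, voxel_ids = colnames(X), parcel_ids = colnames(Y),
                 n_subjects = nrow(X)),
            class = "cov_profile")
}
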