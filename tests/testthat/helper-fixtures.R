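# Shared fixture builders; everything is generated in code.

# tiny cohort for fast covariance / clustering tests
small_cohort <- function(seed = 42, ...) {
  cfg <- synthetic_config(n_subjects = 40, n_parcels = 24,
                          n_seed_voxels = 60, k_true = 3,
                          parcels_per_cluster = 4, ...)
  generate_cohort(cfg, seed = seed)
}

# block atlas: a grid split into `n` labels along the first axis
block_atlas <- function(dims = c(10, 10, 10), n = 4,
                        division = "cortex", hemisphere = "L") {
  labs <- array(0L, dims)
  cuts <- cut(seq_len(dims[1]), n, labels = FALSE)
  for (i in seq_len(dims[1])) labs[i, , ] <- cuts[i]
  label_atlas(labs, tibble::tibble(
    label = seq_len(n), name = paste0("r", seq_len(n)),
    division = division, hemisphere = hemisphere))
}

wide_tbl <- function(M, ids = sprintf("s%02d", seq_len(nrow(M))),
                     prefix = "c") {
  colnames(M) <- colnames(M) %||% sprintf("%s%03d", prefix, seq_len(ncol(M)))
  dplyr::bind_cols(tibble::tibble(subject_id = ids), tibble::as_tibble(M))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
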