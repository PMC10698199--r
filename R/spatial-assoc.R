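# Spatial association of unthresholded network maps with reference maps
# (behavioral term maps, receptor/transporter maps, gene-set expression
# maps): region-level Pearson correlation adjusted for a spatial
# covariate, permutation nulls (plain or autocorrelation-preserving) and
# one-sample t tests of Fisher-z correlations against the null, with
# Benjamini-Hochberg correction across reference maps.

#' Region-wise mean values of a voxel map
#'
#' @param voxel_map 3-D numeric array (e.g. a T map painted on voxels).
#' @param atlas a `label_atlas` on the same grid.
#' @param exclude region ids to drop (e.g. white matter and CSF).
#' @return tibble: `region_id`, `value`; regions with no voxels are
#'   excluded with a warning.
#' @export
extract_region_values <- function(voxel_map, atlas, exclude = integer(0)) {
  stopifnot(identical(dim(voxel_map), dim(atlas$grid)))
  labs <- as.vector(atlas$grid)
  vals <- as.vector(voxel_map)
  keep <- labs != 0 & !(labs %in% exclude)
  mu <- tapply(vals[keep], labs[keep], mean)
  wanted <- setdiff(sort(atlas$label_table$label), exclude)
  got <- as.integer(names(mu))
  empty <- setdiff(wanted, got)
  if (length(empty) > 0) {
    warn(sprintf("excluding %d region(s) with no voxels", length(empty)))
  }
  tibble::tibble(region_id = got, value = as.numeric(mu))
}

# join two (or three) region-value tables on their common regions
common_regions <- function(...) {
  tabs <- list(...)
  ids <- Reduce(intersect, lapply(tabs, function(t) t$region_id))
  lapply(tabs, function(t) t$value[match(ids, t$region_id)])
}

#' Spatial correlation adjusted for a covariate map
#'
#' Pearson correlation of two region-value maps after each is regressed
#' on the covariate map (plus intercept); used to adjust map-to-map
#' associations for a shared spatial confound such as the grey-matter
#' probability profile.
#'
#' @param x,y,covar tibbles with `region_id`, `value`.
#' @return the partial Pearson correlation (scalar).
#' @export
partial_spatial_correlation <- function(x, y, covar) {
  v <- common_regions(x, y, covar)
  if (length(v[[1]]) < 4) abort("need at least 4 common regions")
  if (sd(v[[3]]) == 0) {
    warn("constant covariate; returning plain correlation")
    return(cor(v[[1]], v[[2]]))
  }
  rx <- stats::residuals(lm(v[[1]] ~ v[[3]]))
  ry <- stats::residuals(lm(v[[2]] ~ v[[3]]))
  # a map (numerically) proportional to the covariate leaves no residual
  # variation: the adjusted association is zero by construction
  tol <- 1e-10
  if (sd(rx) <= tol * sd(v[[1]]) || sd(ry) <= tol * sd(v[[2]])) return(0)
  unname(cor(rx, ry))
}

#' Decode a map against a library of term maps
#'
#' Pearson correlation of the query map with every term map over their
#' common regions; terms with r above the threshold are retained, sorted
#' by descending correlation.
#'
#' @param map tibble with `region_id`, `value`.
#' @param term_maps named list of tibbles with `region_id`, `value`.
#' @param threshold retain terms with `r > threshold` (strict; default
#'   0.1).
#' @return tibble: `term`, `r`, descending.
#' @export
decode_terms <- function(map, term_maps, threshold = 0.1) {
  rs <- vapply(term_maps, function(tm) {
    v <- common_regions(map, tm)
    cor(v[[1]], v[[2]])
  }, 0)
  out <- tibble::tibble(term = names(term_maps) %||%
                          as.character(seq_along(term_maps)),
                        r = unname(rs))
  out |>
    dplyr::filter(.data$r > threshold) |>
    dplyr::arrange(dplyr::desc(.data$r))
}

#' Permutation null ensemble for a region map
#'
#' `"shuffle"` permutes region values freely.  `"autocorr_preserving"`
#' draws several candidate permutations per null map and keeps the one
#' whose empirical variogram (squared value differences binned by
#' distance along the region ordering) best matches the observed map's,
#' giving surrogate maps that respect its spatial autocorrelation.
#'
#' @param map tibble with `region_id`, `value`.
#' @param n_perm number of null maps (>= 100).
#' @param mode `"autocorr_preserving"` (default) or `"shuffle"`.
#' @param n_candidates candidates per null map in variogram matching.
#' @param seed RNG seed.
#' @return numeric matrix, regions x `n_perm`; each column one null map.
#' @export
build_null <- function(map, n_perm = 1000,
                       mode = c("autocorr_preserving", "shuffle"),
                       n_candidates = 20, seed = 1L) {
  mode <- match.arg(mode)
  if (n_perm < 100) abort("n_perm must be at least 100")
  v <- map$value
  n <- length(v)
  with_seed(seed, {
    if (mode == "shuffle") {
      out <- replicate(n_perm, v[sample.int(n)])
    } else {
      target <- variogram_chain(v)
      out <- replicate(n_perm, {
        cands <- replicate(n_candidates, sample.int(n), simplify = FALSE)
        scores <- vapply(cands, function(p) {
          sum((variogram_chain(v[p]) - target)^2)
        }, 0)
        v[cands[[which.min(scores)]]]
      })
    }
    rownames(out) <- map$region_id
    out
  })
}

# empirical variogram over the chain ordering, first few lags
variogram_chain <- function(v, max_lag = min(10, length(v) - 1)) {
  vapply(seq_len(max_lag), function(h) {
    d <- v[seq_len(length(v) - h)] - v[(h + 1):length(v)]
    mean(d^2) / 2
  }, 0)
}

#' Null-referenced significance of spatial associations
#'
#' For each reference map, the observed Fisher-z correlations (one per
#' analyzed network map, e.g. left and right seeds) are compared to the
#' null ensemble of z correlations by a one-sample t test against the
#' null mean; p values are BH-corrected across reference maps.  A
#' permutation-tail p is always reported alongside; when only one
#' observed z exists (no t test possible) the tail p stands in.
#'
#' @param observed_z named list (per reference map) of numeric vectors
#'   of observed Fisher-z correlations.
#' @param null_z named list (matching names) of numeric vectors of null
#'   Fisher-z correlations.
#' @return tibble: `map`, `mean_z`, `null_mean`, `p`, `p_perm`, `q`,
#'   `n_obs`, `n_null`.
#' @export
association_test <- function(observed_z, null_z) {
  stopifnot(length(observed_z) > 0)
  nm <- names(observed_z)
  if (is.null(nm)) nm <- as.character(seq_along(observed_z))
  res <- purrr::map_dfr(seq_along(observed_z), function(i) {
    obs <- observed_z[[i]]
    nul <- null_z[[i]]
    if (length(nul) == 0) abort("empty null ensemble")
    null_mean <- mean(nul)
    p_perm <- (1 + sum(abs(nul - null_mean) >= abs(mean(obs) - null_mean))) /
      (1 + length(nul))
    p <- if (length(obs) >= 2 && sd(obs) > 0) {
      t.test(obs, mu = null_mean)$p.value
    } else p_perm
    tibble::tibble(map = nm[i], mean_z = mean(obs), null_mean = null_mean,
                   p = p, p_perm = p_perm,
                   n_obs = length(obs), n_null = length(nul))
  })
  res$q <- p.adjust(res$p, method = "BH")
  res
}

#' Full spatial association of a network map with reference maps
#'
#' Convenience chain: adjusted correlation of the (region-extracted)
#' network map with each reference map, Fisher-z transform, null
#' ensemble per reference map, and the null-referenced test.
#'
#' @param net_map tibble with `region_id`, `value` (unthresholded T
#'   values per region).
#' @param reference_maps named list of tibbles (`region_id`, `value`).
#' @param covar optional covariate map for autocorrelation adjustment.
#' @param n_perm,mode,seed passed to [build_null()].
#' @return tibble as from [association_test()] with an extra `r` column.
#' @export
spatial_association <- function(net_map, reference_maps, covar = NULL,
                                n_perm = 1000,
                                mode = "autocorr_preserving", seed = 1L) {
  corr1 <- function(a, b) {
    if (is.null(covar)) {
      v <- common_regions(a, b); cor(v[[1]], v[[2]])
    } else partial_spatial_correlation(a, b, covar)
  }
  obs <- lapply(reference_maps, function(rm) fisher_z(corr1(net_map, rm)))
  seeds <- child_seeds(seed, length(reference_maps))
  nulls <- lapply(seq_along(reference_maps), function(i) {
    rm <- reference_maps[[i]]
    nm <- build_null(rm, n_perm = n_perm, mode = mode, seed = seeds[i])
    apply(nm, 2, function(col) {
      fisher_z(corr1(net_map, tibble::tibble(region_id = rm$region_id,
                                             value = col)))
    })
  })
  names(nulls) <- names(reference_maps)
  out <- association_test(obs, nulls)
  out$r <- tanh(out$mean_z)
  out
}
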