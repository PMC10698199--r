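# Clustering of seed voxels by covariance-profile similarity: k-means with
# many random restarts, optimal label alignment, bootstrap mode consensus,
# split-half adjusted-Rand stability selection of k, and percent overlap
# against a reference subfield labeling.

#' K-means clustering of covariance profiles
#'
#' Euclidean k-means on the rows (voxels) of a profile matrix, keeping the
#' best of `restarts` random initializations by total within-cluster sum
#' of squares.  Restarts that converge to an empty cluster are
#' re-initialized.
#'
#' @param z a `cov_profile` or a plain numeric matrix (voxels in rows).
#' @param k number of clusters (`k <=` number of voxels).
#' @param restarts random restarts (the original analysis used 500).
#' @param max_iter iteration cap per restart (original: 255).
#' @param seed RNG seed for the initializations.
#' @return integer vector of cluster labels in `1..k`, named by voxel id.
#' @export
kmeans_profiles <- function(z, k, restarts = 500, max_iter = 255,
                            seed = NULL) {
  M <- if (inherits(z, "cov_profile")) z$z else as.matrix(z)
  if (k > nrow(M)) abort("k exceeds the number of voxels")
  if (!all(is.finite(M))) abort("profiles must be finite")
  if (k == 1) return(setNames(rep(1L, nrow(M)), rownames(M)))
  fit <- with_seed(seed, kmeans_restarts(M, k, restarts, max_iter))
  setNames(as.integer(fit$cluster), rownames(M))
}

kmeans_restarts <- function(M, k, restarts, max_iter) {
  cpp_kmeans(M, as.integer(k), as.integer(restarts), as.integer(max_iter))
}

#' Align one labeling to a reference by optimal label permutation
#'
#' Solves the assignment problem on the k x k contingency table, finding
#' the one-to-one relabeling of `candidate` that maximizes agreement with
#' `reference`.  Makes mode consensus across bootstrap replicates well
#' defined.
#'
#' @param candidate,reference integer label vectors of equal length with
#'   the same number of clusters.
#' @return relabeled `candidate`.
#' @export
align_labels <- function(candidate, reference) {
  if (length(candidate) != length(reference)) abort("length mismatch")
  k1 <- length(unique(candidate)); k2 <- length(unique(reference))
  k <- max(candidate, reference)
  if (k1 != k2) abort("differing numbers of clusters")
  tab <- table(factor(candidate, levels = 1:k),
               factor(reference, levels = 1:k))
  perm <- as.integer(e1071::matchClasses(unclass(tab), method = "exact",
                                         verbose = FALSE))
  out <- perm[candidate]
  names(out) <- names(candidate)
  out
}

#' Mode consensus across aligned labelings
#'
#' Per-voxel most frequent cluster label across an ensemble of aligned
#' label vectors; ties break to the smallest label id.
#'
#' @param ensemble list of equal-length integer label vectors, all
#'   aligned to a common reference.
#' @param provenance optional list recorded on the result.
#' @return object of class `parcellation`: `labels`, `k`, `provenance`.
#' @export
consensus_mode <- function(ensemble, provenance = list()) {
  if (length(ensemble) == 0) abort("empty ensemble")
  L <- do.call(rbind, ensemble)
  labels <- apply(L, 2, mode_label)
  labels <- setNames(as.integer(labels), colnames(L) %||% names(ensemble[[1]]))
  new_parcellation(labels, provenance)
}

new_parcellation <- function(labels, provenance = list()) {
  u <- sort(unique(labels))      # compact to 1..k, keeping id order
  relabeled <- setNames(as.integer(match(labels, u)), names(labels))
  structure(list(labels = relabeled, k = length(u),
                 provenance = provenance),
            class = "parcellation")
}

#' @export
tidy.parcellation <- function(x, ...) {
  tibble::tibble(voxel_id = names(x$labels) %||%
                   as.character(seq_along(x$labels)),
                 label = unname(x$labels))
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d voxels, k = %d\n", length(x$labels), x$k))
  print(table(x$labels))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie chance-corrected agreement computed from the contingency
#' table; 1 for identical partitions, about 0 at chance.
#'
#' @param a,b label vectors of equal length (length >= 2).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("length mismatch")
  n <- length(a)
  stopifnot(n >= 2)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  mx <- (ai + bj) / 2
  if (mx == expected) return(0)   # both partitions trivial
  (nij - expected) / (mx - expected)
}

#' Bootstrap consensus parcellation
#'
#' The full chain for one cohort: the profile matrix of the non-resampled
#' sample is clustered to give a reference labeling; each bootstrap
#' replicate is clustered, aligned to the reference by optimal
#' assignment, and the per-voxel mode across replicates is the consensus.
#'
#' @inheritParams bootstrap_covariance
#' @param k number of clusters.
#' @param restarts,max_iter passed to [kmeans_profiles()].
#' @return a `parcellation` with provenance (k, n_boot, restarts, seed).
#' @export
consensus_parcellation <- function(seed_uptake, parcel_uptake, k,
                                   n_boot = 500, restarts = 100,
                                   max_iter = 255, seed = 1L,
                                   id_col = "subject_id") {
  seeds <- child_seeds(seed, 2L)
  full <- voxel_parcel_covariance(seed_uptake, parcel_uptake, id_col)
  ens <- bootstrap_covariance(seed_uptake, parcel_uptake, n_boot,
                              seed = seeds[2], id_col = id_col)
  consensus_from_ensemble(full, ens, k, restarts, max_iter,
                          seed = seeds[1])
}

# consensus for one k given precomputed full-sample profile and bootstrap
# ensemble; shared by consensus_parcellation and split_half_stability
consensus_from_ensemble <- function(full, ens, k, restarts = 100,
                                    max_iter = 255, seed = 1L) {
  seeds <- child_seeds(seed, ens$n_boot + 1L)
  ref <- kmeans_profiles(full, k, restarts, max_iter, seed = seeds[1])
  labs <- lapply(seq_along(ens$matrices), function(i) {
    li <- kmeans_profiles(ens$matrices[[i]], k, restarts, max_iter,
                          seed = seeds[1 + i])
    align_labels(li, ref)
  })
  consensus_mode(labs, provenance = list(k = k, n_boot = ens$n_boot,
                                         restarts = restarts, seed = seed))
}

#' Split-half stability curve for choosing k
#'
#' Subjects are repeatedly split into random halves; the full covariance
#' -> k-means -> bootstrap consensus chain runs independently in each
#' half, and the adjusted Rand index between the two half parcellations
#' is recorded.  The stability of each k is the mean ARI over splits;
#' `selected_k` maximizes it (ties go to the smaller k).
#'
#' @inheritParams bootstrap_covariance
#' @param ks candidate cluster counts (the original study examined 2-6).
#' @param n_splits number of random splits (original: 10,000; desk-scale
#'   runs use 100).
#' @param n_boot_per_half bootstrap replicates inside each half.
#' @param restarts k-means restarts per clustering inside the splits.
#' @return object of class `stability_curve`: tibble `curve` (`k`,
#'   `mean_ari`, `sd_ari`, `n_splits`) plus `selected_k`.
#' @export
split_half_stability <- function(seed_uptake, parcel_uptake, ks = 2:6,
                                 n_splits = 100, n_boot_per_half = 50,
                                 restarts = 5, max_iter = 100,
                                 seed = 1L, id_col = "subject_id") {
  stopifnot(length(ks) >= 1)
  n <- nrow(seed_uptake)
  if (n < 6) abort("need at least 6 subjects for split-half stability")
  split_seeds <- child_seeds(seed, n_splits)
  ari <- matrix(NA_real_, n_splits, length(ks),
                dimnames = list(NULL, as.character(ks)))
  for (s in seq_len(n_splits)) {
    sub_seeds <- child_seeds(split_seeds[s], 5L)
    idx <- with_seed(sub_seeds[1], sample.int(n))
    h1 <- idx[seq_len(floor(n / 2))]
    h2 <- idx[(floor(n / 2) + 1):n]
    if (length(h1) < 3 || length(h2) < 3) abort("half too small")
    halves <- lapply(1:2, function(h) {
      rows <- if (h == 1) h1 else h2
      su <- seed_uptake[rows, , drop = FALSE]
      pu <- parcel_uptake[rows, , drop = FALSE]
      list(full = voxel_parcel_covariance(su, pu, id_col),
           ens = bootstrap_covariance(su, pu, n_boot_per_half,
                                      seed = sub_seeds[1 + h],
                                      id_col = id_col))
    })
    for (j in seq_along(ks)) {
      p1 <- consensus_from_ensemble(halves[[1]]$full, halves[[1]]$ens,
                                    ks[j], restarts, max_iter,
                                    seed = sub_seeds[4])
      p2 <- consensus_from_ensemble(halves[[2]]$full, halves[[2]]$ens,
                                    ks[j], restarts, max_iter,
                                    seed = sub_seeds[5])
      # a consensus that empties a cluster is not a reproducible k-level
      # solution; score such splits at chance level rather than letting
      # two collapsed partitions agree trivially
      ari[s, j] <- if (p1$k < ks[j] || p2$k < ks[j]) 0 else
        adjusted_rand_index(p1$labels, p2$labels)
    }
  }
  curve <- tibble::tibble(
    k = ks,
    mean_ari = colMeans(ari),
    sd_ari = apply(ari, 2, sd),
    n_splits = n_splits
  )
  selected_k <- ks[which.max(curve$mean_ari)]   # which.max ties -> first
  structure(list(curve = curve, selected_k = selected_k, ari = ari),
            class = "stability_curve")
}

#' @export
tidy.stability_curve <- function(x, ...) x$curve

#' @export
glance.stability_curve <- function(x, ...) {
  tibble::tibble(selected_k = x$selected_k,
                 best_mean_ari = max(x$curve$mean_ari),
                 n_splits = x$curve$n_splits[1])
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("<stability_curve> selected k = %d\n", x$selected_k))
  print(x$curve)
  invisible(x)
}

#' @export
autoplot.stability_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$k,
                                             y = .data$mean_ari)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_ari - .data$sd_ari,
      ymax = .data$mean_ari + .data$sd_ari)) +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = 2) +
    ggplot2::labs(x = "number of clusters k",
                  y = "split-half adjusted Rand index") +
    ggplot2::theme_minimal()
}

#' Percent overlap of parcellation subregions with reference fields
#'
#' For each (subregion, reference field) pair: 100 x |intersection| /
#' |subregion voxels|.
#'
#' @param parc a `parcellation` (or integer label vector).
#' @param reference integer labels of the reference fields over the same
#'   voxels (0 allowed for unlabeled).
#' @return tibble: `subregion`, `field`, `percent_overlap`.
#' @export
percent_overlap <- function(parc, reference) {
  labels <- if (inherits(parc, "parcellation")) parc$labels else parc
  if (length(labels) != length(reference)) abort("geometry mismatch")
  tab <- table(subregion = labels, field = reference)
  sizes <- rowSums(tab)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  out$percent_overlap <- 100 * out$Freq / sizes[out$subregion]
  tibble::as_tibble(out[, c("subregion", "field", "percent_overlap")])
}

#' Write a parcellation to NIfTI with a JSON provenance sidecar
#'
#' @param parc a `parcellation`.
#' @param mask the `seed_mask` whose true voxels the labels cover, in
#'   grid order.
#' @param path output `.nii`/`.nii.gz` path; provenance goes to
#'   `<path>.json`.
#' @param affine voxel-to-world transform.
#' @export
write_parcellation <- function(parc, mask, path, affine = iso_affine(2)) {
  g <- mask_grid(mask)
  stopifnot(sum(g) == length(parc$labels))
  out <- array(0L, dim(g))
  out[g] <- parc$labels
  write_volume(out, path, affine = affine)
  jsonlite::write_json(c(parc$provenance, list(k = parc$k)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
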