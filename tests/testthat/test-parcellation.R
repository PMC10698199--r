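# brute-force oracle: best label permutation by exhaustive search
perm_align_oracle <- function(candidate, reference) {
  k <- max(candidate, reference)
  perms <- gtools_permutations(k)
  best <- NULL; best_agree <- -1
  for (i in seq_len(nrow(perms))) {
    relab <- perms[i, ][candidate]
    agree <- sum(relab == reference)
    if (agree > best_agree) { best_agree <- agree; best <- relab }
  }
  best
}

# all permutations of 1..k without external packages
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    ins <- cbind(sub[, seq_len(i - 1), drop = FALSE], k,
                 sub[, seq(i, k - 1)[seq_len(k - i)], drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}

test_that("k-means separates well-spread clouds and handles degenerate k", {
  set.seed(1)
  M <- rbind(matrix(rnorm(40 * 5), 40, 5),
             matrix(rnorm(40 * 5, mean = 20), 40, 5))
  labs <- kmeans_profiles(M, 2, restarts = 10, seed = 1)
  # brute-force nearest-centroid check: each point closer to own centroid
  cen <- rbind(colMeans(M[labs == 1, ]), colMeans(M[labs == 2, ]))
  d <- as.matrix(dist(rbind(M, cen)))[1:80, 81:82]
  expect_equal(unname(apply(d, 1, which.min)), unname(labs))
  expect_equal(adjusted_rand_index(labs, rep(1:2, each = 40)), 1)
  # k = 1: everything one cluster
  expect_true(all(kmeans_profiles(M, 1) == 1))
  # duplicated rows land in the same cluster
  M2 <- rbind(M, M[1, , drop = FALSE])
  l2 <- kmeans_profiles(M2, 2, restarts = 10, seed = 2)
  expect_equal(l2[81], l2[1], ignore_attr = TRUE)
  expect_error(kmeans_profiles(M, 100), "exceeds")
})

test_that("label alignment matches exhaustive permutation search", {
  set.seed(7)
  for (k in 2:4) {
    for (rep in 1:5) {
      reference <- sample(1:k, 40, replace = TRUE)
      reference[1:k] <- 1:k   # every label present
      perm <- sample(k)
      noisy <- perm[reference]
      flip <- sample(40, 6)
      noisy[flip] <- sample(1:k, 6, replace = TRUE)
      if (length(unique(noisy)) != k) next
      got <- align_labels(noisy, reference)
      oracle <- perm_align_oracle(noisy, reference)
      expect_equal(sum(got == reference), sum(oracle == reference))
    }
  }
  # exact permutation recovery and identity
  ref <- rep(1:3, times = c(5, 7, 9))
  cand <- c(2, 3, 1)[ref]
  expect_equal(unname(align_labels(cand, ref)), ref)
  expect_equal(unname(align_labels(ref, ref)), ref)
  expect_error(align_labels(c(1, 1, 2), c(1, 2, 3)), "differing")
})

test_that("mode consensus is deterministic with smallest-label tie-break", {
  expect_equal(unname(consensus_mode(list(c(1, 1, 2), c(1, 2, 2),
                                          c(1, 1, 2)))$labels),
               c(1, 1, 2))
  # voxel with tie {1,2} goes to 1
  expect_equal(unname(consensus_mode(list(c(1L), c(2L)))$labels), 1L)
  # idempotence: consensus of identical members is that labeling
  lab <- c(2, 1, 3, 3, 1)
  cm <- consensus_mode(list(lab, lab, lab))
  expect_equal(unname(cm$labels), c(2, 1, 3, 3, 1))
  expect_equal(cm$k, 3)
})

test_that("adjusted Rand index matches the contingency-table formula", {
  # hand-computed oracle for a=(1,1,2,2), b=(1,2,2,2):
  # n=4, pairs=6, sum_ij C(nij,2)=1, ai: C(2,2)+C(2,2)=2, bj: C(1,2)+C(3,2)=3
  # expected = 2*3/6 = 1, max = (2+3)/2 = 2.5 -> ARI = (1-1)/(2.5-1) = 0
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0)
  a <- c(1, 1, 1, 2, 2, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, rep(1, 6)), 0)  # chance correction
  # symmetry and label-permutation invariance on random partitions,
  # cross-checked against an independent implementation
  skip_if_not_installed("mclust")
  set.seed(3)
  for (i in 1:10) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), adjusted_rand_index(y, x))
    expect_equal(adjusted_rand_index(x, y),
                 adjusted_rand_index(c(5, 2, 9, 1)[x], y))
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})

test_that("bootstrap consensus recovers the planted parcellation deterministically", {
  co <- small_cohort()
  p1 <- consensus_parcellation(co$seed_uptake, co$parcel_uptake, k = 3,
                               n_boot = 15, restarts = 10, seed = 5)
  p2 <- consensus_parcellation(co$seed_uptake, co$parcel_uptake, k = 3,
                               n_boot = 15, restarts = 10, seed = 5)
  expect_identical(p1$labels, p2$labels)
  expect_gte(adjusted_rand_index(p1$labels, co$truth$voxel_labels), 0.95)
  expect_equal(sort(unique(unname(p1$labels))), 1:3)
})

test_that("split-half stability selects the planted k and collapses on noise", {
  co <- small_cohort()
  sc <- split_half_stability(co$seed_uptake, co$parcel_uptake, ks = 2:4,
                             n_splits = 8, n_boot_per_half = 10,
                             restarts = 5, seed = 11)
  expect_equal(sc$selected_k, 3)
  expect_true(all(sc$curve$mean_ari >= -1 & sc$curve$mean_ari <= 1))
  expect_equal(glance(sc)$selected_k, 3)
  expect_s3_class(autoplot(sc), "ggplot")
  # pure noise: stability near zero for every k > 1
  noise <- synthetic_config(n_subjects = 40, n_parcels = 24,
                            n_seed_voxels = 40, k_true = 2,
                            parcels_per_cluster = 4, loading = 0,
                            noise_sd = 1)
  cn <- generate_cohort(noise, seed = 12)
  sn <- split_half_stability(cn$seed_uptake, cn$parcel_uptake, ks = 2:3,
                             n_splits = 8, n_boot_per_half = 10,
                             restarts = 5, seed = 13)
  expect_true(all(abs(sn$curve$mean_ari) < 0.3))
})

test_that("degenerate identical halves give perfect stability", {
  co <- small_cohort()
  # duplicate every subject so each half can contain one copy of each
  su <- dplyr::bind_rows(co$seed_uptake, co$seed_uptake)
  su$subject_id <- sprintf("s%03d", seq_len(nrow(su)))
  pu <- dplyr::bind_rows(co$parcel_uptake, co$parcel_uptake)
  pu$subject_id <- su$subject_id
  sc <- split_half_stability(su, pu, ks = 3, n_splits = 3,
                             n_boot_per_half = 8, restarts = 5, seed = 2)
  expect_gte(sc$curve$mean_ari[1], 0.9)
})

test_that("percent overlap computes the forced arithmetic", {
  parc <- new_parcellation(c(rep(1L, 10), rep(2L, 10)))
  # subregion 1 fully inside field 7, subregion 2 half in 7 half in 8
  reference <- c(rep(7L, 10), rep(7L, 5), rep(8L, 5))
  ov <- percent_overlap(parc, reference)
  get <- function(s, f) ov$percent_overlap[ov$subregion == s & ov$field == f]
  expect_equal(get("1", "7"), 100)
  expect_equal(get("1", "8"), 0)
  expect_equal(get("2", "7"), 50)
  expect_equal(get("2", "8"), 50)
  # row sums equal 100 when fields partition the voxels
  sums <- tapply(ov$percent_overlap, ov$subregion, sum)
  expect_true(all(abs(sums - 100) < 1e-12))
  expect_error(percent_overlap(parc, reference[-1]), "geometry")
})

test_that("parcellation writes to NIfTI with provenance sidecar", {
  g <- array(FALSE, c(6, 6, 6)); g[1:20] <- TRUE
  parc <- new_parcellation(rep(1:2, 10), provenance = list(seed = 1))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_parcellation(parc, seed_mask(g, "L"), path)
  back <- read_volume(path)
  expect_equal(as.vector(back$grid[g]), rep(1:2, 10))
  expect_true(file.exists(paste0(path, ".json")))
  expect_equal(jsonlite::read_json(paste0(path, ".json"))$k, 2)
})
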