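# Synthetic cohorts, reference maps and donor microarray tables with the
# statistical structure the pipeline assumes: a linear latent-factor model
# for across-subject metabolic covariance, additive diagnosis-group uptake
# shifts, biomarker values straddling the published cut-offs, and donor
# expression tables with planted spatial gradients.

#' Configuration for the synthetic uptake cohort
#'
#' The generator plants `k_true` clusters among the seed voxels.  Each
#' cluster c carries a per-subject latent factor f_sc ~ N(0,1); its voxels
#' take uptake mu_gc + loading * f_sc + N(0, noise_sd), and a disjoint set
#' of parcels shares the same factor, so voxels of a cluster genuinely
#' co-vary with "their" parcels across subjects and with nothing else.
#' Remaining parcels are independent noise.  Group effects are additive
#' mean shifts per cluster.
#'
#' @param n_subjects number of subjects.
#' @param n_parcels number of brain parcels.
#' @param n_seed_voxels number of seed (hippocampus) voxels.
#' @param k_true planted cluster count.
#' @param loading factor loading strength (dimensionless).
#' @param noise_sd independent voxel/parcel noise SD.
#' @param parcels_per_cluster parcels tied to each planted cluster.
#' @param baseline mean uptake level (pons-normalized units).
#' @param group_probs named sampling probabilities over diagnosis groups.
#' @param group_effects named list: per-group additive uptake shift,
#'   recycled over clusters.
#' @export
synthetic_config <- function(n_subjects = 100, n_parcels = 60,
                             n_seed_voxels = 200, k_true = 5,
                             loading = 1, noise_sd = 0.5,
                             parcels_per_cluster = 6,
                             baseline = 1.2,
                             group_probs = c(HC = 0.4, earlyMCI = 0.25,
                                             lateMCI = 0.2, AD = 0.15),
                             group_effects = list(HC = 0, earlyMCI = -0.02,
                                                  lateMCI = -0.06,
                                                  AD = -0.12)) {
  stopifnot(k_true >= 1, n_seed_voxels >= k_true, noise_sd >= 0,
            k_true * parcels_per_cluster <= n_parcels)
  structure(list(n_subjects = n_subjects, n_parcels = n_parcels,
                 n_seed_voxels = n_seed_voxels, k_true = k_true,
                 loading = loading, noise_sd = noise_sd,
                 parcels_per_cluster = parcels_per_cluster,
                 baseline = baseline, group_probs = group_probs,
                 group_effects = group_effects),
            class = "synthetic_config")
}

#' Generate a synthetic uptake cohort with planted covariance structure
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer RNG seed; the generator is a pure function of
#'   `(cfg, seed)`.
#' @return list of class `sim_cohort`:
#'   `seed_uptake` — tibble, `subject_id` plus one column per seed voxel;
#'   `parcel_uptake` — tibble, `subject_id` plus one column per parcel;
#'   `subjects` — tibble with group and CSF biomarker values;
#'   `truth` — planted voxel labels, cluster-to-parcel map, group truth.
#' @export
generate_cohort <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$k_true > cfg$n_seed_voxels) abort("more clusters than seed voxels")
  with_seed(seed, {
    n <- cfg$n_subjects; k <- cfg$k_true
    groups <- sample(names(cfg$group_probs), n, replace = TRUE,
                     prob = cfg$group_probs)
    # planted voxel labels: near-equal blocks
    voxel_labels <- sort(rep_len(seq_len(k), cfg$n_seed_voxels))
    cluster_parcels <- split(
      seq_len(k * cfg$parcels_per_cluster),
      rep(seq_len(k), each = cfg$parcels_per_cluster)
    )
    f <- matrix(rnorm(n * k), n, k)                      # latent factors
    shift <- vapply(groups, function(g) cfg$group_effects[[g]], 0)
    seed_mat <- cfg$baseline + shift +
      cfg$loading * f[, voxel_labels, drop = FALSE] +
      matrix(rnorm(n * cfg$n_seed_voxels, sd = cfg$noise_sd),
             n, cfg$n_seed_voxels)
    parcel_factor <- matrix(0, n, cfg$n_parcels)
    for (c in seq_len(k)) parcel_factor[, cluster_parcels[[c]]] <- f[, c]
    parcel_mat <- cfg$baseline + shift + cfg$loading * parcel_factor +
      matrix(rnorm(n * cfg$n_parcels, sd = cfg$noise_sd), n, cfg$n_parcels)
    ids <- sprintf("s%03d", seq_len(n))
    bm <- generate_biomarkers(groups)
    dimnames(seed_mat) <- list(ids, sprintf("v%04d", seq_len(cfg$n_seed_voxels)))
    dimnames(parcel_mat) <- list(ids, sprintf("p%03d", seq_len(cfg$n_parcels)))
    structure(list(
      seed_uptake = dplyr::bind_cols(tibble::tibble(subject_id = ids),
                                     tibble::as_tibble(seed_mat)),
      parcel_uptake = dplyr::bind_cols(tibble::tibble(subject_id = ids),
                                       tibble::as_tibble(parcel_mat)),
      subjects = dplyr::bind_cols(
        tibble::tibble(subject_id = ids, group = groups,
                       vx = 2, vy = 2, vz = 2), bm),
      truth = list(voxel_labels = voxel_labels,
                   cluster_parcel_map = cluster_parcels,
                   groups = stats::setNames(groups, ids))
    ), class = "sim_cohort")
  })
}

# CSF biomarker values per diagnosis group, centred so that controls sit
# on the negative side of the published cut-offs (abeta 977 / p-tau 24 /
# t-tau 266 pg/mL) and dementia-spectrum groups on the positive side.
generate_biomarkers <- function(groups) {
  n <- length(groups)
  ab_mu <- c(HC = 1300, earlyMCI = 950, lateMCI = 820, AD = 650)[groups]
  pt_mu <- c(HC = 18, earlyMCI = 26, lateMCI = 30, AD = 38)[groups]
  tt_mu <- c(HC = 210, earlyMCI = 280, lateMCI = 320, AD = 400)[groups]
  tibble::tibble(
    abeta42 = pmax(rnorm(n, ab_mu, 150), 100),
    ptau = pmax(rnorm(n, pt_mu, 5), 2),
    ttau = pmax(rnorm(n, tt_mu, 60), 20)
  )
}

#' Generate reference maps with controllable spatial autocorrelation
#'
#' Regions lie on an adjacency chain; each map is white noise smoothed by
#' a moving average of half-width `smoothness` along the chain
#' (`smoothness = 0` leaves white noise).
#'
#' @param n_maps,n_regions counts.
#' @param smoothness non-negative integer moving-average half-width.
#' @param seed RNG seed.
#' @return tibble: `region_id` plus one numeric column per map
#'   (`map01`, ...).
#' @export
generate_reference_maps <- function(n_maps, n_regions, smoothness = 0,
                                    seed = 1L) {
  if (n_regions < 2) abort("need at least 2 regions")
  with_seed(seed, {
    maps <- vapply(seq_len(n_maps), function(i) {
      x <- rnorm(n_regions)
      smooth_chain(x, smoothness)
    }, numeric(n_regions))
    maps <- matrix(maps, nrow = n_regions)
    colnames(maps) <- sprintf("map%02d", seq_len(n_maps))
    dplyr::bind_cols(tibble::tibble(region_id = seq_len(n_regions)),
                     tibble::as_tibble(maps))
  })
}

# moving average over a chain with reflecting edges
smooth_chain <- function(x, half_width) {
  if (half_width <= 0) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - half_width):min(n, i + half_width)
    mean(x[idx])
  }, 0)
}

#' Generate donor microarray expression tables with planted gradients
#'
#' Emulates donor-level microarray inputs: a probe annotation table with
#' probe-to-gene multiplicity and occasional missing Entrez ids, a
#' samples-by-probes intensity matrix with above-background flags, and
#' sample coordinates at region centroids.  Designated gradient genes
#' share a monotone spatial gradient across regions; all their probes
#' inherit it plus donor noise.
#'
#' @param n_donors,n_regions,n_probes,n_genes counts
#'   (`n_probes >= n_genes`).
#' @param gradient_genes character vector of gene symbols (subset of the
#'   generated `g0001`... symbols) carrying the planted gradient.
#' @param noise_sd donor/sample noise SD.
#' @param frac_unannotated fraction of probes stripped of their Entrez id.
#' @param seed RNG seed.
#' @return list with `probes` (tibble: probe_id, gene_symbol, entrez_id)
#'   and `donors`, a list per donor of `samples` (sample_id, x, y, z,
#'   hemisphere, division, region_id) and `expression` / `above_bg`
#'   (samples x probes matrices), plus `region_info` (centroids).
#' @export
generate_donor_expression <- function(n_donors = 4, n_regions = 20,
                                      n_probes = 60, n_genes = 40,
                                      gradient_genes = c("g0001", "g0002"),
                                      noise_sd = 0.3,
                                      frac_unannotated = 0.1,
                                      seed = 1L) {
  if (n_genes > n_probes) abort("more genes than probes")
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    gene_of_probe <- genes[c(seq_len(n_genes),
                             sample.int(n_genes, n_probes - n_genes,
                                        replace = TRUE))]
    probes <- tibble::tibble(
      probe_id = sprintf("pr%04d", seq_len(n_probes)),
      gene_symbol = gene_of_probe,
      entrez_id = seq_along(gene_of_probe) + 1000L
    )
    drop <- sample.int(n_probes, round(frac_unannotated * n_probes))
    probes$entrez_id[drop] <- NA_integer_
    # region centroids on a line, alternating hemisphere kept L for
    # simplicity; division split cortex / subcortex
    region_info <- tibble::tibble(
      region_id = seq_len(n_regions),
      x = -40, y = seq(-60, 60, length.out = n_regions), z = 10,
      hemisphere = "L",
      division = rep(c("cortex", "subcortex"),
                     length.out = n_regions)
    )
    gradient <- seq(0, 1, length.out = n_regions)   # monotone in region id
    is_grad <- probes$gene_symbol %in% gradient_genes
    donors <- lapply(seq_len(n_donors), function(d) {
      # one sample per region, at the centroid (plus tiny jitter)
      samples <- region_info
      samples$sample_id <- sprintf("d%02d_s%03d", d, seq_len(n_regions))
      expr <- matrix(rnorm(n_regions * n_probes, mean = 6, sd = noise_sd),
                     n_regions, n_probes)
      expr[, is_grad] <- expr[, is_grad] + 4 * gradient
      dimnames(expr) <- list(samples$sample_id, probes$probe_id)
      above <- matrix(runif(length(expr)) > 0.05, n_regions, n_probes,
                      dimnames = dimnames(expr))
      list(donor_id = sprintf("donor%02d", d),
           samples = samples[, c("sample_id", "x", "y", "z", "hemisphere",
                                 "division", "region_id")],
           expression = expr, above_bg = above)
    })
    list(probes = probes, donors = donors, region_info = region_info,
         gradient_genes = gradient_genes, gradient = gradient)
  })
}
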