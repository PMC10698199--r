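# Regional gene expression from donor microarray tables: probe
# annotation and intensity filtering, differential-stability probe
# selection, distance-constrained sample-to-region assignment, robust
# sigmoid normalization and donor aggregation, plus gene-set expression
# reference maps.

#' Drop probes without a valid Entrez id
#'
#' @param probes tibble with `probe_id`, `gene_symbol`, `entrez_id`.
#' @export
drop_unannotated_probes <- function(probes) {
  keep <- !is.na(probes$entrez_id) & probes$entrez_id > 0
  if (!any(keep)) abort("all probes lack a valid Entrez id")
  probes[keep, , drop = FALSE]
}

#' Filter probes by expression intensity relative to background
#'
#' A probe is discarded when its intensity falls below background in at
#' least `frac` of all samples pooled across donors (at exactly the
#' fraction it is discarded).
#'
#' @param probes probe annotation tibble.
#' @param above_bg list (per donor) of samples x probes logical
#'   matrices, TRUE = above background.
#' @param frac discard threshold on the below-background fraction.
#' @return the surviving probe rows.
#' @export
intensity_filter <- function(probes, above_bg, frac = 0.5) {
  pooled <- do.call(rbind, lapply(above_bg, function(m) {
    m[, probes$probe_id, drop = FALSE]
  }))
  below_frac <- colMeans(!pooled)
  probes[below_frac < frac, , drop = FALSE]
}

#' Differential stability of one probe across donors
#'
#' Mean Spearman rank correlation of the probe's regional expression
#' pattern over all donor pairs, computed on the regions present in both
#' donors of a pair.
#'
#' @param regional list (one element per donor) of named numeric
#'   vectors: regional expression of the probe, names = region ids.
#' @return scalar in `[-1, 1]`.
#' @export
differential_stability <- function(regional) {
  n <- length(regional)
  if (n < 2) abort("need at least 2 donors")
  pairs <- utils::combn(n, 2)
  rhos <- apply(pairs, 2, function(ij) {
    a <- regional[[ij[1]]]; b <- regional[[ij[2]]]
    common <- intersect(names(a), names(b))
    if (length(common) < 3) return(NA_real_)
    suppressWarnings(cor(a[common], b[common], method = "spearman"))
  })
  mean(rhos, na.rm = TRUE)
}

#' Differential stability for every probe
#'
#' @param donor_regional list per donor of regions x probes matrices
#'   (rownames = region ids, colnames = probe ids).
#' @return tibble: `probe_id`, `ds`.
#' @export
differential_stability_all <- function(donor_regional) {
  probes <- colnames(donor_regional[[1]])
  ds <- vapply(probes, function(p) {
    differential_stability(lapply(donor_regional, function(m) m[, p]))
  }, 0)
  tibble::tibble(probe_id = probes, ds = unname(ds))
}

#' Select the most stable probe per gene
#'
#' Per gene, keeps the probe with maximal differential stability; exact
#' ties break to the lexicographically smallest probe id.
#'
#' @param scores tibble with `probe_id`, `ds`.
#' @param probes annotation tibble mapping `probe_id` to `gene_symbol`.
#' @return tibble: `gene_symbol`, `probe_id`, `ds`, one row per gene.
#' @export
select_probe_per_gene <- function(scores, probes) {
  merged <- dplyr::inner_join(probes, scores, by = "probe_id")
  dropped <- setdiff(unique(probes$gene_symbol),
                     unique(merged$gene_symbol))
  if (length(dropped) > 0) {
    warn(sprintf("%d gene(s) without surviving probes excluded",
                 length(dropped)))
  }
  merged |>
    dplyr::arrange(.data$gene_symbol, dplyr::desc(.data$ds),
                   .data$probe_id) |>
    dplyr::distinct(.data$gene_symbol, .keep_all = TRUE) |>
    dplyr::select("gene_symbol", "probe_id", "ds")
}

#' Assign donor tissue samples to atlas regions
#'
#' Each sample goes to the nearest region representative (centroid) with
#' the same hemisphere and gross structural division; samples whose
#' assignment distance exceeds the donor mean + 2 SD are then removed,
#' and samples with no candidate region stay unassigned.
#'
#' @param samples tibble: `sample_id`, `x`, `y`, `z`, `hemisphere`,
#'   `division` (mm, world space).
#' @param regions tibble: `region_id`, `x`, `y`, `z`, `hemisphere`,
#'   `division` (centroids).
#' @return tibble: `sample_id`, `region_id` (`NA` = unassigned),
#'   `distance`, `excluded`.
#' @export
assign_samples <- function(samples, regions) {
  res <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    cand <- regions[regions$hemisphere == s$hemisphere &
                      regions$division == s$division, , drop = FALSE]
    if (nrow(cand) == 0) {
      return(tibble::tibble(sample_id = s$sample_id,
                            region_id = NA_integer_,
                            distance = NA_real_))
    }
    d <- sqrt((cand$x - s$x)^2 + (cand$y - s$y)^2 + (cand$z - s$z)^2)
    j <- which.min(d)
    tibble::tibble(sample_id = s$sample_id, region_id = cand$region_id[j],
                   distance = d[j])
  })
  thr <- mean(res$distance, na.rm = TRUE) +
    2 * sd(res$distance, na.rm = TRUE)
  res$excluded <- !is.na(res$distance) & res$distance > thr
  res$region_id[res$excluded] <- NA_integer_
  res
}

#' Fill regions that received no sample from any donor
#'
#' For each such region, the nearest sample to its centroid is found per
#' donor; the cross-donor average of those samples' expression, weighted
#' by inverse centroid distance, fills the region.  Filled regions are
#' flagged imputed.
#'
#' @param donors list per donor: `samples` tibble and `expression`
#'   matrix (samples x genes/probes).
#' @param regions region centroid tibble (as in [assign_samples()]).
#' @param missing_regions integer region ids to fill.
#' @return tibble: `region_id`, imputed expression columns, `imputed`.
#' @export
fill_missing_regions <- function(donors, regions, missing_regions) {
  purrr::map_dfr(missing_regions, function(rid) {
    r <- regions[regions$region_id == rid, ]
    per_donor <- purrr::map(donors, function(d) {
      s <- d$samples
      dist <- sqrt((s$x - r$x)^2 + (s$y - r$y)^2 + (s$z - r$z)^2)
      j <- which.min(dist)
      row <- d$expression[j, , drop = FALSE]
      list(value = setNames(as.numeric(row), colnames(row)),
           dist = dist[j])
    })
    w <- vapply(per_donor, function(p) 1 / p$dist, 0)
    if (any(!is.finite(w))) {       # a sample exactly at the centroid
      w <- as.numeric(!is.finite(w))
    }
    vals <- do.call(rbind, lapply(per_donor, function(p) p$value))
    est <- colSums(vals * w) / sum(w)
    dplyr::bind_cols(tibble::tibble(region_id = rid, imputed = TRUE),
                     tibble::as_tibble(as.list(est)))
  })
}

#' Robust sigmoid normalization
#'
#' `1 / (1 + exp(-(x - median) / (IQR / 1.349)))`: an outlier-resistant
#' logistic scaling about the median, using the normalized interquartile
#' range (the IQR of a normal sample divided by 1.349 estimates its SD).
#' A zero IQR yields the constant 0.5 with a `degenerate` attribute.
#'
#' @param x numeric vector.
#' @param iqr_divisor normalization constant for the IQR (default
#'   1.349).
#' @export
robust_sigmoid <- function(x, iqr_divisor = 1.349) {
  stopifnot(length(x) > 0)
  iqr <- stats::IQR(x) / iqr_divisor
  if (iqr == 0) {
    out <- rep(0.5, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  1 / (1 + exp(-(x - median(x)) / iqr))
}

#' Rescale to the unit interval
#'
#' `(x - min) / (max - min)`; a constant vector maps to all 0.5 with a
#' `degenerate` attribute.
#'
#' @param x numeric vector.
#' @export
rescale_unit <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    out <- rep(0.5, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

sigmoid_rescale <- function(x, iqr_divisor = 1.349) {
  rescale_unit(as.numeric(robust_sigmoid(x, iqr_divisor)))
}

#' Normalize a donor expression matrix
#'
#' Robust sigmoid plus unit rescaling applied across genes within each
#' sample (rows), then across samples within each gene (columns), in
#' that order.
#'
#' @param mat samples x genes numeric matrix.
#' @param iqr_divisor passed to [robust_sigmoid()].
#' @return matrix of the same shape with values in `[0, 1]`.
#' @export
normalize_matrix <- function(mat, iqr_divisor = 1.349) {
  stopifnot(all(is.finite(mat)))
  m1 <- t(apply(mat, 1, sigmoid_rescale, iqr_divisor = iqr_divisor))
  if (ncol(mat) == 1) m1 <- matrix(m1, ncol = 1)   # apply() collapse
  m2 <- apply(m1, 2, sigmoid_rescale, iqr_divisor = iqr_divisor)
  m2 <- matrix(m2, nrow = nrow(mat), dimnames = dimnames(mat))
  m2
}

#' Aggregate normalized donor expression into a region x gene matrix
#'
#' Samples assigned to the same region are averaged within each donor,
#' then across donors (unweighted); donors lacking a region are skipped
#' for it.  Optionally restricted to one hemisphere's regions.
#'
#' @param donors list per donor: `expression` (samples x genes, already
#'   normalized), `samples` tibble.
#' @param assignments list per donor of tibbles from [assign_samples()].
#' @param regions region centroid tibble.
#' @param hemisphere optional: keep only regions of this hemisphere
#'   (e.g. `"L"` when the other hemisphere is too sparsely sampled).
#' @return object of class `region_expression`: tibble `values`
#'   (`region_id` + one column per gene), `donors_used`, `imputed` ids.
#' @export
aggregate_regions <- function(donors, assignments, regions,
                              hemisphere = NULL) {
  if (!is.null(hemisphere)) {
    regions <- regions[regions$hemisphere %in% hemisphere, , drop = FALSE]
  }
  rids <- sort(regions$region_id)
  per_donor <- purrr::map(seq_along(donors), function(i) {
    d <- donors[[i]]; a <- assignments[[i]]
    a <- a[!is.na(a$region_id) & a$region_id %in% rids, , drop = FALSE]
    expr <- d$expression[a$sample_id, , drop = FALSE]
    rowsplit <- split(seq_len(nrow(expr)), a$region_id)
    t(vapply(rowsplit, function(idx) {
      colMeans(expr[idx, , drop = FALSE])
    }, numeric(ncol(expr))))
  })
  genes <- colnames(donors[[1]]$expression)
  vals <- matrix(NA_real_, length(rids), length(genes),
                 dimnames = list(rids, genes))
  counts <- matrix(0, length(rids), length(genes),
                   dimnames = list(rids, genes))
  for (m in per_donor) {
    hit <- rownames(m)
    vals[hit, ][is.na(vals[hit, ])] <- 0
    vals[hit, ] <- vals[hit, ] + m
    counts[hit, ] <- counts[hit, ] + 1
  }
  vals <- vals / counts
  present <- rowSums(counts) > 0
  if (!all(present)) {
    warn(sprintf("%d region(s) with no assigned samples excluded",
                 sum(!present)))
  }
  out <- dplyr::bind_cols(
    tibble::tibble(region_id = rids[present]),
    tibble::as_tibble(vals[present, , drop = FALSE])
  )
  structure(list(values = out, donors_used = length(donors),
                 hemisphere = hemisphere),
            class = "region_expression")
}

#' @export
tidy.region_expression <- function(x, ...) {
  tidyr::pivot_longer(x$values, -"region_id", names_to = "gene",
                      values_to = "expression")
}

#' Intersect a pathway gene list with a differential-expression list
#'
#' Case-insensitive, whitespace-stripped symbol intersection; an empty
#' result is flagged, not fatal.
#'
#' @param go_list,de_list character vectors of gene symbols.
#' @param set_id identifier recorded on the result.
#' @return object of class `gene_set`: `set_id`, `genes`, `empty`.
#' @export
intersect_genesets <- function(go_list, de_list, set_id = "set") {
  norm <- function(x) toupper(trimws(x))
  genes <- intersect(norm(go_list), norm(de_list))
  structure(list(set_id = set_id, genes = genes,
                 empty = length(genes) == 0),
            class = "gene_set")
}

#' Gene-set mean expression map over regions
#'
#' Per region, the mean normalized expression across the set's genes
#' present in the matrix.
#'
#' @param mat a `region_expression`.
#' @param gs a `gene_set` (or character vector of symbols).
#' @return tibble: `region_id`, `value`, with the used gene count in the
#'   `"n_genes"` attribute.
#' @export
geneset_expression_map <- function(mat, gs) {
  genes <- if (inherits(gs, "gene_set")) gs$genes else toupper(trimws(gs))
  cols <- setdiff(names(mat$values), "region_id")
  hit <- cols[toupper(trimws(cols)) %in% genes]
  if (length(hit) == 0) abort("no gene-set gene present in the matrix")
  vals <- as.matrix(mat$values[hit])
  out <- tibble::tibble(region_id = mat$values$region_id,
                        value = rowMeans(vals))
  attr(out, "n_genes") <- length(hit)
  out
}
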