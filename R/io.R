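# Volume, atlas and mask I/O plus uptake preprocessing steps: reference
# (pons) intensity normalization, native-resolution quality control, atlas
# combination, parcel-wise averaging and CSF biomarker classification.

#' Read a 3-D uptake volume from a NIfTI file
#'
#' @param path path to a single-frame 3-D NIfTI file (`.nii` or `.nii.gz`).
#' @return an `uptake_volume`: list with `grid` (3-D numeric array),
#'   `affine` (4x4 voxel-to-world transform, mm), `voxel_size` (mm,
#'   derived from the norms of the affine columns) and `subject_id`.
#' @export
read_volume <- function(path, subject_id = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) abort("unreadable volume"))
  grid <- as.array(img)
  if (length(dim(grid)) == 4L && dim(grid)[4] == 1L) {
    grid <- array(grid, dim(grid)[1:3])
  }
  if (length(dim(grid)) != 3L) abort("expected a 3-D single-frame volume")
  affine <- unclass(RNifti::xform(img))
  if (!all(is.finite(affine))) abort("non-finite affine")
  new_uptake_volume(grid, affine,
                    subject_id = subject_id %||% basename(path))
}

new_uptake_volume <- function(grid, affine, subject_id = NULL) {
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(voxel_size <= 0)) abort("voxel size must be strictly positive")
  structure(list(grid = grid, affine = affine,
                 voxel_size = unname(voxel_size),
                 subject_id = subject_id),
            class = "uptake_volume")
}

#' Write an uptake volume or label grid to NIfTI
#'
#' @param vol an `uptake_volume`, or a plain 3-D array plus `affine`.
#' @param path destination `.nii`/`.nii.gz` path.
#' @export
write_volume <- function(vol, path, affine = NULL) {
  if (inherits(vol, "uptake_volume")) {
    grid <- vol$grid
    affine <- vol$affine
  } else {
    grid <- vol
    if (is.null(affine)) affine <- diag(4)
  }
  img <- RNifti::asNifti(grid)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Default affine for an isotropic grid
#'
#' @param mm voxel edge length in millimetres.
#' @export
iso_affine <- function(mm = 2) {
  a <- diag(c(mm, mm, mm, 1))
  a
}

#' Intensity-normalize an uptake volume by a reference region
#'
#' Divides every voxel by the mean uptake within the reference mask (the
#' whole pons in the original analysis), so uptake becomes a dimensionless
#' ratio with mean 1 inside the reference.
#'
#' @param vol an `uptake_volume`.
#' @param ref logical 3-D array (or `seed_mask`) with the same geometry.
#' @return the normalized `uptake_volume`.
#' @export
normalize_by_reference <- function(vol, ref) {
  mask <- mask_grid(ref)
  stopifnot(identical(dim(mask), dim(vol$grid)))
  if (!any(mask)) abort("empty reference mask")
  m <- mean(vol$grid[mask])
  if (!is.finite(m) || m <= 0) abort("degenerate reference")
  vol$grid <- vol$grid / m
  vol
}

#' Keep subjects whose native image resolution passes a cut-off
#'
#' A subject passes when the largest native voxel dimension does not
#' exceed `max_mm` (2 mm in the original study).
#'
#' @param cohort data frame with columns `vx`, `vy`, `vz` (native voxel
#'   size, mm), one row per subject.
#' @param max_mm acceptable resolution in mm.
#' @return the passing rows, order preserved.
#' @export
filter_by_resolution <- function(cohort, max_mm = 2) {
  stopifnot(all(c("vx", "vy", "vz") %in% names(cohort)))
  vx <- pmax(cohort$vx, cohort$vy, cohort$vz)
  if (any(!is.finite(vx))) abort("native voxel size missing")
  keep <- vx <= max_mm
  out <- cohort[keep, , drop = FALSE]
  if (nrow(out) == 0L) warn("no subject passes the resolution criterion")
  tibble::as_tibble(out)
}

#' Construct a label atlas
#'
#' @param grid 3-D integer array, 0 = background.
#' @param label_table data frame with columns `label`, `name`, `division`
#'   (cortex/subcortex/cerebellum) and `hemisphere` (L/R/midline).
#' @export
label_atlas <- function(grid, label_table) {
  labs <- sort(unique(as.integer(grid[grid != 0])))
  if (any(grid < 0)) abort("labels must be non-negative")
  missing <- setdiff(labs, label_table$label)
  if (length(missing) > 0) {
    abort(sprintf("grid labels missing from label table: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  structure(list(grid = grid, label_table = tibble::as_tibble(label_table)),
            class = "label_atlas")
}

#' Combine a cortical and a subcortical atlas
#'
#' Subcortical labels are shifted by `offset`; where both atlases label a
#' voxel the subcortical label wins (the cortical label is treated as
#' background there), avoiding artificial correlation between overlapping
#' parcels.
#'
#' @param cortical,subcortical `label_atlas` objects on the same grid.
#' @param offset added to every subcortical label; must be at least the
#'   maximum cortical label (default 400 matches a 400-region cortical
#'   scheme).
#' @export
combine_atlases <- function(cortical, subcortical, offset = 400L) {
  if (!identical(dim(cortical$grid), dim(subcortical$grid))) {
    abort("atlas geometry mismatch")
  }
  max_ctx <- suppressWarnings(max(cortical$grid))
  if (offset < max_ctx) abort("offset below the maximum cortical label")
  grid <- cortical$grid
  sub <- subcortical$grid
  grid[sub != 0] <- sub[sub != 0] + offset
  sub_tab <- subcortical$label_table
  sub_tab$label <- sub_tab$label + offset
  label_atlas(grid, dplyr::bind_rows(cortical$label_table, sub_tab))
}

#' Construct a seed mask
#'
#' @param grid logical 3-D array; `side` one of "L"/"R".
#' @export
seed_mask <- function(grid, side = c("L", "R")) {
  side <- match.arg(side)
  grid <- as.array(grid)
  storage.mode(grid) <- "logical"
  n <- sum(grid)
  if (n == 0) abort("empty seed mask")
  structure(list(grid = grid, n_voxels = n, side = side),
            class = "seed_mask")
}

mask_grid <- function(x) {
  if (inherits(x, "seed_mask")) x$grid else {
    g <- array(as.logical(x), dim(x))
    g
  }
}

#' Seed mask volume in cubic millimetres
#'
#' Voxel count times voxel volume, e.g. 865 voxels at 2 mm isotropic give
#' 6920 mm^3.
#'
#' @param mask a `seed_mask` or logical array.
#' @param voxel_size 3-vector of voxel dimensions in mm.
#' @export
mask_volume_mm3 <- function(mask, voxel_size = c(2, 2, 2)) {
  sum(mask_grid(mask)) * prod(voxel_size)
}

#' Mean uptake per atlas parcel
#'
#' @param vol an `uptake_volume` (or 3-D array).
#' @param atlas a `label_atlas` with the same geometry.
#' @param gm_mask optional grey-matter mask restricting the averaged
#'   voxels; parcels with no in-mask voxels come back as `NA` with
#'   `missing = TRUE`.
#' @return tibble with columns `parcel_id`, `mean_uptake`, `n_voxels`,
#'   `missing`, one row per label in the atlas table.
#' @export
parcel_means <- function(vol, atlas, gm_mask = NULL) {
  grid <- if (inherits(vol, "uptake_volume")) vol$grid else vol
  stopifnot(identical(dim(grid), dim(atlas$grid)))
  labs <- atlas$grid
  inmask <- if (is.null(gm_mask)) rep(TRUE, length(labs)) else {
    mg <- mask_grid(gm_mask)
    stopifnot(identical(dim(mg), dim(grid)))
    as.vector(mg)
  }
  use <- inmask & as.vector(labs != 0)
  vals <- as.vector(grid)[use]
  lab_use <- as.vector(labs)[use]
  sums <- tapply(vals, lab_use, mean)
  all_labs <- sort(atlas$label_table$label)
  mu <- sums[as.character(all_labs)]
  counts <- table(factor(lab_use, levels = all_labs))
  tibble::tibble(
    parcel_id = all_labs,
    mean_uptake = as.numeric(mu),
    n_voxels = as.integer(counts),
    missing = as.integer(counts) == 0L
  )
}

#' Read a subject metadata table
#'
#' Tab-separated with header columns `subject_id`, `group`, `vx`, `vy`,
#' `vz`, `abeta42`, `ptau`, `ttau`; empty biomarker cells are missing.
#'
#' @param path TSV path.
#' @export
read_subject_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    group = readr::col_character(),
    vx = readr::col_double(), vy = readr::col_double(),
    vz = readr::col_double(),
    abeta42 = readr::col_double(), ptau = readr::col_double(),
    ttau = readr::col_double()
  ))
}

#' Default CSF biomarker cut-offs (pg/mL)
#'
#' Elecsys immunoassay positivity cut-offs: amyloid-beta(1-42) 977,
#' phosphorylated tau 24, total tau 266.
#' @export
default_biomarker_cutoffs <- function() {
  list(abeta = 977, p_tau = 24, t_tau = 266)
}

#' Classify CSF amyloid/tau biomarker status
#'
#' The default rule calls a subject biomarker-positive when amyloid is
#' positive (abeta(1-42) below its cut-off) AND at least one tau marker is
#' positive (p-tau or t-tau above its cut-off); negative when the required
#' markers are present and the rule fails; unknown when they are missing.
#'
#' @param data data frame with columns `abeta42`, `ptau`, `ttau` (pg/mL;
#'   `NA` = missing).
#' @param cutoffs list with `abeta`, `p_tau`, `t_tau` cut-offs.
#' @param rule `"amyloid_and_tau"` (default) or `"any"` (any single
#'   marker positive).
#' @return input tibble with a `bm_status` column
#'   (`"positive"`/`"negative"`/`"unknown"`) and the rule recorded in the
#'   `"bm_rule"` attribute.
#' @export
classify_biomarker_status <- function(data,
                                      cutoffs = default_biomarker_cutoffs(),
                                      rule = c("amyloid_and_tau", "any")) {
  rule <- match.arg(rule)
  ab <- data$abeta42; pt <- data$ptau; tt <- data$ttau
  bad <- c(ab, pt, tt)
  if (any(bad <= 0, na.rm = TRUE)) abort("biomarker values must be positive")
  ab_pos <- ab < cutoffs$abeta
  tau_pos <- (pt > cutoffs$p_tau) | (tt > cutoffs$t_tau)
  # tau call is decidable from one marker when it is positive; requires
  # both when negative
  tau_known <- (!is.na(pt) & pt > cutoffs$p_tau) |
    (!is.na(tt) & tt > cutoffs$t_tau) | (!is.na(pt) & !is.na(tt))
  tau_pos[is.na(tau_pos) & tau_known] <- TRUE
  status <- switch(rule,
    amyloid_and_tau = dplyr::case_when(
      !is.na(ab_pos) & !ab_pos ~ "negative",
      tau_known & !tau_pos ~ "negative",
      !is.na(ab_pos) & ab_pos & tau_known & tau_pos ~ "positive",
      TRUE ~ "unknown"
    ),
    any = dplyr::case_when(
      (!is.na(ab_pos) & ab_pos) | (tau_known & tau_pos) ~ "positive",
      !is.na(ab_pos) & tau_known ~ "negative",
      TRUE ~ "unknown"
    )
  )
  out <- tibble::as_tibble(data)
  out$bm_status <- status
  attr(out, "bm_rule") <- rule
  attr(out, "bm_cutoffs") <- cutoffs
  out
}
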