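# Subregional local-metabolism tables and their group statistics:
# one-/two-way ANOVA, post hoc pairwise comparisons with familywise error
# control, and the per-subject anterior-posterior uptake delta.

#' Mean uptake per subject and metabolic subregion
#'
#' @param seed_uptake data frame: `subject_id` plus one column per seed
#'   voxel.
#' @param parc a `parcellation` over those voxels.
#' @param subjects optional subject table (`subject_id`, `group`, and
#'   possibly `bm_status`) joined onto the result.
#' @return long tibble: `subject_id`, `subregion`, `mean_uptake`, plus
#'   any joined metadata; one row per subject x subregion.
#' @export
subregion_means <- function(seed_uptake, parc, subjects = NULL,
                            id_col = "subject_id") {
  M <- uptake_matrix(seed_uptake, id_col)
  labels <- if (inherits(parc, "parcellation")) parc$labels else parc
  if (ncol(M) != length(labels)) abort("labels do not cover the voxels")
  ks <- sort(unique(labels))
  means <- vapply(ks, function(k) {
    rowMeans(M[, labels == k, drop = FALSE])
  }, numeric(nrow(M)))
  colnames(means) <- paste0("sr", ks)
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = rownames(M)),
    tibble::as_tibble(means)
  ) |>
    tidyr::pivot_longer(-"subject_id", names_to = "subregion",
                        values_to = "mean_uptake")
  if (!is.null(subjects)) {
    out <- dplyr::left_join(out, tibble::as_tibble(subjects),
                            by = "subject_id")
  }
  out
}

anova_result <- function(tab) {
  structure(tab, class = c("anova_table", class(tab)))
}

#' One-way ANOVA across subregions
#'
#' Between-subregion ANOVA on mean uptake, typically within one diagnosis
#' group.
#'
#' @param data long table with columns `mean_uptake` and `subregion`.
#' @return an `anova_table` tibble: `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`, including residual and corrected-total rows.
#' @export
one_way_anova <- function(data) {
  stopifnot(length(unique(data$subregion)) >= 2)
  fit <- aov(mean_uptake ~ factor(subregion), data = data)
  tab <- summary(fit)[[1]]
  out <- tibble::tibble(
    term = c("subregion", "residual"),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p.value = tab$`Pr(>F)`
  )
  add_total(out)
}

add_total <- function(out) {
  anova_result(dplyr::bind_rows(out, tibble::tibble(
    term = "corrected_total", df = sum(out$df), sumsq = sum(out$sumsq),
    meansq = NA_real_, statistic = NA_real_, p.value = NA_real_)))
}

#' Two-way ANOVA: subregion x diagnosis group
#'
#' Crossed fixed-effects model with interaction on the long uptake table;
#' unbalanced designs use partial (Type II by default) sums of squares.
#'
#' @param data long table with `mean_uptake`, `subregion`, `group`.
#' @param ss_type `"II"` (default) or `"III"`.
#' @return an `anova_table` with subregion, group, interaction, residual
#'   and corrected-total rows.
#' @export
two_way_anova <- function(data, ss_type = c("II", "III")) {
  ss_type <- match.arg(ss_type)
  data$subregion <- factor(data$subregion)
  data$group <- factor(data$group)
  stopifnot(nlevels(data$subregion) >= 2, nlevels(data$group) >= 2)
  cells <- table(data$subregion, data$group)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    abort(sprintf("empty design cell(s): %s",
                  paste(rownames(cells)[empty[, 1]],
                        colnames(cells)[empty[, 2]],
                        sep = ":", collapse = ", ")))
  }
  contr <- if (ss_type == "III") {
    list(subregion = "contr.sum", group = "contr.sum")
  } else NULL
  fit <- lm(mean_uptake ~ subregion * group, data = data,
            contrasts = contr)
  tab <- car::Anova(fit, type = ss_type)
  rn <- rownames(tab)
  term <- dplyr::recode(rn, subregion = "subregion", group = "group",
                        `subregion:group` = "subregion:group",
                        Residuals = "residual", .default = rn)
  keep <- term %in% c("subregion", "group", "subregion:group", "residual")
  out <- tibble::tibble(
    term = term[keep],
    df = tab$Df[keep],
    sumsq = tab$`Sum Sq`[keep],
    meansq = tab$`Sum Sq`[keep] / tab$Df[keep],
    statistic = tab$`F value`[keep],
    p.value = tab$`Pr(>F)`[keep]
  )
  # corrected total df is N - 1 regardless of SS type
  tot <- tibble::tibble(term = "corrected_total", df = nrow(data) - 1L,
                        sumsq = sum((data$mean_uptake -
                                       mean(data$mean_uptake))^2),
                        meansq = NA_real_, statistic = NA_real_,
                        p.value = NA_real_)
  anova_result(dplyr::bind_rows(out, tot))
}

#' @export
glance.anova_table <- function(x, ...) {
  eff <- x[!x$term %in% c("residual", "corrected_total"), ]
  tibble::tibble(
    df_total = x$df[x$term == "corrected_total"],
    df_residual = x$df[x$term == "residual"],
    n_effects = nrow(eff),
    min_p = suppressWarnings(min(eff$p.value))
  )
}

#' Post hoc pairwise group comparisons within each subregion
#'
#' All pairwise diagnosis-group comparisons of mean uptake, run within
#' each subregion, with familywise-error control.  The default
#' Tukey-Kramer procedure is the standard post-ANOVA pairwise test for
#' (possibly unequal) group means; Bonferroni-corrected t tests are
#' available.
#'
#' @param data long table with `mean_uptake`, `subregion`, `group`.
#' @param method `"tukey"` (default) or `"bonferroni"`.
#' @param alpha familywise significance level.
#' @return tibble: `subregion`, `pair`, `diff`, `p_fwe`, `significant`.
#' @export
posthoc_pairwise <- function(data, method = c("tukey", "bonferroni"),
                             alpha = 0.05) {
  method <- match.arg(method)
  if (length(unique(data$group)) < 2) abort("need at least 2 groups")
  by_sr <- split(data, data$subregion)
  out <- purrr::map_dfr(names(by_sr), function(sr) {
    d <- by_sr[[sr]]
    d$group <- factor(d$group)
    if (method == "tukey") {
      fit <- aov(mean_uptake ~ group, data = d)
      th <- TukeyHSD(fit)$group
      tibble::tibble(subregion = sr, pair = rownames(th),
                     diff = th[, "diff"], p_fwe = th[, "p adj"])
    } else {
      pt <- stats::pairwise.t.test(d$mean_uptake, d$group,
                                   p.adjust.method = "bonferroni",
                                   pool.sd = TRUE)
      pv <- pt$p.value
      idx <- which(!is.na(pv), arr.ind = TRUE)
      mus <- tapply(d$mean_uptake, d$group, mean)
      tibble::tibble(
        subregion = sr,
        pair = paste(rownames(pv)[idx[, 1]], colnames(pv)[idx[, 2]],
                     sep = "-"),
        diff = mus[rownames(pv)[idx[, 1]]] - mus[colnames(pv)[idx[, 2]]],
        p_fwe = pv[idx]
      )
    }
  })
  out$significant <- out$p_fwe < alpha
  out
}

#' Per-subject anterior minus posterior uptake delta
#'
#' delta = mean uptake over the anterior subregion set minus mean uptake
#' over the posterior set, per subject.
#'
#' @param data long table from [subregion_means()].
#' @param anterior_set,posterior_set disjoint character vectors of
#'   subregion ids.
#' @return tibble: `subject_id`, `delta`, plus `group` when present.
#' @export
anterior_posterior_delta <- function(data, anterior_set, posterior_set) {
  stopifnot(length(anterior_set) > 0, length(posterior_set) > 0)
  if (length(intersect(anterior_set, posterior_set)) > 0) {
    abort("anterior and posterior sets overlap")
  }
  per <- data |>
    dplyr::filter(.data$subregion %in% c(anterior_set, posterior_set)) |>
    dplyr::mutate(axis = ifelse(.data$subregion %in% anterior_set,
                                "anterior", "posterior")) |>
    dplyr::group_by(.data$subject_id, .data$axis) |>
    dplyr::summarise(m = mean(.data$mean_uptake), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "axis", values_from = "m") |>
    dplyr::mutate(delta = .data$anterior - .data$posterior) |>
    dplyr::select("subject_id", "delta")
  if ("group" %in% names(data)) {
    per <- dplyr::left_join(
      per, dplyr::distinct(data, .data$subject_id, .data$group),
      by = "subject_id")
  }
  per
}

#' Group-level summary of the anterior-posterior delta
#'
#' @param delta_table output of [anterior_posterior_delta()] with a
#'   `group` column.
#' @return tibble: `group`, `mean_delta`, `sd_delta`, `n`.
#' @export
summarize_delta <- function(delta_table) {
  delta_table |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_delta = mean(.data$delta),
                     sd_delta = sd(.data$delta),
                     n = dplyr::n(), .groups = "drop")
}

#' @export
autoplot.anova_table <- function(object, ...) {
  eff <- object[!object$term %in% c("residual", "corrected_total"), ]
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$term, y = .data$statistic)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "F statistic") +
    ggplot2::theme_minimal()
}
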