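# Seed-based metabolic covariance network maps: per-parcel ordinary least
# squares of parcel uptake on a subregion's mean uptake, with
# Benjamini-Hochberg false discovery rate control over parcels.  T maps
# are kept unthresholded for downstream spatial association.

#' Seed general linear model across all parcels
#'
#' For every parcel, fits parcel uptake ~ seed subregion mean (+ optional
#' covariates) across subjects by ordinary least squares and reports the
#' seed slope with its T statistic, two-sided p and BH-adjusted q.  With
#' no covariates the T statistic equals the correlation t,
#' `r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param parcel_uptake data frame: `subject_id` plus one column per
#'   parcel.
#' @param seed_means data frame with `subject_id` and `seed_mean` (the
#'   subregion's per-subject mean uptake), or a numeric vector in
#'   subject order.
#' @param covariates optional data frame of per-subject nuisance columns
#'   (plus `subject_id`).
#' @return object of class `network_map`: tibble `table` (`parcel_id`,
#'   `estimate`, `statistic`, `p.value`, `q.value`) with `n_subjects`,
#'   `covariates` and the seed id in attributes.
#' @export
seed_glm <- function(parcel_uptake, seed_means, covariates = NULL,
                     seed_id = "seed", id_col = "subject_id") {
  Y <- uptake_matrix(parcel_uptake, id_col)
  if (is.data.frame(seed_means)) {
    stopifnot(all(c(id_col, "seed_mean") %in% names(seed_means)))
    s <- seed_means$seed_mean[match(rownames(Y), seed_means[[id_col]])]
  } else {
    s <- as.numeric(seed_means)
  }
  if (any(is.na(s))) abort("seed means do not cover all subjects")
  X <- cbind(intercept = 1, seed = s)
  covar_names <- character(0)
  if (!is.null(covariates)) {
    C <- uptake_matrix(covariates, id_col)
    C <- C[rownames(Y), , drop = FALSE]
    covar_names <- colnames(C)
    X <- cbind(X, C)
  }
  n <- nrow(Y); p <- ncol(X)
  if (n < p + 1) abort("too few subjects for the design")
  qr_x <- qr(X)
  if (qr_x$rank < p) abort("rank-deficient design")
  beta <- qr.coef(qr_x, Y)                   # p x P
  resid <- Y - X %*% beta
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  tstat <- beta[2, ] / se
  # perfect fits (zero residual) would give infinite T; clip to keep the
  # map finite, p underflows to 0 there anyway
  clip <- 1e8
  perfect <- !is.finite(tstat) | abs(tstat) > clip
  tstat[perfect] <- sign(beta[2, perfect]) * clip
  pval <- 2 * pt(-abs(tstat), df)
  tab <- tibble::tibble(
    parcel_id = colnames(Y),
    estimate = unname(beta[2, ]),
    statistic = unname(tstat),
    p.value = unname(pval),
    q.value = p.adjust(unname(pval), method = "BH")
  )
  structure(list(table = tab, seed_id = seed_id, n_subjects = n,
                 df = df, covariates = covar_names),
            class = "network_map")
}

#' @export
tidy.network_map <- function(x, ...) x$table

#' @export
glance.network_map <- function(x, ...) {
  tibble::tibble(seed_id = x$seed_id, n_subjects = x$n_subjects,
                 n_parcels = nrow(x$table),
                 n_significant = sum(x$table$q.value < 0.05))
}

#' @export
print.network_map <- function(x, ...) {
  cat(sprintf("<network_map> seed '%s', %d parcels, n = %d, %d at q < 0.05\n",
              x$seed_id, nrow(x$table), x$n_subjects,
              sum(x$table$q.value < 0.05)))
  print(head(x$table))
  invisible(x)
}

#' Parcels surviving false discovery rate control
#'
#' Benjamini-Hochberg step-up selection on the network map's p values.
#'
#' @param map a `network_map` (or tibble with `parcel_id`, `p.value`).
#' @param q_level FDR level (default 0.05).
#' @return tibble of the selected rows, ordered by p.
#' @export
fdr_select <- function(map, q_level = 0.05) {
  tab <- if (inherits(map, "network_map")) map$table else
    tibble::as_tibble(map)
  stopifnot(all(tab$p.value >= 0 & tab$p.value <= 1))
  tab$q.value <- p.adjust(tab$p.value, method = "BH")
  tab |>
    dplyr::filter(.data$q.value < q_level) |>
    dplyr::arrange(.data$p.value)
}

#' @export
autoplot.network_map <- function(object, q_level = 0.05, ...) {
  tab <- object$table
  tab$significant <- tab$q.value < q_level
  ggplot2::ggplot(tab, ggplot2::aes(x = seq_len(nrow(tab)),
                                    y = .data$statistic,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "parcel", y = "T statistic",
                  title = sprintf("metabolic network of %s",
                                  object$seed_id)) +
    ggplot2::theme_minimal()
}
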