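# broom-style tidy()/glance() methods for fitted objects.

#' Tidy a microbiability fit
#'
#' One row per variance component with posterior median, shortest 95%
#' HPD interval, and Geweke Z.
#'
#' @param x A `microbiability_fit`.
#' @param ... Unused.
#' @return A tibble `component, estimate, hpd_lower, hpd_upper, geweke_z`.
#' @export
tidy.microbiability_fit <- function(x, ...) {
  d <- x$draws
  comps <- c(sigma2_m = "microbiome", sigma2_pen = "pen",
             sigma2_sire = "sire", sigma2_e = "residual", m2 = "m2")
  purrr::list_rbind(purrr::imap(comps, function(label, col) {
    v <- d[[col]]
    hpd <- hpd_interval(v, 0.95)
    tibble::tibble(
      component = label, estimate = median(v),
      hpd_lower = hpd[["lower"]], hpd_upper = hpd[["upper"]],
      geweke_z = if (var(v) > 0) geweke_z(v) else NA_real_)
  }))
}

#' Glance at a microbiability fit
#' @param x A `microbiability_fit`.
#' @param ... Unused.
#' @return One-row tibble with the m2 posterior median, HPD bounds, draw
#'   count and sampler settings.
#' @export
glance.microbiability_fit <- function(x, ...) {
  hpd <- hpd_interval(x$draws$m2, 0.95)
  tibble::tibble(
    m2_median = median(x$draws$m2),
    m2_hpd_lower = hpd[["lower"]], m2_hpd_upper = hpd[["upper"]],
    n = x$n, n_draws = nrow(x$draws),
    iters = x$settings$iters, burnin = x$settings$burnin,
    thin = x$settings$thin)
}

#' Tidy a PERMANOVA table
#' @param x A `resilink_permanova`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.resilink_permanova <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy a PLS-DA evaluation
#' @param x A `plsda_evaluation`.
#' @param ... Unused.
#' @return The per-class tibble (class, AUC, incidence, p-value, counts).
#' @export
tidy.plsda_evaluation <- function(x, ...) x$per_class

#' Glance at a PLS-DA evaluation
#' @param x A `plsda_evaluation`.
#' @param ... Unused.
#' @return One-row tibble with the overall macro AUC and accuracy.
#' @export
glance.plsda_evaluation <- function(x, ...) {
  tibble::tibble(
    overall_auc = x$overall_auc,
    accuracy = sum(diag(x$confusion)) / sum(x$confusion),
    n_test = sum(x$confusion))
}

#' Tidy a PLS-DA model
#' @param x A `resilink_plsda`.
#' @param ... Unused.
#' @return Tibble of per-feature, per-component weights and VIP scores.
#' @export
tidy.resilink_plsda <- function(x, ...) {
  vip <- vip_scores(x)
  w <- tibble::as_tibble(x$W, .name_repair = ~ paste0("w", seq_along(.x)))
  dplyr::bind_cols(tibble::tibble(feature = x$features, vip = vip), w)
}
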