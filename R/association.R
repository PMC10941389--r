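#' Distance-based PERMANOVA with covariates
#'
#' Sequential (Type-I) permutational multivariate analysis of variance of a
#' sample distance matrix on ordered model terms, by default
#' `room + breed + indicator` so the indicator's sum of squares is
#' conditional on housing and breed. Permutations are free over samples.
#' The partitioning and permutation test are delegated to
#' [vegan::adonis2()] with `by = "terms"`.
#'
#' @param dist A [stats::dist] object (e.g. from [aitchison_distance()]).
#' @param data Metadata tibble aligned to the distance labels, one row per
#'   sample.
#' @param terms Character vector of ordered model terms (columns of
#'   `data`). Default `c("room_id", "breed", "indicator")`.
#' @param n_perm Number of permutations. Default 1000.
#' @param seed Optional seed for the permutation draw.
#' @param exact Use every permutation of the samples instead of random
#'   draws (only feasible for very small n). Default FALSE.
#' @return Tibble of class `resilink_permanova`:
#'   `term, df, sum_sq, pseudo_f, p_value, var_exp` (VarExp in percent of
#'   total SS), including `Residual` and `Total` rows.
#' @export
permanova <- function(dist, data, terms = c("room_id", "breed", "indicator"),
                      n_perm = 1000, seed = NULL, exact = FALSE) {
  stopifnot(inherits(dist, "dist"))
  assert_cols(data, terms, "metadata")
  n <- attr(dist, "Size")
  if (nrow(data) != n) abort("metadata rows must match the distance matrix")
  for (tm in terms) {
    v <- data[[tm]]
    if (dplyr::n_distinct(v) < 2) {
      abort(sprintf("term '%s' is constant", tm))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  perms <- if (exact) {
    if (!requireNamespace("permute", quietly = TRUE)) {
      abort("exact permutations require the 'permute' package")
    }
    permute::allPerms(n, permute::how(maxperm = factorial(n) + 1))
  } else {
    n_perm
  }
  fml <- as.formula(paste("dist ~", paste(terms, collapse = " + ")))
  fit <- vegan::adonis2(fml, data = as.data.frame(data),
                        permutations = perms, by = "terms")
  total_ss <- fit$SumOfSqs[rownames(fit) == "Total"]
  out <- tibble::tibble(
    term = rownames(fit),
    df = fit$Df,
    sum_sq = fit$SumOfSqs,
    pseudo_f = fit$F,
    p_value = fit$`Pr(>F)`,
    var_exp = 100 * fit$SumOfSqs / total_ss)
  class(out) <- c("resilink_permanova", class(out))
  out
}

#' Regression of alpha diversity on a resilience indicator
#'
#' Simple OLS of a diversity measure on an indicator, optionally refitted
#' with adjustment covariates (room, breed). For the simple model the
#' correlation R is the Pearson correlation, whose sign matches the slope.
#'
#' @param data Tibble holding diversity, indicator and covariate columns.
#' @param diversity Name of the diversity column.
#' @param indicator Name of the indicator column.
#' @param covariates Optional character vector of adjustment columns.
#' @return Tibble with one row per model (`simple`, and `adjusted` when
#'   covariates are given): `model, slope, r, p_value, n`.
#' @export
diversity_regression <- function(data, diversity, indicator,
                                 covariates = NULL) {
  assert_cols(data, c(diversity, indicator, covariates), "data")
  d <- data[complete.cases(data[, c(diversity, indicator)]), , drop = FALSE]
  if (nrow(d) < 5) abort("need at least 5 complete pairs")
  y <- d[[diversity]]
  x <- d[[indicator]]
  fit <- lm(y ~ x)
  sm <- summary(fit)
  slope <- coef(fit)[["x"]]
  r <- if (sd(y) == 0 || sd(x) == 0) 0 else cor(x, y)
  p <- if (nrow(sm$coefficients) < 2) NA_real_ else sm$coefficients["x", 4]
  out <- tibble::tibble(model = "simple", slope = slope, r = r,
                        p_value = p, n = nrow(d))
  if (!is.null(covariates)) {
    d2 <- d[complete.cases(d[, covariates]), , drop = FALSE]
    fml <- as.formula(paste(
      diversity, "~", paste(c(indicator, covariates), collapse = " + ")))
    fit2 <- lm(fml, data = d2)
    sm2 <- summary(fit2)$coefficients
    out <- dplyr::bind_rows(out, tibble::tibble(
      model = "adjusted",
      slope = sm2[indicator, 1],
      r = NA_real_,
      p_value = sm2[indicator, 4],
      n = nrow(d2)))
  }
  out
}

#' Kolmogorov-Smirnov tests between resilience classes
#'
#' Two-sample KS statistic and asymptotic p-value for each requested class
#' pair of a value distribution (e.g. Shannon diversity by L/M/H class).
#'
#' @param data Tibble with a value column and a class column.
#' @param value Name of the value column.
#' @param class Name of the class column. Default `"class"`.
#' @param pairs List of length-2 character vectors. Default
#'   `(L,M), (M,H), (L,H)`.
#' @param min_per_class Minimum observations per class. Default 5.
#' @return Tibble `class_a, class_b, statistic, p_value, n_a, n_b`; pairs
#'   with an empty or undersized class are skipped with a warning.
#' @export
ks_class_test <- function(data, value, class = "class",
                          pairs = list(c("L", "M"), c("M", "H"),
                                       c("L", "H")),
                          min_per_class = 5) {
  assert_cols(data, c(value, class), "data")
  rows <- purrr::map(pairs, function(p) {
    a <- data[[value]][data[[class]] == p[1]]
    b <- data[[value]][data[[class]] == p[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < min_per_class || length(b) < min_per_class) {
      warn(sprintf("skipping pair (%s, %s): too few observations",
                   p[1], p[2]))
      return(NULL)
    }
    kt <- suppressWarnings(ks.test(a, b))
    tibble::tibble(class_a = p[1], class_b = p[2],
                   statistic = unname(kt$statistic),
                   p_value = kt$p.value,
                   n_a = length(a), n_b = length(b))
  })
  purrr::list_rbind(rows)
}
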