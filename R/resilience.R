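#' Centred moving median of a daily series
#'
#' Smooths a daily feed-consumption vector with a centred moving median,
#' skipping missing days. A position's window is truncated at the series
#' edges; if fewer than 3 observed values fall inside the window the
#' smoothed value is `NA`.
#'
#' @param x Numeric vector on a unit-step day grid; `NA` marks missing days.
#' @param window Odd window width in days, at least 3. Default 5.
#' @return Numeric vector of smoothed values, same length as `x`.
#' @export
moving_median <- function(x, window = 5) {
  if (window %% 2 == 0) abort("`window` must be odd")
  if (window < 3) abort("`window` must be >= 3")
  h <- (window - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - h):min(n, i + h)]
    w <- w[!is.na(w)]
    if (length(w) < 3) NA_real_ else median(w)
  }, numeric(1))
}

#' Fit a per-animal linear age trend
#'
#' Ordinary least squares of the smoothed series on age, fitted over the
#' non-missing positions. Residuals (smoothed minus predicted) carry the
#' day-to-day variability once growth is removed.
#'
#' @param smoothed Smoothed FCD vector (kg/day), `NA` where undefined.
#' @param ages Integer age vector aligned to `smoothed`.
#' @return List with `intercept`, `slope`, `predicted` and `residuals`
#'   (both full-length, `NA` where `smoothed` is `NA`).
#' @export
fit_linear_trend <- function(smoothed, ages) {
  stopifnot(length(smoothed) == length(ages))
  ok <- !is.na(smoothed)
  if (sum(ok) < 3) abort("need at least 3 non-missing smoothed points")
  if (length(unique(ages[ok])) < 2) abort("all ages identical: singular fit")
  fit <- lm(y ~ a, data = data.frame(y = smoothed[ok], a = ages[ok]))
  b <- coef(fit)
  predicted <- unname(b[1] + b[2] * ages)
  residuals <- ifelse(ok, smoothed - predicted, NA_real_)
  list(intercept = unname(b[1]), slope = unname(b[2]),
       predicted = predicted, residuals = residuals)
}

#' Lag-1 autocorrelation of residuals
#'
#' Sample lag-1 autocorrelation
#' \eqn{r_1 = \sum_t (e_t-\bar e)(e_{t+1}-\bar e) / \sum_t (e_t-\bar e)^2};
#' the mean and the denominator use every observed residual, while the
#' numerator uses only day pairs that do not straddle a missing day.
#'
#' @param residuals Residual vector on the unit-day grid (`NA` = missing).
#' @return The autocorrelation, or `NA` when the residual variance is zero
#'   or fewer than 3 residuals are observed (flagged with a warning).
#' @export
lag1_autocorrelation <- function(residuals) {
  ok <- !is.na(residuals)
  if (sum(ok) < 3) {
    warn("fewer than 3 residuals: lag-1 autocorrelation undefined")
    return(NA_real_)
  }
  e <- residuals - mean(residuals[ok])
  denom <- sum(e[ok]^2)
  if (denom == 0) {
    warn("zero residual variance: lag-1 autocorrelation undefined")
    return(NA_real_)
  }
  n <- length(e)
  pair <- ok[-n] & ok[-1]
  sum(e[-n][pair] * e[-1][pair]) / denom
}

#' Natural log of the residual variance
#'
#' @param residuals Residual vector (`NA` = missing).
#' @return `ln` of the sample variance (denominator n-1), or `NA` with a
#'   warning when the variance is zero or fewer than 2 residuals exist.
#' @export
ln_variance <- function(residuals) {
  e <- residuals[!is.na(residuals)]
  if (length(e) < 2) {
    warn("fewer than 2 residuals: variance undefined")
    return(NA_real_)
  }
  v <- var(e)
  if (v == 0) {
    warn("zero residual variance: ln-variance undefined")
    return(NA_real_)
  }
  log(v)
}

#' Maximal runs of consecutive negative residuals
#'
#' Finds maximal runs of strictly negative residuals lasting more than two
#' consecutive days (length >= 3). A missing day terminates a run.
#'
#' @param residuals Residual vector on the unit-day grid.
#' @param min_length Minimum qualifying run length. Default 3.
#' @return Tibble with columns `start`, `end`, `length`, `area`, where
#'   `area` is the trapezoidal integral of `-residuals` over the run at
#'   unit day spacing. Zero rows when no run qualifies.
#' @export
negative_runs <- function(residuals, min_length = 3) {
  neg <- !is.na(residuals) & residuals < 0
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_length
  starts <- starts[keep]
  ends <- ends[keep]
  area <- purrr::map2_dbl(starts, ends, function(s, e) {
    y <- -residuals[s:e]
    sum((y[-1] + y[-length(y)]) / 2)
  })
  tibble::tibble(start = as.integer(starts), end = as.integer(ends),
                 length = as.integer(ends - starts + 1), area = area)
}

#' Log of the largest negative-run area
#'
#' Integrates `-residuals` over each qualifying negative run (trapezoidal
#' rule, unit spacing) and returns the natural log of the largest area.
#'
#' @inheritParams negative_runs
#' @return `ln(max area)`, or `NA` when no run qualifies.
#' @export
max_negative_area <- function(residuals, min_length = 3) {
  runs <- negative_runs(residuals, min_length = min_length)
  if (nrow(runs) == 0) return(NA_real_)
  log(max(runs$area))
}

#' Sum of residual local minima
#'
#' Sums residual values at interior positions strictly lower than both
#' immediate neighbours. Series endpoints are never minima, and positions
#' adjacent to (or at) a missing day are ineligible.
#'
#' @param residuals Residual vector on the unit-day grid.
#' @return The sum (0 when no local minimum exists).
#' @export
sum_local_minima <- function(residuals) {
  n <- length(residuals)
  if (n < 3) return(0)
  i <- 2:(n - 1)
  ok <- !is.na(residuals[i - 1]) & !is.na(residuals[i]) &
    !is.na(residuals[i + 1])
  is_min <- ok & residuals[i] < residuals[i - 1] &
    residuals[i] < residuals[i + 1]
  sum(residuals[i][is_min])
}

#' Compute the four resilience indicators per animal
#'
#' For each animal: smooth daily FCD with a centred moving median, detrend
#' on age by per-animal OLS, and summarise the residuals as lag-1
#' autocorrelation (`lag1`), log residual variance (`lnvar`), log largest
#' negative-run area (`maxarea`) and the sum of local minima (`summin`).
#' Animals with greater day-to-day variability (high `lnvar`/`maxarea`)
#' are read as less resilient.
#'
#' @param daily Daily tibble from the feed-cleaning step (columns
#'   `animal_id, breed, pen_id, room_id, sire_id, age_days, fcd_kg`).
#' @param window Moving-median window in days. Default 5.
#' @return Tibble with one row per animal:
#'   `animal_id, breed, pen_id, room_id, sire_id, n_obs, lag1, lnvar,
#'   maxarea, summin`.
#' @export
resilience_indicators <- function(daily, window = 5) {
  assert_cols(daily, c("animal_id", "age_days", "fcd_kg"), "daily")
  meta_cols <- intersect(c("breed", "pen_id", "room_id", "sire_id"),
                         names(daily))
  daily <- dplyr::arrange(daily, .data$animal_id, .data$age_days)
  res <- dplyr::group_modify(
    dplyr::group_by(daily, .data$animal_id),
    function(d, key) {
      sm <- moving_median(d$fcd_kg, window = window)
      tr <- fit_linear_trend(sm, d$age_days)
      e <- tr$residuals
      out <- tibble::tibble(
        n_obs = sum(!is.na(d$fcd_kg)),
        lag1 = suppressWarnings(lag1_autocorrelation(e)),
        lnvar = suppressWarnings(ln_variance(e)),
        maxarea = max_negative_area(e),
        summin = sum_local_minima(e))
      for (mc in meta_cols) out[[mc]] <- d[[mc]][1]
      out
    })
  res <- dplyr::ungroup(res)
  res[, c("animal_id", meta_cols, "n_obs",
          "lag1", "lnvar", "maxarea", "summin")]
}

#' Residual decomposition of one animal's series
#'
#' Convenience accessor exposing the smoothing/detrending intermediates of
#' [resilience_indicators()] for plotting and inspection.
#'
#' @param daily Daily tibble filtered to a single animal.
#' @param window Moving-median window in days. Default 5.
#' @return Tibble `age_days, fcd_kg, smoothed, predicted, residual`.
#' @export
residual_series <- function(daily, window = 5) {
  assert_cols(daily, c("animal_id", "age_days", "fcd_kg"), "daily")
  if (dplyr::n_distinct(daily$animal_id) != 1) {
    abort("`daily` must contain exactly one animal")
  }
  daily <- dplyr::arrange(daily, .data$age_days)
  sm <- moving_median(daily$fcd_kg, window = window)
  tr <- fit_linear_trend(sm, daily$age_days)
  tibble::tibble(age_days = daily$age_days, fcd_kg = daily$fcd_kg,
                 smoothed = sm, predicted = tr$predicted,
                 residual = tr$residuals)
}

#' Within-breed resilience classes
#'
#' Bins each indicator within breed by equal-frequency percentile ranks
#' (ntile semantics): values at or below the 5th percentile are class `H`
#' (low variability, high resilience), at or above the 95th percentile
#' class `L`, inside the 47.5th-52.5th band class `M` (control), and all
#' others `unassigned`. Animals with a missing indicator value stay
#' `unassigned`.
#'
#' @param indicators Tibble from [resilience_indicators()].
#' @param which Indicator columns to classify.
#' @param min_per_breed Minimum animals per breed required. Default 20.
#' @return Long tibble `animal_id, breed, indicator, value, class` with
#'   `class` a factor with levels `L`, `M`, `H`, `unassigned`.
#' @export
assign_classes <- function(indicators,
                           which = c("lag1", "lnvar", "maxarea", "summin"),
                           min_per_breed = 20) {
  assert_cols(indicators, c("animal_id", "breed", which), "indicators")
  counts <- table(indicators$breed)
  if (any(counts < min_per_breed)) {
    abort(sprintf("breed(s) with fewer than %d animals: %s", min_per_breed,
                  paste(names(counts)[counts < min_per_breed],
                        collapse = ", ")))
  }
  long <- tidyr::pivot_longer(
    indicators[, c("animal_id", "breed", which)],
    cols = dplyr::all_of(which), names_to = "indicator",
    values_to = "value")
  long <- dplyr::mutate(
    dplyr::group_by(long, .data$breed, .data$indicator),
    .bin = percentile_bin(.data$value, 40))
  long <- dplyr::ungroup(long)
  long$class <- factor(
    dplyr::case_when(
      is.na(long$.bin) ~ "unassigned",
      long$.bin <= 2 ~ "H",
      long$.bin >= 39 ~ "L",
      long$.bin %in% c(20L, 21L) ~ "M",
      TRUE ~ "unassigned"),
    levels = c("L", "M", "H", "unassigned"))
  long[, c("animal_id", "breed", "indicator", "value", "class")]
}

# Equal-frequency percentile bins: rank (first occurrence breaking ties)
# mapped to 1..bins so each bin holds n/bins values up to remainder.
percentile_bin <- function(x, bins = 40) {
  r <- rank(x, ties.method = "first", na.last = "keep")
  n <- sum(!is.na(x))
  as.integer(floor(bins * (r - 1) / n) + 1L)
}

#' Spearman correlations between indicators and performance traits
#'
#' Pairwise-complete Spearman rank correlations of each resilience
#' indicator with each performance trait, overall and within breed, with
#' bootstrap standard errors.
#'
#' @param indicators Tibble from [resilience_indicators()].
#' @param traits Tibble with `animal_id` and numeric trait columns.
#' @param by_breed Also compute within-breed correlations? Default TRUE.
#' @param n_boot Bootstrap resamples for the SE. Default 1000.
#' @param seed Optional seed for the bootstrap.
#' @return Tibble `group, indicator, trait, rho, se, n`.
#' @export
spearman_with_traits <- function(indicators, traits, by_breed = TRUE,
                                 n_boot = 1000, seed = NULL) {
  assert_cols(traits, "animal_id", "traits")
  if (!is.null(seed)) set.seed(seed)
  ind_cols <- intersect(c("lag1", "lnvar", "maxarea", "summin"),
                        names(indicators))
  trait_cols <- setdiff(names(traits), "animal_id")
  joined <- dplyr::inner_join(indicators, traits, by = "animal_id")
  groups <- list(ALL = joined)
  if (by_breed && "breed" %in% names(joined)) {
    groups <- c(groups, split(joined, joined$breed))
  }
  purrr::list_rbind(purrr::imap(groups, function(g, gname) {
    purrr::list_rbind(purrr::map(ind_cols, function(ic) {
      purrr::list_rbind(purrr::map(trait_cols, function(tc) {
        x <- g[[ic]]; y <- g[[tc]]
        ok <- complete.cases(x, y)
        n <- sum(ok)
        if (n < 4) {
          return(tibble::tibble(group = gname, indicator = ic, trait = tc,
                                rho = NA_real_, se = NA_real_, n = n))
        }
        rho <- cor(x[ok], y[ok], method = "spearman")
        bs <- vapply(seq_len(n_boot), function(b) {
          i <- sample.int(n, n, replace = TRUE)
          suppressWarnings(cor(x[ok][i], y[ok][i], method = "spearman"))
        }, numeric(1))
        tibble::tibble(group = gname, indicator = ic, trait = tc,
                       rho = rho, se = sd(bs, na.rm = TRUE), n = n)
      }))
    }))
  }))
}
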