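test_that("moving median matches its definition on hand-checkable cases", {
  expect_equal(moving_median(rep(3, 10)), rep(3, 10))
  expect_equal(moving_median(c(1, 2, 100, 3, 4))[3], 3)
  x <- 1:11 * 1.0
  expect_equal(moving_median(x)[3:9], x[3:9])  # interior of a monotone series
  expect_error(moving_median(1:10, window = 4), "odd")
})

test_that("moving median skips missing days and needs 3 observed values", {
  x <- c(1, NA, 3, 4, NA, NA, 7, 8, 9)
  sm <- moving_median(x, 5)
  expect_true(is.na(sm[1]))       # window x[1:3] holds 2 observed values
  expect_equal(sm[3], 3)          # window x[1:5] holds {1, 3, 4}
  expect_equal(sm[6], 7)          # window x[4:8] holds {4, 7, 8}
  expect_equal(sm[9], 8)          # window x[7:9] holds {7, 8, 9}
})

test_that("linear trend fit matches closed-form OLS and centres residuals", {
  tr <- fit_linear_trend(c(1, 2, 4), 1:3)
  expect_equal(tr$slope, 1.5)
  expect_equal(tr$intercept, -2 / 3)
  # perfect line: zero residuals
  tr2 <- fit_linear_trend(0.5 + 0.1 * (10:30), 10:30)
  expect_equal(tr2$residuals, rep(0, 21), tolerance = 1e-12)
  # residuals sum to ~0 for any fit
  set.seed(1)
  sm <- rnorm(40)
  tr3 <- fit_linear_trend(sm, 1:40)
  expect_lt(abs(sum(tr3$residuals)), 1e-8 * 40)
  expect_error(fit_linear_trend(c(1, 2, 3), c(5, 5, 5)), "singular")
})

test_that("lag-1 autocorrelation matches the direct formula", {
  e <- c(1, -1, 1, -1, 1, -1)
  expect_equal(lag1_autocorrelation(e), -5 / 6)
  expect_warning(out <- lag1_autocorrelation(rep(2, 10)), "zero")
  expect_true(is.na(out))
})

test_that("lag-1 autocorrelation recovers the AR coefficient of a long simulation", {
  set.seed(11)
  n <- 1000
  phi <- 0.5
  e <- numeric(n)
  e[1] <- rnorm(1)
  for (t in 2:n) e[t] <- phi * e[t - 1] + rnorm(1, 0, sqrt(1 - phi^2))
  expect_gt(lag1_autocorrelation(e), 0.45)
  expect_lt(lag1_autocorrelation(e), 0.55)
})

test_that("ln variance follows the two-point value and the scaling law", {
  expect_equal(ln_variance(c(-2, 2)), log(8))
  set.seed(2)
  e <- rnorm(30)
  expect_equal(ln_variance(3 * e), ln_variance(e) + 2 * log(3))
  expect_warning(out <- ln_variance(rep(1, 5)), "zero")
  expect_true(is.na(out))
})

test_that("negative runs respect the >2 consecutive days rule and missing breaks", {
  expect_equal(nrow(negative_runs(c(1, 2, 3))), 0)
  r <- negative_runs(c(-1, -1, -1))
  expect_equal(nrow(r), 1)
  expect_equal(r$length, 3L)
  r2 <- negative_runs(c(-1, -1, NA, -1, -1, -1, -1))
  expect_equal(nrow(r2), 1)          # the leading pair does not qualify
  expect_equal(r2$start, 4L)
  expect_equal(r2$length, 4L)
})

test_that("max negative area integrates runs by the trapezoid rule", {
  e <- c(-1, -1, -1, 1, -2, -2, -2, -2)
  expect_equal(max_negative_area(e), log(6))   # areas 2 and 6
  expect_true(is.na(max_negative_area(c(1, 2, 3))))
  # constant run of depth c over L days has area c*(L-1)
  expect_equal(max_negative_area(rep(-1.5, 5)), log(1.5 * 4))
})

test_that("sum of local minima uses strict interior minima only", {
  expect_equal(sum_local_minima(1:10), 0)
  expect_equal(sum_local_minima(c(0, -3, 0)), -3)
  expect_equal(sum_local_minima(c(2, -1, 2, -4, 2, 1)), -5)
  # plateaus are not minima
  expect_equal(sum_local_minima(c(2, 0, 0, 2)), 0)
})

test_that("indicators match brute-force oracles on randomized series", {
  set.seed(99)
  for (trial in 1:300) {
    n <- sample(8:50, 1)
    e <- random_series(n)
    if (sum(!is.na(e)) < 4 || var(e, na.rm = TRUE) == 0) next
    expect_equal(lag1_autocorrelation(e), oracle_lag1(e), tolerance = 1e-12)
    expect_equal(ln_variance(e), log(var(e, na.rm = TRUE)),
                 tolerance = 1e-12)
    expect_equal(max_negative_area(e), oracle_maxarea(e), tolerance = 1e-12)
    expect_equal(sum_local_minima(e), oracle_summin(e), tolerance = 1e-12)
    expect_equal(moving_median(e, 5), oracle_moving_median(e, 5),
                 tolerance = 1e-12)
  }
})

test_that("indicators are exactly invariant to intercept shifts", {
  set.seed(7)
  fcd <- 2 + 0.02 * (0:41) + rnorm(42, 0, 0.3)
  fcd[c(5, 20)] <- NA
  d0 <- daily_from_vector(fcd)
  i0 <- suppressWarnings(resilience_indicators(d0))
  for (shift in c(3, -1, 0.25)) {
    d1 <- d0
    d1$fcd_kg <- d1$fcd_kg + shift
    i1 <- suppressWarnings(resilience_indicators(d1))
    expect_equal(i1$lag1, i0$lag1, tolerance = 1e-9)
    expect_equal(i1$lnvar, i0$lnvar, tolerance = 1e-9)
    expect_equal(i1$maxarea, i0$maxarea, tolerance = 1e-9)
    expect_equal(i1$summin, i0$summin, tolerance = 1e-9)
  }
})

test_that("linear-in-age terms are absorbed up to median re-selection", {
  # the OLS stage removes an added linear trend exactly; the moving median
  # is only approximately trend-equivariant (the median element of a
  # window can switch), so indicators must stay close but not identical
  set.seed(7)
  fcd <- 2 + 0.02 * (0:41) + rnorm(42, 0, 0.3)
  fcd[c(5, 20)] <- NA
  d0 <- daily_from_vector(fcd)
  i0 <- suppressWarnings(resilience_indicators(d0))
  for (slope in c(0.05, -0.01)) {
    d1 <- d0
    d1$fcd_kg <- d1$fcd_kg + slope * d1$age_days
    i1 <- suppressWarnings(resilience_indicators(d1))
    expect_lt(abs(i1$lag1 - i0$lag1), 0.1)
    expect_lt(abs(i1$lnvar - i0$lnvar), 0.1)
    expect_lt(abs(i1$maxarea - i0$maxarea), 0.15)
    expect_lt(abs(i1$summin - i0$summin), 0.4)
  }
})

test_that("indicator pipeline is deterministic", {
  set.seed(8)
  fcd <- 2 + rnorm(42, 0, 0.3)
  d <- daily_from_vector(fcd)
  expect_identical(resilience_indicators(d), resilience_indicators(d))
})

test_that("deepening a negative run never decreases maxarea", {
  set.seed(21)
  for (trial in 1:50) {
    e <- rnorm(30)
    runs <- negative_runs(e)
    if (nrow(runs) == 0) next
    e2 <- e
    idx <- runs$start[1]:runs$end[1]
    e2[idx] <- e2[idx] - runif(1, 0, 2)
    expect_gte(max_negative_area(e2), max_negative_area(e))
  }
})

test_that("class assignment produces 5 percent tails and control band per breed", {
  set.seed(3)
  n <- 200
  b <- tibble::tibble(animal_id = as.character(1:n), breed = "B",
                      lag1 = rnorm(n), lnvar = rnorm(n),
                      maxarea = rnorm(n), summin = rnorm(n))
  cl <- assign_classes(b)
  per <- table(cl$class[cl$indicator == "lnvar"])
  expect_equal(unname(per[c("L", "M", "H")]), rep(10L, 3),
               ignore_attr = TRUE)
  # H holds the lowest values, L the highest
  v <- cl[cl$indicator == "lnvar", ]
  expect_true(max(v$value[v$class == "H"]) < min(v$value[v$class == "M"]))
  expect_true(min(v$value[v$class == "L"]) > max(v$value[v$class == "M"]))
})

test_that("class assignment is deterministic under ties and errors on tiny breeds", {
  b <- tibble::tibble(animal_id = as.character(1:40), breed = "B",
                      lag1 = rep(c(1, 2), 20), lnvar = rep(1:8, 5),
                      maxarea = rnorm(40), summin = rnorm(40))
  c1 <- assign_classes(b)
  c2 <- assign_classes(b)
  expect_identical(c1, c2)
  tiny <- b[1:10, ]
  expect_error(assign_classes(tiny), "fewer than")
})

test_that("class sizes stay within one of the 5 percent target across n", {
  set.seed(4)
  for (n in c(150, 201, 333)) {
    b <- tibble::tibble(animal_id = as.character(1:n), breed = "B",
                        lag1 = rnorm(n), lnvar = rnorm(n),
                        maxarea = rnorm(n), summin = rnorm(n))
    cl <- assign_classes(b, which = "lnvar")
    per <- table(cl$class)
    for (lab in c("L", "M", "H")) {
      expect_lte(abs(per[[lab]] - ceiling(0.05 * n)), 1)
    }
  }
})

test_that("spearman correlations equal rank-then-pearson and hit the monotone bounds", {
  ind <- tibble::tibble(animal_id = as.character(1:20), breed = "B",
                        lag1 = 1:20 * 1.0, lnvar = 20:1 * 1.0,
                        maxarea = rnorm(20), summin = rnorm(20))
  traits <- tibble::tibble(animal_id = as.character(1:20),
                           muscle = (1:20)^2 * 1.0)
  sp <- spearman_with_traits(ind, traits, by_breed = FALSE, n_boot = 50,
                             seed = 1)
  expect_equal(sp$rho[sp$indicator == "lag1"], 1)
  expect_equal(sp$rho[sp$indicator == "lnvar"], -1)
  # tie handling: rank-then-pearson oracle
  x <- c(1, 2, 2, 3, 5, 8)
  y <- c(2, 1, 4, 4, 6, 7)
  ind2 <- tibble::tibble(animal_id = as.character(1:6), breed = "B",
                         lag1 = x, lnvar = x, maxarea = x, summin = x)
  tr2 <- tibble::tibble(animal_id = as.character(1:6), t = y)
  sp2 <- spearman_with_traits(ind2, tr2, by_breed = FALSE, n_boot = 10,
                              seed = 1)
  expect_equal(sp2$rho[1], cor(rank(x), rank(y)), tolerance = 1e-12)
})
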