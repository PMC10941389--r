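# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths: plain loops, sorting and pair counting only.

# Centred moving median by explicit window sort.
oracle_moving_median <- function(x, window) {
  h <- (window - 1) %/% 2
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - h):min(n, i + h)]
    w <- sort(w[!is.na(w)])
    k <- length(w)
    if (k >= 3) {
      out[i] <- if (k %% 2 == 1) w[(k + 1) / 2] else (w[k / 2] + w[k / 2 + 1]) / 2
    }
  }
  out
}

# Direct evaluation of the lag-1 autocorrelation formula with explicit
# pair loop; pairs spanning a missing value are skipped.
oracle_lag1 <- function(e) {
  ok <- !is.na(e)
  eb <- mean(e[ok])
  num <- 0
  for (t in seq_len(length(e) - 1)) {
    if (ok[t] && ok[t + 1]) num <- num + (e[t] - eb) * (e[t + 1] - eb)
  }
  num / sum((e[ok] - eb)^2)
}

# Exhaustive enumeration of maximal negative runs and their trapezoid
# areas; a missing day terminates a run.
oracle_negative_runs <- function(e, min_length = 3) {
  runs <- list()
  s <- NULL
  n <- length(e)
  for (i in seq_len(n + 1)) {
    inside <- i <= n && !is.na(e[i]) && e[i] < 0
    if (inside && is.null(s)) s <- i
    if (!inside && !is.null(s)) {
      if (i - s >= min_length) runs[[length(runs) + 1]] <- c(s, i - 1)
      s <- NULL
    }
  }
  lapply(runs, function(r) {
    a <- 0
    for (j in r[1]:(r[2] - 1)) a <- a + (-e[j] - e[j + 1]) / 2
    list(start = r[1], end = r[2], area = a)
  })
}

oracle_maxarea <- function(e, min_length = 3) {
  runs <- oracle_negative_runs(e, min_length)
  if (length(runs) == 0) return(NA_real_)
  log(max(vapply(runs, function(r) r$area, numeric(1))))
}

# Neighbour scan for strict interior local minima.
oracle_summin <- function(e) {
  total <- 0
  n <- length(e)
  if (n < 3) return(0)
  for (i in 2:(n - 1)) {
    if (!is.na(e[i - 1]) && !is.na(e[i]) && !is.na(e[i + 1]) &&
        e[i] < e[i - 1] && e[i] < e[i + 1]) {
      total <- total + e[i]
    }
  }
  total
}

# Pair-counting AUC with half credit for ties.
oracle_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# PERMANOVA pseudo-F for a single factor/covariate from a distance matrix
# via Gower centring and hat-matrix traces (McArdle & Anderson form).
oracle_pseudo_f <- function(d_mat, x) {
  n <- nrow(d_mat)
  a_mat <- -0.5 * d_mat^2
  cmat <- diag(n) - matrix(1 / n, n, n)
  g_mat <- cmat %*% a_mat %*% cmat
  xm <- stats::model.matrix(~x)
  h_mat <- xm %*% solve(crossprod(xm)) %*% t(xm)
  k <- qr(xm)$rank
  ss_model <- sum(diag(h_mat %*% g_mat %*% h_mat))
  ss_resid <- sum(diag((diag(n) - h_mat) %*% g_mat %*% (diag(n) - h_mat)))
  (ss_model / (k - 1)) / (ss_resid / (n - k))
}

# Exact permutation p-value by enumerating every ordering of the samples.
oracle_exact_permanova_p <- function(d_mat, x) {
  n <- nrow(d_mat)
  perms <- all_orderings(n)
  f_obs <- oracle_pseudo_f(d_mat, x)
  hits <- 0
  for (i in seq_len(nrow(perms))) {
    f_perm <- oracle_pseudo_f(d_mat, x[perms[i, ]])
    if (f_perm >= f_obs - 1e-12) hits <- hits + 1
  }
  hits / nrow(perms)
}

all_orderings <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_orderings(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  out
}

# Random daily residual-like series with missing values, for property
# tests (fixed RNG state controlled by the caller).
random_series <- function(n, miss_prob = 0.15) {
  e <- stats::rnorm(n)
  e[stats::runif(n) < miss_prob] <- NA
  e
}
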