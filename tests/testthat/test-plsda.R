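make_plsda_fixture <- function(n_per = 30, p = 40, shift = 2, seed = 61) {
  set.seed(seed)
  y <- factor(rep(c("L", "M", "H"), each = n_per),
              levels = c("L", "M", "H"))
  x <- matrix(rnorm(3 * n_per * p), 3 * n_per, p)
  x[y == "L", 1:5] <- x[y == "L", 1:5] + shift
  colnames(x) <- paste0("f", seq_len(p))
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  list(x = x, y = y)
}

test_that("stratified split partitions every stratum near 50/50", {
  set.seed(62)
  d <- tibble::tibble(
    animal_id = as.character(1:61),
    breed = sample(c("DR", "LR"), 61, TRUE),
    class = sample(c("L", "M", "H"), 61, TRUE))
  sp <- stratified_split(d, seed = 5)
  expect_setequal(sp$animal_id, d$animal_id)
  expect_true(all(sp$split %in% c("train", "test")))
  per <- dplyr::count(sp, .data$breed, .data$class, .data$split)
  wide <- tidyr::pivot_wider(per, names_from = "split",
                             values_from = "n", values_fill = 0)
  expect_true(all(abs(wide$train - wide$test) <= 1))
  # deterministic under the seed
  expect_identical(stratified_split(d, seed = 5), sp)
  # a singleton stratum lands on exactly one side
  d1 <- dplyr::bind_rows(d, tibble::tibble(animal_id = "x",
                                           breed = "XX", class = "L"))
  sp1 <- stratified_split(d1, seed = 5)
  expect_equal(sum(sp1$breed == "XX"), 1)
  expect_true(sp1$split[sp1$breed == "XX"] %in% c("train", "test"))
})

test_that("separable classes give perfect training AUC", {
  fx <- make_plsda_fixture(shift = 6)
  two <- fx$y != "H"
  fit <- fit_plsda(fx$x[two, ], droplevels(fx$y[two]), ncomp = 2)
  ev <- evaluate_plsda(fit, fx$x[two, ], droplevels(fx$y[two]))
  expect_equal(ev$per_class$auc[ev$per_class$class == "L"], 1)
  expect_error(fit_plsda(fx$x, factor(rep("L", nrow(fx$x)))), "2 classes")
})

test_that("first component matches an eigen-decomposition PLS oracle", {
  fx <- make_plsda_fixture()
  fit <- fit_plsda(fx$x, fx$y, ncomp = 1)
  xs <- scale(fx$x)
  ymat <- scale(model.matrix(~ fx$y - 1), scale = FALSE)
  m <- crossprod(xs, ymat)
  w_oracle <- eigen(m %*% t(m), symmetric = TRUE)$vectors[, 1]
  t_oracle <- xs %*% w_oracle
  # weights and scores agree up to overall sign
  sgn <- sign(sum(fit$W[, 1] * w_oracle))
  expect_equal(unname(fit$W[, 1]), sgn * w_oracle, tolerance = 1e-6)
  expect_equal(unname(fit$T[, 1]), sgn * as.vector(t_oracle),
               tolerance = 1e-6)
  expect_equal(sum(fit$W[, 1]^2), 1, tolerance = 1e-12)
})

test_that("latent scores align with an independent PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  fx <- make_plsda_fixture()
  fit <- fit_plsda(fx$x, fx$y, ncomp = 2)
  mo <- mixOmics::plsda(fx$x, fx$y, ncomp = 2, scale = TRUE)
  expect_gt(abs(cor(fit$T[, 1], mo$variates$X[, 1])), 0.999)
})

test_that("VIP scores satisfy the normalisation identity and rank signal first", {
  fx <- make_plsda_fixture(shift = 3)
  fit <- fit_plsda(fx$x, fx$y, ncomp = 3)
  vip <- vip_scores(fit)
  expect_equal(sum(vip^2), length(vip), tolerance = 1e-8)
  # the five shifted features should dominate
  expect_true(all(names(sort(vip, decreasing = TRUE))[1:3] %in%
                    paste0("f", 1:5)))
  # single-feature model: VIP identically 1
  one <- fit_plsda(fx$x[, 1, drop = FALSE], fx$y, ncomp = 1)
  expect_equal(unname(vip_scores(one)), 1, tolerance = 1e-12)
})

test_that("AUC equals the Mann-Whitney identity and handles ties", {
  # 5 of 6 (pos, neg) pairs concordant: 0.6 beats 0.1 and 0.2 but not 0.7
  expect_equal(auc_scores(c(0.9, 0.6), c(0.1, 0.2, 0.7)), 5 / 6)
  expect_equal(auc_scores(rep(0.5, 4), rep(0.5, 6)), 0.5)
  set.seed(63)
  for (trial in 1:50) {
    pos <- sample(seq(0, 1, 0.1), 5, TRUE)
    neg <- sample(seq(0, 1, 0.1), 7, TRUE)
    expect_equal(auc_scores(pos, neg), oracle_auc(pos, neg),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(64)
  pos <- rnorm(20, 1)
  neg <- rnorm(30)
  ref <- as.numeric(pROC::auc(
    response = c(rep(1, 20), rep(0, 30)), predictor = c(pos, neg),
    direction = "<", quiet = TRUE))
  expect_equal(auc_scores(pos, neg), ref, tolerance = 1e-10)
})

test_that("component selection favours informative dimensionality", {
  set.seed(65)
  n <- 90
  t1 <- rnorm(n); t2 <- rnorm(n)
  x <- cbind(outer(t1, rnorm(15)) + outer(t2, rnorm(15)) +
               matrix(rnorm(n * 15, 0, 0.4), n, 15))
  colnames(x) <- paste0("f", 1:15)
  y <- factor(ifelse(t1 > 0, "L", ifelse(t2 > 0, "M", "H")),
              levels = c("L", "M", "H"))
  sel <- select_components(x, y, max_comp = 4, folds = 4, repeats = 5,
                           seed = 66)
  expect_gte(sel$best, 2)
  expect_gt(max(sel$auc$cv_auc), 0.8)
  # pure noise: no candidate beats chance by much
  xn <- matrix(rnorm(n * 10), n, 10)
  yn <- factor(sample(c("L", "M", "H"), n, TRUE))
  seln <- select_components(xn, yn, max_comp = 3, folds = 4, repeats = 5,
                            seed = 67)
  expect_true(all(seln$auc$cv_auc > 0.3 & seln$auc$cv_auc < 0.7))
})

test_that("VIP elimination drops floor(0.2 p) per step and recovers planted features", {
  set.seed(68)
  fx <- make_plsda_fixture(n_per = 40, p = 100, shift = 2.5)
  out <- recursive_vip_elimination(fx$x, fx$y, ncomp = 2, folds = 4,
                                   repeats = 2, seed = 69)
  traj <- out$trajectory
  expect_equal(traj$n_features[1], 100)
  if (nrow(traj) > 1) expect_equal(traj$n_features[2], 80)
  if (nrow(traj) > 2) expect_equal(traj$n_features[3], 64)
  expect_equal(max(traj$cv_auc),
               traj$cv_auc[which.max(traj$cv_auc)])
  expect_equal(length(out$features),
               traj$n_features[which.max(traj$cv_auc)])
  # planted features survive preferentially once pruning happened
  if (length(out$features) < 100) {
    hits <- sum(paste0("f", 1:5) %in% out$features)
    expect_gte(hits, 3)
  }
  # reproducible from (seed, config)
  out2 <- recursive_vip_elimination(fx$x, fx$y, ncomp = 2, folds = 4,
                                    repeats = 2, seed = 69)
  expect_identical(out$features, out2$features)
})

test_that("evaluation reports coherent per-class metrics and confusion matrix", {
  fx <- make_plsda_fixture(shift = 6)
  fit <- fit_plsda(fx$x, fx$y, ncomp = 2)
  ev <- evaluate_plsda(fit, fx$x, fx$y)
  expect_true(all(ev$per_class$auc >= 0 & ev$per_class$auc <= 1))
  expect_equal(sum(ev$per_class$incidence), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(ev$confusion)),
               unname(table(fx$y)), ignore_attr = TRUE)
  expect_equal(ev$overall_auc, mean(ev$per_class$auc))
  # broom-style accessors
  expect_equal(tidy(ev), ev$per_class)
  expect_equal(glance(ev)$n_test, length(fx$y))
  # a class absent from the test set is flagged
  sub <- fx$y != "M"
  expect_warning(ev2 <- evaluate_plsda(fit, fx$x[sub, ], fx$y[sub]),
                 "absent")
  expect_true(is.na(ev2$per_class$auc[ev2$per_class$class == "M"]))
})

test_that("label permutation leaves no generalisable signal", {
  set.seed(70)
  fx <- make_plsda_fixture(n_per = 40, p = 30, shift = 2)
  yperm <- sample(fx$y)
  tr <- rep(c(TRUE, FALSE), length.out = length(yperm))
  fit <- fit_plsda(fx$x[tr, ], yperm[tr], ncomp = 2)
  ev <- evaluate_plsda(fit, fx$x[!tr, ], yperm[!tr])
  expect_true(all(ev$per_class$auc > 0.3 & ev$per_class$auc < 0.7))
})
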