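test_that("depth filter removes samples strictly below 700", {
  m <- matrix(0, 5, 3, dimnames = list(paste0("s", 1:5), paste0("a", 1:3)))
  m[1, 1] <- 100; m[2, 1] <- 699; m[3, 1] <- 700; m[4, 1] <- 5000
  out <- filter_samples_by_depth(m)
  expect_setequal(rownames(out), c("s3", "s4"))
  expect_setequal(attr(out, "removed_samples"), c("s1", "s2", "s5"))
  expect_error(filter_samples_by_depth(m, min_total = 1e7), "all samples")
})

test_that("prevalence filter removes ASVs strictly below the rate", {
  m <- matrix(0, 100, 3,
              dimnames = list(paste0("s", 1:100), paste0("a", 1:3)))
  m[1:5, 1] <- 1      # exactly 5% -> retained
  m[1:4, 2] <- 1      # 4% -> removed
  out <- filter_asvs_by_prevalence(m, 0.05)
  expect_setequal(colnames(out), "a1")
  expect_setequal(attr(out, "removed_asvs"), c("a2", "a3"))
})

test_that("CLR transform matches closed forms and centres rows", {
  m <- matrix(c(4, 4, 4, 4), 1, 4,
              dimnames = list("s1", paste0("a", 1:4)))
  expect_equal(unname(clr_transform(m)[1, ]), rep(0, 4))
  m2 <- matrix(c(1, 3), 1, 2, dimnames = list("s1", c("a1", "a2")))
  expect_equal(unname(clr_transform(m2)[1, ]),
               c(-log(3) / 2, log(3) / 2))
  cts <- toy_counts()
  clr <- clr_transform(cts)
  expect_lt(max(abs(rowSums(clr))), 1e-10)
  # default pseudo-value is 0.65 x smallest nonzero count
  expect_equal(attr(clr, "zero_const"), 0.65 * 1)
  zero_row <- rbind(cts, s5 = 0)
  expect_error(clr_transform(zero_row), "s5")
})

test_that("CLR is invariant to sequencing depth on zero-free rows", {
  set.seed(5)
  m <- matrix(rpois(40, 20) + 1, 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("a", 1:10)))
  clr1 <- clr_transform(m)
  clr2 <- clr_transform(m * 7)
  expect_equal(unname(clr1), unname(clr2), tolerance = 1e-12,
               ignore_attr = TRUE)
  d1 <- as.matrix(aitchison_distance(clr1))
  d2 <- as.matrix(aitchison_distance(clr2))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("aitchison distance is a metric on random compositions", {
  set.seed(6)
  m <- matrix(rpois(300, 30) + 1, 10, 30)
  rownames(m) <- paste0("s", 1:10)
  d <- as.matrix(aitchison_distance(clr_transform(m)))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 10))
  for (trial in 1:200) {
    ijk <- sample(10, 3)
    expect_lte(d[ijk[1], ijk[3]],
               d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("alpha diversity matches closed forms and bounds", {
  m <- matrix(1, 1, 8, dimnames = list("s1", paste0("a", 1:8)))
  div <- alpha_diversity(m)
  expect_equal(div$shannon, log(8))
  expect_equal(div$inv_simpson, 8)
  m2 <- matrix(c(5, 0, 0), 1, 3, dimnames = list("s1", paste0("a", 1:3)))
  div2 <- alpha_diversity(m2)
  expect_equal(div2$shannon, 0)
  expect_equal(div2$inv_simpson, 1)
  m3 <- matrix(c(1, 1, 2), 1, 3, dimnames = list("s1", paste0("a", 1:3)))
  div3 <- alpha_diversity(m3)
  p <- c(0.25, 0.25, 0.5)
  expect_equal(div3$shannon, -sum(p * log(p)))
  expect_equal(div3$inv_simpson, 1 / sum(p^2))
  # zero-total sample -> NA
  m4 <- rbind(m3, s2 = 0)
  expect_true(is.na(alpha_diversity(m4)$shannon[2]))
  # bounds across random samples
  set.seed(8)
  mr <- matrix(rpois(200, 5), 10, 20)
  mr[rowSums(mr) == 0, 1] <- 1
  rownames(mr) <- paste0("s", 1:10)
  dr <- alpha_diversity(mr)
  s_obs <- rowSums(mr > 0)
  expect_true(all(dr$shannon >= 0 & dr$shannon <= log(pmax(s_obs, 1)) + 1e-12))
  expect_true(all(dr$inv_simpson >= 1 - 1e-12 &
                    dr$inv_simpson <= s_obs + 1e-12))
})

test_that("diversity outlier removal uses strict Tukey fences", {
  d <- tibble::tibble(sample_id = paste0("s", 1:5),
                      shannon = c(1, 2, 3, 4, 100))
  out <- remove_diversity_outliers(d)
  expect_setequal(attr(out, "removed_samples"), "s5")
  # all-equal values: nothing removed
  d2 <- tibble::tibble(sample_id = paste0("s", 1:6), shannon = rep(2, 6))
  expect_equal(nrow(remove_diversity_outliers(d2)), 6)
  # a value exactly at a fence stays ("beyond" is strict)
  x <- c(1, 2, 3, 4)
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  d3 <- tibble::tibble(sample_id = paste0("s", 1:5),
                       shannon = c(x, fence))
  expect_equal(nrow(remove_diversity_outliers(d3)), 5)
})

test_that("kernel is a scaled Gram matrix: symmetric, PSD, hand-checkable", {
  x <- matrix(c(1, 2, 0, 1, -1, 3), 3, 2,
              dimnames = list(paste0("s", 1:3), c("a1", "a2")))
  k <- build_kernel(x)
  xs <- scale(x)
  expect_equal(unname(k), unname(tcrossprod(xs, xs) / 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(k, t(k))
  set.seed(9)
  m <- matrix(rpois(600, 30) + 1, 20, 30)
  rownames(m) <- paste0("s", 1:20)
  k2 <- build_kernel(clr_transform(m))
  ev <- eigen(k2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * sum(diag(k2)) / nrow(k2))
  # identical samples share identical kernel rows and diagonal entries
  m3 <- rbind(m, m[1, , drop = FALSE])
  rownames(m3) <- c(rownames(m), "s21")
  k3 <- build_kernel(clr_transform(m3))
  expect_equal(k3["s1", "s21"], k3["s1", "s1"], tolerance = 1e-12)
  expect_equal(k3["s21", "s21"], k3["s1", "s1"], tolerance = 1e-12)
})

test_that("zero-variance CLR columns are dropped before scaling with a warning", {
  x <- cbind(matrix(rnorm(20), 10, 2), 0)
  rownames(x) <- paste0("s", 1:10)
  colnames(x) <- paste0("a", 1:3)
  expect_warning(k <- build_kernel(x), "zero-variance")
  expect_equal(attr(k, "n_features"), 2)
})

test_that("filters compose in order and are idempotent", {
  sim <- small_cohort_microbiome(n = 60, n_asv = 80, seed = 17,
                                 low_depth_frac = 0.1)
  counts <- sim$mb$counts
  f1 <- filter_samples_by_depth(counts)
  f2 <- filter_asvs_by_prevalence(f1)
  expect_equal(unname(filter_samples_by_depth(f2)), unname(f2),
               ignore_attr = TRUE)
  expect_equal(unname(filter_asvs_by_prevalence(f2)), unname(f2),
               ignore_attr = TRUE)
  expect_setequal(attr(f1, "removed_samples"),
                  sim$mb$truth$low_depth_samples)
})

test_that("ASV tables round-trip through TSV", {
  cts <- toy_counts()
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(cts, rownames = "sample_id"), path)
  back <- read_asv_table(path)
  expect_equal(back, cts, ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(cts))
})

test_that("BIOM tables load transposed to samples x ASVs", {
  skip_if_not_installed("biomformat")
  cts <- toy_counts()
  path <- withr::local_tempfile(fileext = ".biom")
  suppressWarnings(biomformat::write_biom(biomformat::make_biom(t(cts)),
                                          path))
  back <- read_asv_table(path)
  expect_equal(back[rownames(cts), colnames(cts)], cts,
               ignore_attr = TRUE)
})
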