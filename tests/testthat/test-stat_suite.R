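test_that("neutrality regression recovers hand-computed slopes", {
  d <- data.frame(gc3 = c(0.4, 0.6, 0.8), gc12 = c(0.4, 0.6, 0.8))
  r <- neutrality_regression(d)
  expect_equal(r$slope, 1)
  expect_equal(r$r_squared, 1)
  expect_equal(r$relative_constraint, 0)
  d2 <- data.frame(gc3 = c(0.4, 0.6, 0.8), gc12 = c(0.5, 0.5, 0.5))
  expect_equal(neutrality_regression(d2)$slope, 0)
  # normal-equations oracle: points (0,0), (1,0.5), (2,0.7) -> slope 0.35
  d3 <- data.frame(gc3 = c(0, 1, 2), gc12 = c(0, 0.5, 0.7))
  expect_equal(neutrality_regression(d3)$slope, 0.35)
  expect_error(neutrality_regression(
    data.frame(gc3 = c(0.5, 0.5, 0.5), gc12 = c(0.1, 0.2, 0.3))),
    "zero variance")
})

test_that("neutrality slope is recovered from noisy simulated panels", {
  beta <- 0.3276
  set.seed(71)
  slopes <- replicate(100, {
    gc3 <- runif(18, 0.418, 0.8382)
    gc12 <- beta * gc3 + rnorm(18, 0, 0.02)
    neutrality_regression(data.frame(gc3 = gc3, gc12 = gc12))$slope
  })
  expect_lt(abs(mean(slopes) - beta), 0.05)
})

test_that("parity coordinates follow their definitions", {
  cp <- list(A3 = 10, T3 = 10, G3 = 5, C3 = 15)
  class(cp) <- "composition_profile"
  pt <- parity_point(cp)
  expect_equal(unname(pt[["at_bias"]]), 0.5)
  expect_equal(unname(pt[["gc_bias"]]), 0.25)
  cp2 <- list(A3 = 7, T3 = 7, G3 = 9, C3 = 9)
  class(cp2) <- "composition_profile"
  expect_equal(unname(parity_point(cp2)), c(0.5, 0.5))
  panel <- generate_panel(5, seed = 72)
  for (r in panel) {
    pt <- parity_point(nucleotide_composition(r))
    expect_true(all(pt >= 0 & pt <= 1))
  }
  cp3 <- list(A3 = 0, T3 = 0, G3 = 3, C3 = 1)
  class(cp3) <- "composition_profile"
  expect_true(is.na(parity_point(cp3)[["at_bias"]]))
})

test_that("third-position regressions behave at both extremes", {
  panel <- data.frame(pct_A3 = c(10, 20, 30, 40), pct_A = c(5, 10, 15, 20))
  r <- nt3_regression(panel, "A")
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 0.5)
  set.seed(73)
  big <- data.frame(pct_G3 = rnorm(1000), pct_G = rnorm(1000))
  expect_lt(nt3_regression(big, "G")$r_squared, 0.01)
})

test_that("correlation matrices match base-R oracles with stars", {
  d <- data.frame(x = c(1, 2, 3, 4, 5), y = c(2, 4, 6, 8, 10),
                  z = c(5, 4, 3, 2, 1))
  cm <- correlation_matrix(d)
  expect_equal(cm$r["x", "y"], 1)
  expect_equal(cm$r["x", "z"], -1)
  expect_equal(diag(cm$r), c(x = 1, y = 1, z = 1))
  # z-score covariance oracle on random tables
  set.seed(74)
  tab <- matrix(rnorm(50 * 4), 50, 4,
                dimnames = list(NULL, paste0("v", 1:4)))
  cm2 <- correlation_matrix(as.data.frame(tab))
  zs <- scale(tab)
  expect_equal(cm2$r, stats::cov(zs), tolerance = 1e-12,
               ignore_attr = TRUE)
  # bonferroni multiplies by the number of pairs, capped at 1
  cmb <- correlation_matrix(as.data.frame(tab), correction = "bonferroni")
  np <- 4 * 3 / 2
  expect_equal(cmb$p_adjusted[1, 2], min(cmb$p[1, 2] * np, 1))
})

test_that("spearman correlations are rank-based", {
  d <- data.frame(x = c(1, 2, 3, 4, 5), y = exp(c(1, 2, 3, 4, 5)))
  expect_equal(correlation_matrix(d, method = "spearman")$r["x", "y"], 1)
  expect_lt(correlation_matrix(d, method = "pearson")$r["x", "y"], 1)
})

test_that("constant columns give missing correlations", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(2, 2, 2, 2))
  expect_true(is.na(correlation_matrix(d)$r["x", "y"]))
})

test_that("bootstrap t-test: identical groups give t=0 and p~1", {
  rows <- simulate_rscu_rows(6, 800, seed = 75)
  ok <- colSums(is.na(rows)) == 0
  same <- bootstrap_t_test(rows[1:3, ok], rows[1:3, ok], reps = 199,
                           seed = 77)
  expect_true(all(abs(same$t) < 1e-12, na.rm = TRUE))
  # p ~ 1 up to degenerate resamples (tiny groups occasionally redraw one row)
  expect_true(all(same$p[!is.na(same$t)] > 0.85))
  expect_gt(stats::median(same$p, na.rm = TRUE), 0.95)
})

test_that("bootstrap t-test is deterministic and flags planted shifts", {
  a <- simulate_rscu_rows(18, 500, seed = 78)
  b <- simulate_rscu_rows(62, 500, seed = 79)
  ok <- colSums(is.na(a)) == 0 & colSums(is.na(b)) == 0
  a <- a[, ok]; b <- b[, ok]
  sd_p <- stats::sd(c(a[, "GTA"], b[, "GTA"]))
  a[, "GTA"] <- a[, "GTA"] + 2 * sd_p
  r1 <- bootstrap_t_test(a, b, reps = 499, seed = 80)
  r2 <- bootstrap_t_test(a, b, reps = 499, seed = 80)
  expect_equal(r1, r2)
  expect_lt(r1$p[r1$codon == "GTA"], 0.01)
  expect_gt(mean(r1$p > 0.05, na.rm = TRUE), 0.8)  # other codons mostly null
})

test_that("zero-variance codons give undefined t", {
  a <- matrix(1, 3, 2, dimnames = list(NULL, c("TTT", "TTC")))
  b <- matrix(1, 3, 2, dimnames = list(NULL, c("TTT", "TTC")))
  b[, 2] <- c(0.5, 1, 1.5)
  bt <- bootstrap_t_test(a, b, reps = 100, seed = 81)
  expect_true(is.na(bt$t[1]))
  expect_false(is.na(bt$t[2]))
})

test_that("covariance PCA: collinear rows load one axis; percents sum to 100", {
  set.seed(82)
  base <- rnorm(10)
  x <- outer(seq(1, 5, length.out = 6), base)  # rank-1 after centering
  colnames(x) <- paste0("c", 1:10)
  p <- pca_rscu(x)
  expect_equal(p$variance_percent[1], 100, tolerance = 1e-9)
  y <- matrix(rnorm(8 * 10), 8, 10, dimnames = list(NULL, paste0("c", 1:10)))
  p2 <- pca_rscu(y)
  expect_equal(sum(p2$variance_percent), 100, tolerance = 1e-9)
  expect_true(all(diff(p2$variance_percent) <= 1e-12))
})

test_that("PCA scores and loadings reconstruct the centered data", {
  set.seed(83)
  y <- matrix(rnorm(9 * 12), 9, 12, dimnames = list(NULL, paste0("c", 1:12)))
  p <- pca_rscu(y)
  recon <- p$scores %*% t(p$loadings)
  centered <- scale(y, center = TRUE, scale = FALSE)
  expect_lt(max(abs(recon - centered)), 1e-8)
})

test_that("ordination rejects missing values and tiny panels", {
  y <- matrix(rnorm(12), 3, 4)
  y[1, 1] <- NA
  expect_error(pca_rscu(y), "missing")
  expect_error(pca_rscu(matrix(rnorm(8), 2, 4)), "at least 3")
})
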