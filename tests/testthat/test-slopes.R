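# oracle: MA slope as the first principal axis of the 2x2 covariance matrix
eigen_ma_oracle <- function(x, y) {
  v <- eigen(cov(cbind(x, y)))$vectors[, 1]
  v[2] / v[1]
}

test_that("MA slope recovers noiseless lines and the eigen oracle", {
  x <- seq(-3, 3, length.out = 50)
  expect_equal(ma_slope(x, x)$slope, 1)
  expect_equal(ma_slope(x, -2 * x)$slope, -2)
  set.seed(30)
  for (i in 1:20) {
    xx <- rnorm(200)
    yy <- 0.4 * xx + rnorm(200, sd = runif(1, 0.1, 2))
    expect_equal(ma_slope(xx, yy)$slope, eigen_ma_oracle(xx, yy),
                 tolerance = 1e-10)
  }
})

test_that("MA slope equals its closed form on given covariances", {
  # large-sample bivariate normal with Sxx = 1, Syy = 0.25, Sxy = 0.45:
  # slope from the quadratic in the sample (co)variances
  set.seed(31)
  S <- matrix(c(1, 0.45, 0.45, 0.25), 2)
  L <- chol(S)
  z <- matrix(rnorm(2 * 20000), ncol = 2) %*% L
  sxx <- var(z[, 1]); syy <- var(z[, 2]); sxy <- cov(z[, 1], z[, 2])
  closed <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  expect_equal(ma_slope(z[, 1], z[, 2])$slope, closed, tolerance = 1e-12)
})

test_that("SMA slope follows the variance-ratio definition", {
  x <- rnorm(100)
  expect_equal(sma_slope(x, x)$slope, 1)
  y <- 2 * x + rnorm(100, sd = 1e-9)
  expect_equal(sma_slope(x, y)$slope, 2, tolerance = 1e-6)
  # swapping x and y inverts the slope
  set.seed(32)
  a <- rnorm(300); b <- 0.7 * a + rnorm(300)
  expect_equal(sma_slope(a, b)$slope * sma_slope(b, a)$slope, 1,
               tolerance = 1e-12)
})

test_that("MA and SMA agree exactly when Sxx equals Syy", {
  set.seed(33)
  x <- rnorm(500)
  y <- sample(x)  # same marginal variance, random association
  if (cov(x, y) != 0) {
    expect_equal(ma_slope(x, y)$slope, sma_slope(x, y)$slope,
                 tolerance = 1e-10)
  }
})

test_that("degenerate slope inputs raise errors", {
  expect_error(ma_slope(1:2, 1:2), "at least 3")
  x <- c(1, 2, 3, 4)
  expect_error(sma_slope(rep(1, 4), x), "zero variance")
  # Sxy = 0 with Sxx = Syy: orientation undefined
  expect_error(ma_slope(c(-1, -1, 1, 1), c(-1, 1, -1, 1)), "undefined")
  # non-finite pairs are dropped and counted
  s <- ma_slope(c(x, Inf), c(x, 1))
  expect_equal(s$n_dropped, 1L)
  expect_equal(s$n, 4L)
})

test_that("bootstrap CIs are deterministic and flag exclusion of 0 and 1", {
  x <- rnorm(500, sd = 1)
  b1 <- bootstrap_slope(x, x, method = "MA", B = 200, seed = 7)
  expect_equal(unname(b1$ci), c(1, 1))
  expect_true(b1$excludes_0)
  expect_false(b1$excludes_1)
  b2 <- bootstrap_slope(x, x, method = "MA", B = 200, seed = 7)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$boot, b2$boot)
  expect_warning(bootstrap_slope(x, x, B = 50, seed = 1), "fewer than 100")
  # BCa variant brackets the point estimate and stays near the percentile CI
  set.seed(34)
  xx <- rnorm(150); yy <- xx + rnorm(150, sd = 0.3)
  bca <- bootstrap_slope(xx, yy, method = "MA", B = 300, seed = 8,
                         ci_type = "bca")
  pct <- bootstrap_slope(xx, yy, method = "MA", B = 300, seed = 8)
  expect_true(bca$ci[1] < bca$slope && bca$slope < bca$ci[2])
  expect_lt(max(abs(bca$ci - pct$ci)), 0.1)
})

test_that("eQTL-stratified slopes separate cis-like from trans-like genes", {
  set.seed(35)
  n <- 200
  genes_local <- sprintf("L%03d", 1:n)
  genes_distant <- sprintf("D%03d", 1:n)
  x <- c(rnorm(n, sd = 1), rnorm(n, sd = 1))
  names(x) <- c(genes_local, genes_distant)
  y <- c(x[genes_local] + rnorm(n, sd = 0.2),  # cis: hybrid mirrors parent
         rnorm(n, sd = 0.2))                   # trans: no allelic difference
  names(y) <- names(x)
  ann <- data.frame(
    gene = c(genes_local, genes_distant, "unknown1"),
    has_local = c(rep(TRUE, n), rep(FALSE, n), TRUE),
    has_distant = c(rep(FALSE, n), rep(TRUE, n), FALSE)
  )
  st <- stratified_slopes(x, y, ann, method = "MA", B = 200, seed = 9)
  expect_equal(st$n_unknown, 1L)
  expect_gt(st$slopes$local_only$ci[1], st$slopes$distant_only$ci[2])
  expect_false(st$overlap["local_only", "distant_only"])
  expect_true("both" %in% st$empty_classes)
})

test_that("replicate error variance estimates var(d)/2 per bin", {
  set.seed(36)
  n <- 5000
  base <- rnorm(n)
  ab <- runif(n, 1, 100)
  expect_equal(replicate_error_by_bin(base, base, ab)$error_variance,
               rep(0, 10))
  sigma <- 0.4
  r1 <- base + rnorm(n, sd = sigma)
  r2 <- base + rnorm(n, sd = sigma)
  est <- replicate_error_by_bin(r1, r2, ab)
  expect_equal(mean(est$error_variance), sigma^2, tolerance = 0.1)
  expect_equal(sum(est$n), n)
  expect_error(replicate_error_by_bin(r1[1:5], r2[1:5], ab[1:5]), "fewer genes")
})

test_that("MA slope is monotone in the cis share of expression variance", {
  libs <- c(mrna_BY = 1e6, mrna_RM = 1e6, fp_BY = 1.5e6, fp_RM = 1.5e6,
            mrna_hyb1 = 1e6, mrna_hyb2 = 1e6, fp_hyb1 = 1.5e6,
            fp_hyb2 = 1.5e6)
  slope_at <- function(cis_share, seed) {
    sim <- generate_expression_dataset(sim_config(
      n_genes = 2000, frac_cis = cis_share, frac_trans = 1 - cis_share,
      dispersion = 0, seed = seed, library_sizes = libs
    ))
    fc <- function(d, s1, s2, z) {
      down <- downsample_libraries(sum_replicates(d), seed = z)
      flt <- filter_genes(hypergeometric_equalize(down, seed = z + 1), down)
      setNames(log2(flt$downsampled$counts[, s1] /
                      flt$downsampled$counts[, s2]),
               rownames(flt$downsampled$counts))
    }
    p <- fc(sim$parents, "mrna_BY_1", "mrna_RM_1", seed + 1)
    h <- fc(sim$hybrid, "mrna_BYallele_1", "mrna_RMallele_1", seed + 3)
    g <- intersect(names(p), names(h))
    ma_slope(p[g], h[g])$slope
  }
  shares <- c(0, 0.25, 0.5, 0.75, 1)
  slopes <- vapply(seq_along(shares),
                   function(i) slope_at(shares[i], 90 + 10 * i), numeric(1))
  expect_true(all(diff(slopes) > 0))
  expect_lt(abs(slopes[1]), 0.1)
  expect_equal(slopes[5], 1, tolerance = 0.1)
})

test_that("counting noise shrinks with abundance in simulated replicates", {
  cfg <- sim_config(n_genes = 3000, dispersion = 0, seed = 37,
                    library_sizes = small_libs())
  sim <- generate_expression_dataset(cfg)
  h <- sim$hybrid
  cn <- colnames(h$counts)
  fc_rep <- function(r) {
    by <- h$counts[, paste0("mrna_BYallele_", r)]
    rm_ <- h$counts[, paste0("mrna_RMallele_", r)]
    log2(by / rm_)
  }
  f1 <- fc_rep(1); f2 <- fc_rep(2)
  ab <- rowMeans(h$counts[, grep("mrna", cn)])
  keep <- is.finite(f1) & is.finite(f2)
  est <- replicate_error_by_bin(f1[keep], f2[keep], ab[keep])
  # error variance decreases monotonically (in rank) with abundance
  expect_lt(cor(est$mean_abundance, est$error_variance, method = "spearman"),
            -0.9)
  expect_gt(est$error_variance[1], est$error_variance[10])
})
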