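test_that("rank correlation handles monotone pairs and rejects constants", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(rank_correlation(x, x^3)$rho, 1)
  expect_equal(rank_correlation(x, -sqrt(x))$rho, -1)
  expect_error(rank_correlation(x, rep(2, 5)), "constant")
  expect_error(rank_correlation(1:2, 2:1), "3 paired")
})

test_that("rank correlation is invariant under strictly monotone transforms", {
  set.seed(12)
  x <- rexp(40); y <- x + rnorm(40, sd = 0.5)
  base <- rank_correlation(x, y)$rho
  expect_equal(rank_correlation(exp(x), y)$rho, base)
  expect_equal(rank_correlation(x, y^3 + 10)$rho, base)
})

test_that("coupled dyad and internal-CpG densities correlate positively", {
  # shared CpG-richness factor drives both metrics, as in CpG-rich genes
  set.seed(13)
  richness <- rgamma(200, shape = 2)
  dyads <- rpois(200, lambda = 2 * richness)
  internal <- rpois(200, lambda = 3 * richness)
  expect_gt(rank_correlation(dyads, internal)$rho, 0.5)
})

test_that("paired signed-rank: one-sided counts give V = 0 and the exact tail", {
  a <- 1:20
  b <- a + runif(20, 0.5, 2)   # every mammalian count below its ortholog
  res <- paired_sign_test(a, b)
  expect_equal(res$V, 0)
  expect_equal(res$p_value, 2 * 2^-20, tolerance = 1e-3)
  expect_equal(res$n_effective, 20L)
})

test_that("paired signed-rank agrees with exhaustive enumeration for small n", {
  set.seed(14)
  for (n in c(8, 10, 12)) {
    for (rep in 1:5) {
      a <- rnorm(n); b <- rnorm(n)
      got <- paired_sign_test(a, b)
      oracle <- signed_rank_exact(a - b)
      expect_equal(got$V, oracle$V)
      expect_equal(got$p_value, oracle$p, tolerance = 1e-12)
    }
  }
})

test_that("paired signed-rank drops zero differences and centres under symmetry", {
  a <- c(1, 2, 3, 4, 5, 6)
  b <- c(1, 2, 3, 4, 5, 6) + c(0, 0, 1, -1, 2, -2)
  res <- paired_sign_test(a, b)
  expect_equal(res$n_effective, 4L)
  expect_gt(res$p_value, 0.9)  # antisymmetric differences: null centre
  expect_error(paired_sign_test(a, a), "zero")
})

test_that("score regression recovers an exact line and a weak planted effect", {
  x <- seq(0.1, 5, length.out = 50)
  fit <- suppressWarnings(score_regression(x, 2 * x))
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  # independent vectors: r-squared near zero
  set.seed(15)
  fit0 <- score_regression(rnorm(10000), rnorm(10000))
  expect_lt(fit0$r_squared, 0.001)
  # weak planted effect at genome scale: significant p, tiny r-squared
  n <- 13491
  dens <- rexp(n)
  score <- 0.085 * dens + rnorm(n)   # calibrated to r2 ~ 0.007
  fitw <- score_regression(dens, score)
  expect_lt(fitw$p_value, 1e-10)
  expect_lt(fitw$r_squared, 0.03)
  expect_gt(fitw$r_squared, 0.001)
  expect_error(score_regression(rep(1, 20), rnorm(20)), "zero-variance")
})

test_that("methylation site counting applies percent, coverage and strand rules", {
  sites <- data.frame(gene_id = c("g1", "g1", "g1", "g2"),
                      chrom = "chr1", pos = c(100L, 200L, 300L, 400L))
  p <- tempfile(fileext = ".bed")
  writeLines(c(
    bedmethyl_line("chr1", 100, "+", 30, 95),  # methylated, + strand
    bedmethyl_line("chr1", 101, "-", 30, 92),  # paired - strand
    bedmethyl_line("chr1", 200, "+", 30, 10),  # below percent cutoff
    bedmethyl_line("chr1", 300, "+", 2, 99),   # below coverage
    bedmethyl_line("chr1", 400, "+", 30, 80)   # methylated, + only
  ), p)
  trk <- read_bedmethyl(p)
  res <- methylation_site_counts(sites, trk)
  expect_identical(res$n_sites, c(3L, 1L))
  expect_identical(res$n_methylated, c(1L, 1L))
  # symmetric mode requires both strands to pass
  sym <- methylation_site_counts(sites, trk, symmetric = TRUE)
  expect_identical(sym$n_methylated, c(1L, 0L))
  # monotone non-increasing in the percent cutoff, bounded by n_sites
  for (cut in c(0, 50, 90, 100)) {
    r <- methylation_site_counts(sites, trk, percent_cutoff = cut)
    expect_true(all(r$n_methylated <= r$n_sites))
  }
  m <- vapply(c(0, 50, 90), function(cut) {
    sum(methylation_site_counts(sites, trk, percent_cutoff = cut)$n_methylated)
  }, numeric(1))
  expect_true(all(diff(m) <= 0))
  bad <- data.frame(gene_id = "g", chrom = "chrX", pos = 1L)
  expect_error(methylation_site_counts(bad, trk), "coordinate mismatch")
})

test_that("a gene with 187 sites at 21% methylation counts about 39", {
  sites <- data.frame(gene_id = "high_dyad_gene", chrom = "chr9",
                      pos = seq(1000L, by = 10L, length.out = 187L))
  sim <- simulate_methylation(sites, rate = 0.21, seed = 16)
  res <- methylation_site_counts(sites, sim$track)
  expect_identical(res$n_sites, 187L)
  expect_identical(res$n_methylated, sim$truth$n_methylated)
  expect_lt(abs(res$n_methylated - 0.21 * 187), 3 * sqrt(187 * 0.21 * 0.79))
})

test_that("stage trend regression uses stage rank with F(1, S-2)", {
  medians_exact <- 1:9 / 10
  expr <- matrix(10, nrow = 9, ncol = 9,
                 dimnames = list(paste0("g", 1:9), paste0("s", 1:9)))
  # gene g_i expressed from stage i onward; densities increase with i
  for (s in 1:9) expr[, s] <- ifelse(1:9 <= s, 10, 0)
  dens <- setNames(seq(0.1, 0.9, by = 0.1), paste0("g", 1:9))
  res <- suppressWarnings(stage_density_trend(expr, dens))
  expect_identical(unname(res$df), c(1, 7))
  expect_gt(res$slope, 0)
  expect_lt(res$p_value, 0.001)
  # noiseless linear medians: r-squared 1
  expect_gt(res$r_squared, 0.9)
})

test_that("shuffling stage order destroys the trend most of the time", {
  set.seed(18)
  dens <- setNames(rexp(300), paste0("g", 1:300))
  expr <- simulate_expression_stages(dens, stage_count = 9, strength = 1, seed = 44)
  res <- stage_density_trend(expr, dens)
  expect_lt(res$p_value, 0.01)
  hits <- replicate(30, {
    stage_density_trend(expr[, sample(9)], dens)$p_value > 0.05
  })
  expect_gte(mean(hits), 0.9)
})
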