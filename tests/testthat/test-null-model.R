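test_that("codon usage is estimated as within-family relative counts", {
  u1 <- suppressWarnings(estimate_codon_usage(paste0(rep("TCC", 30), collapse = "")))
  expect_equal(unname(u1["TCC"]), 1)
  expect_equal(unname(u1["AGC"]), 0)

  # serine codons in ratio TCC:AGC:TCA = 1:1:2
  corpus <- paste0(c(rep("TCC", 5), rep("AGC", 5), rep("TCA", 10)), collapse = "")
  u2 <- suppressWarnings(estimate_codon_usage(corpus))
  expect_equal(unname(u2[c("TCC", "AGC", "TCA")]), c(0.25, 0.25, 0.5))

  u3 <- suppressWarnings(
    estimate_codon_usage(paste0(c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
                                collapse = "")))
  ser <- c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC")
  expect_equal(unname(u3[ser]), rep(1 / 6, 6))
})

test_that("families absent from the corpus fall back to uniform with warning", {
  expect_warning(u <- estimate_codon_usage("ATGATGATG"), "uniform")
  expect_equal(unname(u["ATG"]), 1)       # M family observed
  expect_equal(unname(u["GTA"]), 1 / 4)   # V family unobserved -> uniform
  expect_error(suppressWarnings(estimate_codon_usage("NNN")), "no valid codons")
})

test_that("site null proportion mixes role products over the composition", {
  expect_equal(site_null_proportion(c("S/V" = 261)), 1 / 3)
  expect_equal(site_null_proportion(c("M/K" = 10)), 0)
  # half S/V (1/3), half M/V (0) under uniform usage
  expect_equal(site_null_proportion(c("S/V" = 5, "M/V" = 5)), 1 / 6)
  # string form round-trips from conservation calls
  expect_equal(site_null_proportion("S/V:219;N/V:1"),
               (219 / 220) * (1 / 3) + (1 / 220) * (1 / 2))
  # majority-only reduces to the dominant pair
  expect_equal(site_null_proportion("S/V:219;N/V:1", majority_only = TRUE), 1 / 3)
  expect_error(site_null_proportion(c("S/V" = 0)), "empty")
})

test_that("p0 is monotone in role fractions and bounded by per-pair products", {
  u_lo <- codon_usage(c(TCC = 1, AGC = 1, TCA = 8))   # serine ends-C mass 0.2
  u_hi <- codon_usage(c(TCC = 4, AGC = 4, TCA = 2))   # serine ends-C mass 0.8
  comp <- c("S/V" = 7, "N/V" = 3)
  p_lo <- site_null_proportion(comp, u_lo)
  p_hi <- site_null_proportion(comp, u_hi)
  expect_lt(p_lo, p_hi)
  for (u in list(u_lo, u_hi, NULL)) {
    p <- site_null_proportion(comp, u)
    pairs <- vapply(c("S", "N"), function(a) {
      role_fraction(a, "first", u) * role_fraction("V", "second", u)
    }, numeric(1))
    expect_gte(p, min(pairs))
    expect_lte(p, max(pairs))
  }
})

test_that("proportion z-test reproduces the conserved-site arithmetic", {
  zt <- proportion_ztest(219, 261, 0.212)
  expect_equal(zt$expected_rounded, 55)
  expect_equal(zt$excess, 164)
  expect_equal(zt$z, (219 / 261 - 0.212) / sqrt(0.212 * 0.788 / 261),
               tolerance = 1e-12)
  expect_equal(zt$z, 24.8, tolerance = 0.01)
  expect_lt(zt$p_value, 1e-4)
  # null centre: k = n * p0 exactly
  zt0 <- proportion_ztest(60, 200, 0.3)
  expect_equal(zt0$z, 0)
  expect_equal(zt0$p_value, 0.5)
  expect_equal(zt0$excess, 0)
})

test_that("z sign tracks the direction of the departure from p0", {
  above <- proportion_ztest(80, 100, 0.5)
  below <- proportion_ztest(20, 100, 0.5)
  expect_gt(above$z, 0)
  expect_lt(below$z, 0)
  expect_gt(below$p_value, 0.5)
})

test_that("normal-approximation p is close to the exact binomial at small n", {
  cases <- list(c(8, 10, 0.3), c(12, 15, 0.5), c(10, 12, 0.4), c(16, 20, 0.5))
  for (cs in cases) {
    approx_p <- proportion_ztest(cs[1], cs[2], cs[3])$p_value
    exact_p <- stats::binom.test(cs[1], cs[2], cs[3], alternative = "greater")$p.value
    expect_lt(abs(approx_p - exact_p), 0.05)
  }
})

test_that("degenerate p0 falls back to the exact binomial statement", {
  z0 <- proportion_ztest(0, 50, 0)
  expect_true(is.na(z0$z))
  expect_equal(z0$p_value, 1)
  z1 <- proportion_ztest(3, 50, 0)
  expect_equal(z1$p_value, 0)
  z2 <- proportion_ztest(50, 50, 1)
  expect_equal(z2$p_value, 1)
})

test_that("site excess scan tests conserved sites and adjusts with BH", {
  aln <- toy_alignment(rep(c("TCC GTG AAA", "TCC GTG AAA", "TCC GTG TCC"), 4))
  calls <- call_conserved(column_dyad_counts(aln), gene_id = "g", threshold = 0.75)
  res <- site_excess_scan(calls)
  expect_identical(nrow(res), sum(calls$conserved))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_true(all(diff(res$pair_index) > 0))
  # a site sitting exactly at its null is not significant
  null_calls <- data.frame(gene_id = "g", pair_index = 0L, k = 4L, n = 12L,
                           frac = 1 / 3, conserved = TRUE, aa_dyads = "S/V:12",
                           stringsAsFactors = FALSE)
  res0 <- site_excess_scan(null_calls)
  expect_gte(res0$p_value, 0.5)
  expect_equal(res0$excess, 0)
})
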