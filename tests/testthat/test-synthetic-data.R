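test_that("tree simulation is deterministic, ultrametric, and sized to config", {
  cfg <- generator_config(seed = 50, n_species = 40, tree_depth = 2)
  t1 <- simulate_tree(cfg)
  t2 <- simulate_tree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_identical(ape::Ntip(t1), 40L)
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(t1)), 2)
  cherry <- simulate_tree(generator_config(seed = 51, n_species = 2))
  expect_identical(ape::Ntip(cherry), 2L)
})

test_that("alignment generator plants recoverable sites and respects substreams", {
  cfg <- generator_config(seed = 52, n_species = 25, n_genes = 5,
                          codons_per_gene = 80, conservation_prob = 1,
                          plant_mean = 2)
  sim1 <- simulate_ortholog_alignment(cfg, 3)
  sim2 <- simulate_ortholog_alignment(cfg, 3)
  expect_identical(sim1$alignment$codons, sim2$alignment$codons)
  # adding genes to the config never shifts an existing gene's output
  cfg_more <- generator_config(seed = 52, n_species = 25, n_genes = 50,
                               codons_per_gene = 80, conservation_prob = 1,
                               plant_mean = 2)
  sim3 <- simulate_ortholog_alignment(cfg_more, 3)
  expect_identical(sim1$alignment$codons, sim3$alignment$codons)
})

test_that("planted sites with full conservation are dyads in every species", {
  cfg <- generator_config(seed = 53, n_species = 30, codons_per_gene = 60,
                          conservation_prob = 1, plant_mean = 3)
  sim <- simulate_ortholog_alignment(cfg, 1)
  counts <- column_dyad_counts(sim$alignment)
  for (pi in sim$truth$pair_index) {
    expect_identical(counts[[as.character(pi)]]$k, 30L)
  }
})

test_that("unconserved planted sites behave like the codon-usage background", {
  planted <- data.frame(pair_index = 10L, aa1 = "S", aa2 = "V",
                        conservation_prob = 0)
  cfg <- generator_config(seed = 54, n_species = 400, codons_per_gene = 30,
                          gap_prob = 0)
  sim <- simulate_ortholog_alignment(cfg, 1, planted = planted)
  k <- column_dyad_counts(sim$alignment)[["10"]]$k
  # uniform usage: p0 = 1/3; binomial 99.9% envelope around 400/3
  expect_lt(abs(k - 400 / 3), 3.3 * sqrt(400 * (1 / 3) * (2 / 3)))
})

test_that("planted-site validation rejects role-incapable residue pairs", {
  cfg <- generator_config(seed = 55, n_species = 5, codons_per_gene = 20)
  bad_first <- data.frame(pair_index = 1L, aa1 = "M", aa2 = "V",
                          conservation_prob = 1)
  bad_second <- data.frame(pair_index = 1L, aa1 = "S", aa2 = "K",
                           conservation_prob = 1)
  expect_error(simulate_ortholog_alignment(cfg, 1, planted = bad_first),
               "cannot form a dyad")
  expect_error(simulate_ortholog_alignment(cfg, 1, planted = bad_second),
               "cannot form a dyad")
  out_of_range <- data.frame(pair_index = 19L, aa1 = "S", aa2 = "V",
                             conservation_prob = 1)
  expect_error(simulate_ortholog_alignment(cfg, 1, planted = out_of_range),
               "out of range")
})

test_that("gap_prob = 1 without planted sites gives an all-gap alignment", {
  cfg <- generator_config(seed = 56, n_species = 6, codons_per_gene = 15,
                          gap_prob = 1, plant_mean = 0)
  sim <- simulate_ortholog_alignment(cfg, 1)
  expect_true(all(sim$alignment$codons == "---"))
  sc <- scan_alignment(sim$alignment)
  expect_true(all(sc$dyad_count == 0L))
})

test_that("BM trait simulation matches the covariance it claims", {
  cfg <- generator_config(seed = 57, n_species = 6)
  tr <- simulate_tree(cfg)
  V <- brownian_covariance(tr)
  ys <- vapply(1:4000, function(i) simulate_bm_trait(tr, lambda = 1, seed = i),
               numeric(6))
  emp <- stats::cov(t(ys))
  expect_equal(unname(emp), unname(V[rownames(ys), rownames(ys)]),
               tolerance = 0.15)
  # lambda = 0: independent tips, near-zero off-diagonal correlation
  ys0 <- vapply(1:4000, function(i) simulate_bm_trait(tr, lambda = 0, seed = i),
                numeric(6))
  emp0 <- stats::cov(t(ys0))
  offdiag <- emp0[upper.tri(emp0)] / mean(diag(emp0))
  expect_lt(max(abs(offdiag)), 0.1)
  expect_identical(simulate_bm_trait(tr, lambda = 1, seed = 9),
                   simulate_bm_trait(tr, lambda = 1, seed = 9))
})

test_that("methylation simulation honours the per-gene rate at the extremes", {
  sites <- data.frame(gene_id = rep(c("a", "b"), each = 50), chrom = "chr1",
                      pos = seq(10L, by = 10L, length.out = 100L))
  off <- simulate_methylation(sites, rate = 0, seed = 58)
  expect_true(all(off$track$percent < 50))
  expect_identical(sum(off$truth$n_methylated), 0L)
  on <- simulate_methylation(sites, rate = 1, seed = 58)
  expect_identical(sum(on$truth$n_methylated), 100L)
  res <- methylation_site_counts(sites, on$track, symmetric = TRUE)
  expect_identical(res$n_methylated, res$n_sites)  # symmetric at rate 1
  # bedMethyl round trip
  p <- tempfile(fileext = ".bed")
  write_bedmethyl(on$track, p)
  back <- read_bedmethyl(p)
  expect_identical(nrow(back), nrow(on$track))
  expect_equal(back$percent, on$track$percent)
})

test_that("expression staging couples onset to dyad density by strength", {
  dens <- setNames(rexp(200), paste0("g", 1:200))
  flat <- simulate_expression_stages(dens, stage_count = 9, strength = 0, seed = 59)
  res_flat <- stage_density_trend(flat, dens)
  expect_gt(res_flat$p_value, 0.05)
  ramp <- simulate_expression_stages(dens, stage_count = 9, strength = 1, seed = 59)
  res_ramp <- stage_density_trend(ramp, dens)
  expect_lt(res_ramp$p_value, 0.01)
  expect_gt(res_ramp$slope, 0)
  expect_identical(unname(res_ramp$df), c(1, 7))
})

test_that("cohorts are written to disk and read back identically", {
  cfg <- generator_config(seed = 60, n_species = 8, n_genes = 4,
                          codons_per_gene = 30)
  d <- tempfile("cohort")
  co <- simulate_cohort(cfg, d)
  expect_length(co$alignments, 4L)
  files <- list.files(file.path(d, "alignments"), full.names = TRUE)
  expect_length(files, 4L)
  back <- read_codon_alignment(files[1])
  expect_identical(back$codons, co$alignments[[1]]$codons)
  tr <- read_tree(file.path(d, "tree.nwk"))
  expect_identical(sort(tr$tip.label), sort(co$tree$tip.label))
  truth <- read_table_tsv(file.path(d, "truth.tsv"))
  expect_identical(nrow(truth), nrow(co$truth))
})
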