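#' Spearman rank correlation between two per-gene metrics
#'
#' Mid-rank ties, large-sample p-value. Used e.g. to relate per-gene dyad
#' density to single-codon (internal) CpG density.
#'
#' @param x,y Paired numeric vectors (>= 3 genes).
#' @return List with `rho`, `p_value`, `n`.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 paired genes", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Wilcoxon signed-rank test for paired per-gene counts
#'
#' Compares matched counts between two groups (e.g. a mammalian average vs
#' the Drosophila ortholog, gene by gene). Differences `a - b` of zero are
#' dropped; V is the sum of the ranks of the positive differences, so V = 0
#' when every retained pair has `a < b`. The p-value is the exact two-sided
#' signed-rank probability for n <= 25 retained pairs and the normal
#' approximation above that.
#'
#' @param a,b Paired numeric vectors of equal length >= 5.
#' @return List with `V`, `p_value`, `n_effective` (pairs after dropping
#'   zero differences).
#' @export
paired_sign_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5L)
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero", call. = FALSE)
  n <- length(d)
  wt <- suppressWarnings(stats::wilcox.test(d, exact = n <= 25L, correct = TRUE))
  list(V = unname(wt$statistic), p_value = wt$p.value, n_effective = n)
}

#' Regress a per-gene conservation score on dyad density
#'
#' Ordinary least squares of a per-gene score (e.g. a precomputed
#' conservation/acceleration score) on dyads per kilobase; reports the
#' slope, its t-test p-value, and r-squared. In genome-scale data a
#' significant slope with a tiny r-squared is the typical outcome: dyad
#' abundance tracks general gene conservation only weakly.
#'
#' @param dyads_per_kb Per-gene dyad density (>= 10 genes).
#' @param score Per-gene score, same length.
#' @return List with `slope`, `p_value`, `r_squared`, `n`.
#' @export
score_regression <- function(dyads_per_kb, score) {
  stopifnot(length(dyads_per_kb) == length(score))
  keep <- stats::complete.cases(dyads_per_kb, score)
  x <- dyads_per_kb[keep]; y <- score[keep]
  if (length(x) < 10L) stop("need >= 10 genes", call. = FALSE)
  if (stats::var(x) == 0) stop("zero-variance predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       p_value = sm$coefficients[2, 4],
       r_squared = sm$r.squared, n = length(x))
}

#' Count methylated CpG sites per gene from a bedMethyl track
#'
#' A CpG site is keyed by the genomic position of its C on the + strand. A
#' site counts as methylated when a track record overlaps that C with
#' `percent >= percent_cutoff` and `coverage >= min_coverage`. In symmetric
#' mode both strands must pass: the + strand record at the site position
#' and the - strand record one base downstream (the paired C on the
#' opposite strand).
#'
#' @param sites Data.frame of per-gene CpG sites with columns `gene_id`,
#'   `chrom`, `pos` (0-based position of the + strand C).
#' @param track A [read_bedmethyl()] track.
#' @param percent_cutoff Methylation percent threshold (default 50).
#' @param min_coverage Minimum read coverage per record (default 5).
#' @param symmetric Require both strands to pass.
#' @return Data.frame: `gene_id`, `n_sites`, `n_methylated`.
#' @export
methylation_site_counts <- function(sites, track, percent_cutoff = 50,
                                    min_coverage = 5, symmetric = FALSE) {
  stopifnot(is.data.frame(sites), all(c("gene_id", "chrom", "pos") %in% names(sites)))
  if (nrow(sites) && !any(sites$chrom %in% track$chrom)) {
    stop("coordinate mismatch: no site chromosome present in the track", call. = FALSE)
  }
  pass <- track[track$percent >= percent_cutoff & track$coverage >= min_coverage, ]
  plus <- paste(pass$chrom[pass$strand != "-"], pass$start[pass$strand != "-"])
  minus <- paste(pass$chrom[pass$strand == "-"], pass$start[pass$strand == "-"])
  key_plus <- paste(sites$chrom, sites$pos)
  key_minus <- paste(sites$chrom, sites$pos + 1L)
  meth <- if (symmetric) {
    key_plus %in% plus & key_minus %in% minus
  } else {
    key_plus %in% plus | key_minus %in% minus
  }
  agg <- stats::aggregate(meth, by = list(gene_id = sites$gene_id),
                          FUN = function(v) c(length(v), sum(v)))
  data.frame(gene_id = agg$gene_id,
             n_sites = as.integer(agg$x[, 1]),
             n_methylated = as.integer(agg$x[, 2]),
             stringsAsFactors = FALSE)
}

#' Trend of conserved-dyad density across developmental stages
#'
#' For each ordered stage, takes the genes expressed above the RPKM
#' threshold, computes the median conserved-dyad density among them, and
#' regresses the stage medians on stage rank (1..S) by ordinary least
#' squares. The F test has 1 and S - 2 degrees of freedom, so nine stages
#' give F(1, 7).
#'
#' @param expression Numeric matrix or data.frame of RPKM, genes x stages,
#'   rownames = gene ids, columns in stage order.
#' @param dyadC_density Named numeric vector of per-gene conserved-dyad
#'   densities (names = gene ids).
#' @param rpkm_threshold Expression gate; a gene counts as expressed at a
#'   stage when RPKM exceeds this (default 1).
#' @return List with `medians` (per-stage), `n_expressed` (per-stage),
#'   `slope`, `F`, `df`, `p_value`, `r_squared`.
#' @export
stage_density_trend <- function(expression, dyadC_density, rpkm_threshold = 1) {
  expression <- as.matrix(expression)
  stopifnot(ncol(expression) >= 3L)
  if (is.null(rownames(expression)) || is.null(names(dyadC_density))) {
    stop("expression rows and dyadC_density must be named by gene id", call. = FALSE)
  }
  common <- intersect(rownames(expression), names(dyadC_density))
  if (!length(common)) stop("no shared gene ids", call. = FALSE)
  expression <- expression[common, , drop = FALSE]
  dens <- dyadC_density[common]
  medians <- numeric(ncol(expression))
  n_expr <- integer(ncol(expression))
  for (s in seq_len(ncol(expression))) {
    on <- expression[, s] > rpkm_threshold
    if (!any(on)) stop("stage ", s, " has no expressed genes", call. = FALSE)
    medians[s] <- stats::median(dens[on])
    n_expr[s] <- sum(on)
  }
  stage <- seq_along(medians)
  fit <- stats::lm(medians ~ stage)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(medians = medians, n_expressed = n_expr,
       slope = unname(stats::coef(fit)[2]),
       F = unname(fstat[1]), df = unname(fstat[2:3]),
       p_value = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE) |> unname(),
       r_squared = sm$r.squared)
}
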