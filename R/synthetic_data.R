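#' Configuration for the synthetic ortholog-cohort generator
#'
#' Bundles and validates every knob of the generator. All randomness is a
#' pure function of `seed`: each gene and track draws from its own
#' deterministic substream, so adding genes never shifts existing outputs.
#'
#' The defaults emulate a mammalian ortholog cohort at desk scale: 261
#' species (the species count of the ortholog dataset the analysis is
#' designed for), CDS of 500 codons (1.5 kb, a typical human CDS), planted
#' conserved dyad sites carried by 90% of species, whole-codon gaps at 2%,
#' and dyad placement decaying exponentially towards the 3' end so that
#' most sites fall in the first quarter of the gene.
#'
#' @param seed Integer seed (mandatory; there is no implicit entropy).
#' @param n_species Number of species per alignment.
#' @param n_genes Number of genes in the cohort.
#' @param codons_per_gene Codons per gene.
#' @param codon_usage A [codon_usage()] table for background codon draws,
#'   or `NULL` for uniform within-family usage.
#' @param plant_mean Mean number of planted dyad sites per gene (Poisson).
#' @param conservation_prob Probability that a species carries the dyad at
#'   a planted site; with probability `1 - conservation_prob` the species
#'   draws its codons from the background usage instead, so a planted site
#'   with `conservation_prob = 0` behaves exactly like background.
#' @param positional_law `"exponential"` (5'-biased placement) or
#'   `"uniform"`.
#' @param positional_rate Decay rate of the exponential placement law on
#'   the relative CDS position scale.
#' @param gap_prob Per-cell probability of a whole-codon gap (planted site
#'   columns are never gapped).
#' @param tree_depth Root-to-tip depth of the simulated pure-birth tree.
#' @param trait_lambda Lambda used when simulating traits on the tree.
#' @param stage_count Number of developmental stages for expression tables.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_species = 261L,
                             n_genes = 50L,
                             codons_per_gene = 500L,
                             codon_usage = NULL,
                             plant_mean = 1.5,
                             conservation_prob = 0.9,
                             positional_law = c("exponential", "uniform"),
                             positional_rate = 5,
                             gap_prob = 0.02,
                             tree_depth = 1,
                             trait_lambda = 1,
                             stage_count = 9L) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  positional_law <- match.arg(positional_law)
  stopifnot(n_species >= 2, n_genes >= 1, codons_per_gene >= 10,
            plant_mean >= 0, conservation_prob >= 0, conservation_prob <= 1,
            gap_prob >= 0, gap_prob <= 1, tree_depth > 0,
            trait_lambda >= 0, trait_lambda <= 1, stage_count >= 2)
  structure(
    list(seed = as.integer(seed), n_species = as.integer(n_species),
         n_genes = as.integer(n_genes),
         codons_per_gene = as.integer(codons_per_gene),
         codon_usage = codon_usage, plant_mean = plant_mean,
         conservation_prob = conservation_prob,
         positional_law = positional_law, positional_rate = positional_rate,
         gap_prob = gap_prob, tree_depth = tree_depth,
         trait_lambda = trait_lambda, stage_count = as.integer(stage_count)),
    class = "generator_config"
  )
}

# deterministic substream seed below 2^31, derived from (seed, a, b)
.substream_seed <- function(seed, a = 0L, b = 0L) {
  as.integer((as.double(seed %% 2147483647L) * 69069 +
                as.double(a) * 7919 + as.double(b) * 104729) %% 2147483647)
}

#' Simulate an ultrametric pure-birth tree
#'
#' @param config A [generator_config()]; `n_species` tips labelled
#'   `sp001, sp002, ...`, rescaled to `tree_depth` root-to-tip.
#' @return An ape `phylo` tree.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(.substream_seed(config$seed, 1L))
  tr <- ape::rphylo(config$n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * config$tree_depth / depth
  tr$tip.label <- sprintf("sp%03d", seq_len(config$n_species))
  tr
}

# usage-weighted codon sampler within one amino-acid family, optionally
# restricted to role-capable codons
.sample_family_codons <- function(aa, n, usage, restrict = NULL) {
  ct <- .std_code()
  fam <- names(ct$codon_to_aa)[ct$codon_to_aa == aa]
  if (!is.null(restrict)) fam <- intersect(fam, restrict)
  if (!length(fam)) stop("no codon available for ", aa, " under restriction", call. = FALSE)
  if (length(fam) == 1L) return(rep(fam, n))
  p <- if (is.null(usage)) rep(1, length(fam)) else as.numeric(usage[fam])
  if (sum(p) <= 0) p <- rep(1, length(fam))
  sample(fam, n, replace = TRUE, prob = p)
}

#' Simulate one ortholog codon alignment with planted dyad sites
#'
#' The gene's amino-acid sequence is drawn uniformly over the 20 residues;
#' planted sites overwrite the residue pair at their codon-pair position.
#' Each species then draws synonymous codons from the configured usage. At
#' a planted site, a species carries the dyad with `conservation_prob` (its
#' first codon is forced to an ends-C synonym, its second to a starts-G
#' synonym); otherwise it draws from the background usage, so unplanted
#' behaviour is recovered continuously as `conservation_prob` drops to 0.
#' Whole-codon gaps are inserted per cell with `gap_prob`, never at planted
#' columns. Planted residue pairs require a first residue with at least one
#' C-ending codon and a second residue from a G-starting family.
#'
#' @param config A [generator_config()].
#' @param gene_index Gene number (1-based); also the substream selector.
#' @param planted Optional data.frame overriding the gene's planted sites:
#'   columns `pair_index` (0-based), `aa1`, `aa2`, `conservation_prob`.
#'   `NULL` draws the number of sites from Poisson(`plant_mean`), positions
#'   from the configured positional law, `aa1` from the C-ending-capable
#'   residues and `aa2` from the G-starting families.
#' @return List with `alignment` (a [codon_alignment()]) and `truth` (the
#'   planted-site data.frame, possibly 0-row).
#' @export
simulate_ortholog_alignment <- function(config, gene_index, planted = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(.substream_seed(config$seed, 2L, gene_index))
  ct <- .std_code()
  usage <- config$codon_usage
  n_codons <- config$codons_per_gene
  n_sp <- config$n_species
  aas <- setdiff(unique(ct$codon_to_aa), "*")
  g_families <- c("V", "A", "D", "E", "G")
  endc_capable <- aas[vapply(aas, function(a) role_fraction(a, "first") > 0, logical(1))]

  if (is.null(planted)) {
    n_plant <- stats::rpois(1, config$plant_mean)
    max_pairs <- n_codons - 1L
    n_plant <- min(n_plant, max_pairs)
    if (n_plant > 0) {
      rel <- if (config$positional_law == "exponential") {
        # truncated exponential on [0,1): inverse-CDF draw
        u <- stats::runif(n_plant)
        r <- config$positional_rate
        -log(1 - u * (1 - exp(-r))) / r
      } else {
        stats::runif(n_plant)
      }
      idx <- unique(pmin(floor(rel * max_pairs), max_pairs - 1L))
      # dyad pairs must not share a codon; drop adjacent duplicates
      idx <- sort(idx)
      idx <- idx[c(TRUE, diff(idx) > 1L)]
      planted <- data.frame(
        pair_index = as.integer(idx),
        aa1 = sample(endc_capable, length(idx), replace = TRUE),
        aa2 = sample(g_families, length(idx), replace = TRUE),
        conservation_prob = config$conservation_prob,
        stringsAsFactors = FALSE
      )
    } else {
      planted <- data.frame(pair_index = integer(0), aa1 = character(0),
                            aa2 = character(0), conservation_prob = numeric(0),
                            stringsAsFactors = FALSE)
    }
  } else {
    stopifnot(all(c("pair_index", "aa1", "aa2", "conservation_prob") %in% names(planted)))
    bad1 <- !planted$aa1 %in% endc_capable
    bad2 <- !planted$aa2 %in% g_families
    if (any(bad1 | bad2)) {
      stop("planted residue pair cannot form a dyad: first residue needs a ",
           "C-ending codon and the second a G-starting family", call. = FALSE)
    }
    if (any(planted$pair_index < 0 | planted$pair_index > n_codons - 2L)) {
      stop("planted pair_index out of range", call. = FALSE)
    }
  }

  aa_seq <- sample(aas, n_codons, replace = TRUE)
  for (i in seq_len(nrow(planted))) {
    aa_seq[planted$pair_index[i] + 1L] <- planted$aa1[i]
    aa_seq[planted$pair_index[i] + 2L] <- planted$aa2[i]
  }

  codons <- matrix("", nrow = n_sp, ncol = n_codons)
  for (j in seq_len(n_codons)) {
    codons[, j] <- .sample_family_codons(aa_seq[j], n_sp, usage)
  }
  for (i in seq_len(nrow(planted))) {
    j <- planted$pair_index[i] + 1L
    carry <- stats::runif(n_sp) < planted$conservation_prob[i]
    if (any(carry)) {
      codons[carry, j] <- .sample_family_codons(planted$aa1[i], sum(carry),
                                                usage, restrict = ct$ends_c)
      codons[carry, j + 1L] <- .sample_family_codons(planted$aa2[i], sum(carry),
                                                     usage, restrict = ct$starts_g)
    }
  }

  if (config$gap_prob > 0) {
    protected <- unique(c(planted$pair_index + 1L, planted$pair_index + 2L))
    gap <- matrix(stats::runif(n_sp * n_codons) < config$gap_prob,
                  nrow = n_sp, ncol = n_codons)
    if (length(protected)) gap[, protected] <- FALSE
    codons[gap] <- "---"
  }

  aln <- codon_alignment(codons, gene_id = sprintf("gene%04d", gene_index),
                         species_ids = sprintf("sp%03d", seq_len(n_sp)))
  list(alignment = aln, truth = planted)
}

#' Simulate a trait by lambda-transformed Brownian motion on a tree
#'
#' Draws one multivariate-normal trait with covariance equal to the tree's
#' Brownian matrix with off-diagonal entries scaled by `lambda`: `lambda =
#' 1` is pure Brownian motion, `lambda = 0` independent tips.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param lambda Pagel transform in `[0, 1]`.
#' @param seed Integer seed.
#' @param sigma2 Brownian rate (trait variance scale).
#' @param mean Trait mean at the root.
#' @return Named numeric vector over the tree's tips.
#' @export
simulate_bm_trait <- function(tree, lambda = 1, seed, sigma2 = 1, mean = 0) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  V <- .lambda_transform(brownian_covariance(tree), lambda) * sigma2
  set.seed(.substream_seed(seed, 3L))
  z <- stats::rnorm(nrow(V))
  y <- drop(t(chol(V)) %*% z) + mean
  stats::setNames(y, tree$tip.label)
}

#' Simulate a bedMethyl track over per-gene CpG sites
#'
#' Each site's methylation percent is drawn from a two-component mixture:
#' with the gene's methylation rate, a methylated component around 90%
#' (clamped to 60-100); otherwise an unmethylated component around 5%
#' (clamped to 0-40). Records are emitted for both strands (the + strand C
#' at the site position, the - strand C one base downstream), symmetric in
#' their component.
#'
#' @param sites Data.frame with `gene_id`, `chrom`, `pos` (0-based + strand
#'   C position).
#' @param rate Scalar methylation rate, or named vector per gene id.
#' @param seed Integer seed.
#' @param coverage_mean Mean read coverage (Poisson, shifted so coverage is
#'   at least 5).
#' @return List with `track` (a `methylation_track` data.frame) and `truth`
#'   (per-gene data.frame of `n_sites` and `n_methylated`).
#' @export
simulate_methylation <- function(sites, rate, seed, coverage_mean = 30) {
  stopifnot(is.data.frame(sites), all(c("gene_id", "chrom", "pos") %in% names(sites)))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(.substream_seed(seed, 4L))
  n <- nrow(sites)
  r <- if (is.null(names(rate))) rep(rate, n) else as.numeric(rate[sites$gene_id])
  meth <- stats::runif(n) < r
  pct <- ifelse(meth,
                pmin(pmax(stats::rnorm(n, 90, 5), 60), 100),
                pmin(pmax(stats::rnorm(n, 5, 3), 0), 40))
  cov_plus <- stats::rpois(n, coverage_mean - 5) + 5L
  cov_minus <- stats::rpois(n, coverage_mean - 5) + 5L
  track <- data.frame(
    chrom = rep(sites$chrom, 2L),
    start = c(sites$pos, sites$pos + 1L),
    end = c(sites$pos + 1L, sites$pos + 2L),
    strand = rep(c("+", "-"), each = n),
    coverage = c(cov_plus, cov_minus),
    percent = rep(round(pct, 1), 2L),
    stringsAsFactors = FALSE
  )
  ord <- order(track$chrom, track$start, track$strand)
  track <- track[ord, ]
  rownames(track) <- NULL
  attr(track, "sample_id") <- "synthetic"
  class(track) <- c("methylation_track", "data.frame")
  truth <- stats::aggregate(meth, by = list(gene_id = sites$gene_id),
                            FUN = function(v) c(length(v), sum(v)))
  list(track = track,
       truth = data.frame(gene_id = truth$gene_id,
                          n_sites = as.integer(truth$x[, 1]),
                          n_methylated = as.integer(truth$x[, 2]),
                          stringsAsFactors = FALSE))
}

#' Write a methylation track as a bedMethyl file
#'
#' Emits the 11-column bedMethyl dialect read back by [read_bedmethyl()].
#'
#' @param track A `methylation_track` data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(track, path) {
  stopifnot(inherits(track, "methylation_track"))
  out <- data.frame(
    chrom = track$chrom, start = track$start, end = track$end,
    name = ".", score = pmin(as.integer(track$coverage), 1000L),
    strand = track$strand, thickStart = track$start, thickEnd = track$end,
    rgb = "0,0,0", coverage = as.integer(track$coverage),
    percent = track$percent, stringsAsFactors = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Simulate staged expression gating dyad-rich genes on later
#'
#' Genes switch on at an onset stage that increases with their
#' conserved-dyad density percentile times `strength`: at `strength = 0`
#' every gene is on from stage 1 (flat null); at `strength = 1` the
#' densest genes appear only at the last stage, so the median density of
#' expressed genes rises across stages. Expressed gene-stage cells draw
#' RPKM above the conventional 1-RPKM gate, silent cells below it.
#'
#' @param dyadC_density Named per-gene conserved-dyad densities.
#' @param stage_count Number of ordered stages.
#' @param strength Coupling in `[0, 1]` between density rank and onset.
#' @param seed Integer seed.
#' @return Numeric matrix genes x stages of RPKM values (rownames = gene
#'   ids, colnames `stage1..stageS`), with the onset vector as attribute
#'   `"onset"`.
#' @export
simulate_expression_stages <- function(dyadC_density, stage_count = 9L,
                                       strength = 1, seed) {
  stopifnot(stage_count >= 2, strength >= 0, strength <= 1)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(names(dyadC_density))) stop("densities must be named by gene", call. = FALSE)
  set.seed(.substream_seed(seed, 5L))
  n <- length(dyadC_density)
  pct <- (rank(dyadC_density, ties.method = "average") - 1) / max(n - 1, 1)
  onset <- 1L + as.integer(round(pct * (stage_count - 1L) * strength))
  rpkm <- matrix(0, nrow = n, ncol = stage_count,
                 dimnames = list(names(dyadC_density),
                                 paste0("stage", seq_len(stage_count))))
  for (s in seq_len(stage_count)) {
    on <- onset <= s & stats::runif(n) < 0.95
    rpkm[, s] <- ifelse(on, stats::runif(n, 2, 20), stats::runif(n, 0, 0.5))
  }
  attr(rpkm, "onset") <- onset
  rpkm
}

#' Generate a full synthetic cohort on disk
#'
#' Writes one aligned FASTA per gene, the species tree as Newick, and a
#' `truth.tsv` of planted sites, then returns the in-memory objects. This
#' is the stand-in for a real ortholog dataset: every downstream pipeline
#' stage can run from the written directory alone.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created); `NULL` keeps everything in
#'   memory.
#' @return List with `alignments` (list of [codon_alignment()]), `truth`
#'   (row-bound planted-site table with `gene_id`), `tree`, `config`, and
#'   `dir`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  tree <- simulate_tree(config)
  alignments <- vector("list", config$n_genes)
  truths <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    sim <- simulate_ortholog_alignment(config, g)
    alignments[[g]] <- sim$alignment
    tr <- sim$truth
    if (nrow(tr)) tr$gene_id <- sim$alignment$gene_id
    truths[[g]] <- tr
  }
  names(alignments) <- vapply(alignments, `[[`, character(1), "gene_id")
  truth <- do.call(rbind, truths[vapply(truths, nrow, integer(1)) > 0])
  if (is.null(truth)) {
    truth <- data.frame(pair_index = integer(0), aa1 = character(0),
                        aa2 = character(0), conservation_prob = numeric(0),
                        gene_id = character(0), stringsAsFactors = FALSE)
  }
  if (!is.null(dir)) {
    dir.create(file.path(dir, "alignments"), recursive = TRUE, showWarnings = FALSE)
    for (aln in alignments) {
      write_codon_alignment(aln, file.path(dir, "alignments",
                                           paste0(aln$gene_id, ".fasta")))
    }
    ape::write.tree(tree, file.path(dir, "tree.nwk"))
    write_table(truth, file.path(dir, "truth.tsv"))
  }
  list(alignments = alignments, truth = truth, tree = tree,
       config = config, dir = dir)
}
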