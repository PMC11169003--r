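---
title: "Detecting and testing conserved CpG codon dyads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and testing conserved CpG codon dyads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadscan)
```

## The biological question

In vertebrates, DNA methylation acts almost exclusively on CpG
dinucleotides, and methylated cytosines deaminate to thymine at an elevated
rate, depleting CpGs genome-wide. Inside protein-coding sequence a CpG can
sit entirely within one codon, or it can span the junction of two adjacent
codons — the first ending in C, the second starting with G (NNC|GNN). We
call the latter a *CpG codon dyad*. Because most amino acids have
synonymous codons that avoid the junction CpG, a dyad maintained across
hundreds of orthologous species despite the mutational pressure against it
is a candidate target of selection acting on methylation itself rather
than on the protein.

`dyadscan` implements the full analysis around that idea: dyad detection
and density scoring, cross-species conservation calling, a codon-usage
null model with a site-level proportion test, positional distributions
along the CDS, phylogenetic-signal tests of per-species dyad totals, a
gene-body methylation overlay, and a developmental expression trend test.
A seeded synthetic-data generator produces all inputs with known ground
truth, which is what the test suite and the acceptance script exercise.

## The genetic-code backbone

Of the 64 codons, 16 end with C, 16 start with G, and 4 (GAC, GCC, GGC,
GTC) can fill either dyad role, leaving 12 exclusively C-ending and 12
exclusively G-starting codons:

```{r code-partition}
ct <- codon_table()
c(ends_c_only = length(setdiff(ct$ends_c, ct$dual)),
  starts_g_only = length(setdiff(ct$starts_g, ct$dual)),
  dual = length(ct$dual))
```

A useful structural fact drives the null model: every synonymous family
either consists entirely of G-starting codons (valine, alanine, aspartate,
glutamate, glycine) or contains none, so the second-role probability is
always exactly 0 or 1 and a site's null probability is governed by the
first codon's ends-C usage.

## Scanning and densities

`scan_dyads()` reports 0-based junction indices on an ungapped, in-frame
CDS; `scan_internal_cpg()` counts CpGs lying within one codon. The two
partition all in-frame CpGs, which the tests verify against a frame-
agnostic oracle. Densities are dyads per 1000 nucleotides of ungapped CDS
(`dyad_density()`); conserved-site densities use the species-independent
*consensus size*, the number of alignment codon columns times 3 nt
(`consensus_dyad_density()`). The per-nucleotide denominator follows the
convention of reporting dyads per kilobase; a per-codon scale would simply
multiply every density by 3.

## Conservation calling

`column_dyad_counts()` counts, at every adjacent pair of codon columns,
the species whose two codons form a dyad. The denominator `n` is all
sequences in the alignment — a species gapped at the column still counts,
because the conservation rule is phrased as "k of all species". A column
is conserved (`call_conserved()`) when `k/n >= threshold`, boundary
inclusive; the default threshold is the fraction 200/261 (76%), so
alignments with other species counts scale consistently rather than using
an absolute cutoff. The residue composition of each column is tallied from
each species' own translated codons, not a consensus translation, so
mixed-residue sites (e.g. a serine-valine column with one
asparagine-valine species) keep their composition for the null model.

## The codon-usage null and the site test

Under no selection on the CpG, a species shows a dyad at a site with
probability `p0 = sum_w P(first codon ends C) * P(second codon starts G)`,
mixed over the observed residue pairs with weights `w` proportional to
their species counts (`site_null_proportion()`; `majority_only = TRUE`
reduces to the dominant pair). Usage comes from `estimate_codon_usage()`
on a CDS corpus — by default the reference rows of the cohort. Uniform
usage gives the closed forms the tests pin down: a serine-valine site has
`p0 = 2/6 * 1 = 1/3`.

`proportion_ztest()` then compares the observed k of n species against
p0: `z = (k/n - p0) / sqrt(p0(1-p0)/n)`, one-sided upper tail, since the
hypothesis is a conservation *excess*. The expected count `p0*n` is
reported unrounded and rounded (the printed-style arithmetic: with
`p0 = 0.212` and `n = 261`, expectation 55 and an excess of 164 over an
observed 219). When `p0` is 0 or 1 the statistic is degenerate and an
exact binomial tail is substituted. `site_excess_scan()` applies this per
conserved site and appends Benjamini–Hochberg q-values — genome-scale
scans need FDR control even though single-site reports traditionally
print raw p. Two caveats are inherited from the test's design and
documented rather than corrected: species are treated as independent
trials although they are phylogenetically correlated, and the normal tail
differs from the exact binomial near the null centre by the probability
atom at k (the tests bound the disagreement at 0.05 only in the regime
where the z-test is conventionally applicable, `n*p0 >= 5` and
`n*(1-p0) >= 5`, and where excess calls are made).

## Positional distributions

`relative_positions()` maps pair index i in an n-codon gene to
`i/(n-1)`, locating the junction rather than the codon;
`bin_frequencies()` pools these into B half-open bins (default 20, the
last bin closed). `group_contrast()` compares two gene groups with a
two-sample Kolmogorov–Smirnov statistic on the raw positions. Binning
conserves counts exactly, which the property tests assert.

## Phylogenetic signal

Per-species total dyad counts are tested on the species tree with two
statistics implemented from their definitions:

* **Pagel's lambda** (`pagel_lambda()`): the trait is multivariate normal
  with Brownian covariance whose off-diagonal entries are scaled by
  lambda; mean and scale are profiled analytically, and lambda is
  maximised on [0, 1] by bounded 1-D search (tolerance 1e-6), with
  boundary candidates checked explicitly. The p-value is a
  likelihood-ratio test against lambda = 0 on chi-squared(1); a 50:50
  boundary-mixture option exists but is not the default, matching common
  practice.
* **Blomberg's K** (`blomberg_k()`): the observed ratio of raw to
  phylogenetically corrected trait variance about the GLS mean, divided
  by its Brownian expectation `(tr(V) - n/sum(V^-1))/(n-1)`; significance
  by tip permutation with add-one smoothing, seed required.

Both are checked against an independent reference implementation
(`phytools::phylosig`) in the test suite — agreement to at least 6
decimals on the log-likelihood and 8 on K — and calibrated by simulation:
lambda recovered within ±0.15 of 0.5 at 256 tips (mean of replicates) and
K averaging 1 under pure Brownian motion. Traits are analysed raw; both
statistics are affine-invariant, so only genuinely non-linear transforms
(e.g. log) change results, and that choice is left to the caller.

## Methylation overlay and developmental trend

`read_bedmethyl()` parses the 11-column bedMethyl dialect with BED
0-based half-open coordinates. A CpG site is keyed by its + strand C; the
paired − strand record sits one base downstream.
`methylation_site_counts()` calls a site methylated at
`percent >= 50` and `coverage >= 5` by default — conventional WGBS
cutoffs, both exposed as arguments since no single standard exists — with
a symmetric mode requiring both strands to pass.

`stage_density_trend()` computes, per ordered developmental stage, the
median conserved-dyad density among genes expressed above 1 RPKM, and
regresses the stage medians on stage rank 1..S. Stage rank is the
predictor because the stages carry no numeric timescale; with nine stages
the F test has (1, 7) degrees of freedom.

## The synthetic-data generator

`generator_config()` fixes the study conditions; every output is a pure
function of the seed, with per-gene counter-based substreams so enlarging
a cohort never changes existing genes. Defaults: 261 species (the species
count the conservation rule is phrased against), 500-codon CDS (a typical
1.5 kb human coding sequence), planted sites carried by 90% of species,
2% whole-codon gaps, and exponential 5'-biased placement (rate 5 on the
relative-position scale, putting roughly 70% of sites in the first
quarter). Cohort size defaults to 50 genes: large enough for stable
fractions, small enough that a full pipeline run takes seconds.

Two generator semantics matter for interpretation:

* At a planted site a species carries a *forced* dyad with probability
  `conservation_prob`, and otherwise draws from the background codon
  usage. So `conservation_prob = 1` yields exact recovery by the
  conservation caller, and `conservation_prob = 0` reduces the site to
  background, where the column's dyad count is binomial with the
  usage-derived p0 — the consistency the tests check.
* Gaps are whole codons and never land on planted columns, keeping the
  recovery identity exact under gapping.

What the generator does *not* emulate: substitution along branches (no
codon model — conservation is i.i.d. per species, mirroring the
assumption of the proportion test itself), indel evolution, selection on
the protein, or base-composition heterogeneity along the gene. Passing
recovery tests therefore demonstrates correctness of the machinery under
the model's own assumptions, not robustness to phylogenetic correlation
in real ortholog data.

## Orchestration

`run_config()` + `run_pipeline()` run scan, conserve, nulltest,
distribution and signal in order over a directory of per-gene aligned
FASTA (gene id = file stem) plus a Newick tree, writing one TSV per stage
and a manifest of MD5 content hashes; reruns of the same inputs and
settings are byte-identical. `summarize_run()` renders the run as a short
deterministic report (gene counts, dyadC totals, fraction of genes with
at least one conserved site, top excess sites).

## Numerical and design choices

* Partially gapped codons ("TC-") are normalised to the gap codon with a
  warning rather than an error: they occur at alignment boundaries and
  must not abort a cohort-scale run.
* Codons containing N or gaps are role-incapable, never errors, so
  scanning is total on real alignment content.
* Internal stop codons warn but scan: alignment slices may truncate a CDS.
* TSV output fixes doubles at 6 significant digits for deterministic
  round-trips.
* The lambda optimiser's boundary check guards against `optimize()`
  missing an optimum at 0 or 1 by its interval tolerance.
* Problem sizes used by the tests and the acceptance script — cohorts of
  tens of genes, 10–400 species, trees of 128–256 tips, 10,000-replicate
  type-I calibration — are the package's chosen desk-scale study
  conditions; genome-scale figures (thousands of genes across 261
  species) are obtained by pointing `run_pipeline()` at a real ortholog
  directory.

## Known limitations

* The proportion test treats species as independent; a phylogenetically
  corrected null is out of scope and p-values on real ortholog data are
  anti-conservative to an unknown degree.
* Only the standard genetic code is supported; selenocysteine readthrough
  and mitochondrial codes are not.
* Orthology inference, alignment construction and bisulfite read
  processing are upstream of this package: it consumes codon-aware
  alignments and site-level methylation calls as given.
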