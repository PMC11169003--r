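# dyadscan

Detection and evolutionary analysis of **CpG codon dyads** — CpG
dinucleotides that span two adjacent codons (NNC|GNN) in protein-coding
sequence — for molecular evolution and epigenomics researchers working
with codon-aware ortholog alignments.

## Why dyads

DNA methylation in vertebrates targets CpG dinucleotides, and methylated
cytosines deaminate to thymine, depleting CpGs over evolutionary time. A
CpG at a codon junction is special: the genetic code almost always offers
synonymous codons without it (16 codons end in C, 16 start with G, 4 can
do both), so a junction CpG kept by the vast majority of orthologous
species is a candidate target of selection on methylation itself. The
package finds these sites and quantifies the evidence:

- **Scan**: dyad positions, within-codon CpG counts, and densities per kb
  of ungapped CDS (`scan_dyads`, `scan_internal_cpg`, `dyad_density`).
- **Conserve**: per-column dyad counts across species and conserved-site
  (dyadC) calls at an inclusive k/n ≥ threshold rule, default 200/261
  (76%) (`column_dyad_counts`, `call_conserved`).
- **Null test**: codon-usage null probability p0 per site and a one-sided
  proportion z-test of the conservation excess,
  z = (k/n − p0) / √(p0(1−p0)/n), with BH q-values
  (`estimate_codon_usage`, `site_null_proportion`, `proportion_ztest`,
  `site_excess_scan`).
- **Position**: dyad placement along the relative CDS length, binned
  distributions, and group contrasts by Kolmogorov–Smirnov
  (`relative_positions`, `bin_frequencies`, `group_contrast`).
- **Signal**: Pagel's λ (profiled ML on [0,1], LR test) and Blomberg's K
  (variance ratio vs Brownian expectation, permutation test) on
  per-species dyad totals (`pagel_lambda`, `blomberg_k`).
- **Overlay**: bedMethyl methylation calls per gene-body CpG site with
  percent/coverage/symmetric-strand rules (`read_bedmethyl`,
  `methylation_site_counts`), Spearman metric correlations, paired
  signed-rank contrasts, conservation-score regression, and a
  developmental stage trend of conserved-dyad density
  (`stage_density_trend`).
- **Simulate**: seeded generators for codon alignments with planted
  conserved sites, pure-birth trees, λ-transformed Brownian traits,
  methylation tracks and staged expression — all with ground truth
  (`generator_config`, `simulate_cohort`, ...).

## Worked example

Simulate a small ortholog cohort with planted conserved dyads, run the
full pipeline, and summarise:

```r
library(dyadscan)

cfg <- generator_config(seed = 42, n_species = 60, n_genes = 12,
                        codons_per_gene = 120, conservation_prob = 0.95,
                        plant_mean = 2)
dir <- tempfile("cohort")
simulate_cohort(cfg, dir)

rc <- run_config(dir, file.path(dir, "run"), threshold = 200/261,
                 n_permutations = 199)
run_pipeline(rc)
summarize_run(file.path(dir, "run"))
#> CpG codon dyad analysis summary
#> genes analysed: 12
#> species per alignment: 60
#> conserved dyad sites (dyadC): 23
#> genes with >= 1 dyadC: 10 of 12 (83.3%)
#> top sites by excess over codon-usage null:
#>   gene0006 pair 0: k=59/60, expected 8.9, excess 50, p=1.21e-74
#>   gene0010 pair 33: k=59/60, expected 12.2, excess 47, p=2.27e-51
#>   gene0004 pair 34: k=59/60, expected 15.2, excess 44, p=6.54e-39
#>   gene0009 pair 36: k=60/60, expected 15.9, excess 44, p=1.71e-38
#>   gene0011 pair 10: k=60/60, expected 15.9, excess 44, p=1.71e-38
```

Ten of twelve genes carry at least one conserved dyad (every planted site
is recovered; two genes drew no planted sites), and each conserved site's
observed species count k is tested against its codon-usage expectation —
here e.g. 59 of 60 species against an expected 8.9, an excess of 50.

The single-site arithmetic on a published-style example — 219 of 261
orthologs carrying a serine–valine dyad whose usage-weighted null is
21.2% of serine codons:

```r
zt <- proportion_ztest(k = 219, n = 261, p0 = 0.212)
#> expected 55.3 -> 55, excess 164, z = 24.8, p = 6.3e-136
```

Under *uniform* codon usage the serine–valine null is exactly 1/3:

```r
site_null_proportion(c("S/V" = 261))
#> [1] 0.3333333
```

## Layout

```
R/                     implementation (genetic code, I/O, scan, conserve,
                       null model, positional, phylo signal, stats,
                       generator, pipeline)
tests/testthat/        unit, property and acceptance suites
scripts/acceptance.R   headline-quantity reproduction
vignettes/             methods vignette (models, assumptions, choices)
```
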