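# shared fixtures and independent oracles, built in code at test time

# random ungapped CDS of n_codons codons (no stop codons unless allowed)
random_cds <- function(n_codons, allow_stop = FALSE) {
  ct <- dyadscan::codon_table()
  pool <- names(ct$codon_to_aa)
  if (!allow_stop) pool <- pool[ct$codon_to_aa != "*"]
  paste0(sample(pool, n_codons, replace = TRUE), collapse = "")
}

# brute-force dyad oracle: test every adjacent codon pair independently
brute_force_dyads <- function(cds) {
  n <- nchar(cds)
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  k <- length(codons)
  if (k < 2) return(integer(0))
  hits <- vapply(seq_len(k - 1), function(i) {
    dyadscan::is_dyad_pair(codons[i], codons[i + 1])
  }, logical(1))
  which(hits) - 1L
}

# count all CG dinucleotides anywhere in a sequence (frame-agnostic oracle)
total_cg <- function(cds) {
  m <- gregexpr("(?=CG)", cds, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

# exact two-sided signed-rank p by exhaustive enumeration of sign vectors
signed_rank_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vnull <- as.numeric(signs %*% r)
  p_low <- mean(vnull <= v)
  p_high <- mean(vnull >= v)
  list(V = v, p = min(1, 2 * min(p_low, p_high)))
}

# write a small aligned FASTA and return its path
write_fasta <- function(seqs, ids = names(seqs), name = "aln.fasta") {
  path <- file.path(tempfile("fx"), name)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

# toy codon alignment from per-species codon strings like "TCC GTG"
toy_alignment <- function(rows, gene_id = "toy") {
  codons <- do.call(rbind, lapply(rows, function(r) strsplit(r, " ", fixed = TRUE)[[1]]))
  dyadscan::codon_alignment(codons, gene_id = gene_id,
                            species_ids = sprintf("sp%02d", seq_along(rows)))
}

# minimal bedMethyl line (11-column dialect)
bedmethyl_line <- function(chrom, start, strand, coverage, percent) {
  paste(chrom, start, start + 1, ".", min(coverage, 1000), strand,
        start, start + 1, "0,0,0", coverage, percent, sep = "\t")
}
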