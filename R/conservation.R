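#' Per-column dyad counts across the species of an alignment
#'
#' For every adjacent pair of codon columns, counts how many species carry
#' a CpG codon dyad at that junction (both codons non-gap, first ends with
#' C, second starts with G). The denominator `n` is the total number of
#' sequences in the alignment: species gapped at the column still count in
#' `n`, matching a conservation rule phrased as "k of all species". The
#' amino-acid dyad composition of each column is tallied from each species'
#' own translated codons (rows with a gap or untranslatable codon at either
#' position are excluded from the composition, not from `n`).
#'
#' @param aln A [codon_alignment()].
#' @return A list with one element per pair column (named by 0-based pair
#'   index), each a list with `k`, `n`, and `aa_dyads` (a table of
#'   `"aa1/aa2"` strings to species counts). Alignments with a single codon
#'   column yield an empty list.
#' @export
column_dyad_counts <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  code <- .std_code()$codon_to_aa
  m <- aln$codons
  n <- nrow(m)
  ncol_pairs <- ncol(m) - 1L
  if (ncol_pairs < 1L) return(structure(list(), names = character(0)))
  out <- vector("list", ncol_pairs)
  for (j in seq_len(ncol_pairs)) {
    c1 <- m[, j]
    c2 <- m[, j + 1L]
    ok <- c1 != "---" & c2 != "---"
    k <- sum(ok & substr(c1, 3L, 3L) == "C" & substr(c2, 1L, 1L) == "G")
    a1 <- code[c1[ok]]
    a2 <- code[c2[ok]]
    translatable <- !is.na(a1) & !is.na(a2) & a1 != "*" & a2 != "*"
    comp <- table(paste(a1[translatable], a2[translatable], sep = "/"))
    out[[j]] <- list(k = as.integer(k), n = as.integer(n), aa_dyads = comp)
  }
  names(out) <- as.character(seq_len(ncol_pairs) - 1L)
  out
}

#' Call conserved CpG codon dyad sites (dyadC)
#'
#' A pair column is called conserved when the fraction of species carrying
#' the dyad reaches the threshold: `k / n >= threshold`, boundary
#' inclusive. The default threshold is 200/261, the fraction form of a
#' "200 or more of 261 species" rule (76% of species), so alignments with
#' other species counts scale consistently.
#'
#' @param counts Output of [column_dyad_counts()].
#' @param gene_id Gene identifier for the result rows.
#' @param threshold Conservation threshold in `(0, 1]`.
#' @return A data.frame of class `conservation_calls`: `gene_id`,
#'   `pair_index` (0-based), `k`, `n`, `frac`, `conserved` (logical),
#'   `aa_dyads` (composition as `"S/V:219;N/V:1"` strings).
#' @export
call_conserved <- function(counts, gene_id = NA_character_, threshold = 200 / 261) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!length(counts)) {
    out <- data.frame(gene_id = character(0), pair_index = integer(0),
                      k = integer(0), n = integer(0), frac = numeric(0),
                      conserved = logical(0), aa_dyads = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("conservation_calls", "data.frame")
    return(out)
  }
  k <- vapply(counts, `[[`, integer(1), "k")
  n <- vapply(counts, `[[`, integer(1), "n")
  comp <- vapply(counts, function(x) {
    tb <- x$aa_dyads
    if (!length(tb)) return("")
    paste(paste0(names(tb), ":", as.integer(tb)), collapse = ";")
  }, character(1))
  out <- data.frame(
    gene_id = gene_id,
    pair_index = as.integer(names(counts)),
    k = k, n = n, frac = k / n,
    conserved = k / n >= threshold,
    aa_dyads = comp,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("conservation_calls", "data.frame")
  out
}

# parse an "S/V:219;N/V:1" composition string back to a named count vector
.parse_aa_dyads <- function(s) {
  if (is.na(s) || !nzchar(s)) return(stats::setNames(integer(0), character(0)))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) as.integer(x[2]), integer(1)),
                  vapply(kv, `[`, character(1), 1L))
}

#' Conserved-dyad density on the consensus scale
#'
#' Density of conserved sites per kilobase of consensus, where the
#' consensus size of a gene is its species-independent alignment length:
#' number of codon columns times 3 nucleotides.
#'
#' @param calls A [call_conserved()] result for one gene.
#' @param n_codon_columns Number of codon columns in the gene's alignment.
#' @return Conserved dyads per 1000 nt of consensus.
#' @export
consensus_dyad_density <- function(calls, n_codon_columns) {
  stopifnot(n_codon_columns >= 1)
  sum(calls$conserved) * 1000 / (3 * n_codon_columns)
}

#' Count genes carrying at least one conserved dyad
#'
#' @param calls_by_gene A list of [call_conserved()] results, one per gene.
#' @return List with `n_genes`, `n_with_dyadC`, `fraction`.
#' @export
genes_with_any_dyadC <- function(calls_by_gene) {
  if (!length(calls_by_gene)) stop("no genes supplied", call. = FALSE)
  hit <- vapply(calls_by_gene, function(x) any(x$conserved), logical(1))
  list(n_genes = length(hit), n_with_dyadC = sum(hit),
       fraction = mean(hit))
}
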