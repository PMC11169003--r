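#' Scan an ungapped CDS for CpG codon dyads
#'
#' Partitions the sequence into in-frame codons and reports every adjacent
#' codon pair whose junction forms a CpG: the first codon ends with C and
#' the next starts with G. Positions are 0-based indices of the pair's
#' first codon. Codons containing `N` never match. Sequences containing an
#' internal stop codon are scanned anyway (alignment slices may truncate a
#' CDS) but raise a warning.
#'
#' @param cds Ungapped nucleotide sequence (character scalar, A/C/G/T/N),
#'   length a multiple of 3 and at least 6.
#' @return Integer vector of 0-based codon-pair indices, strictly
#'   increasing; maximum value is `n_codons - 2`.
#' @examples
#' scan_dyads("TCCGTGAAA")  # 0: TCC|GTG junction
#' scan_dyads("GCCGCCGCC")  # 0, 1: GCC is a dual-role codon
#' @export
scan_dyads <- function(cds) {
  codons <- .cds_codons(cds)
  n <- length(codons)
  if (n < 2L) return(integer(0))
  idx <- which(substr(codons[-n], 3L, 3L) == "C" &
                 substr(codons[-1L], 1L, 1L) == "G")
  as.integer(idx - 1L)
}

# validate and split an ungapped CDS into codons; warns on internal stops
.cds_codons <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("frame error: CDS length ", n, " is not a multiple of 3", call. = FALSE)
  }
  if (n == 0L) return(character(0))
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- .std_code()$codon_to_aa[codons[-length(codons)]]
  if (any(aa == "*", na.rm = TRUE)) {
    warning("internal stop codon(s) in CDS; scanning anyway", call. = FALSE)
  }
  codons
}

#' Count CpG dinucleotides lying entirely within one codon
#'
#' Counts CG at within-codon offsets 1-2 or 2-3. Together with the junction
#' CpGs reported by [scan_dyads()] this partitions all in-frame CpG
#' dinucleotides of a CDS: every CG is either internal to a codon or spans
#' a codon boundary, never both.
#'
#' @inheritParams scan_dyads
#' @return Integer count.
#' @examples
#' scan_internal_cpg("ACGAAA")  # 1 (ACG)
#' scan_internal_cpg("TCCGTG")  # 0 (the CG is the junction dyad)
#' @export
scan_internal_cpg <- function(cds) {
  codons <- .cds_codons(cds)
  sum(substr(codons, 1L, 2L) == "CG") + sum(substr(codons, 2L, 3L) == "CG")
}

#' Dyad density per 1000 nucleotides
#'
#' The per-gene density score: the dyad count normalised by the ungapped
#' CDS length in nucleotides, scaled to dyads per kilobase.
#'
#' @param dyad_count Number of dyads.
#' @param cds_length_nt Ungapped CDS length in nucleotides (> 0).
#' @return `1000 * dyad_count / cds_length_nt`.
#' @export
dyad_density <- function(dyad_count, cds_length_nt) {
  if (any(cds_length_nt <= 0)) stop("cds_length_nt must be positive", call. = FALSE)
  1000 * dyad_count / cds_length_nt
}

#' Full dyad profile of one coding sequence
#'
#' Convenience wrapper combining [scan_dyads()], [scan_internal_cpg()] and
#' [dyad_density()] for a single species' CDS.
#'
#' @inheritParams scan_dyads
#' @param gene_id,species_id Identifiers carried into the result.
#' @return An object of class `dyad_profile`: list with `gene_id`,
#'   `species_id`, `dyad_positions` (0-based pair indices), `dyad_count`,
#'   `internal_cpg_count`, `cds_length_nt`, `density_per_kb`.
#' @export
dyad_profile <- function(cds, gene_id = NA_character_, species_id = NA_character_) {
  pos <- scan_dyads(cds)
  len <- nchar(cds)
  structure(
    list(gene_id = gene_id, species_id = species_id,
         dyad_positions = pos, dyad_count = length(pos),
         internal_cpg_count = scan_internal_cpg(cds),
         cds_length_nt = len,
         density_per_kb = dyad_density(length(pos), len)),
    class = "dyad_profile"
  )
}

#' Scan every ungapped row of a codon alignment
#'
#' Degaps each species' row of the alignment and profiles it. Used for
#' per-species dyad totals (phylogenetic-signal input) and per-gene
#' densities.
#'
#' @param aln A [codon_alignment()].
#' @return A data.frame with one row per species: `gene_id`, `species_id`,
#'   `dyad_count`, `internal_cpg_count`, `cds_length_nt`, `density_per_kb`,
#'   and `dyad_positions` as a comma-separated string of 0-based indices.
#' @export
scan_alignment <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  rows <- lapply(seq_len(nrow(aln$codons)), function(i) {
    cds <- paste0(aln$codons[i, aln$codons[i, ] != "---"], collapse = "")
    if (nchar(cds) == 0L) {
      return(data.frame(gene_id = aln$gene_id, species_id = aln$species_ids[i],
                        dyad_count = 0L, internal_cpg_count = 0L,
                        cds_length_nt = 0L, density_per_kb = 0,
                        dyad_positions = "", stringsAsFactors = FALSE))
    }
    p <- suppressWarnings(dyad_profile(cds, aln$gene_id, aln$species_ids[i]))
    data.frame(gene_id = p$gene_id, species_id = p$species_id,
               dyad_count = p$dyad_count,
               internal_cpg_count = p$internal_cpg_count,
               cds_length_nt = p$cds_length_nt,
               density_per_kb = p$density_per_kb,
               dyad_positions = paste(p$dyad_positions, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
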