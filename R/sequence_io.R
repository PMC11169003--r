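#' Construct a codon alignment object
#'
#' A codon alignment is a per-gene matrix of aligned codons: one row per
#' species, one column per codon column of the (codon-aware) nucleotide
#' alignment. Cells are 3-letter codons or the gap codon `"---"`.
#'
#' @param codons Character matrix, species x codon columns.
#' @param gene_id Gene identifier.
#' @param species_ids Row identifiers; defaults to `rownames(codons)`.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(codons, gene_id, species_ids = rownames(codons)) {
  if (!is.matrix(codons) || !is.character(codons)) {
    stop("codons must be a character matrix", call. = FALSE)
  }
  if (nrow(codons) < 2L) stop("a codon alignment needs >= 2 species", call. = FALSE)
  if (any(nchar(codons) != 3L)) stop("all cells must be 3-letter codons", call. = FALSE)
  if (is.null(species_ids) || anyDuplicated(species_ids)) {
    stop("species_ids must be unique and non-NULL", call. = FALSE)
  }
  rownames(codons) <- species_ids
  structure(
    list(gene_id = as.character(gene_id), species_ids = as.character(species_ids),
         codons = codons),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment '%s': %d species x %d codon columns\n",
              x$gene_id, nrow(x$codons), ncol(x$codons)))
  invisible(x)
}

# split an alignment row (one string) into codons
.split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Read a codon-aware alignment from aligned FASTA
#'
#' One file per gene, one record per species; the first whitespace-delimited
#' token of each header is taken as the species id. The alignment must be
#' codon-aware (length a multiple of 3, frame preserved); this reader does
#' not re-frame. Any codon cell containing a gap character is normalised to
#' the fully gapped codon `"---"` with a warning, so partially gapped
#' triplets at boundary columns cannot corrupt downstream scans.
#'
#' @param path Aligned FASTA file.
#' @param gene_id Gene identifier; defaults to the file stem.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, gene_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  lens <- Biostrings::width(recs)
  if (length(unique(lens)) != 1L) {
    stop("alignment error: records have unequal lengths (",
         paste(unique(lens), collapse = ", "), ") in ", path, call. = FALSE)
  }
  if (lens[1] %% 3L != 0L) {
    stop("frame error: alignment length ", lens[1], " is not a multiple of 3",
         call. = FALSE)
  }
  ids <- vapply(strsplit(names(recs), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(recs))
  codons <- do.call(rbind, lapply(seqs, .split_codons))
  partial <- grepl("-", codons, fixed = TRUE) & codons != "---"
  if (any(partial)) {
    warning(sum(partial), " partially gapped codon(s) normalised to '---' in ",
            basename(path), call. = FALSE)
    codons[partial] <- "---"
  }
  if (is.null(gene_id)) gene_id <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  codon_alignment(codons, gene_id = gene_id, species_ids = ids)
}

#' Write a codon alignment to aligned FASTA
#'
#' @param aln A [codon_alignment()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  seqs <- apply(aln$codons, 1L, paste0, collapse = "")
  xs <- Biostrings::BStringSet(seqs)
  names(xs) <- aln$species_ids
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces what the downstream
#' phylogenetic-signal tests need: unique tip labels and branch lengths on
#' every edge.
#'
#' @param path Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("tree error: could not parse Newick in ", path, call. = FALSE)
  if (anyDuplicated(tr$tip.label)) stop("tree error: duplicate tip labels", call. = FALSE)
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    stop("tree error: missing branch lengths", call. = FALSE)
  }
  tr
}

#' Read site-level methylation calls in bedMethyl format
#'
#' Parses the 11-column bedMethyl dialect (BED9+2): coverage in column 10
#' and percent methylated in column 11. Coordinates are BED-style 0-based
#' half-open and are preserved as such. A strand of `"."` is accepted and
#' recorded verbatim.
#'
#' @param path Tab-separated bedMethyl file.
#' @param sample_id Identifier for the track; defaults to the file stem.
#' @return An object of class `methylation_track`: a data.frame with columns
#'   `chrom`, `start`, `end`, `strand`, `coverage`, `percent`, and a
#'   `sample_id` attribute.
#' @export
read_bedmethyl <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "",
                           quote = "")
  if (ncol(raw) < 10L) {
    stop("bedMethyl parse error: expected >= 10 tab-separated columns, got ",
         ncol(raw), call. = FALSE)
  }
  pct_col <- if (ncol(raw) >= 11L) 11L else 10L
  cov_col <- pct_col - 1L
  coverage <- suppressWarnings(as.numeric(raw[[cov_col]]))
  percent <- suppressWarnings(as.numeric(raw[[pct_col]]))
  bad <- which(is.na(coverage) | is.na(percent) | coverage < 0 |
                 percent < 0 | percent > 100)
  if (length(bad)) {
    stop("bedMethyl parse error at line ", bad[1],
         ": coverage must be a non-negative number and percent in [0, 100]",
         call. = FALSE)
  }
  start <- suppressWarnings(as.integer(raw[[2]]))
  if (anyNA(start) || any(start < 0)) {
    stop("bedMethyl parse error: non-numeric or negative start coordinate",
         call. = FALSE)
  }
  out <- data.frame(
    chrom = raw[[1]], start = start,
    end = suppressWarnings(as.integer(raw[[3]])),
    strand = raw[[6]], coverage = coverage, percent = percent,
    stringsAsFactors = FALSE
  )
  if (is.null(sample_id)) sample_id <- sub("\\.bed(methyl)?(\\.gz)?$", "", basename(path))
  attr(out, "sample_id") <- sample_id
  class(out) <- c("methylation_track", "data.frame")
  out
}

#' Write a result table as TSV
#'
#' Deterministic output: header row, the column order of the input,
#' tab-separated, `\n` line endings, doubles at 6 significant digits.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6L)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path TSV file with a header row.
#' @return A data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "")
}
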