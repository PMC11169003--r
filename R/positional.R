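#' Relative positions of dyads along a coding sequence
#'
#' Maps 0-based codon-pair indices to fractions of the gene's length so
#' that dyad placement can be pooled across genes of different sizes. A
#' gene of `n_codons` codons has `n_codons - 1` possible junctions, so pair
#' index `i` maps to `i / (n_codons - 1)`, giving 0 for the first junction
#' and values approaching 1 at the last.
#'
#' @param positions Integer vector of 0-based pair indices.
#' @param n_codons Number of codons in the gene (>= 2).
#' @return Numeric vector of fractions in `[0, 1)`.
#' @export
relative_positions <- function(positions, n_codons) {
  stopifnot(n_codons >= 2)
  positions <- as.integer(positions)
  if (length(positions) && (min(positions) < 0 || max(positions) > n_codons - 2L)) {
    stop("pair index out of range for ", n_codons, " codons", call. = FALSE)
  }
  positions / (n_codons - 1L)
}

#' Bin pooled relative positions into a frequency distribution
#'
#' Half-open bins `[e_j, e_{j+1})` over `[0, 1]`, the last bin closed.
#' Frequencies are normalised to sum to 1 when any positions are supplied;
#' an empty input yields all-zero frequencies.
#'
#' @param positions Pooled relative positions in `[0, 1]`.
#' @param bins Number of bins (>= 2), default 20.
#' @return An object of class `positional_distribution`: list with
#'   `bin_edges` (length `bins + 1`), `counts`, `frequencies`,
#'   `n_dyads_total`.
#' @export
bin_frequencies <- function(positions, bins = 20L) {
  stopifnot(bins >= 2)
  if (length(positions) && (min(positions) < 0 || max(positions) > 1)) {
    stop("relative positions must lie in [0, 1]", call. = FALSE)
  }
  edges <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(findInterval(positions, edges, rightmost.closed = TRUE), bins)
  counts <- tabulate(idx, nbins = bins)
  total <- length(positions)
  structure(
    list(bin_edges = edges, counts = counts,
         frequencies = if (total > 0) counts / total else rep(0, bins),
         n_dyads_total = total),
    class = "positional_distribution"
  )
}

#' Contrast the positional distributions of two gene groups
#'
#' Pools the relative dyad positions of each group (e.g. the 1000 genes
#' with the highest vs lowest conserved-dyad density, each required to have
#' at least one conserved dyad), bins both, and quantifies their divergence
#' with a two-sample Kolmogorov-Smirnov statistic on the raw positions.
#'
#' @param top_positions,bottom_positions Relative positions pooled within
#'   each (disjoint) gene group; both non-empty.
#' @param bins Number of bins for the per-group distributions.
#' @return List with `top`, `bottom` (two [bin_frequencies()] objects),
#'   `ks_statistic`, `ks_p_value`.
#' @export
group_contrast <- function(top_positions, bottom_positions, bins = 20L) {
  if (!length(top_positions) || !length(bottom_positions)) {
    stop("both groups must contain at least one position", call. = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(top_positions, bottom_positions))
  list(top = bin_frequencies(top_positions, bins),
       bottom = bin_frequencies(bottom_positions, bins),
       ks_statistic = unname(ks$statistic),
       ks_p_value = ks$p.value)
}
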