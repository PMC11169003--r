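#' Estimate codon usage from a corpus of coding sequences
#'
#' Counts in-frame codons across the supplied ungapped CDS and converts the
#' counts to relative frequencies within each synonymous family. Families
#' with no observed codons fall back to uniform usage with a warning.
#'
#' @param sequences Character vector of ungapped CDS (lengths multiples
#'   of 3). Codons containing `N` are ignored.
#' @return A [codon_usage()] table.
#' @export
estimate_codon_usage <- function(sequences) {
  stopifnot(length(sequences) >= 1L)
  ct <- .std_code()
  sense <- names(ct$codon_to_aa)[ct$codon_to_aa != "*"]
  counts <- stats::setNames(numeric(length(sense)), sense)
  for (s in sequences) {
    codons <- suppressWarnings(.cds_codons(s))
    codons <- codons[codons %in% sense]
    if (length(codons)) {
      tb <- table(codons)
      counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
    }
  }
  if (sum(counts) == 0) stop("no valid codons in corpus", call. = FALSE)
  aa <- ct$codon_to_aa[sense]
  missing_fams <- unique(aa[!aa %in% aa[counts > 0]])
  if (length(missing_fams)) {
    warning("no codons observed for ", paste(missing_fams, collapse = ", "),
            "; using uniform usage for these families", call. = FALSE)
  }
  codon_usage(counts)
}

#' Null probability of a dyad at a site from codon usage
#'
#' Given the amino-acid dyad composition observed at a conserved site (how
#' many species show each residue pair) and a codon usage table, computes
#' the probability that a species drawing synonymous codons at usage
#' frequencies would show a CpG dyad at the site:
#' a mixture over the observed residue pairs of
#' `P(first codon ends C) * P(second codon starts G)`.
#' With `majority_only = TRUE` only the most frequent residue pair is used,
#' the simplification appropriate when one pair dominates the column.
#'
#' @param aa_dyads Named integer vector of species counts per residue pair
#'   (names `"S/V"` style), or the `;`-separated string stored by
#'   [call_conserved()].
#' @param usage A [codon_usage()] table, or `NULL` for uniform usage.
#' @param majority_only Use only the modal residue pair.
#' @return Null proportion `p0` in `[0, 1]`.
#' @examples
#' site_null_proportion(c("S/V" = 261))            # uniform: 2/6 * 1 = 1/3
#' @export
site_null_proportion <- function(aa_dyads, usage = NULL, majority_only = FALSE) {
  if (is.character(aa_dyads) && length(aa_dyads) == 1L) {
    aa_dyads <- .parse_aa_dyads(aa_dyads)
  }
  aa_dyads <- aa_dyads[aa_dyads > 0]
  if (!length(aa_dyads)) stop("empty amino-acid dyad composition", call. = FALSE)
  if (majority_only) {
    aa_dyads <- aa_dyads[which.max(aa_dyads)]
  }
  w <- aa_dyads / sum(aa_dyads)
  pair_p <- vapply(names(aa_dyads), function(nm) {
    aa <- strsplit(nm, "/", fixed = TRUE)[[1]]
    role_fraction(aa[1], "first", usage) * role_fraction(aa[2], "second", usage)
  }, numeric(1))
  sum(w * pair_p)
}

#' One-sample proportion z-test for conservation excess
#'
#' Tests whether the observed number of species carrying a dyad exceeds the
#' codon-usage expectation: `z = (k/n - p0) / sqrt(p0 (1 - p0) / n)` with a
#' one-sided upper-tail normal p-value. The expected count `p0 * n` is also
#' reported, along with the excess over its nearest integer (the
#' printed-style arithmetic: 219 observed - 55 expected = 164). When `p0`
#' is 0 or 1 the z statistic is degenerate and an exact binomial upper-tail
#' p-value is returned instead (with `z = NA`).
#'
#' @param k Observed count of species with the dyad.
#' @param n Number of species.
#' @param p0 Null proportion from [site_null_proportion()].
#' @return List with `z`, `p_value`, `expected` (unrounded `p0 * n`),
#'   `expected_rounded`, `excess` (`k - expected_rounded`).
#' @examples
#' proportion_ztest(219, 261, 0.212)  # expected ~55, excess 164
#' @export
proportion_ztest <- function(k, n, p0) {
  stopifnot(length(k) == 1L, length(n) == 1L, k >= 0, k <= n, p0 >= 0, p0 <= 1)
  expected <- p0 * n
  expected_rounded <- round(expected)
  excess <- k - expected_rounded
  if (p0 <= 0 || p0 >= 1) {
    p <- stats::binom.test(k, n, p = max(min(p0, 1), 0),
                           alternative = "greater")$p.value
    z <- NA_real_
  } else {
    z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  list(z = z, p_value = p, expected = expected,
       expected_rounded = expected_rounded, excess = excess)
}

#' Test every conserved site against its codon-usage null
#'
#' Applies [site_null_proportion()] and [proportion_ztest()] to each
#' conserved site of a set of conservation calls, sorted by gene then pair
#' index, with Benjamini-Hochberg adjusted q-values across sites.
#'
#' @param calls A [call_conserved()] result (one or several genes row-bound).
#' @param usage A [codon_usage()] table (typically from
#'   [estimate_codon_usage()] on the same corpus), or `NULL` for uniform.
#' @param majority_only Passed to [site_null_proportion()].
#' @param conserved_only Test only sites flagged conserved (default); set
#'   `FALSE` to test every pair column with a non-empty composition.
#' @return A data.frame: `gene_id`, `pair_index`, `k`, `n`, `p0`,
#'   `expected`, `excess`, `z`, `p_value`, `q_value`.
#' @export
site_excess_scan <- function(calls, usage = NULL, majority_only = FALSE,
                             conserved_only = TRUE) {
  stopifnot(is.data.frame(calls))
  rows <- if (conserved_only) calls[calls$conserved, , drop = FALSE] else calls
  rows <- rows[nzchar(rows$aa_dyads), , drop = FALSE]
  rows <- rows[order(rows$gene_id, rows$pair_index), , drop = FALSE]
  if (!nrow(rows)) {
    return(data.frame(gene_id = character(0), pair_index = integer(0),
                      k = integer(0), n = integer(0), p0 = numeric(0),
                      expected = numeric(0), excess = numeric(0),
                      z = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), stringsAsFactors = FALSE))
  }
  res <- lapply(seq_len(nrow(rows)), function(i) {
    p0 <- site_null_proportion(rows$aa_dyads[i], usage, majority_only)
    zt <- proportion_ztest(rows$k[i], rows$n[i], p0)
    data.frame(gene_id = rows$gene_id[i], pair_index = rows$pair_index[i],
               k = rows$k[i], n = rows$n[i], p0 = p0,
               expected = zt$expected, excess = zt$excess, z = zt$z,
               p_value = zt$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}
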