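#' The standard genetic code with CpG-dyad role sets
#'
#' Builds the standard (NCBI table 1) genetic code together with the
#' classification of codons by the two roles they can play in a CpG codon
#' dyad: a dyad is a CpG dinucleotide spanning two adjacent codons
#' (NNC|GNN), so the first codon of a dyad must end with C and the second
#' must start with G. Sixteen codons end with C, sixteen start with G, and
#' four (GAC, GCC, GGC, GTC) can serve in both roles; excluding the dual
#' codons leaves 12 exclusively C-ending and 12 exclusively G-starting
#' codons.
#'
#' @return An object of class `codon_table`: a list with
#'   \item{codon_to_aa}{named character vector over all 64 DNA codons;
#'     values are 1-letter amino-acid codes, `"*"` for the three stops.}
#'   \item{ends_c}{character vector of the 16 codons whose third base is C.}
#'   \item{starts_g}{character vector of the 16 codons whose first base is G.}
#'   \item{dual}{the 4 codons in both role sets.}
#' @examples
#' ct <- codon_table()
#' length(setdiff(ct$ends_c, ct$dual))   # 12 exclusively C-ending codons
#' length(ct$dual)                       # 4 dual-role codons
#' @export
codon_table <- function() {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  ends_c <- codons[substr(codons, 3L, 3L) == "C"]
  starts_g <- codons[substr(codons, 1L, 1L) == "G"]
  structure(
    list(
      codon_to_aa = as.character(code) |> stats::setNames(codons),
      ends_c = ends_c,
      starts_g = starts_g,
      dual = intersect(ends_c, starts_g)
    ),
    class = "codon_table"
  )
}

# cached copy; the table is immutable
.codon_table_cache <- new.env(parent = emptyenv())

.std_code <- function() {
  if (is.null(.codon_table_cache$tab)) .codon_table_cache$tab <- codon_table()
  .codon_table_cache$tab
}

.check_codon <- function(x, arg = "codon") {
  if (!is.character(x) || any(nchar(x) != 3L)) {
    stop("malformed ", arg, ": codons must be 3-letter strings", call. = FALSE)
  }
  invisible(toupper(x))
}

#' Test whether two adjacent codons form a CpG codon dyad
#'
#' `TRUE` iff the first codon ends with C and the second starts with G, so
#' that the junction reads 5'-CG-3'. Codons containing `N` or gap characters
#' never form a dyad (they are role-incapable, not errors), so the scan is
#' total over real alignment content.
#'
#' @param first,second 3-letter codon strings over `A,C,G,T,N,-`
#'   (case-insensitive). Vectors are recycled pairwise.
#' @return Logical vector.
#' @examples
#' is_dyad_pair("TCC", "GTG")  # serine-valine dyad: TRUE
#' is_dyad_pair("ATG", "AAA")  # FALSE
#' @export
is_dyad_pair <- function(first, second) {
  first <- .check_codon(first, "first codon")
  second <- .check_codon(second, "second codon")
  substr(first, 3L, 3L) == "C" & substr(second, 1L, 1L) == "G"
}

#' Build a codon usage table
#'
#' A codon usage table stores, for each amino acid, the relative frequency
#' of its synonymous codons (each family sums to 1). Stop codons are
#' excluded: they encode no residue and never form an in-frame dyad before
#' the terminus of a valid CDS.
#'
#' @param freq Named numeric vector of codon weights (any non-negative
#'   scale); missing codons get weight 0. `NULL` gives uniform usage within
#'   every family.
#' @return An object of class `codon_usage`: named numeric vector over the
#'   61 sense codons with per-family relative frequencies.
#' @examples
#' u <- codon_usage(c(TCC = 3, AGC = 1))  # serine usage 0.75 / 0.25
#' u[c("TCC", "AGC")]
#' @export
codon_usage <- function(freq = NULL) {
  ct <- .std_code()
  sense <- names(ct$codon_to_aa)[ct$codon_to_aa != "*"]
  w <- stats::setNames(rep(0, length(sense)), sense)
  if (is.null(freq)) {
    w[] <- 1
  } else {
    if (is.null(names(freq))) stop("freq must be a named vector of codons", call. = FALSE)
    nm <- toupper(names(freq))
    unknown <- setdiff(nm, names(ct$codon_to_aa))
    if (length(unknown)) stop("unknown codons: ", paste(unknown, collapse = ", "), call. = FALSE)
    if (any(freq < 0)) stop("codon weights must be non-negative", call. = FALSE)
    keep <- nm %in% sense
    w[nm[keep]] <- as.numeric(freq)[keep]
  }
  aa <- ct$codon_to_aa[sense]
  for (a in unique(aa)) {
    idx <- which(aa == a)
    s <- sum(w[idx])
    # an amino acid with no observed codons falls back to uniform usage
    w[idx] <- if (s > 0) w[idx] / s else 1 / length(idx)
  }
  structure(w, class = c("codon_usage", "numeric"))
}

#' Probability that an amino acid's codon fills a dyad role
#'
#' For the first-codon role the capable codons are those ending in C; for
#' the second-codon role, those starting with G. Under uniform usage the
#' fraction is the count of capable codons over the family size (e.g. 2 of
#' serine's 6 codons end in C); under an empirical usage table it is the
#' summed within-family frequency of the capable codons. Second-role
#' fractions are always exactly 0 or 1 because every synonymous family
#' either consists entirely of G-starting codons (V, A, D, E, G) or
#' contains none.
#'
#' @param aa 1-letter amino-acid code (one of the 20 standard residues).
#' @param role `"first"` (ends-C) or `"second"` (starts-G).
#' @param usage A [codon_usage()] table, or `NULL` for uniform usage. A plain
#'   named numeric vector is taken as literal within-family frequencies
#'   (codons absent from the vector contribute 0), without renormalisation.
#' @return Proportion in `[0, 1]`.
#' @examples
#' role_fraction("S", "first")   # 2/6
#' role_fraction("V", "second")  # 1
#' role_fraction("S", "first", c(TCC = 0.15, AGC = 0.05))  # 0.20
#' @export
role_fraction <- function(aa, role = c("first", "second"), usage = NULL) {
  role <- match.arg(role)
  ct <- .std_code()
  aa <- toupper(aa)
  stopifnot(length(aa) == 1L)
  fam <- names(ct$codon_to_aa)[ct$codon_to_aa == aa]
  if (aa == "*" || !length(fam)) {
    stop("unknown amino acid: ", aa, call. = FALSE)
  }
  capable <- if (role == "first") intersect(fam, ct$ends_c) else intersect(fam, ct$starts_g)
  if (is.null(usage)) {
    length(capable) / length(fam)
  } else {
    u <- stats::setNames(as.numeric(usage), toupper(names(usage)))
    sum(u[intersect(capable, names(u))])
  }
}
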