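#' Build and validate a pipeline run configuration
#'
#' @param input_dir Directory holding `alignments/*.fasta` (one codon-aware
#'   aligned FASTA per gene; gene id = file stem) and optionally `tree.nwk`.
#' @param output_dir Run directory to create.
#' @param threshold Conservation threshold fraction (default 200/261).
#' @param bins Positional bins.
#' @param seed Seed for every stochastic stage (K permutations).
#' @param n_permutations Permutations for Blomberg's K; 0 skips the
#'   permutation p-value.
#' @param reference_species Species whose ungapped rows form the codon-usage
#'   corpus and the positional scan; `NULL` uses the first record of each
#'   alignment.
#' @param run_signal Compute phylogenetic-signal statistics (requires
#'   `tree.nwk`).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir, threshold = 200 / 261,
                       bins = 20L, seed = 1L, n_permutations = 199L,
                       reference_species = NULL, run_signal = TRUE) {
  if (!dir.exists(file.path(input_dir, "alignments"))) {
    stop("config validation error: no alignments/ directory under ", input_dir,
         call. = FALSE)
  }
  if (run_signal && !file.exists(file.path(input_dir, "tree.nwk"))) {
    stop("config validation error: signal stage requested but ",
         file.path(input_dir, "tree.nwk"), " is missing", call. = FALSE)
  }
  stopifnot(threshold > 0, threshold <= 1, bins >= 2, n_permutations >= 0)
  structure(
    list(input_dir = input_dir, output_dir = output_dir,
         threshold = threshold, bins = as.integer(bins),
         seed = as.integer(seed), n_permutations = as.integer(n_permutations),
         reference_species = reference_species, run_signal = run_signal),
    class = "run_config"
  )
}

#' Run the end-to-end dyad analysis
#'
#' Executes the stages in dependency order — scan, conserve, nulltest,
#' distribution, and (optionally) signal — reading the per-gene alignments
#' once and consuming intermediate results only through the TSVs written to
#' the run directory. A `manifest.tsv` lists every output with its MD5
#' content hash, so identical config and inputs yield identical hashes.
#'
#' @param config A [run_config()].
#' @return The run directory path, invisibly; outputs on disk:
#'   `scan.tsv` (per gene x species profiles), `conserve.tsv` (per-site
#'   calls), `gene_summary.tsv`, `nulltest.tsv`, `distribution.tsv`,
#'   `signal.tsv` (when enabled), `config.tsv`, `manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- sort(list.files(file.path(config$input_dir, "alignments"),
                           pattern = "\\.(fa|fasta|fna)$", full.names = TRUE))
  if (!length(files)) stop("no alignment FASTA files found", call. = FALSE)

  scan_rows <- list(); call_rows <- list(); gene_rows <- list()
  ref_seqs <- character(0); conserved_rel <- numeric(0)
  stage <- "scan"
  for (f in files) {
    res <- tryCatch({
      aln <- read_codon_alignment(f)
      sc <- scan_alignment(aln)
      counts <- column_dyad_counts(aln)
      calls <- call_conserved(counts, gene_id = aln$gene_id,
                              threshold = config$threshold)
      list(aln = aln, sc = sc, calls = calls)
    }, error = function(e) {
      stop("stage ", stage, " failed for gene '",
           sub("\\.(fa|fasta|fna)$", "", basename(f)), "': ",
           conditionMessage(e), call. = FALSE)
    })
    aln <- res$aln
    scan_rows[[aln$gene_id]] <- res$sc
    call_rows[[aln$gene_id]] <- res$calls
    n_cols <- ncol(aln$codons)
    gene_rows[[aln$gene_id]] <- data.frame(
      gene_id = aln$gene_id, n_species = nrow(aln$codons),
      n_codon_columns = n_cols,
      n_conserved = sum(res$calls$conserved),
      dyadC_density_per_kb = consensus_dyad_density(res$calls, n_cols),
      stringsAsFactors = FALSE
    )
    ref_row <- if (is.null(config$reference_species)) 1L else {
      match(config$reference_species, aln$species_ids)
    }
    if (!is.na(ref_row)) {
      cds <- paste0(aln$codons[ref_row, aln$codons[ref_row, ] != "---"],
                    collapse = "")
      if (nzchar(cds)) ref_seqs <- c(ref_seqs, cds)
    }
    if (n_cols >= 2 && any(res$calls$conserved)) {
      conserved_rel <- c(conserved_rel,
                         relative_positions(res$calls$pair_index[res$calls$conserved],
                                            n_cols))
    }
  }
  scan_tab <- do.call(rbind, scan_rows)
  calls_tab <- do.call(rbind, call_rows)
  gene_tab <- do.call(rbind, gene_rows)
  rownames(scan_tab) <- rownames(calls_tab) <- rownames(gene_tab) <- NULL
  write_table(scan_tab, file.path(config$output_dir, "scan.tsv"))
  write_table(calls_tab, file.path(config$output_dir, "conserve.tsv"))
  write_table(gene_tab, file.path(config$output_dir, "gene_summary.tsv"))

  # nulltest: codon usage from the reference rows of the whole cohort
  usage <- suppressWarnings(estimate_codon_usage(ref_seqs))
  null_tab <- site_excess_scan(calls_tab, usage)
  write_table(null_tab, file.path(config$output_dir, "nulltest.tsv"))

  dist <- bin_frequencies(conserved_rel, config$bins)
  write_table(
    data.frame(bin_start = dist$bin_edges[-length(dist$bin_edges)],
               bin_end = dist$bin_edges[-1], count = dist$counts,
               frequency = dist$frequencies, stringsAsFactors = FALSE),
    file.path(config$output_dir, "distribution.tsv")
  )

  if (config$run_signal) {
    tree <- read_tree(file.path(config$input_dir, "tree.nwk"))
    trait <- tapply(scan_tab$dyad_count, scan_tab$species_id, sum)
    trait <- stats::setNames(as.numeric(trait), names(trait))
    lam <- pagel_lambda(trait, tree)
    kk <- blomberg_k(trait, tree, n_permutations = config$n_permutations,
                     seed = if (config$n_permutations > 0) config$seed else NULL)
    write_table(
      data.frame(statistic = c("lambda", "K"),
                 estimate = c(lam$estimate, kk$estimate),
                 test_stat = c(lam$test_stat, kk$test_stat),
                 p_value = c(lam$p_value, kk$p_value),
                 n_tips = c(lam$n_tips, kk$n_tips), stringsAsFactors = FALSE),
      file.path(config$output_dir, "signal.tsv")
    )
  }

  cfg <- config
  cfg$reference_species <- if (is.null(cfg$reference_species)) "" else cfg$reference_species
  write_table(
    data.frame(key = names(cfg), value = vapply(cfg, as.character, character(1)),
               stringsAsFactors = FALSE),
    file.path(config$output_dir, "config.tsv")
  )

  outs <- sort(setdiff(list.files(config$output_dir), "manifest.tsv"))
  manifest <- data.frame(
    file = outs,
    md5 = unname(tools::md5sum(file.path(config$output_dir, outs))),
    stringsAsFactors = FALSE
  )
  write_table(manifest, file.path(config$output_dir, "manifest.tsv"))
  invisible(config$output_dir)
}

#' Summarise a completed pipeline run
#'
#' Produces a deterministic plain-text report from the run directory: gene
#' and species counts, conserved-site totals, the fraction of genes with at
#' least one conserved dyad, and the sites with the largest excess over
#' their codon-usage null.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param top_n Number of top-excess sites to list.
#' @return Character vector of report lines (also printed).
#' @export
summarize_run <- function(run_dir, top_n = 5L) {
  need <- c("manifest.tsv", "gene_summary.tsv", "conserve.tsv", "nulltest.tsv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing)) {
    stop("incomplete run: missing ", paste(missing, collapse = ", "), call. = FALSE)
  }
  genes <- read_table_tsv(file.path(run_dir, "gene_summary.tsv"))
  nulls <- read_table_tsv(file.path(run_dir, "nulltest.tsv"))
  lines <- c(
    "CpG codon dyad analysis summary",
    sprintf("genes analysed: %d", nrow(genes)),
    sprintf("species per alignment: %s",
            paste(sort(unique(genes$n_species)), collapse = ",")),
    sprintf("conserved dyad sites (dyadC): %d", sum(genes$n_conserved)),
    sprintf("genes with >= 1 dyadC: %d of %d (%.1f%%)",
            sum(genes$n_conserved > 0), nrow(genes),
            100 * mean(genes$n_conserved > 0))
  )
  if (nrow(nulls)) {
    top <- nulls[order(-nulls$excess), , drop = FALSE]
    top <- utils::head(top, top_n)
    lines <- c(lines, "top sites by excess over codon-usage null:",
               sprintf("  %s pair %d: k=%d/%d, expected %.1f, excess %d, p=%.2e",
                       top$gene_id, top$pair_index, top$k, top$n,
                       top$expected, top$excess, top$p_value))
  }
  if (nrow(genes) == 0L) lines <- c(lines, "cohort is empty")
  cat(lines, sep = "\n")
  invisible(lines)
}
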