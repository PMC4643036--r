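# End-to-end driver: simulate a synthetic study, run pre-processing, both
# discovery approaches and the interaction analysis, and write every output
# table deterministically. Used by the analysis scripts and the determinism
# checks.

#' Per-library counts for discovered hairpins
#'
#' Sums, for each candidate region, the per-library counts of every unique
#' read with a perfect ungapped genomic hit overlapping the region.
#'
#' @param candidates candidate table from [discover_hairpins()].
#' @param tbl unique-read table the candidates were discovered from.
#' @param genome named character vector of contigs.
#' @return matrix hairpins (identifier) x libraries.
#' @export
quantify_hairpins <- function(candidates, tbl, genome) {
  cm <- urt_counts(tbl)
  out <- matrix(0L, nrow = nrow(candidates), ncol = ncol(cm),
                dimnames = list(candidates$identifier, colnames(cm)))
  if (nrow(candidates) == 0 || nrow(tbl) == 0) return(out)
  hits <- find_alignments(tbl$sequence, genome, "perfect")
  for (i in seq_len(nrow(candidates))) {
    r <- candidates[i, ]
    over <- hits$query[hits$ref == r$contig & hits$end > (r$start - 1L) &
                         hits$start < r$end]
    rows <- which(tbl$sequence %in% over)
    if (length(rows) > 0) {
      out[i, ] <- as.integer(colSums(cm[rows, , drop = FALSE]))
    }
  }
  out
}

#' Run the complete synthetic-study pipeline and write all outputs
#'
#' Simulates a study with [simulate_study()], writes its inputs (FASTQ per
#' library, genome/contaminant/mature-reference FASTA, design table, truth
#' tables), then runs pre-processing, conserved-miRNA profiling, hairpin
#' discovery and the interaction analysis, writing each stage's tables under
#' `out_dir`. Fully deterministic given `seed`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed for all randomness.
#' @param n_category_a,decoy_categories,genome_length,design,baseline_mean,
#'   interaction_log2fc,n_interaction,dispersion passed to [simulate_study()].
#' @param alpha adjusted-p threshold for interaction candidates.
#' @param ... further arguments to [simulate_study()].
#' @return (invisibly) list with every intermediate object and the vector of
#'   written file paths.
#' @export
run_all <- function(out_dir, seed, n_category_a = 6,
                    decoy_categories = c("E", "H"), genome_length = 30000,
                    design = make_design(c("Tamaroi", "EGA_Bellaroi"),
                                         tolerant = "Tamaroi",
                                         replicates = 3),
                    baseline_mean = 15, interaction_log2fc = 2,
                    n_interaction = 2, dispersion = 0.1, alpha = 0.05, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(n_category_a = n_category_a,
                          decoy_categories = decoy_categories,
                          genome_length = genome_length, design = design,
                          baseline_mean = baseline_mean,
                          interaction_log2fc = interaction_log2fc,
                          n_interaction = n_interaction,
                          dispersion = dispersion, seed = seed, ...)
  paths <- character(0)
  wp <- function(p) { paths <<- c(paths, p); p }
  write_fasta(study$genome, wp(file.path(out_dir, "genome.fasta")))
  write_fasta(study$contaminants,
              wp(file.path(out_dir, "contaminants.fasta")))
  write_fasta(study$mature_refs, wp(file.path(out_dir, "mature_refs.fasta")))
  write_design(study$design, wp(file.path(out_dir, "design.tsv")))
  utils::write.table(study$hairpins,
                     wp(file.path(out_dir, "truth_hairpins.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(study$truth_counts,
                   wp(file.path(out_dir, "truth_counts.tsv")))
  fq_dir <- file.path(out_dir, "fastq")
  dir.create(fq_dir, showWarnings = FALSE)
  for (lib in names(study$reads)) {
    write_fastq(study$reads[[lib]],
                wp(file.path(fq_dir, paste0(lib, ".fastq"))))
  }
  # pre-processing
  pp <- preprocess_libraries(study$reads, study$design, study$contaminants)
  utils::write.table(pp$hairpin_table,
                     wp(file.path(out_dir, "unique_reads_filtered.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pp$log, wp(file.path(out_dir, "filter_log.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # conserved profiling on the wide (15-50 nt) partition
  ann <- annotate_conserved(pp$approach1_table, study$mature_refs)
  totals <- colSums(urt_counts(pp$approach1_table))
  rpm <- compute_rpm(ann$counts, totals)
  write_matrix_tsv(rpm, wp(file.path(out_dir, "conserved_rpm.tsv")),
                   id_col = "miRNA")
  candidates <- call_candidates(rpm)
  profile <- profile_conserved(rpm, study$design)
  write_matrix_tsv(profile$stress$log2fc,
                   wp(file.path(out_dir, "stress_log2fc.tsv")),
                   id_col = "miRNA")
  summary_df <- data.frame(miRNA = rownames(rpm),
                           candidate = rownames(rpm) %in% candidates,
                           genotype_group = profile$genotype_group,
                           tissue = profile$tissue_predominance,
                           stress_responsive = rownames(rpm) %in%
                             profile$stress$flagged,
                           stringsAsFactors = FALSE)
  utils::write.table(summary_df,
                     wp(file.path(out_dir, "conserved_summary.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # hairpin discovery
  cand <- discover_hairpins(pp$hairpin_table, study$genome,
                            mature_refs = study$mature_refs)
  utils::write.table(cand, wp(file.path(out_dir, "hairpin_candidates.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(cand) > 0) {
    write_bed6(cand, wp(file.path(out_dir, "hairpin_candidates.bed")))
    write_fasta(stats::setNames(cand$sequence, cand$identifier),
                wp(file.path(out_dir, "hairpin_candidates.fasta")))
  }
  # interaction analysis on category-A hairpins
  hp_counts <- quantify_hairpins(cand, pp$hairpin_table, study$genome)
  fits <- NULL
  flagged <- NULL
  if (nrow(hp_counts) > 1) {
    fits <- interaction_fit(hp_counts, study$design,
                            library_totals = totals)
    flagged <- select_candidates(fits, alpha = alpha,
                                 candidates =
                                   cand$identifier[cand$category == "A"])
    utils::write.table(fits, wp(file.path(out_dir, "interaction_fits.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(flagged,
                       wp(file.path(out_dir, "interaction_flagged.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(study = study, preprocess = pp, rpm = rpm,
                 conserved_candidates = candidates, profile = profile,
                 hairpins = cand, hairpin_counts = hp_counts, fits = fits,
                 flagged = flagged, paths = paths))
}
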