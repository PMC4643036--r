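#!/usr/bin/env Rscript
# Simulate the synthetic small RNA study: a genome with planted pre-miRNA
# hairpins (true miRNA coverage signatures plus decoys), contaminant
# references, and adapter-ligated reads for a reduced factorial design
# (2 genotypes x 2 tissues x 2 treatments x 3 replicates). The full-scale
# study layout (4 genotypes x 6 replicates = 96 libraries) is available via
# make_design(); the reduced design keeps this walkthrough fast.
#
# Writes raw inputs and ground truth under results/study/.

suppressPackageStartupMessages(library(durmiR))

seed <- 20240915
out <- "results/study"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

study <- simulate_study(
  n_category_a = 12,
  decoy_categories = c("C", "D", "E", "E", "G", "H", "H"),
  genome_length = 60000,
  baseline_mean = 40, dispersion = 0.05,
  interaction_log2fc = 2, n_interaction = 4, # 4 hairpins respond
  known_fraction = 0.7, # ~30% of planted matures are absent from the refs
  seed = seed, n_mrna = 2, n_junk = 10,
  n_background = 4000) # unannotated bulk dominating the library totals

write_fasta(study$genome, file.path(out, "genome.fasta"))
write_fasta(study$contaminants, file.path(out, "contaminants.fasta"))
write_fasta(study$mature_refs, file.path(out, "mature_refs.fasta"))
write_design(study$design, file.path(out, "design.tsv"))
write.table(study$hairpins, file.path(out, "truth_hairpins.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(study$effects, file.path(out, "truth_effects.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_matrix_tsv(study$truth_counts, file.path(out, "truth_counts.tsv"))
dir.create(file.path(out, "fastq"), showWarnings = FALSE)
for (lib in names(study$reads)) {
  write_fastq(study$reads[[lib]],
              file.path(out, "fastq", paste0(lib, ".fastq.gz")))
}

n_reads <- sum(vapply(study$reads, nrow, integer(1)))
cat(sprintf(
  "Simulated %d libraries (%d reads total), %d hairpins (%d with a planted\n",
  nrow(study$design), n_reads, nrow(study$hairpins), 4),
  "tolerance x treatment interaction), genome of",
  format(sum(nchar(study$genome)), big.mark = ","), "bp.\n")
cat("Truth categories:",
    paste(names(table(study$hairpins$truth_category)),
          table(study$hairpins$truth_category), collapse = ", "), "\n")
cat("Outputs in", out, "\n")
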