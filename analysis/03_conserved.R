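#!/usr/bin/env Rscript
# Conserved miRNA profiling: annotate unique reads against the mature
# reference set (<= 2 mismatches), normalize to reads per million, apply the
# candidate rule (> 2 RPM in at least half the libraries) and the
# differential-abundance criteria (0.01 zero floor, >= 10 RPM in one side,
# fold change > 1.5), and classify genotype groups I-IV, tissue
# predominance, and stress response.
#
# Reads results/study/ and results/preprocess/, writes results/conserved/.

suppressPackageStartupMessages(library(durmiR))

out <- "results/conserved"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- parse_design("results/study/design.tsv")
mature_refs <- read_fasta("results/study/mature_refs.fasta")
wide <- read.delim("results/preprocess/unique_reads_wide.tsv",
                   check.names = FALSE)

ann <- annotate_conserved(wide, mature_refs)
totals <- colSums(as.matrix(wide[, design$library_id]))
rpm <- compute_rpm(ann$counts, totals)
write_matrix_tsv(rpm, file.path(out, "rpm.tsv"), id_col = "miRNA")

candidates <- call_candidates(rpm)
profile <- profile_conserved(rpm, design)
write_matrix_tsv(profile$stress$log2fc, file.path(out, "stress_log2fc.tsv"),
                 id_col = "miRNA")
summary_df <- data.frame(
  miRNA = rownames(rpm),
  candidate = rownames(rpm) %in% candidates,
  genotype_group = profile$genotype_group,
  tissue_predominance = profile$tissue_predominance,
  stress_responsive = rownames(rpm) %in% profile$stress$flagged)
write.table(summary_df, file.path(out, "conserved_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d of %d reference miRNAs detected above zero RPM.\n",
            sum(rowSums(rpm) > 0), nrow(rpm)))
cat(sprintf("%d candidate conserved miRNAs (>2 RPM in >=50%% of libraries).\n",
            length(candidates)))
cat(sprintf("%d stress-responsive; genotype groups: %s\n",
            length(profile$stress$flagged),
            paste(names(table(profile$genotype_group)),
                  table(profile$genotype_group), collapse = ", ")))
cat("Outputs in", out, "\n")
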