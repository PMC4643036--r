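#!/usr/bin/env Rscript
# De novo hairpin discovery: perfect and imperfect (2-5 mismatch) genomic
# alignment of the filtered 19-26 nt unique reads, opposite-strand locus
# pairing (inner gap 54-1000 bp, regions +/- 20 bp), fold-back validation,
# read-coverage metrics, category A-H assignment and known/novel splitting.
#
# Reads results/study/ and results/preprocess/, writes results/hairpins/.

suppressPackageStartupMessages(library(durmiR))

out <- "results/hairpins"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- read_fasta("results/study/genome.fasta")
mature_refs <- read_fasta("results/study/mature_refs.fasta")
tbl <- read.delim("results/preprocess/unique_reads_filtered.tsv",
                  check.names = FALSE)
truth <- read.delim("results/study/truth_hairpins.tsv")

cand <- discover_hairpins(tbl, genome, mature_refs = mature_refs)
write.table(cand, file.path(out, "hairpin_candidates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_bed6(cand, file.path(out, "hairpin_candidates.bed"))
write_fasta(stats::setNames(cand$sequence, cand$identifier),
            file.path(out, "hairpin_candidates.fasta"))
writeLines(paste(cand$identifier, cand$sequence,
                 vapply(seq_len(nrow(cand)), function(i) {
                   fold_hairpin(cand$sequence[i])$structure
                 }, character(1)), sep = "\n"),
           file.path(out, "hairpin_structures.txt"))

m <- match(cand$start, truth$start - 20L)
cat(sprintf("%d candidate hairpins pass the structural gate.\n", nrow(cand)))
cat("Category counts:",
    paste(names(table(cand$category)), table(cand$category),
          collapse = ", "), "\n")
cat(sprintf("Known (exact mature match): %d; novel: %d.\n",
            sum(cand$status == "known"), sum(cand$status == "novel")))
recov <- table(truth = truth$truth_category[m], called = cand$category)
cat("Recovery vs planted truth (rows = truth, cols = called):\n")
print(recov)
cat("Outputs in", out, "\n")
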