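#!/usr/bin/env Rscript
# Tolerance x treatment interaction analysis: per-hairpin counts, log2-CPM,
# moderated linear-model test of the interaction coefficient, BH adjustment,
# restriction to category-A candidates and the automated read-coverage
# signature check standing in for manual inspection.
#
# Reads earlier results/, writes results/interaction/.

suppressPackageStartupMessages(library(durmiR))

out <- "results/interaction"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- parse_design("results/study/design.tsv")
genome <- read_fasta("results/study/genome.fasta")
tbl <- read.delim("results/preprocess/unique_reads_filtered.tsv",
                  check.names = FALSE)
cand <- read.delim("results/hairpins/hairpin_candidates.tsv",
                   check.names = FALSE)
truth <- read.delim("results/study/truth_hairpins.tsv")

counts <- quantify_hairpins(cand, tbl, genome)
# CPM denominators: all putative small RNA reads per library (pre-filter)
wide <- read.delim("results/preprocess/unique_reads_wide.tsv",
                   check.names = FALSE)
totals <- colSums(as.matrix(wide[, design$library_id]))
fits <- interaction_fit(counts, design, library_totals = totals)
write.table(fits, file.path(out, "interaction_fits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

flagged <- select_candidates(fits, alpha = 0.05,
                             candidates = cand$identifier[cand$category == "A"])
# signature check on the flagged hairpins
hits <- find_alignments(tbl$sequence, genome, "perfect")
hits$count <- tbl$total_count[match(hits$query, tbl$sequence)]
flagged$signature_pass <- vapply(flagged$feature_id, function(id) {
  r <- cand[cand$identifier == id, ]
  over <- hits[hits$ref == r$contig & hits$end > r$start - 1L &
                 hits$start < r$end, ]
  mat_win <- if (r$strand == "+") c(r$start - 1L, r$start - 1L + 50L) else
    c(r$end - 50L, r$end)
  signature_check(c(r$start - 1L, r$end), over, mature_window = mat_win)$pass
}, logical(1))
write.table(flagged, file.path(out, "interaction_flagged.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

effects <- read.delim("results/study/truth_effects.tsv")
planted <- effects$feature_id[effects$interaction_log2fc != 0]
m <- match(cand$start[match(flagged$feature_id, cand$identifier)],
           truth$start - 20L)
cat(sprintf("%d of %d category-A hairpins show a significant interaction\n",
            nrow(flagged), sum(cand$category == "A")),
    sprintf("(BH-adjusted p <= 0.05); %d of them pass the signature check.\n",
            sum(flagged$signature_pass)))
cat("Flagged hairpins map to planted features:",
    paste(truth$feature_id[m], collapse = ", "),
    "| truth with planted interaction:", paste(planted, collapse = ", "),
    "\n")
cat("Outputs in", out, "\n")
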