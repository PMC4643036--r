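# Shared synthetic fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Reduced study: 2 genotypes x 2 tissues x 2 treatments x 3 replicates,
# 6 true-signature hairpins plus one decoy of each plantable non-A category.
tiny_study <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- simulate_study(
      n_category_a = 6, decoy_categories = c("C", "D", "E", "G", "H"),
      genome_length = 30000, baseline_mean = 15, seed = 4711,
      n_mrna = 1, n_junk = 5)
  }
  .fixtures$study
}

tiny_preprocessed <- function() {
  if (is.null(.fixtures$pp)) {
    st <- tiny_study()
    .fixtures$pp <- preprocess_libraries(st$reads, st$design,
                                         st$contaminants)
  }
  .fixtures$pp
}

# Table of per-row direction patterns for the genotype-group classifier:
# 8 cells per feature, CG then WG, each "B" (tolerant-favoring), "S"
# (sensitive-favoring) or "." (not called).
pattern_to_results <- function(cells) {
  stopifnot(length(cells) == 8)
  trt <- rep(c("control", "water_deficit"), each = 4)
  data.frame(treatment = trt,
             called = cells != ".",
             direction = ifelse(cells == "B", "tolerant",
                                ifelse(cells == "S", "sensitive", "none")),
             stringsAsFactors = FALSE)
}

# Printed direction patterns of the 22 genotype-pattern rows (groups I-IV):
# per row: group then CG (Ta/Be FL, Ta/Be H, Ya/Tj FL, Ya/Tj H) and WG cells.
genotype_pattern_fixture <- function() {
  rows <- list(
    miR160f  = list("I",   c(".", "B", "B", "B", ".", ".", ".", ".")),
    miR166a  = list("I",   c("B", "B", ".", ".", "B", "B", ".", ".")),
    miR393h  = list("I",   c(".", ".", "B", "B", ".", ".", "B", ".")),
    miR408   = list("I",   c("B", "B", ".", ".", "B", ".", ".", ".")),
    miR5054  = list("I",   c("B", ".", "B", "B", "B", ".", ".", ".")),
    miR5077  = list("I",   c("B", "B", ".", ".", "B", "B", ".", ".")),
    miR528   = list("I",   c("B", "B", "B", ".", "B", ".", ".", ".")),
    miR166j  = list("II",  c(".", ".", "S", "S", "S", "S", ".", ".")),
    miR395b  = list("II",  c("S", "S", "S", ".", "S", ".", "S", "S")),
    miR396d  = list("II",  c(".", ".", "S", ".", ".", ".", "S", "S")),
    miR396g  = list("II",  c(".", ".", "S", ".", "S", "S", ".", ".")),
    miR5200  = list("II",  c("S", "S", "S", "S", "S", "S", ".", "S")),
    miR156k  = list("III", c(".", "B", ".", ".", ".", ".", "S", "S")),
    miR168   = list("III", c(".", "B", "B", "B", "S", "S", ".", ".")),
    miR319b  = list("III", c("B", "B", ".", ".", "S", ".", ".", ".")),
    miR393b  = list("III", c(".", ".", ".", "B", "S", "S", ".", ".")),
    miR398b  = list("III", c("B", "B", ".", ".", "S", "S", ".", ".")),
    miR399e  = list("III", c(".", "B", ".", "B", "S", "S", ".", ".")),
    miR444b  = list("III", c(".", "B", ".", "B", ".", ".", ".", "S")),
    miR5071  = list("III", c(".", ".", "B", "B", "S", "S", ".", ".")),
    miR528a  = list("III", c("B", "B", ".", ".", ".", "S", ".", "S")),
    miR6300  = list("IV",  c(".", "S", "S", ".", ".", "B", ".", "B")))
  data.frame(name = names(rows),
             group = vapply(rows, `[[`, character(1), 1),
             pattern = I(lapply(rows, `[[`, 2)),
             stringsAsFactors = FALSE)
}
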