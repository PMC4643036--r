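# Adapter-ligated read simulation: hairpin reads following per-category
# coverage signatures, contaminant reads, breakdown products of longer
# transcripts, and low-abundance junk -- each truth-tagged via the read id.

# One read sequence per (hairpin, read type).
hairpin_read_seq <- function(hp, type, genome) {
  switch(type,
    mature = hp$mature_seq,
    star = hp$star_seq,
    anti = revcomp(hp$mature_seq),
    loop = {
      loop_seq <- substr(genome[[hp$contig]],
                         hp$start + hp$arm_length,
                         hp$start + hp$arm_length + hp$loop_length - 1)
      off <- sample.int(max(1, nchar(loop_seq) - hp$arm_length + 1), 1)
      substr(loop_seq, off, off + hp$arm_length - 1)
    },
    stop("unknown read type ", type))
}

add_adapter <- function(insert, adapter3, read_length) {
  substr(paste0(insert, adapter3, strrep("A", read_length)), 1, read_length)
}

#' Simulate per-library small RNA reads with known truth
#'
#' For every library of the design and every planted hairpin, a negative
#' binomial count is drawn from the feature's effect specification and split
#' into read types (mature / star / loop / antisense) according to the
#' hairpin's truth-category signature. Read inserts get the 3' adapter
#' appended and are truncated to `read_length`; qualities are constant.
#' Contaminant reads are exact substrings of the contaminant references,
#' mixed in at `contaminant_fraction` of each library. Optional breakdown
#' products emulate fragments of longer transcripts: adapter-free 36 nt
#' fragments tiling a synthetic mRNA (the untrimmed partition used for
#' assembly) plus short adapter-carrying substrings of the same mRNA (the
#' reads the assembly filter must remove).
#'
#' @param design study design.
#' @param genome genome with planted hairpins.
#' @param hairpins hairpin truth table from [plant_hairpins()].
#' @param effects effect table from [make_effects()] keyed by
#'   `hairpins$feature_id`; every hairpin must have an effect spec.
#' @param contaminants named character vector of contaminant references (or
#'   NULL for none).
#' @param adapter3 3' adapter sequence (nonempty).
#' @param read_length raw read length in nt.
#' @param contaminant_fraction expected fraction of contaminant reads per
#'   library.
#' @param n_mrna number of synthetic breakdown-product source transcripts.
#' @param n_junk number of distinct low-abundance junk sequences (each seen
#'   at most 5 times in total).
#' @param n_background singleton random 19-26 nt reads per library,
#'   emulating the unannotated bulk of a real small RNA library: they enter
#'   the library totals (the RPM/CPM denominators) but are removed from the
#'   unique-read table by the abundance filter.
#' @param seed optional RNG seed.
#' @return list with `reads` (per-library data.frames of read_id, sequence,
#'   quality), `truth_counts` (hairpin x library matrix of simulated
#'   non-contaminant hairpin reads), `clean_seqs` (unique sequences derived
#'   from hairpins), `contaminant_seqs`, `breakdown_seqs`, `mrna`
#'   (the breakdown source transcripts).
#' @export
simulate_reads <- function(design, genome, hairpins, effects,
                           contaminants = NULL,
                           adapter3 = "AGATCGGAAGAGCACACGTCT",
                           read_length = 36,
                           contaminant_fraction = 0.1,
                           n_mrna = 0, n_junk = 0, n_background = 0,
                           seed = NULL) {
  stopifnot(nchar(adapter3) > 0)
  missing_fx <- setdiff(hairpins$feature_id, effects$feature_id)
  if (length(missing_fx) > 0) {
    stop("missing effect spec for hairpin(s): ",
         paste(missing_fx, collapse = ", "))
  }
  effects <- effects[match(hairpins$feature_id, effects$feature_id), ]
  with_seed(seed, {
    counts <- simulate_counts(effects, design)
    types <- c("mature", "star", "loop", "anti")
    mrna <- if (n_mrna > 0) {
      stats::setNames(random_dna(n_mrna, 300), sprintf("mrna%02d", 1:n_mrna))
    } else character(0)
    clean_seqs <- character(0)
    contaminant_seqs <- character(0)
    breakdown_seqs <- character(0)
    reads <- vector("list", nrow(design))
    names(reads) <- design$library_id
    for (l in seq_len(nrow(design))) {
      lib_seqs <- character(0)
      lib_ids <- character(0)
      for (h in seq_len(nrow(hairpins))) {
        hp <- hairpins[h, ]
        n <- counts[h, l]
        if (n == 0) next
        sig <- CATEGORY_SIGNATURES[[hp$truth_category]]
        split <- as.vector(stats::rmultinom(1, n, sig))
        for (t in seq_along(types)) {
          if (split[t] == 0) next
          if (types[t] == "loop") {
            ins <- vapply(seq_len(split[t]), function(i)
              hairpin_read_seq(hp, "loop", genome), character(1))
          } else {
            ins <- rep(hairpin_read_seq(hp, types[t], genome), split[t])
          }
          lib_seqs <- c(lib_seqs, add_adapter(ins, adapter3, read_length))
          lib_ids <- c(lib_ids, sprintf("hp_%s_%s_%d", hp$feature_id,
                                        types[t], seq_len(split[t])))
          clean_seqs <- c(clean_seqs, unique(ins))
        }
      }
      n_hp <- length(lib_seqs)
      if (!is.null(contaminants) && contaminant_fraction > 0 && n_hp > 0) {
        n_cont <- stats::rpois(1, contaminant_fraction * n_hp /
                                 (1 - contaminant_fraction))
        if (n_cont > 0) {
          src <- sample(names(contaminants), n_cont, replace = TRUE)
          ins <- vapply(src, function(s) {
            len <- sample(19:24, 1)
            off <- sample.int(nchar(contaminants[[s]]) - len + 1, 1)
            substr(contaminants[[s]], off, off + len - 1)
          }, character(1), USE.NAMES = FALSE)
          lib_seqs <- c(lib_seqs, add_adapter(ins, adapter3, read_length))
          lib_ids <- c(lib_ids, sprintf("cont_%s_%d", src, seq_len(n_cont)))
          contaminant_seqs <- c(contaminant_seqs, unique(ins))
        }
      }
      if (n_mrna > 0) {
        # adapter-free fragments tiling each transcript (untrimmed partition)
        for (m in names(mrna)) {
          offs <- seq(1, nchar(mrna[[m]]) - read_length + 1, by = 6)
          frag <- substring(mrna[[m]], offs, offs + read_length - 1)
          lib_seqs <- c(lib_seqs, frag)
          lib_ids <- c(lib_ids, sprintf("%s_frag_%d", m, seq_along(frag)))
          # short breakdown products carrying the adapter
          boffs <- sample.int(nchar(mrna[[m]]) - 21 + 1, 3)
          bp <- substring(mrna[[m]], boffs, boffs + 20)
          lib_seqs <- c(lib_seqs, add_adapter(bp, adapter3, read_length))
          lib_ids <- c(lib_ids, sprintf("%s_bp_%d", m, seq_along(bp)))
          breakdown_seqs <- c(breakdown_seqs, unique(bp))
        }
      }
      if (n_junk > 0) {
        jn <- sample(1:5, n_junk, replace = TRUE)
        junk <- random_dna(n_junk, 21)
        lib_seqs <- c(lib_seqs, add_adapter(rep(junk, jn), adapter3,
                                            read_length))
        lib_ids <- c(lib_ids, sprintf("junk_%d", seq_len(sum(jn))))
      }
      if (n_background > 0) {
        bg <- random_dna(n_background, sample(19:26, n_background,
                                              replace = TRUE))
        lib_seqs <- c(lib_seqs, add_adapter(bg, adapter3, read_length))
        lib_ids <- c(lib_ids, sprintf("bg_%d", seq_len(n_background)))
      }
      reads[[l]] <- data.frame(
        read_id = sprintf("%s_%05d_%s", design$library_id[l],
                          seq_along(lib_seqs), lib_ids),
        sequence = lib_seqs,
        quality = strrep("I", nchar(lib_seqs)),
        stringsAsFactors = FALSE)
    }
    list(reads = reads, truth_counts = counts,
         clean_seqs = unique(clean_seqs),
         contaminant_seqs = unique(contaminant_seqs),
         breakdown_seqs = unique(breakdown_seqs),
         mrna = mrna)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper tying together genome construction, hairpin planting,
#' effect specification and read simulation; the default layout is a reduced
#' 2 genotypes (1 tolerant, 1 sensitive) x 2 tissues x 2 treatments x 3
#' replicates design. All randomness flows from the single `seed`.
#'
#' @param n_category_a hairpins planted with the true-miRNA coverage
#'   signature (category A).
#' @param decoy_categories truth categories of additional planted decoys.
#' @param genome_length total genome size (single contig).
#' @param design study design; default the reduced test design.
#' @param baseline_mean expected hairpin read count per library.
#' @param interaction_log2fc interaction effect planted on category-A
#'   hairpins (0 = null).
#' @param n_interaction number of category-A hairpins receiving the
#'   interaction effect.
#' @param dispersion negative-binomial dispersion.
#' @param known_fraction fraction of planted mature sequences included in
#'   the mature-reference set; the remainder are "novel" (no reference
#'   match) to downstream annotation.
#' @param seed master RNG seed.
#' @param ... passed through to [simulate_reads()].
#' @return list with design, genome, hairpins, effects, contaminants,
#'   mature_refs (planted matures plus decoy references) and every element
#'   returned by [simulate_reads()].
#' @export
simulate_study <- function(n_category_a = 8, decoy_categories = c("E", "H"),
                           genome_length = 50000,
                           design = make_design(c("Tamaroi", "EGA_Bellaroi"),
                                                tolerant = "Tamaroi",
                                                replicates = 3),
                           baseline_mean = 15, interaction_log2fc = 0,
                           n_interaction = 0, dispersion = 0.1,
                           known_fraction = 1, seed = NULL, ...) {
  with_seed(seed, {
    genome <- make_genome(1, genome_length)
    categories <- c(rep("A", n_category_a), decoy_categories)
    planted <- plant_hairpins(genome, categories)
    ints <- rep(0, nrow(planted$hairpins))
    if (n_interaction > 0) ints[seq_len(n_interaction)] <- interaction_log2fc
    effects <- make_effects(planted$hairpins$feature_id,
                            baseline_mean = baseline_mean,
                            interaction_log2fc = ints,
                            dispersion = dispersion)
    contaminants <- make_contaminants()
    sim <- simulate_reads(design, planted$genome, planted$hairpins, effects,
                          contaminants = contaminants, ...)
    n_hp <- nrow(planted$hairpins)
    known <- sort(sample(n_hp, round(known_fraction * n_hp)))
    mature_refs <- stats::setNames(
      c(planted$hairpins$mature_seq[known], random_dna(10, 21)),
      c(sprintf("mir_%s", planted$hairpins$feature_id[known]),
        sprintf("decoy_ref_%02d", 1:10)))
    c(list(design = design, genome = planted$genome,
           hairpins = planted$hairpins, effects = effects,
           contaminants = contaminants, mature_refs = mature_refs), sim)
  })
}
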