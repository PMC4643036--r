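# De novo pre-miRNA hairpin discovery: nominate loci from opposite-strand
# perfect/imperfect read alignments, validate fold-back structure, compute
# the three Boolean coverage metrics, assign categories A-H, and split known
# from novel candidates.

#' Find genomic alignments of unique reads
#'
#' Perfect mode reports every 0-mismatch ungapped occurrence on either
#' strand; imperfect mode every occurrence with 2-5 mismatches (1-mismatch
#' hits are excluded, matching the printed range). Exhaustive over offsets.
#'
#' @param reads character vector of unique 19-26 nt read sequences.
#' @param genome named character vector of contigs.
#' @param mode "perfect" or "imperfect".
#' @return data.frame of hits: `query`, `ref` (contig), `start`, `end`
#'   (0-based half-open, forward strand), `strand`, `mismatches`.
#' @export
find_alignments <- function(reads, genome, mode = c("perfect", "imperfect")) {
  mode <- match.arg(mode)
  if (mode == "perfect") {
    map_ungapped(reads, genome, max_mismatch = 0)
  } else {
    map_ungapped(reads, genome, max_mismatch = 5, min_mismatch = 2)
  }
}

#' Enumerate candidate hairpin locus pairs
#'
#' For each read, every (perfect, imperfect) alignment pair on the same
#' contig in opposite orientations whose inner-edge gap (the prospective loop
#' plus spacer) lies in `[gap_min, gap_max]` nominates a region spanning both
#' alignments extended by `flank` bp and clipped to the contig. Duplicate
#' regions are collapsed to a non-redundant set; each region keeps the
#' perfect hit with the highest read support as its mature-arm
#' representative.
#'
#' @param perfect,imperfect hit tables from [find_alignments()].
#' @param gap_min,gap_max inner-edge separation bounds (bp).
#' @param flank extension (bp) on both sides of the paired alignments.
#' @param contig_lengths named integer vector of contig lengths (for
#'   clipping).
#' @param read_counts optional named vector (by read sequence) of total
#'   counts, used to pick the representative mature arm of a collapsed
#'   region; defaults to 1 per read.
#' @param collapse collapse duplicate regions to a non-redundant set
#'   (default); `FALSE` returns every accepted (perfect, imperfect) pair.
#' @return data.frame with `contig`, `region_start`, `region_end` (0-based
#'   half-open), `mature_start`, `mature_end`, `strand` (of the perfect hit),
#'   `query`, `inner_gap`.
#' @export
enumerate_locus_pairs <- function(perfect, imperfect, gap_min = 54,
                                  gap_max = 1000, flank = 20,
                                  contig_lengths = NULL, read_counts = NULL,
                                  collapse = TRUE) {
  if (nrow(perfect) == 0 || nrow(imperfect) == 0) {
    return(data.frame(contig = character(0), region_start = integer(0),
                      region_end = integer(0), mature_start = integer(0),
                      mature_end = integer(0), strand = character(0),
                      query = character(0), inner_gap = integer(0),
                      stringsAsFactors = FALSE))
  }
  pairs <- merge(perfect, imperfect, by = c("query", "ref"),
                 suffixes = c("_p", "_i"))
  if (nrow(pairs) == 0) return(enumerate_locus_pairs(perfect[0, ], imperfect))
  pairs <- pairs[pairs$strand_p != pairs$strand_i, , drop = FALSE]
  gap <- ifelse(pairs$start_p >= pairs$end_i,
                pairs$start_p - pairs$end_i,
                pairs$start_i - pairs$end_p)
  keep <- gap >= gap_min & gap <= gap_max &
    (pairs$start_p >= pairs$end_i | pairs$start_i >= pairs$end_p)
  pairs <- pairs[keep, , drop = FALSE]
  gap <- gap[keep]
  if (nrow(pairs) == 0) {
    return(enumerate_locus_pairs(perfect[0, ], imperfect))
  }
  rs <- pmin(pairs$start_p, pairs$start_i) - flank
  re <- pmax(pairs$end_p, pairs$end_i) + flank
  rs <- pmax(rs, 0L)
  if (!is.null(contig_lengths)) {
    re <- pmin(re, contig_lengths[pairs$ref])
  }
  out <- data.frame(contig = pairs$ref, region_start = as.integer(rs),
                    region_end = as.integer(re),
                    mature_start = pairs$start_p, mature_end = pairs$end_p,
                    strand = pairs$strand_p, query = pairs$query,
                    inner_gap = as.integer(gap), stringsAsFactors = FALSE)
  if (!collapse) {
    out <- out[order(out$contig, out$region_start, out$region_end,
                     out$mature_start, out$query), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  # collapse duplicate regions, keeping the best-supported mature arm
  support <- if (is.null(read_counts)) rep(1, nrow(out)) else
    as.numeric(read_counts[out$query])
  key <- paste(out$contig, out$region_start, out$region_end)
  ord <- order(key, -support)
  out <- out[ord[!duplicated(key[ord])], , drop = FALSE]
  out <- out[order(out$contig, out$region_start, out$region_end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fold a candidate hairpin by maximum-scoring base pairing
#'
#' Computes the optimal Watson-Crick + G/U wobble nested pairing (minimum
#' loop 3 nt) by dynamic programming, scoring `pair_score` per base pair and
#' charging `helix_penalty` for every helix opening (each maximal run of
#' stacked pairs, so bulges and interior loops are re-charged). The penalty
#' makes the long arm-to-arm duplex of a genuine pre-miRNA outscore the
#' scattered short helices random sequence always offers;
#' `helix_penalty = 0` gives plain maximum base pairing. The fold is only a
#' fold-back plausibility gate, not an energy model. Derives mature-arm
#' statistics
#' against a supplied mature interval from the best antiparallel duplex the
#' mature arm can form with any other same-length window of the hairpin
#' (the miRNA/miRNA* duplex a biogenesis-compatible stem-loop must offer):
#' number of unpaired mature bases in that duplex, the largest internal run
#' of unpaired mature bases (bulge/interior loop), whether an opposite-arm
#' duplex window exists at all (`arm_span_paired`), and the fraction of the
#' mature arm paired within the duplex (`dominant_stem_frac`).
#'
#' @param seq hairpin sequence (ACGT/U), 4-1100 nt.
#' @param mature optional c(start, end), 1-based inclusive interval of the
#'   mature arm within `seq`.
#' @param min_loop minimum hairpin loop (unpaired nt); also the minimum
#'   separation between the mature arm and its duplex window.
#' @param pair_score,helix_penalty integer scoring weights for the global
#'   fold.
#' @return list with `structure` (dot-bracket), `n_pairs`, `score`,
#'   `partner` (1-based pairing partner per position, 0 if unpaired), and,
#'   when `mature` is given: `mature_unpaired`, `largest_bulge`,
#'   `arm_span_paired`, `dominant_stem_frac`, `duplex_start` (1-based start
#'   of the best duplex window).
#' @export
fold_hairpin <- function(seq, mature = NULL, min_loop = 3, pair_score = 2,
                         helix_penalty = 5) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  stopifnot(n >= 4, n <= 1100)
  res <- .nussinov_fold(seq, min_loop, pair_score, helix_penalty)
  out <- list(structure = res$structure, n_pairs = res$n_pairs,
              score = res$score, partner = res$partner)
  if (!is.null(mature)) {
    out <- c(out, duplex_stats(seq, mature, min_loop = min_loop))
  }
  out
}

# Pairing table for the duplex scan (Watson-Crick + G/U wobble).
.pairs_ok <- matrix(FALSE, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                                 c("A", "C", "G", "T")))
.pairs_ok["A", "T"] <- .pairs_ok["T", "A"] <- TRUE
.pairs_ok["G", "C"] <- .pairs_ok["C", "G"] <- TRUE
.pairs_ok["G", "T"] <- .pairs_ok["T", "G"] <- TRUE

# Best antiparallel duplex between the mature arm and any other same-length
# window of the hairpin separated by at least `min_loop` nt: the window
# minimizing unpaired mature bases (tie: the most distal window).
duplex_stats <- function(seq, mature, min_loop = 3) {
  n <- nchar(seq)
  L <- mature[2] - mature[1] + 1
  chars <- strsplit(seq, "")[[1]]
  m <- chars[mature[1]:mature[2]]
  starts <- setdiff(seq_len(n - L + 1),
                    seq(max(1, mature[1] - L - min_loop + 1),
                        min(n - L + 1, mature[2] + min_loop)))
  if (length(starts) == 0) {
    return(list(mature_unpaired = L, largest_bulge = L,
                arm_span_paired = FALSE, dominant_stem_frac = 0,
                duplex_start = NA_integer_))
  }
  best_mm <- L + 1L
  best_s <- NA_integer_
  best_v <- rep(FALSE, L)
  for (s in starts) {
    w <- chars[(s + L - 1):s] # antiparallel: mature 5' pairs window 3'
    v <- .pairs_ok[cbind(m, w)]
    mm <- sum(!v)
    better <- mm < best_mm ||
      (mm == best_mm && !is.na(best_s) &&
         abs(s - mature[1]) > abs(best_s - mature[1]))
    if (better) {
      best_mm <- mm
      best_s <- s
      best_v <- v
    }
  }
  r <- rle(!best_v)
  runs <- which(r$values)
  interior <- runs[runs > 1 & runs < length(r$values)]
  list(mature_unpaired = as.integer(best_mm),
       largest_bulge = if (length(interior) > 0)
         as.integer(max(r$lengths[interior])) else 0L,
       arm_span_paired = TRUE,
       dominant_stem_frac = (L - best_mm) / L,
       duplex_start = best_s)
}

#' Structural gate for hairpin candidates
#'
#' Passes a folded candidate when the mature arm behaves like one arm of a
#' miRNA/miRNA* duplex: at most `max_unpaired` unpaired mature bases, no
#' internal unpaired run (bulge) longer than `max_bulge`, mature bases
#' pairing predominantly outside the mature arm, and at least
#' `min_stem_frac` of the mature arm paired within a single dominant stem.
#'
#' @param fold result of [fold_hairpin()] computed with a mature interval.
#' @param max_unpaired,max_bulge,min_stem_frac gate thresholds.
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failed checks, empty when passing).
#' @export
mircheck_like <- function(fold, max_unpaired = 4, max_bulge = 2,
                          min_stem_frac = 0.6) {
  stopifnot(!is.null(fold$mature_unpaired))
  reasons <- character(0)
  if (fold$mature_unpaired > max_unpaired) reasons <- c(reasons, "mature_unpaired")
  if (fold$largest_bulge > max_bulge) reasons <- c(reasons, "bulge")
  if (!isTRUE(fold$arm_span_paired)) reasons <- c(reasons, "arm_span")
  if (fold$dominant_stem_frac < min_stem_frac) reasons <- c(reasons, "stem")
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Read-coverage metrics over a candidate region
#'
#' Each overlapping read is assigned to the subregion holding the majority
#' of its bases: the 5' terminal `window` bp, the 3' terminal `window` bp,
#' or the loop (everything strictly between the windows; empty for regions
#' of at most `2 * window` bp, where the loop metric is vacuously true).
#' Exact ties go to the terminal window. Fractions are weighted by read
#' counts.
#'
#' @param region c(start, end), 0-based half-open region on the contig.
#' @param hits data.frame of alignments overlapping the region (`start`,
#'   `end` 0-based half-open, `strand`, optionally `count`).
#' @param window terminal window size (bp).
#' @return list with `strand_bias`, `terminal_fraction`, `loop_fraction`,
#'   and `booleans` (strand_bias >= 0.95, terminal_fraction >= 0.95,
#'   loop_fraction <= 0.05).
#' @export
coverage_metrics <- function(region, hits, window = 50) {
  if (nrow(hits) == 0) stop("coverage_metrics: no overlapping reads")
  counts <- if ("count" %in% colnames(hits)) hits$count else rep(1, nrow(hits))
  total <- sum(counts)
  strand_bias <- max(sum(counts[hits$strand == "+"]),
                     sum(counts[hits$strand == "-"])) / total
  t5 <- c(region[1], min(region[1] + window, region[2]))
  t3 <- c(max(region[2] - window, region[1]), region[2])
  ov <- function(lo, hi) pmax(0, pmin(hits$end, hi) - pmax(hits$start, lo))
  o5 <- ov(t5[1], t5[2])
  o3 <- ov(t3[1], t3[2])
  olp <- ov(t5[2], t3[1])
  # majority assignment, ties to the terminal windows
  assign <- ifelse(o5 >= olp & o5 >= o3, "t5",
                   ifelse(o3 >= olp, "t3", "loop"))
  f5 <- sum(counts[assign == "t5"]) / total
  f3 <- sum(counts[assign == "t3"]) / total
  floop <- sum(counts[assign == "loop"]) / total
  metrics <- list(strand_bias = strand_bias,
                  terminal_fraction = max(f5, f3),
                  loop_fraction = floop)
  metrics$booleans <- c(strand = strand_bias >= 0.95,
                        terminal = metrics$terminal_fraction >= 0.95,
                        loop = floop <= 0.05)
  metrics
}

#' Map the three Boolean coverage metrics to a category A-H
#'
#' The printed truth table: A = YYY, B = YYN, C = YNY, D = YNN, E = NYY,
#' F = NYN, G = NNY, H = NNN (order: strand bias, terminal concentration,
#' loop depletion).
#'
#' @param strand,terminal,loop logical scalars or vectors (recycled).
#' @return character vector of categories.
#' @export
assign_category <- function(strand, terminal, loop) {
  idx <- 4L * (1L - as.integer(strand)) + 2L * (1L - as.integer(terminal)) +
    (1L - as.integer(loop)) + 1L
  LETTERS[1:8][idx]
}

#' Match a hairpin sequence against known mature miRNAs
#'
#' A reference matches when it occurs verbatim as a substring of the hairpin
#' sense-strand sequence (U normalized to T). Candidates with at least one
#' match are "known", the rest "novel".
#'
#' @param hairpin_seq hairpin sequence (sense strand).
#' @param mature_refs named character vector of mature miRNA references.
#' @param both_strands also search the reverse complement of the hairpin.
#' @return character vector of matching reference names (possibly empty).
#' @export
match_known <- function(hairpin_seq, mature_refs, both_strands = FALSE) {
  refs <- normalize_seq(mature_refs)
  hp <- normalize_seq(hairpin_seq)
  hit <- vapply(refs, function(r) grepl(r, hp, fixed = TRUE), logical(1))
  if (both_strands) {
    rc <- revcomp(hp)
    hit <- hit | vapply(refs, function(r) grepl(r, rc, fixed = TRUE),
                        logical(1))
  }
  names(refs)[hit]
}

#' Discover pre-miRNA hairpin candidates
#'
#' Composition of the discovery stages: genomic perfect and imperfect (2-5
#' mismatch) alignment of the filtered 19-26 nt unique reads, opposite-
#' strand locus pairing with a 54-1000 bp inner gap, region extension and
#' collapsing, fold-back validation, coverage metrics over the perfect
#' alignments, category assignment and known/novel splitting. Candidates are
#' sorted by (category, contig, start).
#'
#' @param tbl filtered unique-read table (19-26 nt sequences).
#' @param genome named character vector of contigs.
#' @param mature_refs named character vector of known mature miRNAs.
#' @param gap_min,gap_max inner-gap bounds (bp).
#' @param flank region extension (bp).
#' @param require_mircheck drop candidates failing the structural gate
#'   (the printed pipeline's RNAFold/miRcheck step).
#' @param match_both_strands search both hairpin strands for known matches.
#' @return data.frame of hairpin candidates: identifier, contig, start, end
#'   (1-based inclusive), strand, category, the three metric fractions and
#'   booleans, mircheck fields, status and known matches.
#' @export
discover_hairpins <- function(tbl, genome, mature_refs = NULL, gap_min = 54,
                              gap_max = 1000, flank = 20,
                              require_mircheck = TRUE,
                              match_both_strands = FALSE) {
  reads <- tbl$sequence[nchar(tbl$sequence) >= 19 & nchar(tbl$sequence) <= 26]
  reads <- sort(reads) # input-order invariance
  counts <- stats::setNames(tbl$total_count, tbl$sequence)[reads]
  perfect <- find_alignments(reads, genome, "perfect")
  # restrict the imperfect scan to reads and contigs with a perfect hit
  sub_reads <- unique(perfect$query)
  sub_contigs <- unique(perfect$ref)
  imperfect <- if (length(sub_reads) > 0) {
    find_alignments(sub_reads, genome[sub_contigs], "imperfect")
  } else perfect[0, ]
  regions <- enumerate_locus_pairs(perfect, imperfect, gap_min = gap_min,
                                   gap_max = gap_max, flank = flank,
                                   contig_lengths = nchar(genome),
                                   read_counts = counts)
  if (nrow(regions) == 0) {
    return(data.frame(identifier = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  }
  perfect$count <- counts[perfect$query]
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    seq_fwd <- substr(genome[[r$contig]], r$region_start + 1, r$region_end)
    # hairpin sense strand = strand of the representative mature-arm hit
    if (r$strand == "+") {
      hp_seq <- seq_fwd
      m_start <- r$mature_start - r$region_start + 1L
      m_end <- r$mature_end - r$region_start
    } else {
      hp_seq <- revcomp(seq_fwd)
      m_start <- r$region_end - r$mature_end + 1L
      m_end <- r$region_end - r$mature_start
    }
    fold <- fold_hairpin(hp_seq, mature = c(m_start, m_end))
    gate <- mircheck_like(fold)
    if (require_mircheck && !gate$pass) next
    over <- perfect[perfect$ref == r$contig &
                      perfect$end > r$region_start &
                      perfect$start < r$region_end, , drop = FALSE]
    if (nrow(over) == 0) next
    met <- coverage_metrics(c(r$region_start, r$region_end), over)
    matches <- if (is.null(mature_refs)) character(0) else
      match_known(hp_seq, mature_refs, both_strands = match_both_strands)
    out[[i]] <- data.frame(
      identifier = format_hairpin_identifier(r$contig, r$region_start + 1L,
                                             r$region_end, m_start,
                                             m_end - m_start + 1L),
      contig = r$contig, start = r$region_start + 1L, end = r$region_end,
      strand = r$strand, sequence = hp_seq,
      mature_start = m_start, mature_length = m_end - m_start + 1L,
      strand_bias = met$strand_bias,
      terminal_fraction = met$terminal_fraction,
      loop_fraction = met$loop_fraction,
      metric_strand = met$booleans[["strand"]],
      metric_terminal = met$booleans[["terminal"]],
      metric_loop = met$booleans[["loop"]],
      category = assign_category(met$booleans[["strand"]],
                                 met$booleans[["terminal"]],
                                 met$booleans[["loop"]]),
      mircheck_pass = gate$pass,
      mircheck_reasons = paste(gate$reasons, collapse = ";"),
      n_pairs = fold$n_pairs,
      status = if (length(matches) > 0) "known" else "novel",
      known_matches = paste(matches, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(identifier = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$category, res$contig, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
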