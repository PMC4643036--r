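# Independent brute-force oracles. These deliberately share no code with the
# implementation: plain R loops and character comparisons only.

# Every offset of `query` (and its reverse complement) against each reference
# with Hamming distance in [min_mm, max_mm]; full-overlap alignments only.
brute_hamming_hits <- function(queries, refs, max_mm, min_mm = 0) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  rows <- list()
  for (q in unique(queries)) {
    for (st in c("+", "-")) {
      p <- if (st == "+") q else rc(q)
      pc <- strsplit(p, "")[[1]]
      lp <- length(pc)
      for (ri in seq_along(refs)) {
        rch <- strsplit(refs[[ri]], "")[[1]]
        if (lp > length(rch)) next
        for (off in 0:(length(rch) - lp)) {
          mm <- sum(pc != rch[(off + 1):(off + lp)])
          if (mm >= min_mm && mm <= max_mm) {
            rows[[length(rows) + 1]] <- data.frame(
              query = q, ref = names(refs)[ri], start = off, end = off + lp,
              strand = st, mismatches = mm, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(query = character(0), ref = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  do.call(rbind, rows)
}

# canonical ordering for hit-set comparison
sort_hits <- function(h) {
  h <- h[order(h$query, h$ref, h$start, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# All (perfect, imperfect) pairs by explicit double loop.
brute_locus_pairs <- function(perfect, imperfect, gap_min = 54,
                              gap_max = 1000, flank = 20,
                              contig_lengths = NULL) {
  rows <- list()
  for (i in seq_len(nrow(perfect))) {
    for (j in seq_len(nrow(imperfect))) {
      p <- perfect[i, ]
      q <- imperfect[j, ]
      if (p$query != q$query || p$ref != q$ref) next
      if (p$strand == q$strand) next
      gap <- if (p$start >= q$end) p$start - q$end
             else if (q$start >= p$end) q$start - p$end
             else -1
      if (gap < gap_min || gap > gap_max) next
      rs <- max(min(p$start, q$start) - flank, 0)
      re <- max(p$end, q$end) + flank
      if (!is.null(contig_lengths)) re <- min(re, contig_lengths[[p$ref]])
      rows[[length(rows) + 1]] <- data.frame(
        contig = p$ref, region_start = rs, region_end = re,
        mature_start = p$start, mature_end = p$end, strand = p$strand,
        query = p$query, inner_gap = gap, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(contig = character(0), region_start = integer(0),
                      region_end = integer(0), mature_start = integer(0),
                      mature_end = integer(0), strand = character(0),
                      query = character(0), inner_gap = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$region_start, out$region_end,
                   out$mature_start, out$query), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive enumeration of every nested structure (min loop 3) and its
# score under the package's objective (pair_score per pair, helix_penalty
# per maximal stack run); returns the optimum score and the maximum pair
# count among optimal-score structures.
enum_structures <- function(chars, i, j) {
  if (j - i < 4) return(list(list()))
  out <- enum_structures(chars, i + 1, j)
  pairable <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  for (k in seq(i + 4, j)) {
    if (!pairable(chars[i], chars[k])) next
    inner <- enum_structures(chars, i + 1, k - 1)
    outer <- if (k + 1 <= j) enum_structures(chars, k + 1, j) else list(list())
    for (a in inner) for (b in outer) {
      out[[length(out) + 1]] <- c(list(c(i, k)), a, b)
    }
  }
  out
}

score_structure <- function(pairs, pair_score = 2, helix_penalty = 5) {
  if (length(pairs) == 0) return(c(score = 0, n_pairs = 0))
  m <- do.call(rbind, pairs)
  key <- paste(m[, 1], m[, 2])
  stacked <- paste(m[, 1] - 1, m[, 2] + 1) %in% key
  c(score = pair_score * nrow(m) - helix_penalty * sum(!stacked),
    n_pairs = nrow(m))
}

brute_fold_best <- function(seq, pair_score = 2, helix_penalty = 5) {
  chars <- strsplit(seq, "")[[1]]
  structs <- enum_structures(chars, 1, length(chars))
  sc <- vapply(structs, score_structure, numeric(2),
               pair_score = pair_score, helix_penalty = helix_penalty)
  best <- max(sc["score", ])
  c(score = best, n_pairs = max(sc["n_pairs", sc["score", ] == best]))
}

# Independently coded differential-abundance rule evaluator (scalar).
de_rule_oracle <- function(a, b, zero_floor = 0.01, min_rpm = 10,
                           fc_threshold = 1.5) {
  if (a == 0) a <- zero_floor
  if (b == 0) b <- zero_floor
  fc <- if (a > b) a / b else b / a
  called <- FALSE
  if (max(a, b) >= min_rpm && fc > fc_threshold) called <- TRUE
  list(fold_change = fc, called = called,
       direction = if (a > b) "a" else if (b > a) "b" else "tie")
}

random_dna_str <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
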