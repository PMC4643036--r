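# Adapter trimming, partitioning, collapsing and the filter cascade.

test_that("adapter trimming finds prefix matches of at least min_overlap", {
  adapter <- "AGATCGGAAGAG"
  r <- trim_adapter(c("ACGTACGTAGATCGGA", # 8 nt adapter prefix at the end
                      "ACGTACGTACGTACGT", # no adapter
                      adapter), adapter, min_overlap = 8)
  expect_equal(r$sequence[1], "ACGTACGT")
  expect_true(r$trimmed[1])
  expect_equal(r$sequence[2], "ACGTACGTACGTACGT")
  expect_false(r$trimmed[2])
  expect_equal(r$sequence[3], "") # read equal to adapter -> empty insert
  expect_true(r$trimmed[3])
  # a 7 nt overlap is treated as absent
  r2 <- trim_adapter("ACGTACGTAGATCGG", adapter, min_overlap = 8)
  expect_false(r2$trimmed)
})

test_that("partitioning separates the 19-26, untrimmed and 15-50 sets", {
  tr <- data.frame(sequence = c(strrep("A", 21), strrep("C", 30),
                                strrep("G", 40), strrep("T", 10),
                                "ACGNACGTACGTACGTACGTA"),
                   trimmed = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  p <- partition_reads(tr)
  expect_equal(p$hairpin_set, strrep("A", 21))
  expect_equal(p$untrimmed_set, strrep("G", 40))
  # trimmed 30-mer is excluded from the hairpin set but kept for the wide
  # 15-50 nt window; the 10-mer is outside both; N-containing reads dropped
  expect_setequal(p$approach1_set, c(strrep("A", 21), strrep("C", 30)))
  expect_equal(p$dropped, "ACGNACGTACGTACGTACGTA")
})

test_that("collapsing conserves per-library read counts", {
  des <- parse_design(data.frame(
    library_id = c("L1", "L2"), genotype = "g", tolerance = 1,
    tissue = "head", treatment = "control", replicate = 1:2))
  tbl <- collapse_unique(list(L1 = c("ACGT", "ACGT", "TTTT"),
                              L2 = c("ACGT")), des)
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$L1[tbl$sequence == "ACGT"], 2L)
  expect_equal(tbl$L2[tbl$sequence == "ACGT"], 1L)
  expect_equal(tbl$L1[tbl$sequence == "TTTT"], 1L)
  expect_equal(tbl$total_count, c(3L, 1L))

  expect_error(collapse_unique(list(LX = "AA"), des), "unknown library_id")

  set.seed(8)
  reads <- sample(random_dna_str(300, 21), 10000, replace = TRUE)
  half <- split(reads, rep(c("L1", "L2"), each = 5000))
  big <- collapse_unique(half, des)
  expect_equal(sum(big$total_count), 10000)
  expect_equal(sum(big$L1), 5000)
})

test_that("low-abundance filtering removes totals of at most 5", {
  des <- parse_design(data.frame(
    library_id = "L1", genotype = "g", tolerance = 1, tissue = "head",
    treatment = "control", replicate = 1))
  tbl <- collapse_unique(list(L1 = rep(c("AAAA", "CCCC"), c(5, 6))), des)
  out <- filter_low_abundance(tbl)
  expect_equal(out$sequence, "CCCC")
  expect_equal(attr(out, "removed")$sequence, "AAAA")
  empty <- filter_low_abundance(tbl[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("map_ungapped agrees with the brute-force Hamming oracle", {
  set.seed(15)
  refs <- stats::setNames(random_dna_str(3, 400), c("r1", "r2", "r3"))
  # queries: exact substrings, mutated substrings, and random sequences
  pick <- function(mut) {
    ref <- sample(refs, 1)
    off <- sample.int(nchar(ref) - 21, 1)
    s <- substr(ref, off, off + 20)
    chars <- strsplit(s, "")[[1]]
    for (p in sample(21, mut)) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
    paste(chars, collapse = "")
  }
  queries <- c(vapply(1:15, function(i) pick(0), character(1)),
               vapply(1:15, function(i) pick(2), character(1)),
               vapply(1:15, function(i) pick(3), character(1)),
               random_dna_str(15, 21))
  got <- sort_hits(map_ungapped(queries, refs, max_mismatch = 2))
  want <- sort_hits(brute_hamming_hits(queries, refs, max_mm = 2))
  expect_equal(got, want)

  # every exact-substring query hits at 0 mismatches
  expect_true(all(vapply(queries[1:15], function(q) {
    any(got$query == q & got$mismatches == 0)
  }, logical(1))))

  # query longer than every reference: no hit, not an error
  long <- strrep("A", 500)
  expect_equal(nrow(map_ungapped(long, refs, max_mismatch = 2)), 0)
})

test_that("contaminant filtering removes truth-tagged contaminants only", {
  st <- tiny_study()
  des1 <- parse_design(data.frame(
    library_id = "L1", genotype = "g", tolerance = 1, tissue = "head",
    treatment = "control", replicate = 1))
  clean <- st$clean_seqs[nchar(st$clean_seqs) == 21][1:20]
  cont <- st$contaminant_seqs[1:min(20, length(st$contaminant_seqs))]
  tbl <- collapse_unique(list(L1 = c(clean, cont)), des1)
  out <- filter_contaminants(tbl, st$contaminants)
  expect_setequal(out$sequence, clean)
  expect_equal(nrow(attr(out, "removed")), length(cont))
  expect_equal(sum(attr(out, "removal_log")), length(cont))
})

test_that("the de Bruijn assembler recovers a tiled transcript and the
           breakdown filter removes its fragments", {
  set.seed(21)
  mrna <- random_dna_str(1, 60)
  offs <- seq(1, 60 - 36 + 1, by = 4)
  frags <- substring(mrna, offs, offs + 35) # overlapping untrimmed fragments
  contigs <- assemble_contigs(frags, k = 17)
  expect_true(any(nchar(contigs) >= 50))
  expect_true(mrna %in% contigs)

  des1 <- parse_design(data.frame(
    library_id = "L1", genotype = "g", tolerance = 1, tissue = "head",
    treatment = "control", replicate = 1))
  breakdown <- substr(mrna, 20, 40) # a 21-mer substring of the transcript
  clean <- random_dna_str(5, 21)
  tbl <- collapse_unique(list(L1 = c(breakdown, clean)), des1)
  out <- assemble_and_filter_breakdown(tbl, frags)
  expect_setequal(out$sequence, clean)
  expect_equal(attr(out, "removed")$sequence, breakdown)

  # no untrimmed reads -> no contigs -> table unchanged
  out2 <- assemble_and_filter_breakdown(tbl, character(0))
  expect_setequal(out2$sequence, tbl$sequence)

  # contigs shorter than 50 bp are not used for filtering
  short_frags <- substring(mrna, seq(1, 14, by = 4), seq(1, 14, by = 4) + 35)
  ctg <- assemble_contigs(short_frags, k = 17)
  expect_true(all(nchar(ctg) < 50))
  out3 <- assemble_and_filter_breakdown(tbl, short_frags)
  expect_setequal(out3$sequence, tbl$sequence)
})

test_that("the full cascade is monotone with high recall and low leakage", {
  st <- tiny_study()
  pp <- tiny_preprocessed()
  # monotone row counts along the printed filter order
  expect_true(all(diff(pp$log$rows) <= 0))
  tbl <- pp$hairpin_table
  # recall of clean planted reads that clear the abundance rule
  all_reads <- unlist(lapply(st$reads, `[[`, "sequence"), use.names = FALSE)
  trimmed <- trim_adapter(all_reads, "AGATCGGAAGAGCACACGTCT")
  counts <- table(trimmed$sequence)
  eligible <- st$clean_seqs[nchar(st$clean_seqs) >= 19 &
                              nchar(st$clean_seqs) <= 26]
  eligible <- eligible[counts[eligible] > 5]
  expect_gte(mean(eligible %in% tbl$sequence), 0.99)
  # contaminant leakage
  cont <- st$contaminant_seqs[nchar(st$contaminant_seqs) >= 19 &
                                nchar(st$contaminant_seqs) <= 26]
  expect_lte(mean(cont %in% tbl$sequence), 0.01)
  # breakdown products are gone
  expect_false(any(st$breakdown_seqs %in% tbl$sequence))
})
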