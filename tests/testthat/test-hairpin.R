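# Hairpin discovery: genomic alignment, locus pairing, folding, the
# structural gate, coverage metrics and category assignment.

test_that("find_alignments reports planted perfect and imperfect hits", {
  set.seed(51)
  g <- make_genome(1, 2000, seed = 51)
  read <- substr(g[[1]], 501, 521)
  perfect <- find_alignments(read, g, "perfect")
  expect_equal(nrow(perfect), 1)
  expect_equal(perfect$start, 500L)
  expect_equal(perfect$strand, "+")
  expect_equal(perfect$mismatches, 0L)

  # plant the reverse complement with 3 substitutions elsewhere
  rc <- strsplit(revcomp(read), "")[[1]]
  for (p in c(4, 10, 16)) rc[p] <- setdiff(c("A", "C", "G", "T"), rc[p])[1]
  g2 <- g
  substr(g2[[1]], 1001, 1021) <- paste(rc, collapse = "")
  imp <- find_alignments(read, g2, "imperfect")
  hit <- imp[imp$start == 1000L, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$strand, "-")
  expect_equal(hit$mismatches, 3L)

  # a 1-mismatch occurrence is excluded from the imperfect set
  one <- strsplit(read, "")[[1]]
  one[11] <- setdiff(c("A", "C", "G", "T"), one[11])[1]
  g3 <- g
  substr(g3[[1]], 1501, 1521) <- paste(one, collapse = "")
  imp3 <- find_alignments(read, g3, "imperfect")
  expect_false(any(imp3$start == 1500L))
})

test_that("alignments agree with the brute-force scan over both strands", {
  set.seed(52)
  g <- stats::setNames(random_dna_str(2, 600), c("c1", "c2"))
  reads <- c(substr(g[1], 100, 120), substr(g[2], 300, 320),
             revcomp(substr(g[1], 200, 220)), random_dna_str(10, 21))
  got_p <- sort_hits(find_alignments(reads, g, "perfect"))
  want_p <- sort_hits(brute_hamming_hits(reads, g, max_mm = 0))
  expect_equal(got_p, want_p)
  got_i <- sort_hits(find_alignments(reads, g, "imperfect"))
  want_i <- sort_hits(brute_hamming_hits(reads, g, max_mm = 5, min_mm = 2))
  expect_equal(got_i, want_i)
})

test_that("locus pairing applies orientation and gap constraints", {
  perfect <- data.frame(query = "q", ref = "c1", start = 100L, end = 121L,
                        strand = "+", mismatches = 0L)
  imp <- function(start, end, strand) {
    data.frame(query = "q", ref = "c1", start = start, end = end,
               strand = strand, mismatches = 3L)
  }
  ok <- enumerate_locus_pairs(perfect, imp(181L, 202L, "-"))
  expect_equal(nrow(ok), 1)
  expect_equal(ok$inner_gap, 60L)
  expect_equal(ok$region_start, 80L)
  expect_equal(ok$region_end, 222L)

  expect_equal(nrow(enumerate_locus_pairs(perfect, imp(161L, 182L, "-"))), 0)
  expect_equal(nrow(enumerate_locus_pairs(perfect, imp(181L, 202L, "+"))), 0)
  # overlapping intervals are rejected
  expect_equal(nrow(enumerate_locus_pairs(perfect, imp(110L, 131L, "-"))), 0)
})

test_that("locus pairing equals the brute-force all-pairs oracle", {
  set.seed(53)
  for (rep in 1:10) {
    n_reads <- 8
    reads <- sprintf("q%02d", 1:n_reads)
    mk_hits <- function(n) {
      start <- sample.int(4000, n, replace = TRUE)
      data.frame(query = sample(reads, n, replace = TRUE),
                 ref = sample(c("c1", "c2"), n, replace = TRUE),
                 start = start, end = start + 21L,
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 mismatches = 0L, stringsAsFactors = FALSE)
    }
    perfect <- mk_hits(20)
    imperfect <- mk_hits(30)
    imperfect$mismatches <- 3L
    lens <- c(c1 = 4200L, c2 = 4200L)
    got <- enumerate_locus_pairs(perfect, imperfect, contig_lengths = lens,
                                 collapse = FALSE)
    want <- brute_locus_pairs(perfect, imperfect, contig_lengths = lens)
    expect_equal(got, want)
  }
})

test_that("folding matches small closed-form cases", {
  f <- fold_hairpin("GGGAAACCC")
  expect_equal(f$n_pairs, 3)
  expect_equal(f$structure, "(((...)))")
  expect_equal(fold_hairpin("AAAAAA")$n_pairs, 0)
  expect_error(fold_hairpin("ACGTXA"), "non-ACGU")
  # U is accepted as T
  expect_equal(fold_hairpin("GGGAAACCC")$n_pairs,
               fold_hairpin("gggaaaccc")$n_pairs)
})

test_that("folding equals exhaustive enumeration on short sequences", {
  set.seed(54)
  for (r in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(8:13, 1),
                      replace = TRUE), collapse = "")
    want <- brute_fold_best(s)
    f <- fold_hairpin(s)
    expect_equal(f$score, unname(want["score"]), label = s)
    expect_equal(f$n_pairs, unname(want["n_pairs"]), label = s)
  }
})

test_that("the structural gate accepts planted duplexes and rejects noise", {
  st <- tiny_study()
  hp <- st$hairpins[st$hairpins$truth_category == "A", ][1, ]
  sq <- substr(st$genome[[hp$contig]], hp$start - 20, hp$end + 20)
  g <- mircheck_like(fold_hairpin(sq, mature = c(21, 41)))
  expect_true(g$pass)
  expect_length(g$reasons, 0)

  # shuffled sequence of the same composition fails almost always
  set.seed(55)
  fails <- vapply(1:60, function(i) {
    shuf <- paste(sample(strsplit(sq, "")[[1]]), collapse = "")
    !mircheck_like(fold_hairpin(shuf, mature = c(21, 41)))$pass
  }, logical(1))
  expect_gte(mean(fails), 0.95)

  # a mature arm with no duplex window anywhere fails on mature_unpaired
  no_arm <- paste0(strrep("A", 20), strrep("A", 21), strrep("A", 60))
  g2 <- mircheck_like(fold_hairpin(no_arm, mature = c(21, 41)))
  expect_false(g2$pass)
  expect_true("mature_unpaired" %in% g2$reasons)
})

test_that("coverage metrics implement the 95/95/5 thresholds", {
  region <- c(0L, 200L)
  mk_hits <- function(n5, n3, nloop, nminus) {
    data.frame(
      start = c(rep(10L, n5), rep(160L, n3), rep(90L, nloop),
                rep(10L, nminus)),
      end = c(rep(31L, n5), rep(181L, n3), rep(111L, nloop),
              rep(31L, nminus)),
      strand = c(rep("+", n5 + n3 + nloop), rep("-", nminus)),
      count = rep(1, n5 + n3 + nloop + nminus))
  }
  m <- coverage_metrics(region, mk_hits(94, 1, 2, 3))
  expect_equal(m$strand_bias, 0.97)
  expect_equal(m$terminal_fraction, 0.97)
  expect_equal(m$loop_fraction, 0.02)
  expect_equal(unname(m$booleans), c(TRUE, TRUE, TRUE))

  m2 <- coverage_metrics(region, mk_hits(91, 1, 2, 6)) # 94% on one strand
  expect_false(m2$booleans[["strand"]])

  # a 100 bp region has no loop bases: metric 3 vacuously true
  m3 <- coverage_metrics(c(0L, 100L),
                         data.frame(start = c(5L, 70L), end = c(26L, 91L),
                                    strand = "+", count = c(50, 50)))
  expect_equal(m3$loop_fraction, 0)
  expect_true(m3$booleans[["loop"]])

  expect_error(coverage_metrics(region, mk_hits(0, 0, 0, 0)),
               "no overlapping reads")
})

test_that("the category map is the printed truth table and a bijection", {
  expect_equal(assign_category(TRUE, TRUE, TRUE), "A")
  expect_equal(assign_category(FALSE, FALSE, FALSE), "H")
  expect_equal(assign_category(TRUE, FALSE, TRUE), "C")
  grid <- expand.grid(s = c(TRUE, FALSE), t = c(TRUE, FALSE),
                      l = c(TRUE, FALSE))
  cats <- assign_category(grid$s, grid$t, grid$l)
  expect_setequal(cats, LETTERS[1:8])
  expect_equal(length(unique(cats)), 8)
})

test_that("known/novel splitting requires a perfect substring match", {
  hp <- paste0("AAAA", "ACGTACGTACGTACGTACGTA", "TTTT")
  refs <- c(exact = "ACGTACGTACGTACGTACGTA",
            near = "ACGTACGTACTTACGTACGTA", # 1 mismatch
            rna = "ACGUACGUACGUACGUACGUA") # U-form of the exact match
  m <- match_known(hp, refs)
  expect_setequal(m, c("exact", "rna"))
  expect_false("near" %in% m)
  # a reference matching only the reverse strand is found when asked for
  rc_ref <- c(rc = revcomp("ACGTACGTACGTACGTACGTA"))
  expect_length(match_known(hp, rc_ref), 0)
  expect_equal(match_known(hp, rc_ref, both_strands = TRUE), "rc")
})

test_that("discovery recovers planted hairpins into their categories and is
           deterministic", {
  st <- tiny_study()
  pp <- tiny_preprocessed()
  cand <- discover_hairpins(pp$hairpin_table, st$genome,
                            mature_refs = st$mature_refs)
  truth <- st$hairpins
  m <- match(cand$start, truth$start - 20L)
  recovered <- truth$truth_category[m]
  # every planted category-A hairpin is recovered as category A
  a_truth <- truth$feature_id[truth$truth_category == "A"]
  a_found <- truth$feature_id[m][cand$category == "A"]
  expect_setequal(a_found, a_truth)
  # no planted decoy lands in category A
  expect_false(any(recovered[cand$category == "A"] != "A"))
  # planted matures make candidates "known"; identifiers parse back
  expect_true(all(cand$status[cand$category == "A"] == "known"))
  parsed <- parse_hairpin_identifier(cand$identifier)
  expect_equal(parsed$start, cand$start)
  expect_equal(parsed$end, cand$end)

  # same inputs -> byte-identical output, and input order does not matter
  cand2 <- discover_hairpins(pp$hairpin_table[rev(seq_len(nrow(
    pp$hairpin_table))), ], st$genome, mature_refs = st$mature_refs)
  expect_identical(cand, cand2)
})

test_that("a random genome with random reads yields no spurious candidates", {
  g <- make_genome(1, 20000, seed = 61)
  des1 <- parse_design(data.frame(
    library_id = "L1", genotype = "g", tolerance = 1, tissue = "head",
    treatment = "control", replicate = 1))
  set.seed(61)
  tbl <- collapse_unique(list(L1 = random_dna_str(300, 21)), des1)
  cand <- discover_hairpins(tbl, g)
  expect_lte(nrow(cand), 1)
})
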