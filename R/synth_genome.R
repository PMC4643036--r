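# Synthetic genome and planted pre-miRNA hairpins with known ground truth.
# The genome stands in for a survey-sequence contig set; hairpins are planted
# as mature arm + loop + star arm, where the star arm is the reverse
# complement of the mature arm carrying a fixed number of substitutions
# (the miRNA/miRNA* duplex imperfection a rediscovery pipeline must accept).

#' Generate a synthetic genome of uniform-random contigs
#'
#' @param n_contigs number of contigs.
#' @param lengths integer vector of contig lengths (recycled), each >= 200.
#' @param seed optional RNG seed; identical seeds give identical genomes.
#' @return named character vector of contigs (`ctg01`, `ctg02`, ...).
#' @export
make_genome <- function(n_contigs, lengths, seed = NULL) {
  lengths <- rep(as.integer(lengths), length.out = n_contigs)
  if (any(lengths < 200)) stop("contig lengths must be >= 200 nt")
  with_seed(seed, {
    stats::setNames(random_dna(n_contigs, lengths),
                    sprintf("ctg%02d", seq_len(n_contigs)))
  })
}

# Read-type mixtures realizing each coverage-category signature.
# Components: mature (sense reads from the mature arm), star (sense reads
# from the star arm), loop (sense reads inside the loop), anti (antisense
# reads over the mature arm). Chosen with margin from the 95/95/5 category
# thresholds so that multinomial sampling noise does not flip the truth
# category at realistic depths. Categories B and F cannot be realized when
# every read is assigned to exactly one subregion (>=95% in one terminal
# window forces <=5% in the loop), so they are not plantable.
CATEGORY_SIGNATURES <- list(
  A = c(mature = 0.975, star = 0.010, loop = 0.010, anti = 0.005),
  C = c(mature = 0.550, star = 0.420, loop = 0.020, anti = 0.010),
  D = c(mature = 0.450, star = 0.300, loop = 0.230, anti = 0.020),
  E = c(mature = 0.550, star = 0.010, loop = 0.010, anti = 0.430),
  G = c(mature = 0.350, star = 0.300, loop = 0.020, anti = 0.330),
  H = c(mature = 0.300, star = 0.250, loop = 0.300, anti = 0.150)
)

# Mutate `star_mismatches` positions of the reverse complement of the mature
# arm, keeping a >= `margin` nt buffer from both arm ends and no more than
# two adjacent substitutions (duplex imperfections enter as small bulges or
# 1-2 nt interior loops, as in genuine miRNA/miRNA* duplexes).
mutate_star <- function(mature, star_mismatches, margin = 2) {
  star <- revcomp(mature)
  n <- nchar(star)
  eligible <- seq(margin + 1, n - margin)
  if (length(eligible) < star_mismatches) {
    stop("arm too short for ", star_mismatches, " star mismatches")
  }
  for (attempt in 1:100) {
    pos <- sort(sample(eligible, star_mismatches))
    if (star_mismatches < 3) break
    adj <- rle(diff(pos) == 1)
    if (max(adj$lengths[adj$values], 0) < 2) break # no run of 3+ mismatches
  }
  chars <- strsplit(star, "")[[1]]
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

#' Plant a single pre-miRNA hairpin into a genome
#'
#' Writes mature arm + loop + star arm onto the forward strand of a contig.
#' The star arm is the reverse complement of the mature arm with exactly
#' `star_mismatches` substitutions placed at least 2 nt from both arm ends,
#' so rediscovery sees a perfect mature-arm alignment facing an imperfect
#' (2-5 mismatch) opposite-strand alignment across the loop.
#'
#' @param genome named character vector of contigs.
#' @param contig contig name; default: sampled.
#' @param position 1-based start of the hairpin; default: sampled away from
#'   existing loci.
#' @param arm_length mature/star arm length in nt.
#' @param loop_length unpaired spacer between the arms in nt.
#' @param star_mismatches substitutions between star arm and the reverse
#'   complement of the mature arm; discovery requires 2-5, and values outside
#'   that range are refused unless `allow_edge_cases = TRUE`.
#' @param truth_category planted coverage category (one of A, C, D, E, G, H).
#' @param existing data.frame of previously planted loci (contig/start/end),
#'   or NULL; overlap with an existing locus is an error.
#' @param allow_edge_cases allow star_mismatches outside 2-5 (produces truth
#'   the discovery stage cannot recover).
#' @param margin minimum distance (nt) kept between planted loci and from
#'   contig ends.
#' @return list with the modified `genome` and a one-row `hairpin` data.frame
#'   (contig, strand, start, end, mature_start, star_start, arm_length,
#'   loop_length, star_mismatches, truth_category, mature_seq, star_seq,
#'   hairpin_id).
#' @export
plant_hairpin <- function(genome, contig = NULL, position = NULL,
                          arm_length = 21, loop_length = 60,
                          star_mismatches = 3, truth_category = "A",
                          existing = NULL, allow_edge_cases = FALSE,
                          margin = 60) {
  if (!truth_category %in% names(CATEGORY_SIGNATURES)) {
    stop("truth_category must be one of ",
         paste(names(CATEGORY_SIGNATURES), collapse = ", "),
         " (categories B and F have no realizable read signature)")
  }
  if (!allow_edge_cases && (star_mismatches < 2 || star_mismatches > 5)) {
    stop("star_mismatches must be in 2-5 for a discoverable hairpin; ",
         "set allow_edge_cases = TRUE to override")
  }
  total_len <- 2L * arm_length + loop_length
  if (is.null(contig)) contig <- sample(names(genome), 1)
  clen <- nchar(genome[[contig]])
  if (is.null(position)) {
    ok <- FALSE
    for (attempt in 1:200) {
      position <- sample.int(clen - total_len - 2L * margin, 1) + margin
      if (is.null(existing)) { ok <- TRUE; break }
      same <- existing[existing$contig == contig, , drop = FALSE]
      if (nrow(same) == 0 ||
          all(position > same$end + margin |
              position + total_len - 1 < same$start - margin)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place hairpin without overlap on ", contig)
  } else {
    if (!is.null(existing)) {
      same <- existing[existing$contig == contig, , drop = FALSE]
      if (nrow(same) > 0 &&
          any(position <= same$end & position + total_len - 1 >= same$start)) {
        stop("hairpin overlaps an existing planted locus on ", contig)
      }
    }
  }
  if (position + total_len - 1 > clen) stop("hairpin does not fit on contig")
  mature <- random_dna(1, arm_length)
  star <- mutate_star(mature, star_mismatches)
  loop <- random_dna(1, loop_length)
  insert <- paste0(mature, loop, star)
  seqc <- genome[[contig]]
  genome[[contig]] <- paste0(substr(seqc, 1, position - 1), insert,
                             substr(seqc, position + total_len, clen))
  hp <- data.frame(
    contig = contig, strand = "+",
    start = position, end = position + total_len - 1L,
    mature_start = position, star_start = position + arm_length + loop_length,
    arm_length = arm_length, loop_length = loop_length,
    star_mismatches = star_mismatches, truth_category = truth_category,
    mature_seq = mature, star_seq = star,
    stringsAsFactors = FALSE)
  hp$hairpin_id <- format_hairpin_identifier(hp$contig, hp$start, hp$end,
                                             1L, arm_length)
  list(genome = genome, hairpin = hp)
}

#' Plant a set of non-overlapping hairpins
#'
#' @param genome named character vector of contigs.
#' @param categories vector of truth categories, one hairpin planted per
#'   element.
#' @param arm_length arm length in nt.
#' @param loop_range range from which loop lengths are drawn uniformly.
#' @param star_mismatch_range range from which star mismatch counts are
#'   drawn; default 2-4 keeps the planted duplex within the structural gate's
#'   tolerance.
#' @param seed optional RNG seed.
#' @return list(genome, hairpins) with one row per planted hairpin; feature
#'   ids are `hp001`, `hp002`, ...
#' @export
plant_hairpins <- function(genome, categories, arm_length = 21,
                           loop_range = c(54, 90),
                           star_mismatch_range = c(2, 4), seed = NULL) {
  with_seed(seed, {
    hps <- NULL
    for (i in seq_along(categories)) {
      res <- plant_hairpin(
        genome,
        arm_length = arm_length,
        loop_length = sample(seq(loop_range[1], loop_range[2]), 1),
        star_mismatches = sample(seq(star_mismatch_range[1],
                                     star_mismatch_range[2]), 1),
        truth_category = categories[i],
        existing = hps)
      genome <- res$genome
      hps <- rbind(hps, res$hairpin)
    }
    hps$feature_id <- sprintf("hp%03d", seq_len(nrow(hps)))
    list(genome = genome, hairpins = hps)
  })
}

#' Generate labelled contaminant reference sequences
#'
#' Stand-ins for the rRNA / organellar / vector / repeat reference sets a
#' small RNA filter cascade maps against. The class is encoded as the prefix
#' of each sequence name (`rRNA_1`, `vector_2`, ...).
#'
#' @param classes contaminant class labels.
#' @param n_per_class sequences per class.
#' @param length length of each reference sequence.
#' @param seed optional RNG seed.
#' @return named character vector of sequences.
#' @export
make_contaminants <- function(classes = c("rRNA", "organellar", "vector",
                                          "repeat"),
                              n_per_class = 2, length = 500, seed = NULL) {
  with_seed(seed, {
    ids <- as.vector(t(outer(classes, seq_len(n_per_class), paste, sep = "_")))
    stats::setNames(random_dna(length(ids), length), ids)
  })
}
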