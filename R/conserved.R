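# Conserved miRNA profiling: annotate unique reads against a mature-miRNA
# reference set, normalize to reads per million, and apply the explicit
# differential-abundance criteria and pattern classifications (genotype
# groups I-IV, tissue predominance, stress response).

#' Differential-abundance criteria
#'
#' @param zero_floor RPM substituted for exact zeros before fold changes.
#' @param min_rpm minimum RPM required in at least one member of a pair.
#' @param fc_threshold fold change must strictly exceed this to be called.
#' @param candidate_min_rpm candidate rule: RPM must strictly exceed this.
#' @param candidate_min_fraction candidate rule: in at least this fraction of
#'   libraries.
#' @param annot_max_mismatch mismatches tolerated when annotating reads.
#' @return list of criteria.
#' @export
de_criteria <- function(zero_floor = 0.01, min_rpm = 10, fc_threshold = 1.5,
                        candidate_min_rpm = 2, candidate_min_fraction = 0.5,
                        annot_max_mismatch = 2) {
  stopifnot(zero_floor > 0, min_rpm > 0, fc_threshold > 0,
            candidate_min_rpm > 0, candidate_min_fraction > 0,
            candidate_min_fraction <= 1)
  list(zero_floor = zero_floor, min_rpm = min_rpm,
       fc_threshold = fc_threshold, candidate_min_rpm = candidate_min_rpm,
       candidate_min_fraction = candidate_min_fraction,
       annot_max_mismatch = annot_max_mismatch)
}

#' Annotate unique reads against mature miRNA references
#'
#' A read is assigned to a reference when its best ungapped offset alignment
#' (overlap at least `min(len_read, len_ref) - 2`, accommodating the +/- 2 nt
#' length variation of mature references) carries at most `max_mismatch`
#' mismatches. Reads tied between several best-scoring references count
#' toward all of them and are flagged.
#'
#' @param tbl unique-read table.
#' @param mature_refs named character vector of mature miRNA sequences
#'   (U allowed, normalized to T).
#' @param max_mismatch maximum mismatches over the overlap.
#' @return list with `counts` (miRNA x library matrix), `assignments`
#'   (data.frame sequence/miRNA/mismatches/multi).
#' @export
annotate_conserved <- function(tbl, mature_refs, max_mismatch = 2) {
  stopifnot(length(mature_refs) > 0)
  refs <- normalize_seq(mature_refs)
  mm <- .overlap_mismatches(tbl$sequence, unname(refs), 2L)
  cm <- urt_counts(tbl)
  counts <- matrix(0L, nrow = length(refs), ncol = ncol(cm),
                   dimnames = list(names(refs), colnames(cm)))
  assigned <- which(apply(mm, 1, function(x) any(!is.na(x) & x <= max_mismatch)))
  rows <- lapply(assigned, function(i) {
    x <- mm[i, ]
    best <- min(x, na.rm = TRUE)
    hits <- which(!is.na(x) & x == best)
    data.frame(sequence = tbl$sequence[i], miRNA = names(refs)[hits],
               mismatches = best, multi = length(hits) > 1,
               stringsAsFactors = FALSE)
  })
  for (i in seq_along(assigned)) {
    hit_idx <- match(rows[[i]]$miRNA, names(refs))
    for (h in hit_idx) {
      counts[h, ] <- counts[h, ] + cm[assigned[i], ]
    }
  }
  assignments <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(sequence = character(0), miRNA = character(0),
               mismatches = integer(0), multi = logical(0))
  list(counts = counts, assignments = assignments)
}

#' Reads-per-million normalization
#'
#' `RPM[f, l] = counts[f, l] / library_totals[l] * 1e6`.
#'
#' @param counts feature x library count matrix.
#' @param library_totals per-library totals of putative small RNA reads (the
#'   denominators); must be positive and named consistently with `counts`.
#' @return RPM matrix.
#' @export
compute_rpm <- function(counts, library_totals) {
  if (!is.null(names(library_totals)) && !is.null(colnames(counts))) {
    library_totals <- library_totals[colnames(counts)]
  }
  bad <- which(!(library_totals > 0))
  if (length(bad) > 0) {
    stop("non-positive library total for library ",
         (names(library_totals) %||% as.character(bad))[bad[1]])
  }
  sweep(counts, 2, library_totals, "/") * 1e6
}

#' Candidate conserved miRNA rule
#'
#' A feature is kept when its RPM strictly exceeds `candidate_min_rpm` in at
#' least `ceiling(candidate_min_fraction * n_libraries)` libraries.
#'
#' @param rpm RPM matrix (features x libraries).
#' @param criteria criteria from [de_criteria()].
#' @return character vector of retained feature names.
#' @export
call_candidates <- function(rpm, criteria = de_criteria()) {
  need <- ceiling(criteria$candidate_min_fraction * ncol(rpm))
  keep <- rowSums(rpm > criteria$candidate_min_rpm) >= need
  rownames(rpm)[keep]
}

#' Pairwise differential-abundance call
#'
#' Applies the printed rules to two (group-mean) RPM values per feature:
#' exact zeros are floored at `zero_floor`; the fold change is
#' `max(a, b) / min(a, b)` with a direction flag; the feature is called when
#' the fold change strictly exceeds `fc_threshold` and `max(a, b)` is at
#' least `min_rpm`.
#'
#' @param rpm_a,rpm_b numeric vectors of RPM values (same features).
#' @param criteria criteria from [de_criteria()].
#' @param labels optional c(label_a, label_b) used for the direction column.
#' @return data.frame with `fold_change`, `log2fc` (signed, positive toward
#'   a), `direction`, `called`, `reason`.
#' @export
pairwise_de <- function(rpm_a, rpm_b, criteria = de_criteria(),
                        labels = c("a", "b")) {
  stopifnot(length(rpm_a) == length(rpm_b), all(rpm_a >= 0), all(rpm_b >= 0))
  a <- ifelse(rpm_a == 0, criteria$zero_floor, rpm_a)
  b <- ifelse(rpm_b == 0, criteria$zero_floor, rpm_b)
  fc <- pmax(a, b) / pmin(a, b)
  direction <- ifelse(a > b, labels[1], ifelse(b > a, labels[2], "tie"))
  pass_rpm <- pmax(a, b) >= criteria$min_rpm
  pass_fc <- fc > criteria$fc_threshold
  called <- pass_rpm & pass_fc
  reason <- ifelse(called, "passed",
                   ifelse(!pass_rpm, "below_min_rpm", "below_fc"))
  out <- data.frame(fold_change = fc, log2fc = log2(a / b),
                    direction = direction, called = called, reason = reason,
                    stringsAsFactors = FALSE)
  if (!is.null(names(rpm_a))) out <- cbind(feature_id = names(rpm_a), out)
  out
}

#' Mean RPM per factor cell
#'
#' Averages the replicate libraries of each combination of the given factors.
#'
#' @param rpm RPM matrix with library columns.
#' @param design study design.
#' @param factors design columns defining the cells.
#' @return matrix features x cells; cell names join factor levels with ".".
#' @export
group_mean_rpm <- function(rpm, design,
                           factors = c("genotype", "tissue", "treatment")) {
  key <- interaction(design[factors], sep = ".", drop = TRUE)
  cells <- levels(key)
  out <- sapply(cells, function(cell) {
    rowMeans(rpm[, design$library_id[key == cell], drop = FALSE])
  })
  rownames(out) <- rownames(rpm)
  out
}

#' Classify genotype-contrast patterns into groups I-IV
#'
#' Summarizes tolerant-vs-sensitive genotype comparisons across treatments.
#' Using only called comparisons: group I = every called cell favors the
#' tolerant genotype; II = every called cell favors the sensitive genotype;
#' III = tolerant-favoring under control and sensitive-favoring under water
#' deficit (at least one called cell in each treatment); IV = the reverse.
#' Anything mixed within a treatment, or with no called cell, is
#' unclassified.
#'
#' @param results data.frame with columns `treatment` ("control" /
#'   "water_deficit"), `called` (logical) and `direction` ("tolerant" /
#'   "sensitive") covering the comparison strata of one miRNA.
#' @return one of "I", "II", "III", "IV", "unclassified".
#' @export
classify_genotype_group <- function(results) {
  called <- results[results$called, , drop = FALSE]
  if (nrow(called) == 0) return("unclassified")
  dirs <- function(trt) unique(called$direction[called$treatment == trt])
  d_cg <- dirs("control")
  d_wg <- dirs("water_deficit")
  if (length(d_cg) > 1 || length(d_wg) > 1) return("unclassified")
  all_dirs <- unique(called$direction)
  if (identical(all_dirs, "tolerant")) return("I")
  if (identical(all_dirs, "sensitive")) return("II")
  if (identical(d_cg, "tolerant") && identical(d_wg, "sensitive")) return("III")
  if (identical(d_cg, "sensitive") && identical(d_wg, "tolerant")) return("IV")
  "unclassified"
}

#' Classify tissue predominance across the eight genotype x treatment strata
#'
#' Head- (or leaf-) predominant when at least `min_called` of the 8 strata
#' are called and every called stratum shares that direction.
#'
#' @param results data.frame with `called` and `direction` ("head" /
#'   "flag_leaf"), one row per stratum.
#' @param min_called minimum number of called strata required.
#' @return "head_predominant", "leaf_predominant" or "none".
#' @export
classify_tissue_predominance <- function(results, min_called = 6) {
  called <- results[results$called, , drop = FALSE]
  if (nrow(called) < min_called) return("none")
  dirs <- unique(called$direction)
  if (identical(dirs, "head")) return("head_predominant")
  if (identical(dirs, "flag_leaf")) return("leaf_predominant")
  "none"
}

#' Call stress-responsive miRNAs across genotype x tissue strata
#'
#' A feature is flagged when the water-deficit vs control comparison is
#' called in at least one stratum. Strata that cannot be called (below the
#' minimum RPM) contribute a log2 fold change of zero to the returned
#' matrix, matching how undetermined cells enter downstream clustering.
#'
#' @param de_list named list (stratum label) of [pairwise_de()] results where
#'   side "a" is the water-deficit group; all elements share the feature
#'   order given in `feature_ids`.
#' @param feature_ids character vector of feature names.
#' @return list with `flagged` (character vector) and `log2fc` (features x
#'   strata matrix, zeros where not called).
#' @export
call_stress_responsive <- function(de_list, feature_ids) {
  lfc <- sapply(de_list, function(d) ifelse(d$called, d$log2fc, 0))
  called_any <- Reduce(`|`, lapply(de_list, function(d) d$called))
  rownames(lfc) <- feature_ids
  list(flagged = feature_ids[called_any], log2fc = lfc)
}

#' Run all three pattern analyses from an RPM matrix
#'
#' Convenience wrapper producing per-miRNA genotype groups (I-IV), tissue
#' predominance, and stress-response flags with the log2 fold-change matrix,
#' using mean RPM across the replicates of each factor cell and tolerant vs
#' sensitive genotype pairings.
#'
#' @param rpm RPM matrix (features x libraries).
#' @param design study design.
#' @param pairs optional data.frame with columns `tolerant`, `sensitive`
#'   listing genotype pairings; by default tolerant and sensitive genotypes
#'   are paired in design order.
#' @param criteria criteria from [de_criteria()].
#' @return list with `genotype_group`, `tissue_predominance` (named
#'   character vectors) and `stress` (result of [call_stress_responsive()]).
#' @export
profile_conserved <- function(rpm, design, pairs = NULL,
                              criteria = de_criteria()) {
  gm <- group_mean_rpm(rpm, design)
  cell <- function(g, tis, trt) gm[, paste(g, tis, trt, sep = "."), drop = TRUE]
  if (is.null(pairs)) {
    tol <- unique(design$genotype[design$tolerance == 1])
    sen <- unique(design$genotype[design$tolerance == 0])
    n <- min(length(tol), length(sen))
    pairs <- data.frame(tolerant = tol[seq_len(n)],
                        sensitive = sen[seq_len(n)])
  }
  feature_ids <- rownames(rpm)
  tissues <- unique(design$tissue)
  treatments <- unique(design$treatment)
  # genotype groups
  grp <- vapply(feature_ids, function(f) {
    rows <- list()
    for (p in seq_len(nrow(pairs))) for (tis in tissues) for (trt in treatments) {
      de <- pairwise_de(cell(pairs$tolerant[p], tis, trt)[f],
                        cell(pairs$sensitive[p], tis, trt)[f],
                        criteria, labels = c("tolerant", "sensitive"))
      rows[[length(rows) + 1]] <- data.frame(treatment = trt,
                                             called = de$called,
                                             direction = de$direction,
                                             stringsAsFactors = FALSE)
    }
    classify_genotype_group(do.call(rbind, rows))
  }, character(1))
  # tissue predominance
  genotypes <- unique(design$genotype)
  tis_pred <- vapply(feature_ids, function(f) {
    rows <- list()
    for (g in genotypes) for (trt in treatments) {
      de <- pairwise_de(cell(g, "head", trt)[f], cell(g, "flag_leaf", trt)[f],
                        criteria, labels = c("head", "flag_leaf"))
      rows[[length(rows) + 1]] <- data.frame(called = de$called,
                                             direction = de$direction,
                                             stringsAsFactors = FALSE)
    }
    classify_tissue_predominance(do.call(rbind, rows))
  }, character(1))
  # stress response per genotype x tissue
  de_list <- list()
  for (g in genotypes) for (tis in tissues) {
    de_list[[paste(g, tis, sep = ".")]] <-
      pairwise_de(cell(g, tis, "water_deficit"), cell(g, tis, "control"),
                  criteria, labels = c("up", "down"))
  }
  list(genotype_group = grp, tissue_predominance = tis_pred,
       stress = call_stress_responsive(de_list, feature_ids))
}
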