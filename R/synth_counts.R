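# Negative-binomial count generator realizing the factorial abundance
# structure: per-feature baseline plus log2 effects for tolerance class,
# tissue, treatment and the tolerance x treatment interaction.

#' Build effect specifications for simulated features
#'
#' Each feature gets an expected baseline count and log2 fold-change offsets
#' that enter a log-link factorial mean:
#' `mu = baseline * 2^(tol*b_tol + tissue*b_tis + trt*b_trt + tol*trt*b_int)`
#' with tolerance, tissue (head = 1) and treatment (water deficit = 1) coded
#' 0/1. Counts are negative binomial with the given dispersion.
#'
#' @param feature_ids character vector of feature names.
#' @param baseline_mean expected count at the reference level (> 0).
#' @param tolerance_log2fc,tissue_log2fc,treatment_log2fc,interaction_log2fc
#'   log2 effects (recycled across features).
#' @param dispersion negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @return data.frame of effect specifications.
#' @export
make_effects <- function(feature_ids, baseline_mean = 50,
                         tolerance_log2fc = 0, tissue_log2fc = 0,
                         treatment_log2fc = 0, interaction_log2fc = 0,
                         dispersion = 0.1) {
  n <- length(feature_ids)
  ef <- data.frame(
    feature_id = feature_ids,
    baseline_mean = rep(baseline_mean, length.out = n),
    tolerance_log2fc = rep(tolerance_log2fc, length.out = n),
    tissue_log2fc = rep(tissue_log2fc, length.out = n),
    treatment_log2fc = rep(treatment_log2fc, length.out = n),
    interaction_log2fc = rep(interaction_log2fc, length.out = n),
    dispersion = rep(dispersion, length.out = n),
    stringsAsFactors = FALSE)
  if (any(ef$baseline_mean <= 0)) stop("baseline_mean must be > 0")
  if (any(ef$dispersion <= 0)) stop("dispersion must be > 0")
  ef
}

# Expected count of each feature in each library under an effect table.
effect_means <- function(effects, design) {
  tol <- design$tolerance
  tis <- as.integer(design$tissue == "head")
  trt <- as.integer(design$treatment == "water_deficit")
  lfc <- outer(effects$tolerance_log2fc, tol) +
    outer(effects$tissue_log2fc, tis) +
    outer(effects$treatment_log2fc, trt) +
    outer(effects$interaction_log2fc, tol * trt)
  mu <- effects$baseline_mean * 2^lfc
  dimnames(mu) <- list(effects$feature_id, design$library_id)
  mu
}

#' Simulate a feature-by-library negative-binomial count matrix
#'
#' @param effects effect table from [make_effects()].
#' @param design study design from [make_design()] / [parse_design()].
#' @param seed optional RNG seed.
#' @return integer matrix, features x libraries.
#' @export
simulate_counts <- function(effects, design, seed = NULL) {
  mu <- effect_means(effects, design)
  with_seed(seed, {
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = rep(1 / effects$dispersion,
                                               ncol(mu))),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    counts
  })
}
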