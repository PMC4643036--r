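# Tolerance x treatment interaction analysis on hairpin counts: per-feature
# ordinary least squares on log2-CPM with empirical-Bayes variance
# moderation (method-of-moments hyperparameters on the log sample
# variances), a moderated t for the interaction coefficient, and
# Benjamini-Hochberg adjustment.

#' log2 counts-per-million with a prior count
#'
#' `log2((count + prior) / (total + 2 * prior) * 1e6)`.
#'
#' @param counts feature x library count matrix.
#' @param prior_count prior count added to stabilize zeros.
#' @param library_totals per-library totals; defaults to column sums.
#' @return log2-CPM matrix.
#' @export
cpm_log2 <- function(counts, prior_count = 0.5, library_totals = NULL) {
  if (is.null(library_totals)) library_totals <- colSums(counts)
  if (any(library_totals <= 0)) {
    stop("non-positive library total for library ",
         colnames(counts)[which(library_totals <= 0)[1]])
  }
  log2(sweep(sweep(counts + prior_count, 2,
                   library_totals + 2 * prior_count, "/"),
             2, 1e6, "*"))
}

#' Design matrix for the interaction model
#'
#' Columns: intercept, tolerance (0/1), treatment (0/1, water deficit = 1),
#' tissue (0/1, head = 1), tolerance x treatment product.
#'
#' @param design study design.
#' @return numeric design matrix with one row per library.
#' @export
interaction_design_matrix <- function(design) {
  tol <- design$tolerance
  trt <- as.integer(design$treatment == "water_deficit")
  tis <- as.integer(design$tissue == "head")
  X <- cbind(intercept = 1, tolerance = tol, treatment = trt, tissue = tis,
             interaction = tol * trt)
  rownames(X) <- design$library_id
  if (qr(X)$rank < ncol(X)) {
    r1 <- qr(X)$rank
    aliased <- colnames(X)[qr(X)$pivot[(r1 + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  X
}

#' Fit per-feature linear models by ordinary least squares
#'
#' @param logcpm feature x library matrix (response rows).
#' @param X design matrix from [interaction_design_matrix()].
#' @return list with `coefficients` (features x columns), `sigma2` (residual
#'   variances), `df` (residual degrees of freedom), `unscaled_se` (sqrt of
#'   the diagonal of (X'X)^-1 per column).
#' @export
fit_linear <- function(logcpm, X) {
  stopifnot(ncol(logcpm) == nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  if (ncol(logcpm) <= ncol(X)) {
    stop("need more libraries than model columns for residual variance")
  }
  xtx_inv <- chol2inv(qr.R(qrX))
  coefs <- t(qr.coef(qrX, t(logcpm)))
  fitted <- coefs %*% t(X)
  res <- logcpm - fitted
  df <- nrow(X) - qrX$rank
  sigma2 <- rowSums(res^2) / df
  colnames(coefs) <- colnames(X)
  list(coefficients = coefs, sigma2 = sigma2, df = rep(df, nrow(logcpm)),
       unscaled_se = stats::setNames(sqrt(diag(xtx_inv)), colnames(X)))
}

# Invert the trigamma function by Newton iteration (monotone decreasing).
trigamma_inverse <- function(x, tol = 1e-8, max_iter = 100) {
  vapply(x, function(xi) {
    if (xi <= 0) return(Inf)
    y <- 0.5 + 1 / xi
    for (i in seq_len(max_iter)) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) < tol * y) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderation of residual variances
#'
#' Estimates the prior degrees of freedom d0 and prior variance s0^2 by
#' method of moments on the log sample variances (matching the marginal
#' scaled-F distribution of per-feature variances), shrinks each variance to
#' `(d0 * s0^2 + df * s2) / (d0 + df)`, and forms a moderated t for the
#' requested coefficient with `d0 + df` degrees of freedom, followed by
#' Benjamini-Hochberg adjustment across features.
#'
#' @param fit result of [fit_linear()].
#' @param coef name (or index) of the tested coefficient; default
#'   "interaction".
#' @return data.frame with the coefficient estimate, `sigma2`, `s2_post`,
#'   `t`, `p_value`, `adj_p`, plus `d0` and `s0_2` attributes.
#' @export
moderate <- function(fit, coef = "interaction") {
  s2 <- fit$sigma2
  dg <- fit$df
  n <- length(s2)
  if (n < 2) {
    warning("fewer than 2 features: no shrinkage possible, ",
            "falling back to the ordinary t-statistic")
    d0 <- 0
    s0_2 <- NA_real_
    s2_post <- s2
  } else {
    z <- log(s2)
    e <- z - digamma(dg / 2) + log(dg / 2)
    ebar <- mean(e)
    evar <- stats::var(e) - mean(trigamma(dg / 2))
    if (is.na(evar) || evar <= 0) {
      d0 <- Inf
      s0_2 <- exp(ebar)
      s2_post <- rep(s0_2, n)
    } else {
      d0 <- 2 * trigamma_inverse(evar)
      s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
      s2_post <- (d0 * s0_2 + dg * s2) / (d0 + dg)
    }
  }
  beta <- fit$coefficients[, coef]
  se <- sqrt(s2_post) * fit$unscaled_se[coef]
  tstat <- beta / se
  df_total <- dg + d0
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(feature_id = rownames(fit$coefficients) %||%
                      as.character(seq_len(n)),
                    coefficient = beta, sigma2 = s2, s2_post = s2_post,
                    df = dg, t = tstat, p_value = p,
                    adj_p = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  rownames(out) <- NULL
  out
}

#' Fit and test the tolerance x treatment interaction for all features
#'
#' @param counts feature x library count matrix.
#' @param design study design.
#' @param prior_count prior count for [cpm_log2()].
#' @param library_totals per-library totals of all small RNA reads (the CPM
#'   denominators); defaults to the column sums of `counts`, but should be
#'   the full library totals when the features are a small subset of each
#'   library.
#' @return moderated fit table from [moderate()].
#' @export
interaction_fit <- function(counts, design, prior_count = 0.5,
                            library_totals = NULL) {
  lc <- cpm_log2(counts, prior_count = prior_count,
                 library_totals = library_totals)
  X <- interaction_design_matrix(design)
  moderate(fit_linear(lc[, rownames(X), drop = FALSE], X))
}

#' Select significant interaction candidates
#'
#' @param fits moderated fit table.
#' @param alpha adjusted-p threshold.
#' @param candidates optional feature ids to restrict to (e.g. category-A
#'   hairpins).
#' @return subset of `fits` with `adj_p <= alpha`, sorted by p-value.
#' @export
select_candidates <- function(fits, alpha = 0.05, candidates = NULL) {
  if (!is.null(candidates)) {
    fits <- fits[fits$feature_id %in% candidates, , drop = FALSE]
    fits$adj_p <- stats::p.adjust(fits$p_value, method = "BH")
  }
  out <- fits[!is.na(fits$adj_p) & fits$adj_p <= alpha, , drop = FALSE]
  out[order(out$p_value), , drop = FALSE]
}

#' Automated read-coverage signature check
#'
#' Deterministic stand-in for manual inspection of flagged hairpins: passes
#' when the strand bias is at least 0.98, at least 0.90 of reads fall in the
#' mature terminal window, and the modal 5' read end within that window
#' accounts for at least half of its reads (crisp processing). The score is
#' the product of the three fractions.
#'
#' @param region c(start, end), 0-based half-open candidate region.
#' @param hits overlapping read alignments (`start`, `end`, `strand`,
#'   optional `count`).
#' @param mature_window c(start, end) of the mature terminal window within
#'   the region (0-based half-open, genomic); defaults to the 5' terminal
#'   50 bp.
#' @param min_strand,min_mature,min_modal thresholds.
#' @return list with `pass`, `score` and the three component fractions.
#' @export
signature_check <- function(region, hits, mature_window = NULL,
                            min_strand = 0.98, min_mature = 0.90,
                            min_modal = 0.5) {
  if (nrow(hits) == 0) stop("signature_check: no overlapping reads")
  counts <- if ("count" %in% colnames(hits)) hits$count else rep(1, nrow(hits))
  total <- sum(counts)
  strand_bias <- max(sum(counts[hits$strand == "+"]),
                     sum(counts[hits$strand == "-"])) / total
  if (is.null(mature_window)) {
    mature_window <- c(region[1], min(region[1] + 50, region[2]))
  }
  mid <- (hits$start + hits$end) / 2
  in_mat <- mid >= mature_window[1] & mid < mature_window[2]
  mature_frac <- sum(counts[in_mat]) / total
  modal_frac <- if (any(in_mat)) {
    starts <- tapply(counts[in_mat], hits$start[in_mat], sum)
    max(starts) / sum(counts[in_mat])
  } else 0
  pass <- strand_bias >= min_strand && mature_frac >= min_mature &&
    modal_frac >= min_modal
  list(pass = pass, score = strand_bias * mature_frac * modal_frac,
       strand_bias = strand_bias, mature_fraction = mature_frac,
       modal_5p_fraction = modal_frac)
}
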