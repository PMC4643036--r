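# Interaction analysis: log-CPM, per-feature linear models, empirical-Bayes
# moderation, candidate selection and the coverage-signature check.

test_that("log2-CPM matches its definition and is scale invariant", {
  cnt <- matrix(c(0, 100), 2, 1, dimnames = list(c("z", "h"), "L1"))
  lc <- cpm_log2(cnt, library_totals = c(L1 = 1e6))
  expect_equal(lc["z", 1], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  expect_equal(lc["z", 1], -1, tolerance = 0.01)
  expect_equal(lc["h", 1], log2(100.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  expect_equal(lc["h", 1], 6.65, tolerance = 0.01)
  # doubling all counts and totals: unchanged within 1e-6 at large counts
  big <- matrix(c(5e6, 2e6), 2, 1, dimnames = list(NULL, "L1"))
  d <- cpm_log2(2 * big, library_totals = c(L1 = 2e7)) -
    cpm_log2(big, library_totals = c(L1 = 1e7))
  expect_lt(max(abs(d)), 1e-6)
  expect_error(cpm_log2(cnt, library_totals = c(L1 = 0)), "non-positive")
})

test_that("noise-free data reproduces the generating coefficients exactly", {
  des <- make_design(c("g1", "g2"), tolerant = "g1", replicates = 3)
  X <- interaction_design_matrix(des)
  beta <- c(5, 1, -1, 0, 2)
  y <- matrix(as.vector(X %*% beta), 1, nrow(X),
              dimnames = list("f1", des$library_id))
  fit <- fit_linear(y, X)
  expect_equal(unname(fit$coefficients[1, ]), beta, tolerance = 1e-10)
  expect_equal(unname(fit$sigma2[1]), 0, tolerance = 1e-18)
  expect_equal(fit$df[1], nrow(X) - 5)
})

test_that("residual variances estimate the noise variance", {
  des <- make_design(c("g1", "g2"), tolerant = "g1", replicates = 3)
  X <- interaction_design_matrix(des)
  set.seed(71)
  y <- matrix(rnorm(2000 * nrow(X), sd = 0.7), 2000, nrow(X),
              dimnames = list(NULL, des$library_id))
  fit <- fit_linear(y, X)
  expect_equal(mean(fit$sigma2), 0.49, tolerance = 0.05 * 0.49)
})

test_that("a design missing a factor cell is a rank error naming the column", {
  des <- make_design(c("g1", "g2"), tolerant = "g1", replicates = 3)
  # drop every tolerant water-deficit library: interaction aliased
  broken <- des[!(des$tolerance == 1 & des$treatment == "water_deficit"), ]
  expect_error(interaction_design_matrix(broken), "interaction")
})

test_that("moderation reproduces the reference empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  des <- make_design(c("g1", "g2"), tolerant = "g1", replicates = 3)
  ef <- make_effects(sprintf("f%04d", 1:500), baseline_mean = 80,
                     dispersion = 0.1)
  cnt <- simulate_counts(ef, des, seed = 72)
  lc <- cpm_log2(cnt)
  X <- interaction_design_matrix(des)
  mine <- moderate(fit_linear(lc, X))
  ref <- limma::eBayes(limma::lmFit(lc, X))
  expect_equal(attr(mine, "d0"), ref$df.prior, tolerance = 1e-6)
  expect_equal(attr(mine, "s0_2"), ref$s2.prior, tolerance = 1e-6)
  expect_equal(mine$s2_post, unname(ref$s2.post), tolerance = 1e-9)
  expect_equal(mine$t, unname(ref$t[, "interaction"]), tolerance = 1e-9)
  expect_equal(mine$p_value, unname(ref$p.value[, "interaction"]),
               tolerance = 1e-9)
})

test_that("the moderated t reduces to the ordinary t as d0 vanishes", {
  des <- make_design(c("g1", "g2"), tolerant = "g1", replicates = 3)
  X <- interaction_design_matrix(des)
  set.seed(73)
  y <- matrix(rnorm(20 * nrow(X)), 20, nrow(X),
              dimnames = list(NULL, des$library_id))
  fit <- fit_linear(y, X)
  # the d0 -> 0 limit of the posterior variance is the per-feature variance
  d0 <- 0
  s2_post <- (d0 * 1 + fit$df * fit$sigma2) / (d0 + fit$df)
  t_limit <- fit$coefficients[, "interaction"] /
    (sqrt(s2_post) * fit$unscaled_se["interaction"])
  t_ols <- fit$coefficients[, "interaction"] /
    (sqrt(fit$sigma2) * fit$unscaled_se["interaction"])
  expect_equal(unname(t_limit), unname(t_ols), tolerance = 1e-12)
})

test_that("a single feature falls back to the ordinary t with a warning", {
  des <- make_design(c("g1", "g2"), tolerant = "g1", replicates = 3)
  X <- interaction_design_matrix(des)
  set.seed(74)
  y <- matrix(rnorm(nrow(X)), 1, nrow(X),
              dimnames = list("f1", des$library_id))
  fit <- fit_linear(y, X)
  expect_warning(m <- moderate(fit), "no shrinkage")
  expect_equal(m$s2_post, unname(fit$sigma2[1]))
})

test_that("BH adjustment is monotone in the p-values", {
  des <- make_design(c("g1", "g2"), tolerant = "g1", replicates = 3)
  ef <- make_effects(sprintf("f%03d", 1:300), baseline_mean = 80,
                     interaction_log2fc = c(rep(1.5, 30), rep(0, 270)),
                     dispersion = 0.1)
  cnt <- simulate_counts(ef, des, seed = 75)
  fit <- interaction_fit(cnt, des, library_totals =
                           stats::setNames(rep(1e6, nrow(des)),
                                           des$library_id))
  ord <- order(fit$p_value)
  expect_true(all(diff(fit$adj_p[ord]) >= -1e-12))
  expect_true(all(fit$adj_p >= fit$p_value - 1e-12))
  # flag set does not depend on feature order
  fit2 <- interaction_fit(cnt[sample(nrow(cnt)), ], des, library_totals =
                            stats::setNames(rep(1e6, nrow(des)),
                                            des$library_id))
  expect_setequal(select_candidates(fit)$feature_id,
                  select_candidates(fit2)$feature_id)
})

test_that("candidate selection respects the restriction set", {
  des <- make_design(c("g1", "g2"), tolerant = "g1", replicates = 3)
  ef <- make_effects(sprintf("f%03d", 1:50), baseline_mean = 80,
                     interaction_log2fc = c(rep(2, 10), rep(0, 40)),
                     dispersion = 0.1)
  cnt <- simulate_counts(ef, des, seed = 76)
  fit <- interaction_fit(cnt, des, library_totals =
                           stats::setNames(rep(1e6, nrow(des)),
                                           des$library_id))
  sel <- select_candidates(fit, candidates = sprintf("f%03d", 1:20))
  expect_true(all(sel$feature_id %in% sprintf("f%03d", 1:20)))
  expect_true(all(diff(sel$p_value) >= 0))
  expect_equal(nrow(select_candidates(fit, candidates = character(0))), 0)
})

test_that("the signature check demands crisp 5' processing", {
  region <- c(0L, 160L)
  crisp <- data.frame(start = rep(10L, 97), end = rep(31L, 97),
                      strand = "+", count = 1)
  crisp <- rbind(crisp, data.frame(start = 120L, end = 141L, strand = "-",
                                   count = 1))
  r <- signature_check(region, crisp)
  expect_true(r$pass)
  expect_gt(r$score, 0.9)

  # same totals but read starts smeared across the mature window
  smear <- data.frame(start = 1:40, end = 22:61, strand = "+", count = 2)
  r2 <- signature_check(region, smear)
  expect_false(r2$pass)
  expect_lt(r2$modal_5p_fraction, 0.5)

  # passing the A-category thresholds at exactly 95/95/5 is not enough
  border <- data.frame(start = rep(c(2L, 6L, 10L, 14L), 10), end = 23L,
                       strand = "+", count = 1)
  r3 <- signature_check(region, border)
  expect_false(r3$pass)
})
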