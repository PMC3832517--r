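test_that("category probabilities match direct evaluation and sum to one", {
  expect_equal(category_probabilities(0, c(0, 0)), rep(1 / 3, 3),
               tolerance = 1e-12)
  # eta = 0.5, tau = (-0.3, 0.3): exponents (0, 0.8, 1.0), normalized
  e <- exp(c(0, 0.8, 1.0))
  expect_equal(category_probabilities(0.5, c(-0.3, 0.3)), e / sum(e),
               tolerance = 1e-12)
  expect_equal(category_probabilities(0.5, c(-0.3, 0.3)),
               c(0.1682, 0.3744, 0.4573), tolerance = 1e-3)
  # extreme eta concentrates all mass on the top category, without overflow
  expect_equal(category_probabilities(800, c(0, 0))[3], 1)
  expect_equal(category_probabilities(-800, c(0, 0))[1], 1)

  set.seed(5)
  eta <- stats::rnorm(200, 0, 3)
  tau <- stats::rnorm(2, 0, 2)
  P <- category_probabilities(eta, tau)
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(rowSums(P), rep(1, 200), tolerance = 1e-12)
  # monotone: P(top category) and the expected score increase in eta
  ord <- order(eta)
  expect_true(all(diff(P[ord, 3]) > 0))
  expect_true(all(diff(expected_score_variance(eta, tau)$E[ord]) > 0))
})

test_that("expected score and variance behave as the model dictates", {
  ew <- expected_score_variance(0, c(0, 0))
  expect_equal(ew$E, 1)
  expect_equal(ew$W, 2 / 3)
  hi <- expected_score_variance(50, c(0, 0))
  expect_equal(hi$E, 2, tolerance = 1e-12)
  expect_equal(hi$W, 0, tolerance = 1e-12)
  # brute-force bound: 3-category step variance never exceeds 1
  grid <- expand.grid(eta = seq(-5, 5, by = 0.25),
                      t1 = seq(-4, 4, by = 0.5), t2 = seq(-4, 4, by = 0.5))
  Wmax <- max(mapply(function(e, a, b)
    expected_score_variance(e, c(a, b))$W, grid$eta, grid$t1, grid$t2))
  expect_lte(Wmax, 1)
  expect_gte(Wmax, 0)
})

test_that("JMLE satisfies the score equations on the toy matrix", {
  fit <- jmle_fit(toy_cells())
  expect_true(fit$converged)
  obs <- fit$obs
  k <- obs$category - 1
  for (fac in c("respondent_id", "stimulus_id", "condition")) {
    res <- tapply(k - obs$expected, obs[[fac]], sum)
    expect_lt(max(abs(res)), fit$control$conv_score)
  }
  # centering constraints hold exactly
  expect_equal(mean(fit$stimuli$gamma), 0, tolerance = 1e-12)
  expect_equal(mean(fit$conditions$epsilon), 0, tolerance = 1e-12)
  expect_equal(mean(fit$groups$beta), 0, tolerance = 1e-12)
  expect_equal(sum(fit$tau), 0, tolerance = 1e-12)
  # alpha/beta decomposition reassembles theta
  expect_equal(fit$respondents$alpha +
                 fit$groups$beta[match(fit$respondents$group,
                                       fit$groups$group)],
               fit$respondents$theta, tolerance = 1e-12)
})

test_that("identical condition patterns give a zero condition contrast", {
  # both conditions carry the same categories per respondent/stimulus
  ref <- data.frame(
    respondent_id = rep(c("r1", "r2", "r3", "r4"), each = 3),
    group = "heterosexual", condition = "HEG_HOB",
    stimulus_id = rep(c("s1", "s2", "s3"), 4),
    category = c(1L, 2L, 3L, 3L, 2L, 1L, 2L, 3L, 1L, 2L, 2L, 3L),
    stringsAsFactors = FALSE)
  mirrored <- ref
  mirrored$condition <- "HOG_HEB"
  sym <- rbind(ref, mirrored)
  fit <- jmle_fit(sym)
  expect_equal(fit$conditions$epsilon, c(0, 0), tolerance = 1e-6)
})

test_that("linear_predictor reassembles eta and rejects unknown ids", {
  fit <- jmle_fit(toy_cells())
  expect_equal(linear_predictor(fit, fit$obs), fit$obs$eta,
               tolerance = 1e-12)
  bad <- fit$obs[1, ]
  bad$stimulus_id <- "nonexistent"
  expect_error(linear_predictor(fit, bad), "unknown element")
})

test_that("standard errors follow the Rasch information and its scaling", {
  # W at eta = 0, tau = (0,0) is 2/3, so one such observation gives
  # SE = sqrt(3/2)
  W <- expected_score_variance(0, c(0, 0))$W
  expect_equal(1 / sqrt(W), sqrt(3 / 2), tolerance = 1e-12)

  # doubling every observation halves the squared SE, leaves measures put
  cells <- toy_cells()
  f1 <- jmle_fit(cells)
  f2 <- jmle_fit(rbind(cells, cells))
  expect_equal(f2$stimuli$gamma, f1$stimuli$gamma, tolerance = 1e-3)
  expect_equal(f2$stimuli$se, f1$stimuli$se / sqrt(2), tolerance = 1e-3)

  # finite-difference observed information reproduces sum(W) per element
  obs <- f1$obs
  h <- 1e-4
  ll <- function(gshift) {
    gam <- stats::setNames(f1$stimuli$gamma, f1$stimuli$stimulus_id)
    gam["s1"] <- gam["s1"] + gshift
    eta <- f1$respondents$theta[match(obs$respondent_id,
                                      f1$respondents$respondent_id)] +
      gam[obs$stimulus_id] +
      f1$conditions$epsilon[match(obs$condition,
                                  f1$conditions$condition)]
    P <- category_probabilities(eta, f1$tau)
    sum(log(P[cbind(seq_len(nrow(obs)), obs$category)]))
  }
  info_fd <- -(ll(h) - 2 * ll(0) + ll(-h)) / h^2
  info_model <- sum(obs$variance[obs$stimulus_id == "s1"])
  expect_equal(info_fd, info_model, tolerance = 0.05)
  expect_equal(f1$stimuli$se[f1$stimuli$stimulus_id == "s1"],
               1 / sqrt(info_model), tolerance = 1e-6)
})

test_that("fit statistics have expectation one and outfit is the sensitive one", {
  # residuals exactly matching their variances give unit mean squares
  W <- c(0.4, 0.5, 0.66)
  fs <- fit_statistics(sqrt(W), W)
  expect_equal(fs$infit, 1)
  expect_equal(fs$outfit, 1)
  # a single aberrant low-variance observation inflates outfit more
  r <- c(rep(0.1, 20), 1.9)
  W2 <- c(rep(0.6, 20), 0.05)
  fs2 <- fit_statistics(r, W2)
  expect_gt(fs2$outfit, fs2$infit)
  expect_gt(fs2$outfit, 2)
})

test_that("separation reliability matches its definition and bounds", {
  expect_equal(separation_reliability(c(-1, 0, 1), rep(0.1, 3)), 0.99,
               tolerance = 1e-12)
  # SEs shrinking to zero push R to 1
  expect_gt(separation_reliability(c(-1, 0, 1), rep(1e-6, 3)), 0.999999)
  # observed variance equal to mean squared error gives 0
  expect_equal(separation_reliability(c(-1, 1), rep(sqrt(2), 2)), 0)
  # error swamping the spread clips at 0, and constant measures warn
  expect_equal(separation_reliability(c(-0.01, 0.01), c(5, 5)), 0)
  expect_warning(r0 <- separation_reliability(c(1, 1), c(0.1, 0.1)),
                 "zero observed variance")
  expect_equal(r0, 0)
})

test_that("fixed all-same chi-square matches the weighted formula", {
  cs <- fixed_chisquare(c(1, -1), c(0.5, 0.5))
  expect_equal(cs$chisq, 8)
  expect_equal(cs$df, 1)
  expect_equal(cs$p, stats::pchisq(8, 1, lower.tail = FALSE))
  expect_equal(fixed_chisquare(c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.3))$chisq, 0,
               tolerance = 1e-12)
  # invariant under a constant shift of all measures
  m <- c(0.2, -0.5, 1.1)
  s <- c(0.1, 0.3, 0.2)
  expect_equal(fixed_chisquare(m + 5, s)$chisq, fixed_chisquare(m, s)$chisq,
               tolerance = 1e-9)
})

test_that("extreme respondents are dropped, imputed and flagged", {
  cells <- toy_cells()
  ext <- data.frame(respondent_id = "r5", group = "gay",
                    condition = rep(c("HEG_HOB", "HOG_HEB"), each = 3),
                    stimulus_id = rep(c("s1", "s2", "s3"), 2),
                    category = 3L, stringsAsFactors = FALSE)
  fit <- jmle_fit(rbind(cells, ext))
  r5 <- fit$respondents[fit$respondents$respondent_id == "r5", ]
  expect_true(r5$extreme)
  expect_true(is.finite(r5$theta))
  # imputed measure exceeds every non-extreme respondent's
  expect_gt(r5$theta, max(fit$respondents$theta[!fit$respondents$extreme]))
  # other elements unaffected by the extreme respondent
  base <- jmle_fit(cells)
  expect_equal(fit$stimuli$gamma, base$stimuli$gamma, tolerance = 0.02)
  # facet summary excludes the imputed measure
  fs <- facet_summary(fit)
  expect_equal(fs$n_elements[fs$facet == "respondents"], 4)
  expect_true(all(fs$reliability >= 0 & fs$reliability <= 1))
})

test_that("stimulus measures are recovered from model-true data", {
  cfg <- sim_config(n_per_group = c(heterosexual = 200, gay = 200,
                                    bisexual = 200),
                    delta_true = c(heterosexual = 1.0, gay = -0.2,
                                   bisexual = 0.3),
                    seed = 301)
  truth <- gen_truth(cfg)
  cells <- simulate_categories(truth)
  fit <- jmle_fit(cells)
  m <- match(fit$stimuli$stimulus_id, truth$stimuli$stimulus_id)
  expect_gte(stats::cor(fit$stimuli$gamma, truth$stimuli$gamma[m]), 0.9)
  # condition measures on the same logit scale as the truth
  expect_equal(iat_effect(fit)$delta, mean(cfg$delta_true),
               tolerance = 0.1)
})
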