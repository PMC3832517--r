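# Synthetic-data generator: a 7-block Sexuality-IAT session (3 practice + 4
# critical blocks, two associative mappings counterbalanced across
# respondents) with known true facet parameters, so that every stage of the
# pipeline can be tested for parameter recovery without any external data.

.default_positive <- c("beautiful", "glorious", "joyful", "lovely",
                       "marvelous", "pleasure", "wonderful")
.default_negative <- c("agony", "awful", "horrible", "humiliate", "nasty",
                       "painful", "terrible", "tragic")
.default_targets <- c("het_image_1", "het_image_2", "hom_image_1",
                      "hom_image_2")

#' Simulation configuration
#'
#' Defaults emulate the three-group online Sexuality-IAT study the package
#' models: 689 heterosexual, 47 gay and 53 bisexual respondents; 7 positive
#' and 8 negative attribute words; group IAT effects of 1.08, -0.20 and 0.29
#' logits. Latent speeds map to latencies through a shifted-lognormal model:
#' `log(latency) = rt_mu0 - rt_slope * eta + Normal(0, rt_sigma^2)` per
#' trial. `rt_slope` is calibrated so that one logit of latent speed is
#' recovered as approximately one logit by the tertile-discretized Rasch
#' pipeline under the default acquisition noise.
#'
#' @param n_per_group Named integer vector of respondents per group.
#' @param n_positive,n_negative Numbers of positive / negative attribute
#'   stimuli. The study's word lists are used up to 7/8; larger counts get
#'   generated names.
#' @param trials_per_cell Critical trials per respondent x condition x
#'   stimulus cell (split over the condition's two blocks).
#' @param sd_alpha,sd_gamma SDs (logits) of the respondent and stimulus
#'   parameters.
#' @param delta_true Named numeric vector: true IAT effect per group
#'   (logits); its unweighted mean becomes the main condition effect, the
#'   rest condition x group bias.
#' @param stimulus_bias Optional `data.frame` with columns `stimulus_id`,
#'   `group`, `condition`, `bias` (logits) injecting stimulus-level bias.
#' @param tau_true Threshold vector (logits), summing to zero.
#' @param rt_mu0 Log-milliseconds intercept of the latency model.
#' @param rt_slope Log-milliseconds per logit of latent speed.
#' @param rt_sigma Trial-level SD of log latency.
#' @param frac_fast,frac_slow Fractions of trials replaced by out-of-range
#'   latencies (< 300 ms, > 10,000 ms).
#' @param error_rate Bernoulli rate of error trials.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_per_group = c(heterosexual = 689, gay = 47,
                                       bisexual = 53),
                       n_positive = 7, n_negative = 8,
                       trials_per_cell = 4,
                       sd_alpha = 1.0, sd_gamma = 0.2,
                       delta_true = c(heterosexual = 1.08, gay = -0.20,
                                      bisexual = 0.29),
                       stimulus_bias = NULL,
                       tau_true = c(-0.5, 0.5),
                       rt_mu0 = log(700), rt_slope = 0.142,
                       rt_sigma = 0.35,
                       frac_fast = 0.01, frac_slow = 0.005,
                       error_rate = 0.05, seed = 1L) {
  stopifnot(length(n_per_group) >= 1, !is.null(names(n_per_group)),
            all(n_per_group >= 1), trials_per_cell >= 1,
            frac_fast >= 0, frac_fast <= 1, frac_slow >= 0, frac_slow <= 1,
            error_rate >= 0, error_rate <= 1,
            setequal(names(delta_true), names(n_per_group)))
  structure(list(n_per_group = n_per_group, n_positive = n_positive,
                 n_negative = n_negative,
                 trials_per_cell = as.integer(trials_per_cell),
                 sd_alpha = sd_alpha, sd_gamma = sd_gamma,
                 delta_true = delta_true, stimulus_bias = stimulus_bias,
                 tau_true = tau_true, rt_mu0 = rt_mu0,
                 rt_slope = rt_slope, rt_sigma = rt_sigma,
                 frac_fast = frac_fast, frac_slow = frac_slow,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_config")
}

.stim_names <- function(n, defaults, prefix) {
  if (n <= length(defaults)) defaults[seq_len(n)]
  else c(defaults, sprintf("%s%02d", prefix, seq_len(n - length(defaults))))
}

#' Draw the true parameters of a simulated study
#'
#' Respondent speeds are Normal(0, `sd_alpha`^2); stimulus speeds are drawn
#' and re-centered; the two condition measures are set to plus/minus half the
#' unweighted mean of the group IAT effects, and the remainder of each
#' group's effect is realized as condition x group bias. Deterministic under
#' the config seed.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"iat_truth"`: `respondents` (id, group, alpha),
#'   `stimuli` (id, class, gamma), `epsilon` (named, centered), `cg_bias`
#'   (condition x group bias matrix as a `data.frame`), `tau`, `delta_true`,
#'   `stimulus_bias` and the `config`.
#' @export
gen_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- names(config$n_per_group)
  n_tot <- sum(config$n_per_group)
  respondents <- data.frame(
    respondent_id = sprintf("R%04d", seq_len(n_tot)),
    group = rep(groups, config$n_per_group),
    alpha = stats::rnorm(n_tot, 0, config$sd_alpha),
    stringsAsFactors = FALSE)
  pos <- .stim_names(config$n_positive, .default_positive, "pos")
  neg <- .stim_names(config$n_negative, .default_negative, "neg")
  gamma <- stats::rnorm(length(pos) + length(neg), 0, config$sd_gamma)
  gamma <- gamma - mean(gamma)
  stimuli <- data.frame(
    stimulus_id = c(pos, neg),
    stimulus_class = rep(c("attribute_positive", "attribute_negative"),
                         c(length(pos), length(neg))),
    gamma = gamma, stringsAsFactors = FALSE)
  dbar <- mean(config$delta_true)
  epsilon <- c(HEG_HOB = dbar / 2, HOG_HEB = -dbar / 2)
  cg <- expand.grid(condition = names(epsilon), group = groups,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  extra <- config$delta_true[cg$group] - dbar
  cg$bias <- ifelse(cg$condition == "HEG_HOB", extra / 2, -extra / 2)
  structure(list(respondents = respondents, stimuli = stimuli,
                 epsilon = epsilon, cg_bias = cg, tau = config$tau_true,
                 delta_true = config$delta_true,
                 stimulus_bias = config$stimulus_bias, config = config),
            class = "iat_truth")
}

# True linear predictor for vectors of respondent/condition/stimulus indices.
.true_eta <- function(truth, alpha, group, condition, stimulus_gamma,
                      stimulus_id) {
  cg_key <- paste(truth$cg_bias$condition, truth$cg_bias$group, sep = "\r")
  eta <- alpha + stimulus_gamma + unname(truth$epsilon[condition]) +
    truth$cg_bias$bias[match(paste(condition, group, sep = "\r"), cg_key)]
  sb <- truth$stimulus_bias
  if (!is.null(sb) && nrow(sb) > 0) {
    sb_key <- paste(sb$stimulus_id, sb$group, sb$condition, sep = "\r")
    m <- match(paste(stimulus_id, group, condition, sep = "\r"), sb_key)
    eta <- eta + ifelse(is.na(m), 0, sb$bias[m])
  }
  eta
}

#' Simulate a categorized cell matrix directly from the model
#'
#' Draws each cell's speed category from the rating-scale model at its true
#' linear predictor (including condition x group and injected stimulus
#' biases). This is the model-true path: fitting these data with
#' [jmle_fit()] recovers the truth up to sampling error on the same logit
#' scale.
#'
#' @param truth An [gen_truth()] object.
#' @param seed Integer seed (default `config$seed + 1`).
#' @return A cell `data.frame` ready for [jmle_fit()].
#' @export
simulate_categories <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "iat_truth"))
  if (is.null(seed)) seed <- truth$config$seed + 1L
  set.seed(seed)
  r <- truth$respondents
  s <- truth$stimuli
  conds <- names(truth$epsilon)
  grid <- expand.grid(stimulus_idx = seq_len(nrow(s)), condition = conds,
                      respondent_idx = seq_len(nrow(r)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eta <- .true_eta(truth,
                   alpha = r$alpha[grid$respondent_idx],
                   group = r$group[grid$respondent_idx],
                   condition = grid$condition,
                   stimulus_gamma = s$gamma[grid$stimulus_idx],
                   stimulus_id = s$stimulus_id[grid$stimulus_idx])
  P <- .rsm_prob(eta, truth$tau)
  u <- stats::runif(nrow(P))
  cum <- t(apply(P, 1, cumsum))
  category <- 1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
  data.frame(respondent_id = r$respondent_id[grid$respondent_idx],
             group = r$group[grid$respondent_idx],
             condition = grid$condition,
             stimulus_id = s$stimulus_id[grid$stimulus_idx],
             stimulus_class = s$stimulus_class[grid$stimulus_idx],
             mean_latency_ms = NA_real_, n_trials = 1L,
             category = as.integer(category), stringsAsFactors = FALSE)
}

#' Simulate full 7-block trial-level sessions
#'
#' Generates, per respondent, three practice blocks (target categorization,
#' attribute categorization, reversed target categorization) and four
#' critical blocks (two per associative mapping, mapping order alternating
#' with respondent index to emulate counterbalancing). Trial latencies follow
#' `log(latency) = rt_mu0 - rt_slope * eta + Normal(0, rt_sigma^2)`, where
#' `eta` is the trial's true latent speed; a configurable fraction of trials
#' is replaced by out-of-range latencies, and error flags are Bernoulli.
#' Target-stimulus trials are included in critical blocks (with zero
#' stimulus effect) and must be discarded by preprocessing, as in the real
#' task.
#'
#' @param truth An [gen_truth()] object.
#' @param seed Integer seed (default `config$seed + 2`).
#' @return A trial `data.frame` in the [read_trials()] schema.
#' @export
simulate_latencies <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "iat_truth"))
  cfg <- truth$config
  if (is.null(seed)) seed <- cfg$seed + 2L
  set.seed(seed)
  r <- truth$respondents
  s <- truth$stimuli
  conds <- names(truth$epsilon)
  Tcell <- cfg$trials_per_cell
  t1 <- ceiling(Tcell / 2)
  t2 <- Tcell - t1
  n_targets <- length(.default_targets)

  one_resp <- function(i) {
    first <- conds[if (i %% 2 == 0) 1L else 2L]
    second <- setdiff(conds, first)
    crit_cond <- c(first, first, second, second)
    crit_block <- c(3L, 4L, 6L, 7L)
    crit_reps <- c(t1, t2, t1, t2)
    blocks <- list(
      data.frame(block = 1L, block_role = "practice",
                 condition = NA_character_,
                 stimulus_id = rep(.default_targets, 2),
                 stimulus_class = "target", gamma = 0,
                 stringsAsFactors = FALSE),
      data.frame(block = 2L, block_role = "practice",
                 condition = NA_character_,
                 stimulus_id = rep(s$stimulus_id, 2),
                 stimulus_class = rep(s$stimulus_class, 2),
                 gamma = rep(s$gamma, 2), stringsAsFactors = FALSE),
      data.frame(block = 5L, block_role = "practice",
                 condition = NA_character_,
                 stimulus_id = rep(.default_targets, 2),
                 stimulus_class = "target", gamma = 0,
                 stringsAsFactors = FALSE)
    )
    for (b in seq_along(crit_block)) {
      reps <- crit_reps[b]
      if (reps == 0) next
      blocks[[length(blocks) + 1L]] <- data.frame(
        block = crit_block[b], block_role = "critical",
        condition = crit_cond[b],
        stimulus_id = c(rep(s$stimulus_id, reps),
                        rep(.default_targets, reps)),
        stimulus_class = c(rep(s$stimulus_class, reps),
                           rep("target", reps * n_targets)),
        gamma = c(rep(s$gamma, reps), rep(0, reps * n_targets)),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, blocks)
    out$respondent_id <- r$respondent_id[i]
    out$group <- r$group[i]
    out$alpha <- r$alpha[i]
    out
  }
  trials <- do.call(rbind, lapply(seq_len(nrow(r)), one_resp))

  is_crit <- trials$block_role == "critical"
  eta <- trials$alpha + trials$gamma
  eta[is_crit] <- .true_eta(truth,
                            alpha = trials$alpha[is_crit],
                            group = trials$group[is_crit],
                            condition = trials$condition[is_crit],
                            stimulus_gamma = trials$gamma[is_crit],
                            stimulus_id = trials$stimulus_id[is_crit])
  n <- nrow(trials)
  lat <- exp(stats::rnorm(n, cfg$rt_mu0 - cfg$rt_slope * eta, cfg$rt_sigma))
  # the base response process stays inside the task's valid range; trials
  # outside [300, 10000] ms arise only from the contamination fractions
  lat <- pmin(pmax(lat, 300), 10000)
  u <- stats::runif(n)
  fast <- u < cfg$frac_fast
  slow <- !fast & u < cfg$frac_fast + cfg$frac_slow
  lat[fast] <- stats::runif(sum(fast), 150, 299)
  lat[slow] <- stats::runif(sum(slow), 10001, 14000)
  trials$latency_ms <- round(lat, 1)
  trials$error <- stats::runif(n) < cfg$error_rate
  trials <- trials[, c("respondent_id", "group", "block", "block_role",
                       "condition", "stimulus_id", "stimulus_class",
                       "latency_ms", "error")]
  rownames(trials) <- NULL
  trials
}

#' Write a reproducible fixture to disk
#'
#' Simulates a full study and writes `trials.csv` (the [read_trials()]
#' schema) plus a `truth.json` sidecar holding the generating parameters.
#' Byte-identical for identical configs.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the two file paths and the truth object.
#' @export
make_fixture <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- gen_truth(config)
  trials <- simulate_latencies(truth)
  trials_path <- file.path(dir, "trials.csv")
  truth_path <- file.path(dir, "truth.json")
  utils::write.csv(trials, trials_path, row.names = FALSE, quote = FALSE)
  side <- list(
    seed = config$seed,
    delta_true = as.list(config$delta_true),
    epsilon = as.list(truth$epsilon),
    tau = truth$tau,
    cg_bias = truth$cg_bias,
    stimuli = truth$stimuli,
    respondents = truth$respondents,
    rt_model = list(mu0 = config$rt_mu0, slope = config$rt_slope,
                    sigma = config$rt_sigma)
  )
  jsonlite::write_json(side, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(trials = trials_path, truth = truth_path,
                 truth_object = truth))
}

#' Run a complete synthetic study through the pipeline
#'
#' Convenience wrapper chaining [gen_truth()], [simulate_latencies()],
#' [preprocess_trials()], [jmle_fit()] and the contrast / D-score analyses.
#'
#' @param config A [sim_config()] object.
#' @param components Character subset of `c("dsf", "dscore")` to compute in
#'   addition to the fit and IAT effects.
#' @param control Passed to [jmle_fit()].
#' @return A list with `truth`, `trials`, `prep`, `fit`, `overall`,
#'   `by_group`, and (optionally) `dsf` and `dscores`.
#' @export
run_synthetic_study <- function(config, components = character(0),
                                control = mfrm_control()) {
  truth <- gen_truth(config)
  trials <- simulate_latencies(truth)
  prep <- preprocess_trials(trials)
  fit <- jmle_fit(prep$cells, control = control)
  overall <- iat_effect(fit)
  by_group <- group_iat_effects(fit, overall = overall)
  out <- list(truth = truth, trials = trials, prep = prep, fit = fit,
              overall = overall, by_group = by_group)
  if ("dsf" %in% components) out$dsf <- dsf_table(fit)
  if ("dscore" %in% components) {
    ds <- dscore(trials)
    out$dscores <- ds
    out$dscore_groups <- dscore_group_summary(ds)
  }
  out
}
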