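# Many-facet rating-scale Rasch model, estimated by joint maximum likelihood
# (JMLE). The log-odds of adjacent speed categories for a cell is
#   eta - tau_k,  eta = alpha_respondent + beta_group + gamma_stimulus +
#                       epsilon_condition,
# with one shared threshold vector tau across all cells (rating-scale form).
# Respondents are estimated as a combined parameter theta = alpha + beta that
# absorbs the grand level; groups, stimuli, conditions and tau are centered.

#' Estimation control parameters
#'
#' @param conv_score Convergence tolerance on the largest absolute score
#'   residual (observed minus expected raw score) over free elements, in step
#'   score points.
#' @param conv_param Convergence tolerance on the largest absolute parameter
#'   change per iteration, in logits.
#' @param max_iter Maximum number of JMLE iterations.
#' @param extreme_adjust Score-point adjustment used to impute measures for
#'   extreme (all-minimum or all-maximum) respondents: the measure giving an
#'   expected raw score `extreme_adjust` step points inside the extreme.
#' @param step_max Largest Newton step (logits) taken for any parameter in one
#'   iteration; guards against overshoot early on.
#' @return A list of class `"mfrm_control"`.
#' @export
mfrm_control <- function(conv_score = 0.01, conv_param = 0.001,
                         max_iter = 200, extreme_adjust = 0.3,
                         step_max = 1.0) {
  structure(list(conv_score = conv_score, conv_param = conv_param,
                 max_iter = max_iter, extreme_adjust = extreme_adjust,
                 step_max = step_max),
            class = "mfrm_control")
}

# Category probability matrix (rows = observations, cols = categories 1..K)
# for the rating-scale model: P(step k) proportional to
# exp(k * eta - sum_{h<=k} tau_h), k = 0..K-1.
.rsm_prob <- function(eta, tau) {
  K <- length(tau) + 1L
  k <- 0:(K - 1L)
  ctau <- c(0, cumsum(tau))
  M <- outer(eta, k) - rep(ctau, each = length(eta))
  M <- M - do.call(pmax, as.data.frame(M))
  E <- exp(M)
  E / rowSums(E)
}

#' Category probabilities of the rating-scale model
#'
#' For linear predictor `eta` and thresholds `tau`, the probability of
#' category `k + 1` (step score `k` in `0..K-1`, `K = length(tau) + 1`) is
#' proportional to `exp(k * eta - sum(tau[1:k]))`. Overflow is guarded by
#' subtracting the largest exponent before normalizing.
#'
#' @param eta Numeric vector of linear predictors (logits).
#' @param tau Numeric threshold vector (logits), length `K - 1`.
#' @return A matrix with `length(eta)` rows and `K` columns summing to 1 per
#'   row; a plain vector if `eta` is scalar.
#' @export
category_probabilities <- function(eta, tau) {
  P <- .rsm_prob(eta, tau)
  if (length(eta) == 1L) as.vector(P) else P
}

#' Expected step score and model variance
#'
#' @param eta Numeric vector of linear predictors (logits).
#' @param tau Threshold vector (logits).
#' @return A list with `E` (expected step score, in `[0, K-1]`) and `W`
#'   (model variance of the step score), each the length of `eta`.
#' @export
expected_score_variance <- function(eta, tau) {
  P <- .rsm_prob(eta, tau)
  k <- 0:(ncol(P) - 1L)
  E <- as.vector(P %*% k)
  W <- as.vector(P %*% k^2) - E^2
  list(E = E, W = W)
}

#' Linear predictor of a fitted model for a set of cells
#'
#' `eta = alpha_respondent + beta_group + gamma_stimulus +
#' epsilon_condition`. Every id in `cells` must be known to the fit.
#'
#' @param fit An `"mfrm_fit"` object.
#' @param cells Cell `data.frame` with `respondent_id`, `group`,
#'   `stimulus_id`, `condition`.
#' @return Numeric vector of logits, one per row of `cells`.
#' @export
linear_predictor <- function(fit, cells) {
  stopifnot(inherits(fit, "mfrm_fit"))
  p <- coef(fit)
  a <- p$alpha[cells$respondent_id]
  b <- p$beta[cells$group]
  g <- p$gamma[cells$stimulus_id]
  e <- p$epsilon[cells$condition]
  bad <- is.na(a) | is.na(b) | is.na(g) | is.na(e)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("unknown element id in cells (first offending row ", i, ")",
         call. = FALSE)
  }
  unname(a + b + g + e)
}

.rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

.clip <- function(x, m) pmin(pmax(x, -m), m)

# Solve for the eta offset giving expected total score `target` over
# observations with fixed offsets `base` (gamma + epsilon part) and
# thresholds tau. Used for extreme-score imputation.
.solve_theta <- function(target, base, tau, tol = 1e-9, max_iter = 100) {
  theta <- 0
  for (i in seq_len(max_iter)) {
    ew <- expected_score_variance(theta + base, tau)
    res <- target - sum(ew$E)
    if (abs(res) < tol) break
    theta <- theta + .clip(res / max(sum(ew$W), 1e-10), 2)
  }
  theta
}

#' Fit the many-facet rating-scale Rasch model by JMLE
#'
#' Estimates a speed measure for every respondent, group, attribute stimulus
#' and associative condition from the categorized cell matrix, by alternating
#' Newton updates of the score equations until the largest absolute score
#' residual and parameter change fall below the control tolerances. Group,
#' stimulus, condition and threshold estimates are re-centered to mean zero
#' each iteration; respondents absorb the grand level. The group measure
#' `beta_g` is identified post hoc as the group mean of the combined
#' respondent parameter minus the unweighted mean of the group means
#' (re-centered so `mean(beta) = 0`), and `alpha_n = theta_n - beta_g(n)`.
#'
#' Respondents with all-minimum or all-maximum categories (extreme scores)
#' carry no information about their measure; they are excluded from
#' estimation and their measure is imputed as the value whose expected score
#' lies `extreme_adjust` step points inside the extreme, with the standard
#' error flagged as extrapolated.
#'
#' @param cells Categorized cell matrix (from [preprocess_trials()] or
#'   [simulate_categories()]); rows with `NA` category are ignored.
#' @param control An [mfrm_control()] object.
#' @return An object of class `"mfrm_fit"`: a list with element tables
#'   (`respondents`, `groups`, `stimuli`, `conditions`, each holding measure,
#'   SE, n_obs, raw score, infit, outfit), `tau` and `tau_se`, the observed
#'   cells with fitted `eta`, `expected`, `variance` and `residual` columns
#'   (`obs`), and convergence information.
#' @export
jmle_fit <- function(cells, control = mfrm_control()) {
  stopifnot(inherits(control, "mfrm_control"))
  need <- c("respondent_id", "group", "condition", "stimulus_id", "category")
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0) {
    stop("cells lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  obs <- cells[!is.na(cells$category), , drop = FALSE]
  if (nrow(obs) == 0) stop("no categorized cells to fit", call. = FALSE)
  K <- max(obs$category)
  if (K < 2) stop("need at least 2 observed categories", call. = FALSE)
  if (!all(seq_len(K) %in% obs$category)) {
    stop("every category in 1..", K, " must be observed at least once; ",
         "collapse categories before fitting", call. = FALSE)
  }
  maxk <- K - 1L

  # peel off extreme respondents (removal cannot create respondent extremes,
  # but re-check stimuli/conditions afterwards)
  extreme <- data.frame(respondent_id = character(0), group = character(0),
                        raw = numeric(0), n = integer(0), max = logical(0),
                        stringsAsFactors = FALSE)
  repeat {
    ridf <- factor(obs$respondent_id)
    k <- obs$category - 1L
    tot <- .rowsum_vec(as.numeric(k), as.integer(ridf), nlevels(ridf))
    n <- .rowsum_vec(rep(1, nrow(obs)), as.integer(ridf), nlevels(ridf))
    ex <- tot == 0 | tot == n * maxk
    if (!any(ex)) break
    ids <- levels(ridf)[ex]
    gmap <- obs$group[match(ids, obs$respondent_id)]
    extreme <- rbind(extreme,
                     data.frame(respondent_id = ids, group = gmap,
                                raw = tot[ex], n = as.integer(n[ex]),
                                max = (tot == n * maxk)[ex],
                                stringsAsFactors = FALSE))
    obs <- obs[!(obs$respondent_id %in% ids), , drop = FALSE]
    if (nrow(obs) == 0) {
      stop("all respondents have extreme scores; nothing to estimate",
           call. = FALSE)
    }
  }

  ridf <- factor(obs$respondent_id)
  sidf <- factor(obs$stimulus_id)
  cidf <- factor(obs$condition)
  ri <- as.integer(ridf); si <- as.integer(sidf); ci <- as.integer(cidf)
  nR <- nlevels(ridf); nS <- nlevels(sidf); nC <- nlevels(cidf)
  k <- as.numeric(obs$category - 1L)
  one <- rep(1, nrow(obs))

  # stimulus / condition extremes are unsupported: abort with guidance
  for (f in list(list(i = si, n = nS, lab = "stimulus"),
                 list(i = ci, n = nC, lab = "condition"))) {
    tot <- .rowsum_vec(k, f$i, f$n)
    nn <- .rowsum_vec(one, f$i, f$n)
    if (any(tot == 0 | tot == nn * maxk)) {
      stop("extreme ", f$lab, " score encountered; the facet measure is not ",
           "finite on these data", call. = FALSE)
    }
  }

  grp_of_resp <- obs$group[match(levels(ridf), obs$respondent_id)]
  if (anyDuplicated(unique(obs[, c("respondent_id", "group")])$respondent_id)) {
    stop("respondent(s) with more than one group label", call. = FALSE)
  }

  raw_r <- .rowsum_vec(k, ri, nR)
  n_r <- .rowsum_vec(one, ri, nR)
  p0 <- pmin(pmax(raw_r / (n_r * maxk), 0.02), 0.98)
  theta <- log(p0 / (1 - p0))
  gamma <- numeric(nS)
  eps <- numeric(nC)
  tau <- numeric(maxk)

  iter <- 0L
  max_res <- Inf
  max_change <- Inf
  sm <- control$step_max
  for (iter in seq_len(control$max_iter)) {
    old <- c(theta, gamma, eps, tau)

    ew <- expected_score_variance(theta[ri] + gamma[si] + eps[ci], tau)
    theta <- theta + .clip(.rowsum_vec(k - ew$E, ri, nR) /
                             pmax(.rowsum_vec(ew$W, ri, nR), 1e-10), sm)

    ew <- expected_score_variance(theta[ri] + gamma[si] + eps[ci], tau)
    gamma <- gamma + .clip(.rowsum_vec(k - ew$E, si, nS) /
                             pmax(.rowsum_vec(ew$W, si, nS), 1e-10), sm)
    gamma <- gamma - mean(gamma)

    ew <- expected_score_variance(theta[ri] + gamma[si] + eps[ci], tau)
    eps <- eps + .clip(.rowsum_vec(k - ew$E, ci, nC) /
                         pmax(.rowsum_vec(ew$W, ci, nC), 1e-10), sm)
    eps <- eps - mean(eps)

    P <- .rsm_prob(theta[ri] + gamma[si] + eps[ci], tau)
    for (h in seq_len(maxk)) {
      Pge <- rowSums(P[, (h + 1):K, drop = FALSE])
      Oh <- sum(k >= h)
      Eh <- sum(Pge)
      Vh <- max(sum(Pge * (1 - Pge)), 1e-10)
      tau[h] <- tau[h] + .clip((Eh - Oh) / Vh, sm)
    }
    tau <- tau - mean(tau)

    ew <- expected_score_variance(theta[ri] + gamma[si] + eps[ci], tau)
    res_r <- abs(.rowsum_vec(k - ew$E, ri, nR))
    res_s <- abs(.rowsum_vec(k - ew$E, si, nS))
    res_c <- abs(.rowsum_vec(k - ew$E, ci, nC))
    P <- .rsm_prob(theta[ri] + gamma[si] + eps[ci], tau)
    res_t <- vapply(seq_len(maxk), function(h) {
      abs(sum(rowSums(P[, (h + 1):K, drop = FALSE])) - sum(k >= h))
    }, numeric(1))
    max_res <- max(res_r, res_s, res_c, res_t)
    max_change <- max(abs(c(theta, gamma, eps, tau) - old))
    if (max_res < control$conv_score && max_change < control$conv_param) break
  }
  converged <- max_res < control$conv_score &&
    max_change < control$conv_param
  if (!converged) {
    stop("JMLE did not converge after ", iter, " iterations (max score ",
         "residual ", signif(max_res, 3), ", max parameter change ",
         signif(max_change, 3), "); raise max_iter or check the data",
         call. = FALSE)
  }

  eta <- theta[ri] + gamma[si] + eps[ci]
  ew <- expected_score_variance(eta, tau)
  W <- ew$W
  resid <- k - ew$E

  info_r <- .rowsum_vec(W, ri, nR)
  info_s <- .rowsum_vec(W, si, nS)
  info_c <- .rowsum_vec(W, ci, nC)
  se_r <- 1 / sqrt(info_r)
  se_s <- 1 / sqrt(info_s)
  se_c <- 1 / sqrt(info_c)

  # beta: two-stage decomposition of the combined respondent parameter
  glev <- sort(unique(grp_of_resp))
  gmeans <- vapply(glev, function(g) mean(theta[grp_of_resp == g]),
                   numeric(1))
  beta <- gmeans - mean(gmeans)
  alpha <- theta - beta[match(grp_of_resp, glev)]
  gi <- match(obs$group, glev)
  info_g <- .rowsum_vec(W, gi, length(glev))
  se_g <- 1 / sqrt(info_g)

  fit_elem <- function(idx, n_elem) {
    r2 <- resid^2
    data.frame(
      outfit = .rowsum_vec(r2 / pmax(W, 1e-10), idx, n_elem) /
        .rowsum_vec(one, idx, n_elem),
      infit = .rowsum_vec(r2, idx, n_elem) / pmax(.rowsum_vec(W, idx, n_elem),
                                                  1e-10)
    )
  }
  fr <- fit_elem(ri, nR); fs <- fit_elem(si, nS); fc <- fit_elem(ci, nC)
  fg <- fit_elem(gi, length(glev))

  respondents <- data.frame(
    respondent_id = levels(ridf), group = grp_of_resp,
    theta = theta, alpha = alpha, se = se_r,
    n_obs = as.integer(n_r), raw_score = raw_r,
    max_score = as.integer(n_r * maxk),
    extreme = FALSE, infit = fr$infit, outfit = fr$outfit,
    stringsAsFactors = FALSE)

  # impute measures for extreme respondents
  if (nrow(extreme) > 0) {
    all_cells <- cells[!is.na(cells$category), , drop = FALSE]
    adj <- control$extreme_adjust
    ex_rows <- lapply(seq_len(nrow(extreme)), function(i) {
      id <- extreme$respondent_id[i]
      oc <- all_cells[all_cells$respondent_id == id, , drop = FALSE]
      base <- gamma[match(oc$stimulus_id, levels(sidf))] +
        eps[match(oc$condition, levels(cidf))]
      if (anyNA(base)) base <- base[!is.na(base)]
      target <- if (extreme$max[i]) extreme$n[i] * maxk - adj else adj
      th <- .solve_theta(target, base, tau)
      ew_i <- expected_score_variance(th + base, tau)
      data.frame(respondent_id = id, group = extreme$group[i],
                 theta = th, alpha = NA_real_,
                 se = 1 / sqrt(sum(ew_i$W)),
                 n_obs = extreme$n[i], raw_score = extreme$raw[i],
                 max_score = as.integer(extreme$n[i] * maxk),
                 extreme = TRUE, infit = NA_real_, outfit = NA_real_,
                 stringsAsFactors = FALSE)
    })
    ex_df <- do.call(rbind, ex_rows)
    ex_df$alpha <- ex_df$theta -
      ifelse(ex_df$group %in% glev, beta[match(ex_df$group, glev)], 0)
    respondents <- rbind(respondents, ex_df)
    respondents <- respondents[order(respondents$respondent_id), ,
                               drop = FALSE]
    rownames(respondents) <- NULL
  }

  groups <- data.frame(group = glev, beta = unname(beta), se = se_g,
                       n_obs = as.integer(.rowsum_vec(one, gi,
                                                      length(glev))),
                       infit = fg$infit, outfit = fg$outfit,
                       stringsAsFactors = FALSE)
  stimuli <- data.frame(stimulus_id = levels(sidf), gamma = gamma, se = se_s,
                        n_obs = as.integer(.rowsum_vec(one, si, nS)),
                        infit = fs$infit, outfit = fs$outfit,
                        stringsAsFactors = FALSE)
  conditions <- data.frame(condition = levels(cidf), epsilon = eps,
                           se = se_c,
                           n_obs = as.integer(.rowsum_vec(one, ci, nC)),
                           infit = fc$infit, outfit = fc$outfit,
                           stringsAsFactors = FALSE)

  tau_se <- vapply(seq_len(maxk), function(h) {
    P <- .rsm_prob(eta, tau)
    Pge <- rowSums(P[, (h + 1):K, drop = FALSE])
    1 / sqrt(max(sum(Pge * (1 - Pge)), 1e-10))
  }, numeric(1))

  obs_out <- obs
  obs_out$eta <- eta
  obs_out$expected <- ew$E
  obs_out$variance <- W
  obs_out$residual <- resid
  rownames(obs_out) <- NULL

  structure(list(respondents = respondents, groups = groups,
                 stimuli = stimuli, conditions = conditions,
                 tau = tau, tau_se = tau_se, n_categories = K,
                 obs = obs_out, converged = converged, iterations = iter,
                 max_score_residual = max_res,
                 max_param_change = max_change, control = control),
            class = "mfrm_fit")
}

#' @export
coef.mfrm_fit <- function(object, ...) {
  list(alpha = stats::setNames(object$respondents$alpha,
                               object$respondents$respondent_id),
       theta = stats::setNames(object$respondents$theta,
                               object$respondents$respondent_id),
       beta = stats::setNames(object$groups$beta, object$groups$group),
       gamma = stats::setNames(object$stimuli$gamma,
                               object$stimuli$stimulus_id),
       epsilon = stats::setNames(object$conditions$epsilon,
                                 object$conditions$condition),
       tau = object$tau)
}

#' @export
print.mfrm_fit <- function(x, ...) {
  cat("Many-facet rating-scale Rasch fit (JMLE)\n")
  cat(sprintf("  %d respondents (%d extreme), %d groups, %d stimuli, %d conditions, %d categories\n",
              nrow(x$respondents), sum(x$respondents$extreme),
              nrow(x$groups), nrow(x$stimuli), nrow(x$conditions),
              x$n_categories))
  cat(sprintf("  converged in %d iterations (max score residual %.2g)\n",
              x$iterations, x$max_score_residual))
  cat("  condition measures (logits):\n")
  for (i in seq_len(nrow(x$conditions))) {
    cat(sprintf("    %-10s %+.3f (SE %.3f)\n", x$conditions$condition[i],
                x$conditions$epsilon[i], x$conditions$se[i]))
  }
  cat(sprintf("  thresholds tau: %s\n",
              paste(sprintf("%+.3f", x$tau), collapse = ", ")))
  invisible(x)
}

#' Infit and outfit mean-square statistics
#'
#' For an element's score residuals `r = x - E` with model variances `W`:
#' outfit (unweighted mean square) `= mean(r^2 / W)`; infit
#' (information-weighted mean square) `= sum(r^2) / sum(W)`. Both have
#' expectation 1 under model fit; values between 0.5 and 2 are conventionally
#' read as acceptable. A single aberrant observation with small `W` inflates
#' outfit much more than infit.
#'
#' @param residual Numeric vector of score residuals.
#' @param variance Numeric vector of model variances, same length.
#' @return A list with `infit` and `outfit`.
#' @export
fit_statistics <- function(residual, variance) {
  stopifnot(length(residual) == length(variance), length(residual) >= 1,
            all(variance > 0))
  list(infit = sum(residual^2) / sum(variance),
       outfit = mean(residual^2 / variance))
}

#' Separation reliability of a set of element estimates
#'
#' `R = max(0, (var(measures) - mean(se^2)) / var(measures))`: the share of
#' the observed spread of a facet's estimates attributable to true
#' differences rather than measurement error. The observed variance uses the
#' `n - 1` denominator.
#'
#' @param measure Numeric vector of element measures (logits).
#' @param se Numeric vector of standard errors, same length.
#' @return Reliability in `[0, 1]`.
#' @export
separation_reliability <- function(measure, se) {
  stopifnot(length(measure) == length(se), length(measure) >= 2)
  v <- stats::var(measure)
  if (v <= 0) {
    warning("zero observed variance of measures; reliability set to 0",
            call. = FALSE)
    return(0)
  }
  max(0, (v - mean(se^2)) / v)
}

#' Fixed all-same chi-square for a facet
#'
#' Tests the null hypothesis that all elements of a facet share one measure.
#' With weights `w_i = 1/se_i^2`:
#' `chisq = sum(w m^2) - (sum(w m))^2 / sum(w)`, `df = L - 1`, p from the
#' chi-square distribution.
#'
#' @param measure,se Element measures and standard errors.
#' @return A list with `chisq`, `df` and `p`.
#' @export
fixed_chisquare <- function(measure, se) {
  stopifnot(length(measure) == length(se), length(measure) >= 2)
  w <- 1 / se^2
  chisq <- sum(w * measure^2) - sum(w * measure)^2 / sum(w)
  chisq <- max(chisq, 0)
  df <- length(measure) - 1L
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df,
                                                 lower.tail = FALSE))
}

#' Per-facet summary: reliability and fixed chi-square
#'
#' Extreme respondents (imputed measures, extrapolated SEs) are excluded.
#'
#' @param fit An `"mfrm_fit"` object.
#' @return A `data.frame` with one row per facet: `facet`, `n_elements`,
#'   `reliability`, `chisq`, `df`, `p`.
#' @export
facet_summary <- function(fit) {
  stopifnot(inherits(fit, "mfrm_fit"))
  resp <- fit$respondents[!fit$respondents$extreme, , drop = FALSE]
  pieces <- list(
    respondents = list(m = resp$theta, s = resp$se),
    groups = list(m = fit$groups$beta, s = fit$groups$se),
    stimuli = list(m = fit$stimuli$gamma, s = fit$stimuli$se),
    conditions = list(m = fit$conditions$epsilon, s = fit$conditions$se)
  )
  rows <- lapply(names(pieces), function(nm) {
    p <- pieces[[nm]]
    cs <- fixed_chisquare(p$m, p$s)
    data.frame(facet = nm, n_elements = length(p$m),
               reliability = separation_reliability(p$m, p$s),
               chisq = cs$chisq, df = cs$df, p = cs$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Element-level parameter table of a fit
#'
#' One row per element of every facet, in the layout used by the text
#' reports: facet, element id, measure (logits), SE, n_obs, infit, outfit,
#' extreme flag.
#'
#' @param fit An `"mfrm_fit"` object.
#' @return A `data.frame`.
#' @export
parameter_table <- function(fit) {
  stopifnot(inherits(fit, "mfrm_fit"))
  r <- fit$respondents
  rows <- rbind(
    data.frame(facet = "respondent", element = r$respondent_id,
               measure = r$theta, se = r$se, n_obs = r$n_obs,
               infit = r$infit, outfit = r$outfit, extreme = r$extreme,
               stringsAsFactors = FALSE),
    data.frame(facet = "group", element = fit$groups$group,
               measure = fit$groups$beta, se = fit$groups$se,
               n_obs = fit$groups$n_obs, infit = fit$groups$infit,
               outfit = fit$groups$outfit, extreme = FALSE,
               stringsAsFactors = FALSE),
    data.frame(facet = "stimulus", element = fit$stimuli$stimulus_id,
               measure = fit$stimuli$gamma, se = fit$stimuli$se,
               n_obs = fit$stimuli$n_obs, infit = fit$stimuli$infit,
               outfit = fit$stimuli$outfit, extreme = FALSE,
               stringsAsFactors = FALSE),
    data.frame(facet = "condition", element = fit$conditions$condition,
               measure = fit$conditions$epsilon, se = fit$conditions$se,
               n_obs = fit$conditions$n_obs, infit = fit$conditions$infit,
               outfit = fit$conditions$outfit, extreme = FALSE,
               stringsAsFactors = FALSE),
    data.frame(facet = "threshold",
               element = paste0("tau", seq_along(fit$tau)),
               measure = fit$tau, se = fit$tau_se, n_obs = nrow(fit$obs),
               infit = NA_real_, outfit = NA_real_, extreme = FALSE,
               stringsAsFactors = FALSE)
  )
  rownames(rows) <- NULL
  rows
}
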