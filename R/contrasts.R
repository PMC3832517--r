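# Interaction (bias) analysis on top of a converged main fit: differential
# stimulus / condition functioning, IAT effects and group contrasts. The main
# fit is frozen; each interaction cell gets a single offset delta solved from
# its own score equation (two-pass procedure).

#' Estimate interaction (bias) terms
#'
#' For every combination of the requested facets, solves for the offset
#' `delta` added to the fitted linear predictor of the cell's observations so
#' that the observed and expected raw scores agree:
#' `delta <- delta + sum(x - E) / sum(W)` (Newton), to tolerance `tol` on the
#' score residual. Main-effect parameters are untouched. `SE = 1/sqrt(sum(W))`
#' at the solution.
#'
#' Cells with all-minimum or all-maximum observed categories have no finite
#' bias estimate: `delta` and `se` are `NA` and the cell is flagged
#' `extreme`, with a warning.
#'
#' @param fit A converged `"mfrm_fit"`.
#' @param facets Character vector of grouping columns among
#'   `"stimulus_id"`, `"condition"`, `"group"`, `"respondent_id"`. Default is
#'   the stimulus x condition x group interaction behind the differential
#'   stimulus functioning table.
#' @param tol Convergence tolerance on the absolute score residual.
#' @param max_iter Maximum Newton iterations.
#' @return A `data.frame` with the facet columns, `delta`, `se`, `n_obs`,
#'   `ors` (observed raw score: sum of the cell's categories 1..K) and
#'   `extreme`.
#' @export
estimate_bias <- function(fit, facets = c("stimulus_id", "condition",
                                          "group"),
                          tol = 1e-4, max_iter = 100) {
  stopifnot(inherits(fit, "mfrm_fit"))
  obs <- fit$obs
  bad <- setdiff(facets, names(obs))
  if (length(bad) > 0) {
    stop("unknown facet column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(obs[, facets, drop = FALSE], drop = TRUE, sep = "\r",
                     lex.order = TRUE)
  ki <- as.integer(key)
  nK <- nlevels(key)
  k <- as.numeric(obs$category - 1L)
  maxk <- fit$n_categories - 1L
  one <- rep(1, nrow(obs))
  tot <- .rowsum_vec(k, ki, nK)
  n <- .rowsum_vec(one, ki, nK)
  is_extreme <- tot == 0 | tot == n * maxk
  if (any(is_extreme)) {
    warning(sum(is_extreme), " extreme interaction cell(s): bias not ",
            "estimable, excluded from downstream t-tests", call. = FALSE)
  }
  delta <- numeric(nK)
  free <- which(!is_extreme)
  ew <- expected_score_variance(obs$eta + delta[ki], fit$tau)
  den <- pmax(.rowsum_vec(ew$W, ki, nK), 1e-10)
  if (length(free) > 0) {
    for (i in seq_len(max_iter)) {
      ew <- expected_score_variance(obs$eta + delta[ki], fit$tau)
      num <- .rowsum_vec(k - ew$E, ki, nK)
      den <- pmax(.rowsum_vec(ew$W, ki, nK), 1e-10)
      if (max(abs(num[free])) < tol) break
      delta[free] <- delta[free] + .clip(num[free] / den[free], 1)
    }
  }
  delta[is_extreme] <- NA_real_
  first <- !duplicated(ki)
  out <- obs[first, facets, drop = FALSE]
  ord <- order(ki[first])
  out <- out[ord, , drop = FALSE]
  out$delta <- delta
  out$se <- ifelse(is_extreme, NA_real_, 1 / sqrt(den))
  out$n_obs <- as.integer(n)
  out$ors <- as.integer(tot + n)  # categories are steps + 1
  out$extreme <- is_extreme
  rownames(out) <- NULL
  out
}

.sig_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Differential stimulus functioning table
#'
#' For each attribute stimulus and respondent group, compares the
#' condition-specific stimulus measures `MSR_c = gamma_stimulus +
#' delta_(stimulus, condition, group)` between the two associative
#' conditions: `t = (MSR_1 - MSR_2) / sqrt(SE_1^2 + SE_2^2)`,
#' `df = n_1 + n_2 - 2`, Cohen's `d = 2|t| / sqrt(df)` (unsigned), two-sided
#' p from the t distribution, significance markers `*` p < 0.05 and `**`
#' p < 0.01. Rows are sorted by `t` descending within group.
#'
#' @param fit A converged `"mfrm_fit"`.
#' @param bias Optional precomputed [estimate_bias()] result for
#'   `c("stimulus_id", "condition", "group")`; computed if `NULL`.
#' @param conditions Length-2 character vector giving the column order
#'   (condition 1 first). Defaults to `c("HEG_HOB", "HOG_HEB")` when present,
#'   otherwise the sorted condition labels.
#' @return A `data.frame` with columns `group`, `stimulus_id`, `ors1`,
#'   `msr1`, `se1`, `ors2`, `msr2`, `se2`, `t`, `sig`, `df`, `d`,
#'   `incomplete`.
#' @export
dsf_table <- function(fit, bias = NULL, conditions = NULL) {
  stopifnot(inherits(fit, "mfrm_fit"))
  if (is.null(bias)) {
    bias <- estimate_bias(fit, c("stimulus_id", "condition", "group"))
  }
  if (is.null(conditions)) {
    lab <- fit$conditions$condition
    conditions <- if (all(c("HEG_HOB", "HOG_HEB") %in% lab)) {
      c("HEG_HOB", "HOG_HEB")
    } else {
      sort(lab)
    }
  }
  stopifnot(length(conditions) == 2)
  gam <- stats::setNames(fit$stimuli$gamma, fit$stimuli$stimulus_id)
  b1 <- bias[bias$condition == conditions[1], , drop = FALSE]
  b2 <- bias[bias$condition == conditions[2], , drop = FALSE]
  key1 <- paste(b1$group, b1$stimulus_id, sep = "\r")
  key2 <- paste(b2$group, b2$stimulus_id, sep = "\r")
  keys <- union(key1, key2)
  m1 <- match(keys, key1)
  m2 <- match(keys, key2)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(group = parts[, 1], stimulus_id = parts[, 2],
                    stringsAsFactors = FALSE)
  out$ors1 <- b1$ors[m1]
  out$msr1 <- unname(gam[out$stimulus_id]) + b1$delta[m1]
  out$se1 <- b1$se[m1]
  out$ors2 <- b2$ors[m2]
  out$msr2 <- unname(gam[out$stimulus_id]) + b2$delta[m2]
  out$se2 <- b2$se[m2]
  n1 <- b1$n_obs[m1]
  n2 <- b2$n_obs[m2]
  out$t <- dsf_t(out$msr1, out$se1, out$msr2, out$se2)
  out$df <- n1 + n2 - 2L
  out$d <- ifelse(is.na(out$t), NA_real_, 2 * abs(out$t) / sqrt(out$df))
  p <- 2 * stats::pt(-abs(out$t), out$df)
  out$sig <- .sig_stars(p)
  out$incomplete <- is.na(out$msr1) | is.na(out$msr2)
  out <- out[order(out$group, -xtfrm(out$t)), , drop = FALSE]
  out <- out[, c("group", "stimulus_id", "ors1", "msr1", "se1", "ors2",
                 "msr2", "se2", "t", "sig", "df", "d", "incomplete")]
  rownames(out) <- NULL
  out
}

#' t statistic for the difference of two measures
#'
#' Tests whether two (approximately independent) logit measures differ:
#' `t = (msr1 - msr2) / sqrt(se1^2 + se2^2)`. This is the statistic printed
#' per stimulus and group in the differential stimulus functioning table.
#'
#' @param msr1,msr2 Measures (logits).
#' @param se1,se2 Their standard errors.
#' @return Numeric vector of t statistics.
#' @export
dsf_t <- function(msr1, se1, msr2, se2) {
  (msr1 - msr2) / sqrt(se1^2 + se2^2)
}

#' Cohen's d from a t statistic
#'
#' `d = 2 |t| / sqrt(df)`, reported unsigned.
#'
#' @param t t statistic(s).
#' @param df Degrees of freedom (positive).
#' @return Numeric vector of effect sizes.
#' @export
cohens_d_from_t <- function(t, df) {
  if (any(df <= 0)) stop("df must be positive", call. = FALSE)
  2 * abs(t) / sqrt(df)
}

#' Overall IAT effect from the condition measures
#'
#' The IAT effect is the distance between the two associative-condition
#' measures, `delta = epsilon_1 - epsilon_2` with condition 1 the
#' Heterosexuals-Good/Homosexuals-Bad mapping by default, so that a positive
#' effect means that mapping is easier. `SE = sqrt(se_1^2 + se_2^2)`,
#' `z = delta / SE`, two-sided normal p.
#'
#' @param x Either an `"mfrm_fit"` or a `data.frame` with columns
#'   `condition`, `measure` and (optionally) `se`.
#' @param conditions Length-2 character vector fixing the sign convention
#'   (first minus second); defaults as in [dsf_table()].
#' @return A one-row `data.frame`: `scope = "overall"`, `delta`, `se`, `z`,
#'   `p` (`NA` when SEs are unavailable).
#' @export
iat_effect <- function(x, conditions = NULL) {
  if (inherits(x, "mfrm_fit")) {
    est <- data.frame(condition = x$conditions$condition,
                      measure = x$conditions$epsilon,
                      se = x$conditions$se, stringsAsFactors = FALSE)
  } else {
    est <- as.data.frame(x)
    if (is.null(est$se)) est$se <- NA_real_
  }
  stopifnot(all(c("condition", "measure") %in% names(est)),
            nrow(est) == 2)
  if (is.null(conditions)) {
    conditions <- if (all(c("HEG_HOB", "HOG_HEB") %in% est$condition)) {
      c("HEG_HOB", "HOG_HEB")
    } else {
      sort(est$condition)
    }
  }
  i1 <- match(conditions[1], est$condition)
  i2 <- match(conditions[2], est$condition)
  if (anyNA(c(i1, i2))) {
    stop("condition label(s) not found: ",
         paste(setdiff(conditions, est$condition), collapse = ", "),
         call. = FALSE)
  }
  delta <- est$measure[i1] - est$measure[i2]
  se <- sqrt(est$se[i1]^2 + est$se[i2]^2)
  z <- delta / se
  data.frame(scope = "overall", delta = delta, se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
}

#' Group-specific IAT effects (differential condition functioning)
#'
#' Shifts the overall IAT effect by each group's condition x group bias
#' terms: `delta_g = delta + (delta_(cond1, g) - delta_(cond2, g))`, with
#' `SE` combined from the two bias-cell SEs, and a two-sided normal z-test.
#' Groups with fewer than 2 respondents are skipped with a warning.
#'
#' @param fit A converged `"mfrm_fit"`.
#' @param overall Optional precomputed [iat_effect()] row.
#' @param bias Optional precomputed [estimate_bias()] result for
#'   `c("condition", "group")`.
#' @param conditions Sign convention, as in [iat_effect()].
#' @return A `data.frame` with one row per group: `scope` (group label),
#'   `delta`, `se`, `z`, `p`.
#' @export
group_iat_effects <- function(fit, overall = NULL, bias = NULL,
                              conditions = NULL) {
  stopifnot(inherits(fit, "mfrm_fit"))
  if (is.null(overall)) overall <- iat_effect(fit, conditions = conditions)
  if (is.null(bias)) bias <- estimate_bias(fit, c("condition", "group"))
  if (is.null(conditions)) {
    lab <- fit$conditions$condition
    conditions <- if (all(c("HEG_HOB", "HOG_HEB") %in% lab)) {
      c("HEG_HOB", "HOG_HEB")
    } else {
      sort(lab)
    }
  }
  n_resp <- table(fit$respondents$group)
  rows <- lapply(sort(unique(bias$group)), function(g) {
    if (!is.na(n_resp[g]) && n_resp[g] < 2) {
      warning("group ", g, " has fewer than 2 respondents; skipped",
              call. = FALSE)
      return(NULL)
    }
    b1 <- bias[bias$group == g & bias$condition == conditions[1], ,
               drop = FALSE]
    b2 <- bias[bias$group == g & bias$condition == conditions[2], ,
               drop = FALSE]
    if (nrow(b1) != 1 || nrow(b2) != 1) return(NULL)
    delta <- overall$delta + (b1$delta - b2$delta)
    se <- sqrt(b1$se^2 + b2$se^2)
    z <- delta / se
    data.frame(scope = g, delta = delta, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two IAT effects
#'
#' Normal z-test on the difference of two effects, either signed or in
#' absolute value (to compare the strength of opposite-direction
#' preferences): `z = (v1 - v2) / sqrt(se1^2 + se2^2)` with `v = delta` or
#' `|delta|`.
#'
#' @param effect1,effect2 One-row `data.frame`s as returned by
#'   [iat_effect()] / rows of [group_iat_effects()].
#' @param absolute Compare `|delta|` instead of `delta`.
#' @return A one-row `data.frame`: `scope1`, `scope2`, `absolute`, `z`, `p`.
#' @export
compare_effects <- function(effect1, effect2, absolute = FALSE) {
  v1 <- if (absolute) abs(effect1$delta) else effect1$delta
  v2 <- if (absolute) abs(effect2$delta) else effect2$delta
  se <- sqrt(effect1$se^2 + effect2$se^2)
  z <- (v1 - v2) / se
  data.frame(scope1 = effect1$scope, scope2 = effect2$scope,
             absolute = absolute, z = z, p = 2 * stats::pnorm(-abs(z)),
             stringsAsFactors = FALSE)
}
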