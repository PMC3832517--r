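# Conventional IAT D2 scores, computed from the same trial-level data as the
# Rasch pipeline and used as a cross-check on the model-based IAT effects.

#' D-score computation options
#'
#' The D2 variant: latencies above `drop_slow_ms` are deleted; error trials
#' keep their recorded latencies (no penalty); latencies below `flag_fast_ms`
#' are retained in scoring but a respondent is flagged when their fraction
#' exceeds `flag_fast_fraction`; the divisor is the combined two-block
#' standard deviation (n - 1). Optionally, trials faster than 400 ms can be
#' deleted (`drop_fast_400`, off by default).
#'
#' @param compatible Condition label treated as the compatible mapping:
#'   positive D means faster responding there.
#' @param drop_slow_ms Delete trials slower than this (ms).
#' @param flag_fast_ms,flag_fast_fraction Anticipatory-response flag rule.
#' @param drop_fast_400 Also delete trials faster than 400 ms.
#' @return A list of class `"dscore_config"`.
#' @export
dscore_config <- function(compatible = "HEG_HOB", drop_slow_ms = 10000,
                          flag_fast_ms = 300, flag_fast_fraction = 0.10,
                          drop_fast_400 = FALSE) {
  structure(list(compatible = compatible, drop_slow_ms = drop_slow_ms,
                 flag_fast_ms = flag_fast_ms,
                 flag_fast_fraction = flag_fast_fraction,
                 drop_fast_400 = isTRUE(drop_fast_400)),
            class = "dscore_config")
}

.d_pair <- function(lat_comp, lat_incomp) {
  if (length(lat_comp) < 1 || length(lat_incomp) < 1) return(NA_real_)
  all_lat <- c(lat_comp, lat_incomp)
  if (length(all_lat) < 3) return(NA_real_)
  s <- stats::sd(all_lat)
  if (!is.finite(s) || s == 0) return(NA_real_)
  (mean(lat_incomp) - mean(lat_comp)) / s
}

#' Per-respondent conventional D2 scores
#'
#' For each respondent, critical-block trials are split into block pairs
#' (within each condition, the first critical block forms pair 1 and the
#' second pair 2, so the counterbalanced order is handled by the condition
#' labels, not the block indices). Within a pair,
#' `D_pair = (mean incompatible latency - mean compatible latency) / SD` of
#' all latencies in the pair's two blocks combined; the respondent's D is
#' the mean of the available pair Ds.
#'
#' @param trials Trial `data.frame` (unfiltered; this function applies its
#'   own D2 trial rules from `config`).
#' @param config A [dscore_config()] object.
#' @return A `data.frame` with one row per respondent: `respondent_id`,
#'   `group`, `d`, `d_pair1`, `d_pair2`, `n_trials_used`, `excluded`,
#'   `reason`.
#' @export
dscore <- function(trials, config = dscore_config()) {
  stopifnot(inherits(config, "dscore_config"))
  crit <- trials[trials$block_role == "critical", , drop = FALSE]
  if (nrow(crit) == 0) stop("no critical-block trials", call. = FALSE)
  conds <- unique(crit$condition)
  if (!(config$compatible %in% conds)) {
    stop("compatible condition ", config$compatible, " absent from data",
         call. = FALSE)
  }
  ids <- unique(trials$respondent_id)
  rows <- lapply(ids, function(id) {
    ti <- crit[crit$respondent_id == id, , drop = FALSE]
    grp <- trials$group[match(id, trials$respondent_id)]
    flagged <- nrow(ti) > 0 &&
      mean(ti$latency_ms < config$flag_fast_ms) > config$flag_fast_fraction
    use <- ti[ti$latency_ms <= config$drop_slow_ms, , drop = FALSE]
    if (config$drop_fast_400) {
      use <- use[use$latency_ms >= 400, , drop = FALSE]
    }
    comp <- use$condition == config$compatible
    if (!any(comp) || all(comp)) {
      return(data.frame(respondent_id = id, group = grp, d = NA_real_,
                        d_pair1 = NA_real_, d_pair2 = NA_real_,
                        n_trials_used = nrow(use), excluded = TRUE,
                        reason = "missing_condition",
                        stringsAsFactors = FALSE))
    }
    # pair index: rank of the block within its condition
    pair <- integer(nrow(use))
    for (cond in unique(use$condition)) {
      sel <- use$condition == cond
      blocks <- sort(unique(use$block[sel]))
      pair[sel] <- match(use$block[sel], blocks)
    }
    dp <- vapply(1:2, function(p) {
      sel <- pair == p
      .d_pair(use$latency_ms[sel & comp], use$latency_ms[sel & !comp])
    }, numeric(1))
    d <- if (all(is.na(dp))) NA_real_ else mean(dp, na.rm = TRUE)
    data.frame(respondent_id = id, group = grp, d = d, d_pair1 = dp[1],
               d_pair2 = dp[2], n_trials_used = nrow(use),
               excluded = flagged || is.na(d),
               reason = if (flagged) "fast_fraction" else
                 if (is.na(d)) "no_scorable_pair" else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group summaries of D scores
#'
#' Arithmetic mean and `n - 1` standard deviation of the per-respondent D
#' scores, over non-excluded respondents, per group. Empty groups are
#' omitted with a warning.
#'
#' @param results Output of [dscore()].
#' @return A `data.frame` with `group`, `mean_d`, `sd_d`, `n`.
#' @export
dscore_group_summary <- function(results) {
  ok <- results[!results$excluded & !is.na(results$d), , drop = FALSE]
  groups <- sort(unique(results$group))
  rows <- lapply(groups, function(g) {
    x <- ok$d[ok$group == g]
    if (length(x) == 0) {
      warning("group ", g, " has no scorable respondents; omitted",
              call. = FALSE)
      return(NULL)
    }
    data.frame(group = g, mean_d = mean(x),
               sd_d = if (length(x) > 1) stats::sd(x) else NA_real_,
               n = length(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
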