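# Publication-style text rendering of the differential-stimulus-functioning
# table and the IAT-effect summary.

.fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
}

#' Render the differential stimulus functioning report
#'
#' Produces a plain-text report with one block per respondent group, rows
#' sorted by t descending, and columns ORS / MSR / SE per associative
#' condition followed by t, significance markers, df and Cohen's d. An
#' optional effects section lists the IAT effect per scope with its z and p.
#'
#' @param dsf A [dsf_table()] `data.frame` (may be empty: header-only
#'   report).
#' @param effects Optional `data.frame` of effects
#'   (rbind of [iat_effect()] and [group_iat_effects()] rows).
#' @param file Connection or path for [writeLines()]; `""` prints to the
#'   console.
#' @return Invisibly, the character vector of report lines.
#' @export
render_dsf_report <- function(dsf, effects = NULL, file = "") {
  hdr <- sprintf("%-12s %6s %7s %5s %6s %7s %5s %7s %-3s %6s %6s",
                 "Stimulus", "ORS1", "MSR1", "SE1", "ORS2", "MSR2", "SE2",
                 "t", "", "df", "d")
  lines <- c("Differential stimulus functioning",
             "Condition 1 / condition 2 columns follow the fit's sign convention",
             "")
  if (!is.null(dsf) && nrow(dsf) > 0) {
    for (g in unique(dsf$group)) {
      di <- dsf[dsf$group == g, , drop = FALSE]
      lines <- c(lines, sprintf("%s (n cells = %d)", g, nrow(di)), hdr)
      for (i in seq_len(nrow(di))) {
        lines <- c(lines, sprintf(
          "%-12s %6s %7s %5s %6s %7s %5s %7s %-3s %6s %6s",
          di$stimulus_id[i], ifelse(is.na(di$ors1[i]), "", di$ors1[i]),
          .fmt_num(di$msr1[i]), .fmt_num(di$se1[i]),
          ifelse(is.na(di$ors2[i]), "", di$ors2[i]),
          .fmt_num(di$msr2[i]), .fmt_num(di$se2[i]),
          .fmt_num(di$t[i]), di$sig[i],
          ifelse(is.na(di$df[i]), "", di$df[i]), .fmt_num(di$d[i])))
      }
      lines <- c(lines, "")
    }
  } else {
    lines <- c(lines, hdr, "")
  }
  lines <- c(lines, "* p < 0.05; ** p < 0.01 (two-sided)")
  if (!is.null(effects) && nrow(effects) > 0) {
    lines <- c(lines, "", "IAT effects (logits)",
               sprintf("%-14s %8s %7s %8s %10s", "Scope", "Delta", "SE",
                       "z", "p"))
    for (i in seq_len(nrow(effects))) {
      lines <- c(lines, sprintf("%-14s %8s %7s %8s %10s",
                                effects$scope[i],
                                .fmt_num(effects$delta[i]),
                                .fmt_num(effects$se[i], 3),
                                .fmt_num(effects$z[i]),
                                format.pval(effects$p[i], digits = 3,
                                            eps = 1e-16)))
    }
  }
  writeLines(lines, con = file)
  invisible(lines)
}
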