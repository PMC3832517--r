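#' Reference differential-stimulus-functioning table
#'
#' The published three-group Sexuality-IAT differential stimulus functioning
#' table (heterosexual, gay and bisexual respondents; 15 attribute stimuli),
#' shipped as a plain-text fixture: observed raw scores, condition-specific
#' stimulus measures and standard errors (logits) per associative condition
#' (column 1 = Heterosexuals-Good/Homosexuals-Bad), with the reported t,
#' significance markers, df and Cohen's d. Used to regression-test the
#' package's t and effect-size arithmetic against printed values.
#'
#' @return A `data.frame` with columns `group`, `stimulus_id`, `ors1`,
#'   `msr1`, `se1`, `ors2`, `msr2`, `se2`, `t`, `sig`, `df`, `d`.
#' @export
dsf_reference <- function() {
  path <- system.file("extdata", "sexuality_iat_dsf_reference.csv",
                      package = "iatfacets", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sig = "character"))
}
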