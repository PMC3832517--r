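# Fixtures built in code: tiny trial sets, a hand-picked toy cell matrix for
# oracle comparisons, and small simulation configs.

make_trials <- function(latency_ms, respondent_id = "R1",
                        group = "heterosexual", block = 3L,
                        block_role = "critical", condition = "HEG_HOB",
                        stimulus_id = "pleasure",
                        stimulus_class = "attribute_positive",
                        error = FALSE) {
  data.frame(respondent_id = respondent_id, group = group, block = block,
             block_role = block_role, condition = condition,
             stimulus_id = stimulus_id, stimulus_class = stimulus_class,
             latency_ms = latency_ms, error = error,
             stringsAsFactors = FALSE)
}

write_trials_csv <- function(trials, path = tempfile(fileext = ".csv"),
                             sep = ",") {
  utils::write.table(trials, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  path
}

# 4 respondents x 2 conditions x 3 stimuli with fixed categories; no extreme
# element, every category observed. Used by the brute-force JMLE oracle.
toy_cells <- function() {
  cat <- c(3, 2, 3,  2, 1, 2,   # r1: c1, c2
           2, 2, 1,  1, 1, 2,   # r2
           3, 3, 2,  2, 2, 3,   # r3
           2, 1, 2,  1, 2, 1)   # r4
  grid <- expand.grid(stimulus_id = c("s1", "s2", "s3"),
                      condition = c("HEG_HOB", "HOG_HEB"),
                      respondent_id = c("r1", "r2", "r3", "r4"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(respondent_id = grid$respondent_id,
             group = ifelse(grid$respondent_id %in% c("r1", "r2"),
                            "heterosexual", "gay"),
             condition = grid$condition, stimulus_id = grid$stimulus_id,
             category = as.integer(cat), stringsAsFactors = FALSE)
}

# Minimal fake fit carrying just what estimate_bias() consumes.
fake_fit <- function(eta, category, tau = c(0, 0), group = "g1",
                     condition = "c1", stimulus_id = "s1") {
  obs <- data.frame(respondent_id = paste0("r", seq_along(eta)),
                    group = group, condition = condition,
                    stimulus_id = stimulus_id,
                    category = as.integer(category), eta = eta,
                    stringsAsFactors = FALSE)
  structure(list(obs = obs, tau = tau, n_categories = length(tau) + 1L),
            class = "mfrm_fit")
}

small_sim_config <- function(seed = 7, ...) {
  sim_config(n_per_group = c(heterosexual = 20, gay = 20, bisexual = 20),
             delta_true = c(heterosexual = 1.0, gay = -0.2, bisexual = 0.3),
             trials_per_cell = 2, seed = seed, ...)
}
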