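# Shared simulation experiments used by the acceptance checks: the recovery
# battery, the null battery, the model-true fit battery, and the brute-force
# JMLE oracle. scripts/acceptance.R re-implements the same experiments
# against the installed package.

recovery_config <- function(seed) {
  sim_config(n_per_group = c(heterosexual = 200, gay = 200, bisexual = 200),
             delta_true = c(heterosexual = 1.0, gay = -0.2, bisexual = 0.3),
             trials_per_cell = 4, seed = seed)
}

run_recovery_battery <- function(seeds) {
  truth <- c(heterosexual = 1.0, gay = -0.2, bisexual = 0.3)
  out <- lapply(seeds, function(s) {
    res <- run_synthetic_study(recovery_config(s))
    g <- res$by_group
    g$true_delta <- truth[g$scope]
    g$seed <- s
    g
  })
  do.call(rbind, out)
}

run_null_battery <- function(seeds) {
  vapply(seeds, function(s) {
    cfg <- sim_config(n_per_group = c(heterosexual = 30, gay = 30,
                                      bisexual = 30),
                      delta_true = c(heterosexual = 0, gay = 0,
                                     bisexual = 0),
                      trials_per_cell = 2, rt_slope = 0, seed = s)
    run_synthetic_study(cfg)$overall$z
  }, numeric(1))
}

# Direct joint likelihood maximization over the 8 free parameters of the toy
# instance (theta_1..4; gamma_1, gamma_2 with gamma_3 = -gamma_1 - gamma_2;
# epsilon_1 with epsilon_2 = -epsilon_1; tau_1 with tau_2 = -tau_1),
# independent of the package's estimation path.
toy_bruteforce <- function(cells) {
  ri <- match(cells$respondent_id, sort(unique(cells$respondent_id)))
  si <- match(cells$stimulus_id, sort(unique(cells$stimulus_id)))
  ci <- match(cells$condition, sort(unique(cells$condition)))
  kk <- cells$category - 1
  negll <- function(par) {
    theta <- par[1:4]
    gam <- c(par[5], par[6], -par[5] - par[6])
    eps <- c(par[7], -par[7])
    tau <- c(par[8], -par[8])
    ll <- 0
    for (i in seq_along(kk)) {
      eta <- theta[ri[i]] + gam[si[i]] + eps[ci[i]]
      ex <- c(0, eta - tau[1], 2 * eta - tau[1] - tau[2])
      ll <- ll + ex[kk[i] + 1] - log(sum(exp(ex)))
    }
    -ll
  }
  opt <- stats::optim(rep(0, 8), negll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(theta = opt$par[1:4],
       gamma = c(opt$par[5], opt$par[6], -opt$par[5] - opt$par[6]),
       epsilon = c(opt$par[7], -opt$par[7]),
       tau = c(opt$par[8], -opt$par[8]),
       value = -opt$value, convergence = opt$convergence)
}
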