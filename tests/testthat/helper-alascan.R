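# Shared fixtures and independent oracles for the test suite.

# exact logistic concentration-response data
make_logistic_data <- function(pec50 = 8, top = 100, bottom = 0,
                               conc = default_grid(), experiment_id = 1L) {
  tibble::tibble(concentration = conc,
                 response = logistic3(conc, pec50, top, bottom),
                 experiment_id = experiment_id)
}

# exact operational-model data for one or more ligands
make_operational_data <- function(truth, conc = default_grid()) {
  dplyr::bind_rows(lapply(seq_len(nrow(truth)), function(i) {
    tibble::tibble(
      ligand_id = truth$ligand_id[i], concentration = conc,
      response = operational_model(conc, truth$log_tau[i],
                                   truth$log_ka[i], truth$em[i],
                                   truth$bottom[i]))
  }))
}

# per-experiment value sets with exact mean and SEM (n = 3)
values_with <- function(mean, sem) {
  s <- sem * sqrt(3)
  mean + c(-s, 0, s)
}

# Monte-Carlo oracle for Dunnett's many-to-one adjusted p: simulates the
# null distribution of max |t| from raw Gaussian data (independent of the
# package's multivariate-t evaluation)
mc_dunnett_oracle <- function(t_obs, n0, ni, n_draws = 1e5, seed = 1) {
  set.seed(seed)
  k <- length(ni) + 1
  df <- n0 + sum(ni) - k
  m0 <- stats::rnorm(n_draws, 0, 1 / sqrt(n0))
  tmax <- rep(0, n_draws)
  ssq <- stats::rchisq(n_draws, df) / df
  for (i in seq_along(ni)) {
    mi <- stats::rnorm(n_draws, 0, 1 / sqrt(ni[i]))
    ti <- (mi - m0) / sqrt(ssq * (1 / ni[i] + 1 / n0))
    tmax <- pmax(tmax, abs(ti))
  }
  vapply(t_obs, function(t) mean(tmax >= abs(t)), double(1))
}

# single-construct cAMP truth panel (3 ligands) for recovery tests
camp_truth <- function() {
  lib <- scenario_library()
  tp <- lib$wild_type
  tp$functional <- tp$functional[tp$functional$pathway_id == "cAMP", ]
  tp
}
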