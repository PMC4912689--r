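test_that("a tau = 1 curve plateaus halfway to the system maximum", {
  truth <- tibble::tibble(ligand_id = "L", log_tau = 0, log_ka = -7,
                          em = 100, bottom = 0)
  f <- fit_operational(make_operational_data(truth))
  plateau <- f$bottom + (f$em - f$bottom) *
    10^f$log_tau / (10^f$log_tau + 1)
  expect_equal(plateau, 50, tolerance = 1e-6)
})

test_that("noiseless parameters are recovered in the identifiable setup", {
  # Em and bottom fixed: tau and K_A are then exactly determined
  truth <- tibble::tibble(ligand_id = "L", log_tau = 0.7, log_ka = -7,
                          em = 100, bottom = 0)
  f <- fit_operational(make_operational_data(truth), fix_em = 100,
                       fix_bottom = 0)
  expect_equal(f$log_tau, 0.7, tolerance = 1e-5)
  expect_equal(f$log_ka, -7, tolerance = 1e-5)
  expect_equal(f$pec50_derived, 7 + log10(10^0.7 + 1), tolerance = 1e-5)
})

test_that("derived pEC50 matches an independent logistic fit", {
  # the EC50 identity pEC50 = -logKA + log10(tau + 1) must hold for every
  # converged fit on exact data, whatever point of the Em ridge is reported
  for (lt in c(-0.5, 0.3, 1.2)) {
    truth <- tibble::tibble(ligand_id = "L", log_tau = lt, log_ka = -7.4,
                            em = 90, bottom = 5)
    d <- make_operational_data(truth)
    op <- fit_operational(d)
    lg <- fit_logistic(d[c("concentration", "response")])
    expect_equal(op$pec50_derived, -op$log_ka + log10(10^op$log_tau + 1),
                 tolerance = 1e-9)
    expect_lt(abs(lg$pec50 - op$pec50_derived), 0.05)
  }
})

test_that("K_A fixed to binding pins the tau/Em decomposition", {
  truth <- camp_truth()
  p <- generate_panel(truth, seed = 11)
  pki <- stats::setNames(truth$binding$pki, truth$binding$ligand_id)
  f <- fit_operational(p$response, ka_policy = "fix_to_binding",
                       binding = pki)
  expect_true(all(f$status == "ka_fixed"))
  expect_true(all(f$sem_log_ka == 0))
  truth_tau <- truth$functional$log_tau[
    match(f$ligand_id, truth$functional$ligand_id)]
  expect_true(all(abs(f$log_tau - truth_tau) < 0.15))
})

test_that("fits are invariant to response-unit rescaling", {
  truth <- camp_truth()
  p <- generate_panel(truth, seed = 4)
  pki <- stats::setNames(truth$binding$pki, truth$binding$ligand_id)
  f1 <- fit_operational(p$response, ka_policy = "fix_to_binding",
                        binding = pki)
  p2 <- p$response; p2$response <- p2$response * 12.5
  f2 <- fit_operational(p2, ka_policy = "fix_to_binding", binding = pki)
  expect_equal(f2$log_tau, f1$log_tau, tolerance = 1e-4)
  expect_equal(f2$log_ka, f1$log_ka, tolerance = 1e-12)
  expect_equal(f2$em, f1$em * 12.5, tolerance = 1e-3)
})

test_that("flat panels come back as no_response", {
  set.seed(2)
  d <- tibble::tibble(ligand_id = "L", concentration = default_grid(),
                      response = 3 + rnorm(11, 0, 0.4))
  f <- fit_operational(d)
  expect_equal(f$status, "no_response")
  expect_true(is.na(f$log_tau))
})

test_that("expression correction obeys its analytic identities", {
  # fraction 1 with no error: identity
  c1 <- correct_tau(0.4, 0.05, 1, 0)
  expect_equal(c1$log_tau_c, 0.4)
  expect_equal(c1$sem_log_tau_c, 0.05)
  # fraction 0.5: tau_c doubles
  c2 <- correct_tau(0.4, 0.05, 0.5, 0)
  expect_equal(c2$log_tau_c, 0.4 + log10(2), tolerance = 1e-12)
  # delta-method SEM, hand-computed:
  # 0.08 / (0.80 ln 10) = 0.0434294; sqrt(0.05^2 + 0.0434294^2) = 0.0662278
  c3 <- correct_tau(0.40, 0.05, 0.80, 0.08)
  expect_equal(c3$log_tau_c, 0.40 - log10(0.80), tolerance = 1e-12)
  expect_equal(c3$sem_log_tau_c,
               sqrt(0.05^2 + (0.08 / (0.80 * log(10)))^2),
               tolerance = 1e-12)
  expect_equal(c3$sem_log_tau_c, 0.0662278, tolerance = 1e-6)
  expect_gte(c3$sem_log_tau_c, 0.05)
})

test_that("non-determined expression propagates as absent tau_c", {
  fits <- tibble::tibble(construct_id = c("WT", "M1"), log_tau = c(1, 1),
                         sem_log_tau = c(0.1, 0.1))
  expr <- tibble::tibble(construct_id = c("WT", "M1"),
                         expression_fraction = c(1, NA),
                         sem = c(0.05, NA),
                         status = c("ok", "not_determined"))
  out <- correct_tau_table(fits, expr, "WT")
  expect_true(is.na(out$log_tau_c[out$construct_id == "M1"]))
  expect_equal(out$log_tau_c[out$construct_id == "WT"], 1)
  expect_equal(out$sem_log_tau_c[out$construct_id == "WT"], 0.1)
})

test_that("an expression-only deficit is compensated by tau_c", {
  lib <- scenario_library()
  tp <- lib$expression_deficit
  tp$functional <- tp$functional[tp$functional$pathway_id == "cAMP", ]
  in_ci <- logical(0); in_3s <- logical(0)
  for (seed in 1:5) {
    p <- generate_panel(tp, seed = seed)
    res <- analyze_panel(p, run_config())
    op <- res$operational
    wt <- op[op$construct_id == "WT", ]
    mut <- op[op$construct_id == "N210A", ]
    i <- match(wt$ligand_id, mut$ligand_id)
    # raw tau reflects the 70% expression loss...
    expect_true(all(mut$log_tau[i] < wt$log_tau - 0.3))
    # ...while corrected tau recovers wild-type
    diff <- abs(mut$log_tau_c[i] - wt$log_tau_c)
    se <- sqrt(mut$sem_log_tau_c[i]^2 + wt$sem_log_tau_c^2)
    in_ci <- c(in_ci, diff < 1.96 * se)
    in_3s <- c(in_3s, diff < 3 * se)
  }
  # 95% CIs miss occasionally by construction; gross misses should not occur
  expect_gte(mean(in_ci), 0.7)
  expect_true(all(in_3s))
})
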