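test_that("the noiseless limit reproduces operational-model means exactly", {
  tp <- camp_truth()
  p <- generate_panel(tp, cv = 0, exp_effect_sd = 0, binding_sd = 0,
                      seed = 1)
  f <- tp$functional
  for (i in seq_len(nrow(f))) {
    d <- p$response[p$response$ligand_id == f$ligand_id[i], ]
    mu <- operational_model(d$concentration, f$log_tau[i], f$log_ka[i],
                            f$em[i], f$bottom[i])
    expect_equal(d$response, mu, tolerance = 1e-12)
  }
  # binding means equal the one-site curve at the inverse Cheng-Prusoff
  # pIC50 for the tracer parameters used
  b <- p$binding[p$binding$ligand_id == "GLP-1", ]
  pic50 <- tp$binding$pki[tp$binding$ligand_id == "GLP-1"] -
    log10(1 + p$config$tracer_conc / p$config$tracer_kd)
  expect_equal(b$specific_binding,
               competition1(b$log_conc, pic50, 100, 0), tolerance = 1e-12)
})

test_that("generation is byte-identical under a fixed seed", {
  tp <- camp_truth()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_panel(generate_panel(tp, seed = 99), d1)
  write_panel(generate_panel(tp, seed = 99), d2)
  for (f in c("response.csv", "binding.csv", "expression.csv",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # and a different seed changes the draws
  p3 <- generate_panel(tp, seed = 100)
  p1 <- generate_panel(tp, seed = 99)
  expect_false(identical(p1$response$response, p3$response$response))
})

test_that("generated tables stay consistent with their own truth file", {
  tp <- camp_truth()
  p <- generate_panel(tp, seed = 12)
  # per-curve mean responses at the top concentration track the true
  # plateau within a few noise SEs
  top_conc <- max(p$response$concentration)
  f <- tp$functional
  for (i in seq_len(nrow(f))) {
    d <- p$response[p$response$ligand_id == f$ligand_id[i] &
                      p$response$concentration == top_conc, ]
    mu <- operational_model(top_conc, f$log_tau[i], f$log_ka[i], f$em[i],
                            f$bottom[i])
    expect_lt(abs(mean(d$response) - mu) / mu, 0.1)
  }
})

test_that("the scenario library covers the documented phenotype classes", {
  lib <- scenario_library()
  expect_setequal(
    names(lib),
    c("wild_type", "bias_reference", "mutant_classes",
      "expression_deficit", "enhanced_efficacy", "dead_surface",
      "full_panel"))
  # every scenario carries a wild-type construct and finite truths for it
  for (tp in lib) {
    wt <- tp$functional[tp$functional$construct_id == "WT", ]
    expect_gt(nrow(wt), 0)
    expect_true(all(is.finite(wt$log_tau)))
  }
  # the dead-surface mutant is flagged, never a zero fraction
  ds <- lib$dead_surface$expression
  expect_equal(ds$status[ds$construct_id == "W306A"], "not_determined")
  expect_true(is.na(
    ds$expression_fraction[ds$construct_id == "W306A"]))
  # the full panel tiles 56 mutant positions
  expect_equal(length(lib$full_panel$tags$positions), 56)
})

test_that("a grid that misses a curve's EC50 triggers a warning", {
  tp <- camp_truth()
  expect_warning(
    generate_panel(tp, seed = 1,
                   grid = default_grid(top = 1e-10, n = 10, dilution = 3)),
    "EC50")
})

test_that("a too-narrow grid is rejected outright", {
  tp <- camp_truth()
  expect_error(
    generate_panel(tp, seed = 1, grid = c(0, 1e-9, 2e-9, 4e-9, 8e-9,
                                          1.6e-8, 3.2e-8)),
    "4 log units")
})

test_that("the >30-fold mutant class is classified fold_gt_30 reliably", {
  lib <- scenario_library()
  tp <- lib$mutant_classes
  keep <- c("WT", "V206A", "E294A")  # 50-fold affinity / efficacy losses
  tp$functional <- tp$functional[tp$functional$pathway_id == "cAMP" &
                                   tp$functional$construct_id %in% keep, ]
  tp$binding <- tp$binding[tp$binding$construct_id %in% keep, ]
  tp$expression <- tp$expression[tp$expression$construct_id %in% keep, ]
  cfg <- run_config()
  hits_aff <- hits_eff <- logical(0)
  for (seed in 1:100) {
    d <- analyze_panel(generate_panel(tp, seed = seed), cfg)$deltas
    hits_aff <- c(hits_aff, as.character(
      d$category[d$construct_id == "V206A" & d$measure == "pKi" &
                   d$ligand_id == "GLP-1"]) == "fold_gt_30")
    hits_eff <- c(hits_eff, as.character(
      d$category[d$construct_id == "E294A" & d$measure == "log_tau_c" &
                   d$ligand_id == "GLP-1"]) == "fold_gt_30")
  }
  expect_gte(mean(hits_aff), 0.9)
  expect_gte(mean(hits_eff), 0.9)
})
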