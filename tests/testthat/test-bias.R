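tc_fixture <- function() {
  tibble::tibble(
    ligand_id = rep(c("GLP-1", "oxyntomodulin", "exendin-4"), each = 2),
    pathway_id = rep(c("cAMP", "pERK"), 3),
    log_tka = c(8.9, 8.5, 6.8, 7.4, 9.4, 9.05),
    sem_log_tka = c(0.05, 0.06, 0.08, 0.07, 0.05, 0.06))
}

test_that("transduction coefficients subtract logKA with quadrature SEM", {
  fits <- tibble::tibble(
    ligand_id = "L", pathway_id = "cAMP",
    log_tau_c = 0.5, sem_log_tau_c = 0.1,
    log_ka = -7.0, sem_log_ka = 0.1)
  tc <- transduction_coefficients(fits)
  expect_equal(tc$log_tka, 7.5)
  expect_equal(tc$sem_log_tka, sqrt(0.02), tolerance = 1e-12)
  # a joint-fit covariance enters var(a - b) = va + vb - 2 cov
  fits$cov_log_tau_log_ka <- -0.005
  tc2 <- transduction_coefficients(fits)
  expect_equal(tc2$sem_log_tka, sqrt(0.1^2 + 0.1^2 + 0.01),
               tolerance = 1e-12)
})

test_that("non-converged fits are dropped and reported", {
  fits <- tibble::tibble(
    ligand_id = c("A", "B"), pathway_id = "cAMP",
    log_tau_c = c(0.5, NA), sem_log_tau_c = 0.1,
    log_ka = c(-7, -7), sem_log_ka = 0.1,
    status = c("ok", "no_response"))
  tc <- transduction_coefficients(fits)
  expect_equal(nrow(tc), 1)
  expect_equal(attr(tc, "dropped")$ligand_id, "B")
})

test_that("reference normalization identities hold exactly", {
  b <- bias_factors(tc_fixture(), "GLP-1", "cAMP")
  expect_true(all(b$delta_log_tka[b$ligand_id == "GLP-1"] == 0))
  expect_true(all(b$ddelta_log_tka[b$pathway_id == "cAMP"] == 0))
  # reference ligand keeps the SEM of its own replicates
  expect_equal(b$sem_delta[b$ligand_id == "GLP-1" & b$pathway_id == "cAMP"],
               0.05)
  # worked arithmetic: oxyntomodulin pERK
  # delta(cAMP) = 6.8 - 8.9 = -2.1; delta(pERK) = 7.4 - 8.5 = -1.1
  ox <- b[b$ligand_id == "oxyntomodulin", ]
  expect_equal(ox$delta_log_tka[ox$pathway_id == "pERK"], -1.1,
               tolerance = 1e-12)
  expect_equal(ox$ddelta_log_tka[ox$pathway_id == "pERK"], 1.0,
               tolerance = 1e-12)
})

test_that("delta is antisymmetric and transitive across ligands", {
  tc <- tc_fixture()
  b_ref_g <- bias_factors(tc, "GLP-1", "cAMP")
  b_ref_o <- bias_factors(tc, "oxyntomodulin", "cAMP")
  b_ref_e <- bias_factors(tc, "exendin-4", "cAMP")
  at <- function(b, l, p) b$delta_log_tka[b$ligand_id == l &
                                            b$pathway_id == p]
  # antisymmetry
  expect_equal(at(b_ref_g, "oxyntomodulin", "pERK"),
               -at(b_ref_o, "GLP-1", "pERK"), tolerance = 1e-12)
  # transitivity: D(e vs g) = D(e vs o) + D(o vs g)
  expect_equal(at(b_ref_g, "exendin-4", "pERK"),
               at(b_ref_o, "exendin-4", "pERK") +
                 at(b_ref_g, "oxyntomodulin", "pERK"),
               tolerance = 1e-12)
})

test_that("bias is invariant to pathway-wide shifts of the coefficients", {
  # a system or observation bias moves every ligand of one pathway equally;
  # the double normalization must cancel it
  tc <- tc_fixture()
  b0 <- bias_factors(tc, "GLP-1", "cAMP")
  tc2 <- tc
  tc2$log_tka[tc2$pathway_id == "pERK"] <-
    tc2$log_tka[tc2$pathway_id == "pERK"] + 1.7
  b1 <- bias_factors(tc2, "GLP-1", "cAMP")
  expect_equal(b1$ddelta_log_tka, b0$ddelta_log_tka, tolerance = 1e-12)
})

test_that("a missing reference cell is an error naming the cell", {
  tc <- tc_fixture()[-2, ]  # drop GLP-1 x pERK
  expect_error(bias_factors(tc, "GLP-1", "cAMP"), "pERK")
  tc2 <- tc_fixture()[-1, ]  # drop GLP-1 x cAMP
  expect_error(bias_factors(tc2, "GLP-1", "cAMP"), "GLP-1")
})

test_that("multiple cell backgrounds require an explicit assertion", {
  tc <- tc_fixture()
  tc$cell_background <- rep(c("CHO", "HEK"), 3)
  expect_error(bias_factors(tc, "GLP-1", "cAMP"), "cell background")
  b <- bias_factors(tc, "GLP-1", "cAMP", assert_matched_system = TRUE)
  expect_s3_class(b, "bias_table")
})

test_that("web-of-bias export is radar-plot shaped", {
  b <- bias_factors(tc_fixture(), "GLP-1", "cAMP")
  path <- withr::local_tempfile(fileext = ".json")
  web_of_bias(b, pathway_order = c("cAMP", "pERK"), path = path)
  w <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(w$pathways, c("cAMP", "pERK"))
  expect_equal(w$reference_ligand_id, "GLP-1")
  expect_equal(w$ligands$oxyntomodulin$pERK, 10^1.0, tolerance = 1e-9)
  expect_equal(w$ligands$`GLP-1`$cAMP, 1)
})

test_that("bias comparison runs a Welch test on propagated SEMs", {
  out <- compare_bias(1.0, 0.1, 5, 0.0, 0.1, 5)
  expect_lt(out$p, 0.001)
  expect_equal(out$difference, 1.0)
  out2 <- compare_bias(0.5, 0.3, 4, 0.45, 0.3, 4)
  expect_gt(out2$p, 0.5)
})
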