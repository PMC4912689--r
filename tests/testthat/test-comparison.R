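test_that("identical groups give adjusted p near 1", {
  set.seed(1)
  v <- rep(c(1.02, 0.98, 1.01, 0.99), 4)
  g <- rep(c("WT", "A", "B", "C"), each = 4)
  out <- dunnett_test(v, g, control = "WT")
  expect_true(all(out$p_adj > 0.99))
  expect_false(any(out$significant))
})

test_that("an extreme separation gives vanishing adjusted p", {
  set.seed(2)
  v <- c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1))
  g <- rep(c("WT", "M"), each = 5)
  out <- dunnett_test(v, g, control = "WT")
  expect_lt(out$p_adj, 1e-6)
})

test_that("adjusted p agrees with multcomp's Dunnett procedure", {
  for (seed in c(3, 17)) {
    set.seed(seed)
    d <- data.frame(
      g = factor(rep(c("WT", "M1", "M2", "M3"), each = 4),
                 levels = c("WT", "M1", "M2", "M3")),
      y = c(rnorm(4, 0), rnorm(4, 0.4), rnorm(4, 0.9), rnorm(4, 1.4)))
    mine <- dunnett_test(d$y, as.character(d$g), control = "WT")
    gl <- summary(multcomp::glht(
      stats::aov(y ~ g, data = d),
      linfct = multcomp::mcp(g = "Dunnett")),
      test = multcomp::adjusted("single-step"))
    ref <- stats::setNames(as.numeric(gl$test$pvalues),
                           sub(" - WT", "", names(gl$test$coefficients)))
    # both sides integrate the same multivariate t numerically; agree to
    # absolute 5e-4
    expect_lt(max(abs(mine$p_adj[match(names(ref), mine$group)] -
                        unname(ref))), 5e-4)
  }
})

test_that("Dunnett-adjusted p never falls below the unadjusted p", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- rnorm(20, rep(c(0, 0.3, 0.8, 1.5), each = 5), 0.5)
    g <- rep(c("WT", "M1", "M2", "M3"), each = 5)
    out <- dunnett_test(v, g, control = "WT")
    praw <- 2 * stats::pt(-abs(out$t), out$df)
    expect_true(all(out$p_adj + 1e-9 >= praw))
  }
})

test_that("groups with fewer than two values are excluded and reported", {
  v <- c(1, 1.1, 0.9, 2, 2.1, 1.9, 5)
  g <- c("WT", "WT", "WT", "M1", "M1", "M1", "M2")
  out <- dunnett_test(v, g, control = "WT")
  expect_equal(attr(out, "excluded"), "M2")
  expect_false("M2" %in% out$group)
})

test_that("deltas, folds and SEMs follow the quadrature arithmetic", {
  est <- tibble::tibble(
    construct_id = rep(c("WT", "M1"), each = 3),
    value = c(values_with(8.0, 0.1), values_with(7.0, 0.1)))
  d <- delta_vs_wildtype(est, "WT", "pKi")
  expect_equal(d$delta, -1.0, tolerance = 1e-12)
  expect_equal(d$fold_change, 10, tolerance = 1e-12)
  expect_equal(d$sem_delta, sqrt(0.1^2 + 0.1^2), tolerance = 1e-12)
  expect_equal(d$direction, "reduced")

  # a mutant identical to wild-type: delta 0, fold 1
  est2 <- tibble::tibble(
    construct_id = rep(c("WT", "M1"), each = 3),
    value = rep(values_with(8.0, 0.1), 2))
  d2 <- delta_vs_wildtype(est2, "WT", "pKi")
  expect_equal(d2$delta, 0)
  expect_equal(d2$fold_change, 1)
  expect_false(d2$significant)
})

test_that("heat bins follow the half-open lower-inclusive convention", {
  folds <- c(2.9, 3.0, 4.0, 5.0, 9.99, 10.0, 29.9, 30.0, 100)
  d <- tibble::tibble(
    construct_id = "M", ligand_id = "L", measure = "pKi",
    delta = -log10(folds), sem_delta = 0.01, p_adj = 1e-4,
    significant = TRUE, fold_change = folds, direction = "reduced")
  out <- classify_heat(d)
  expect_equal(as.character(out$category),
               c("no_effect", "fold_3_5", "fold_3_5", "fold_5_10",
                 "fold_5_10", "fold_10_30", "fold_10_30", "fold_gt_30",
                 "fold_gt_30"))
  expect_equal(out$category_code,
               c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
})

test_that("the significance gate and directions control the category", {
  d <- tibble::tibble(
    construct_id = c("A", "B", "C", "D", "E"),
    ligand_id = "L", measure = "log_tau_c",
    delta = c(-log10(12), 0.8, -0.9, NA, NA),
    sem_delta = 0.05, p_adj = c(0.2, 1e-4, 1e-4, NA, NA),
    significant = c(FALSE, TRUE, TRUE, NA, NA),
    fold_change = c(12, 10^0.8, 10^0.9, NA, NA),
    direction = c("reduced", "enhanced", "reduced", NA, NA))
  out <- classify_heat(d, wt_window_ok = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(as.character(out$category),
               c("no_effect",   # not significant despite 12-fold
                 "enhanced",    # significant gain
                 "fold_5_10",
                 "fold_gt_30",  # no response, wild-type window supports it
                 "not_determined"))
})

test_that("higher true fold never classifies into a lower bin", {
  folds <- c(3, 4, 6, 12, 35, 80)
  d <- tibble::tibble(
    construct_id = letters[seq_along(folds)], ligand_id = "L",
    measure = "pKi", delta = -log10(folds), sem_delta = 0.01,
    p_adj = 1e-5, significant = TRUE, fold_change = folds,
    direction = "reduced")
  codes <- classify_heat(d)$category_code
  expect_true(all(diff(codes) >= 0))
})
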