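#' Dunnett's many-to-one comparison against a common control
#'
#' One-way ANOVA followed by Dunnett's post-test: each treatment group is
#' compared with the control using t statistics on the pooled within-group
#' variance (df = N - k), and two-sided adjusted p values are taken from the
#' multivariate t distribution of the maximum |t| with the exact pairwise
#' correlations `rho_ij = sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`
#' (equicorrelation 1/2 at equal group sizes). The multivariate t
#' probability is evaluated numerically (absolute tolerance 1e-5 on a fixed
#' internal quasi-random stream, so results are reproducible and do not
#' disturb the caller's RNG).
#'
#' @param values Numeric response values (one per experimental unit).
#' @param group Group labels, same length as `values`.
#' @param control Label of the control group.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A tibble with one row per non-control group: `group`, `n`,
#'   `estimate` (group mean minus control mean), `se`, `t`, `df`, `p_adj`,
#'   `significant`. Groups with fewer than 2 values are excluded and listed
#'   in `attr(, "excluded")`.
#' @export
dunnett_test <- function(values, group, control, alpha = 0.05) {
  stopifnot(length(values) == length(group), control %in% group)
  keep <- is.finite(values)
  values <- values[keep]; group <- as.character(group)[keep]

  ns <- table(group)
  excluded <- names(ns)[ns < 2]
  if (control %in% excluded) stop("control group needs >= 2 values")
  ok <- !(group %in% excluded)
  values <- values[ok]; group <- group[ok]

  g <- split(values, group)
  trt <- setdiff(names(g), control)
  if (length(trt) == 0) stop("no treatment groups to compare")
  n0 <- length(g[[control]])
  m0 <- mean(g[[control]])
  ni <- vapply(g[trt], length, integer(1))
  mi <- vapply(g[trt], mean, double(1))
  k <- length(g)
  df <- length(values) - k
  s2 <- sum(vapply(g, function(x) sum((x - mean(x))^2), double(1))) / df
  se <- sqrt(s2 * (1 / ni + 1 / n0))
  tstat <- (mi - m0) / se

  lam <- sqrt(ni / (ni + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1

  p_adj <- vapply(seq_along(tstat), function(i) {
    tt <- abs(tstat[i])
    if (!is.finite(tt)) return(NA_real_)
    pr <- with_local_seed(290816, mvtnorm::pmvt(
      lower = rep(-tt, length(tstat)), upper = rep(tt, length(tstat)),
      df = df, corr = corr, algorithm = mvtnorm::GenzBretz(
        abseps = 1e-5, maxpts = 250000)))
    max(1 - as.numeric(pr), 0)
  }, double(1))

  out <- tibble::tibble(
    group = trt, n = as.integer(ni), estimate = mi - m0, se = se,
    t = tstat, df = df, p_adj = p_adj,
    significant = p_adj < alpha)
  attr(out, "excluded") <- excluded
  out
}

#' Mutant-minus-wild-type differences with Dunnett-adjusted significance
#'
#' For one pharmacological measure (pKi, log tau_c, pEC50, or log10 Emax),
#' takes per-experiment parameter estimates for every construct, forms
#' `delta = mean(mutant) - mean(wild-type)` with SEMs combined in
#' quadrature, and adjusts significance with [dunnett_test()] run once per
#' ligand family (all mutants versus wild-type). Negative deltas denote
#' impaired function; `fold_change = 10^|delta|`.
#'
#' @param estimates Data frame of per-experiment values with columns
#'   `construct_id`, `value`, optionally `ligand_id` (one test family per
#'   ligand) and `experiment_id`.
#' @param wt_id Wild-type construct id.
#' @param measure Label stored in the output (`"pKi"`, `"log_tau_c"`,
#'   `"pEC50"`, `"Emax"`, ...). Values must already be on the log10 scale.
#' @param alpha Significance level (default 0.05).
#' @return A `DeltaEstimate` tibble: `construct_id`, `ligand_id`, `measure`,
#'   `delta`, `sem_delta`, `p_adj`, `significant`, `fold_change`,
#'   `direction` (`"reduced"`/`"enhanced"`).
#' @export
delta_vs_wildtype <- function(estimates, wt_id, measure, alpha = 0.05) {
  stopifnot(all(c("construct_id", "value") %in% names(estimates)),
            wt_id %in% estimates$construct_id)
  if (!"ligand_id" %in% names(estimates)) estimates$ligand_id <- "all"

  fam <- split(estimates, estimates$ligand_id)
  out <- purrr::map(fam, function(d) {
    d <- d[is.finite(d$value), ]
    dt <- dunnett_test(d$value, d$construct_id, control = wt_id,
                       alpha = alpha)
    stats_tbl <- dplyr::summarise(
      dplyr::group_by(d, .data$construct_id),
      m = mean(.data$value), s = sem(.data$value), .groups = "drop")
    wt <- stats_tbl[stats_tbl$construct_id == wt_id, ]
    mut <- stats_tbl[stats_tbl$construct_id != wt_id, ]
    i <- match(mut$construct_id, dt$group)
    tibble::tibble(
      construct_id = mut$construct_id,
      ligand_id = d$ligand_id[1],
      measure = measure,
      delta = mut$m - wt$m,
      sem_delta = sqrt(mut$s^2 + wt$s^2),
      p_adj = dt$p_adj[i],
      significant = dt$significant[i],
      fold_change = 10^abs(mut$m - wt$m),
      direction = ifelse(mut$m - wt$m < 0, "reduced", "enhanced"))
  })
  dplyr::bind_rows(out)
}

#' Heat-category levels used for mutational effects
#'
#' Ordered category set for fold-change heat classification, with the
#' integer codes emitted for structure mapping: no_effect = 0, fold_3_5 = 1,
#' fold_5_10 = 2, fold_10_30 = 3, fold_gt_30 = 4, enhanced = 5,
#' not_determined = -1.
#'
#' @return Named integer vector of category codes.
#' @export
heat_levels <- function() {
  c(no_effect = 0L, fold_3_5 = 1L, fold_5_10 = 2L, fold_10_30 = 3L,
    fold_gt_30 = 4L, enhanced = 5L, not_determined = -1L)
}

#' Classify mutant effects into fold-change heat categories
#'
#' Applies the reporting convention used for receptor alanine-scan heatmaps:
#' non-significant effects (and significant effects below 3-fold) render as
#' `no_effect`; significant losses are binned by fold change into half-open
#' lower-inclusive intervals [3,5), [5,10), [10,30), [30,Inf) —
#' `fold_3_5`, `fold_5_10`, `fold_10_30`, `fold_gt_30`; significant gains
#' are `enhanced`. Mutants with no detectable response cannot yield a
#' finite delta: they are floored to `fold_gt_30` when the wild-type
#' response window is at least `bins[length(bins)]`-fold above noise
#' (`wt_window_ok`), otherwise `not_determined`.
#'
#' @param delta A `DeltaEstimate` tibble from [delta_vs_wildtype()]. Rows
#'   with `NA` delta are treated as no-response mutants.
#' @param bins Strictly increasing fold thresholds (> 1), default
#'   `c(3, 5, 10, 30)`.
#' @param wt_window_ok Logical (scalar or per row): wild-type window
#'   supports the `> max(bins)`-fold floor for no-response mutants.
#' @return `delta` with `category` (factor over [heat_levels()]) and
#'   integer `category_code` appended.
#' @export
classify_heat <- function(delta, bins = c(3, 5, 10, 30),
                          wt_window_ok = TRUE) {
  stopifnot(all(diff(bins) > 0), all(bins > 1))
  wt_window_ok <- rep_len(wt_window_ok, nrow(delta))
  labs <- c("fold_3_5", "fold_5_10", "fold_10_30", "fold_gt_30")
  if (length(bins) != 4) labs <- paste0("bin", seq_along(bins))

  category <- character(nrow(delta))
  for (i in seq_len(nrow(delta))) {
    if (!is.finite(delta$delta[i])) {
      category[i] <- if (wt_window_ok[i]) "fold_gt_30" else "not_determined"
    } else if (!isTRUE(delta$significant[i]) ||
               delta$fold_change[i] < bins[1]) {
      category[i] <- "no_effect"  # below the reporting threshold
    } else if (delta$direction[i] == "enhanced") {
      category[i] <- "enhanced"
    } else {
      idx <- findInterval(delta$fold_change[i], bins)
      category[i] <- labs[idx]
    }
  }
  delta$category <- factor(category, levels = names(heat_levels()))
  delta$category_code <- unname(heat_levels()[category])
  delta
}
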