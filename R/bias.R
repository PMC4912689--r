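#' Transduction coefficients log(tau/K_A)
#'
#' Combines expression-corrected operational efficacy with the functional
#' dissociation constant into the transduction coefficient
#' `log(tau/K_A) = log tau_c - log K_A`, the composite efficacy-affinity
#' measure whose between-ligand, between-pathway differences quantify
#' biased agonism. SEMs combine in quadrature with the log tau / log K_A
#' covariance subtracted twice when both come from one joint fit
#' (`var(a - b) = var a + var b - 2 cov(a, b)`).
#'
#' @param fits Tibble with columns `ligand_id`, `pathway_id`, `log_tau_c`,
#'   `sem_log_tau_c`, `log_ka`, `sem_log_ka`; optional
#'   `cov_log_tau_log_ka` and `status` (non-`"ok"`/`"ka_fixed"` rows are
#'   dropped and listed in `attr(, "dropped")`).
#' @param use_corrected Use `log_tau_c` (default); `FALSE` falls back to raw
#'   `log_tau`/`sem_log_tau` for sensitivity analyses.
#' @return Tibble: `ligand_id`, `pathway_id`, `log_tka`, `sem_log_tka`.
#' @export
transduction_coefficients <- function(fits, use_corrected = TRUE) {
  tau_col <- if (use_corrected) "log_tau_c" else "log_tau"
  sem_col <- paste0("sem_", tau_col)
  stopifnot(all(c("ligand_id", "pathway_id", tau_col, sem_col, "log_ka",
                  "sem_log_ka") %in% names(fits)))
  if (!"cov_log_tau_log_ka" %in% names(fits)) fits$cov_log_tau_log_ka <- 0
  if (!"status" %in% names(fits)) fits$status <- "ok"

  usable <- fits$status %in% c("ok", "ka_fixed") &
    is.finite(fits[[tau_col]]) & is.finite(fits$log_ka)
  dropped <- fits[!usable, c("ligand_id", "pathway_id", "status")]
  fits <- fits[usable, ]
  cv <- ifelse(is.finite(fits$cov_log_tau_log_ka),
               fits$cov_log_tau_log_ka, 0)
  out <- tibble::tibble(
    ligand_id = fits$ligand_id,
    pathway_id = fits$pathway_id,
    log_tka = fits[[tau_col]] - fits$log_ka,
    sem_log_tka = sqrt(pmax(fits[[sem_col]]^2 + fits$sem_log_ka^2 - 2 * cv,
                            0)))
  attr(out, "dropped") <- dropped
  out
}

#' Bias factors: delta and delta-delta log(tau/K_A)
#'
#' Normalizes transduction coefficients first to a reference ligand within
#' each pathway (`Delta = log(tau/K_A)_ligand - log(tau/K_A)_ref_ligand`,
#' cancelling system/observation bias), then to a reference pathway within
#' each ligand (`DeltaDelta = Delta_pathway - Delta_ref_pathway`). A
#' non-zero DeltaDelta means the ligand is biased toward (positive) or away
#' from (negative) that pathway relative to the reference ligand. SEMs
#' propagate in quadrature; reference-ligand rows keep Delta = 0 with the
#' SEM of their own replicates, and reference-pathway rows have
#' DeltaDelta = 0.
#'
#' @param tc Transduction-coefficient table from
#'   [transduction_coefficients()].
#' @param ref_ligand,ref_pathway Reference ligand and pathway ids. The
#'   reference ligand must be measured in every pathway present and the
#'   reference pathway for every ligand present.
#' @param assert_matched_system Cross-pathway normalization is only valid
#'   when all pathways were assayed in one cell background with matched
#'   receptor expression. If `tc` carries a `cell_background` column with
#'   more than one value, set this to `TRUE` to assert the backgrounds are
#'   comparable; otherwise the call errors.
#' @return A `BiasTable` tibble: `ligand_id`, `pathway_id`, `log_tka`,
#'   `delta_log_tka`, `sem_delta`, `ddelta_log_tka`, `sem_ddelta`, plus
#'   `reference_ligand_id`/`reference_pathway_id` attributes.
#' @export
bias_factors <- function(tc, ref_ligand, ref_pathway,
                         assert_matched_system = FALSE) {
  if ("cell_background" %in% names(tc) &&
      length(unique(tc$cell_background)) > 1 && !assert_matched_system) {
    stop("pathways span multiple cell backgrounds; cross-pathway ",
         "normalization needs assert_matched_system = TRUE")
  }
  tc$cell_background <- NULL
  pathways <- unique(tc$pathway_id)
  ligands <- unique(tc$ligand_id)
  for (p in pathways) {
    if (!any(tc$ligand_id == ref_ligand & tc$pathway_id == p))
      stop("reference ligand '", ref_ligand, "' missing for pathway '", p,
           "'")
  }
  for (l in ligands) {
    if (!any(tc$ligand_id == l & tc$pathway_id == ref_pathway))
      stop("reference pathway '", ref_pathway, "' missing for ligand '", l,
           "'")
  }

  ref_l <- tc[tc$ligand_id == ref_ligand, ]
  i <- match(tc$pathway_id, ref_l$pathway_id)
  is_ref_l <- tc$ligand_id == ref_ligand
  out <- tc
  out$delta_log_tka <- ifelse(is_ref_l, 0, tc$log_tka - ref_l$log_tka[i])
  out$sem_delta <- ifelse(is_ref_l, tc$sem_log_tka,
                          sqrt(tc$sem_log_tka^2 + ref_l$sem_log_tka[i]^2))

  ref_p <- out[out$pathway_id == ref_pathway, ]
  j <- match(out$ligand_id, ref_p$ligand_id)
  is_ref_p <- out$pathway_id == ref_pathway
  out$ddelta_log_tka <- ifelse(is_ref_p, 0,
                               out$delta_log_tka - ref_p$delta_log_tka[j])
  out$sem_ddelta <- ifelse(is_ref_p, out$sem_delta,
                           sqrt(out$sem_delta^2 + ref_p$sem_delta[j]^2))
  attr(out, "reference_ligand_id") <- ref_ligand
  attr(out, "reference_pathway_id") <- ref_pathway
  class(out) <- c("bias_table", class(out))
  out
}

#' Compare bias factors between two ligands
#'
#' Two-sided Welch t-test on the difference of DeltaDelta log(tau/K_A)
#' values using their propagated SEMs, with Welch-Satterthwaite degrees of
#' freedom from the supplied replicate counts.
#'
#' @param dd1,dd2 DeltaDelta estimates.
#' @param sem1,sem2 Their propagated SEMs.
#' @param n1,n2 Effective replicate counts behind each estimate.
#' @return Tibble with `difference`, `se`, `t`, `df`, `p`.
#' @export
compare_bias <- function(dd1, sem1, n1, dd2, sem2, n2) {
  se <- sqrt(sem1^2 + sem2^2)
  df <- se^4 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  t <- (dd1 - dd2) / se
  tibble::tibble(difference = dd1 - dd2, se = se, t = t, df = df,
                 p = 2 * stats::pt(-abs(t), df))
}

#' Export web-of-bias (radar) plot data
#'
#' Converts a bias table to the structure of a "web of bias" radar plot:
#' one polygon per ligand whose spokes are the pathways in a fixed order,
#' with spoke values `10^DeltaDelta log(tau/K_A)` (plotted on a log scale).
#'
#' @param bias A `bias_table` from [bias_factors()].
#' @param pathway_order Spoke order; defaults to the order of appearance.
#' @param path Optional file to write the structure to as JSON.
#' @return A list with `pathways` (spoke order) and `ligands` (named list
#'   of per-spoke `10^DeltaDelta` values), invisibly if written.
#' @export
web_of_bias <- function(bias, pathway_order = unique(bias$pathway_id),
                        path = NULL) {
  stopifnot(all(bias$pathway_id %in% pathway_order))
  polys <- lapply(split(bias, bias$ligand_id), function(d) {
    i <- match(pathway_order, d$pathway_id)
    stats::setNames(10^d$ddelta_log_tka[i], pathway_order)
  })
  out <- list(
    reference_ligand_id = attr(bias, "reference_ligand_id"),
    reference_pathway_id = attr(bias, "reference_pathway_id"),
    scale = "log",
    pathways = pathway_order,
    ligands = lapply(polys, as.list))
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
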