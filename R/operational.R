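#' Fit the operational model of agonism to a construct x pathway panel
#'
#' Estimates log tau (operational efficacy) and log K_A (functional
#' dissociation constant) for every ligand assayed on one receptor construct
#' in one pathway, using [operational_model()]. Because log tau and log K_A
#' are near-collinear for full agonists, the default policy
#' (`em_policy = "shared_per_pathway"`) fits the system maximum `Em` and the
#' basal `bottom` jointly across all ligands of the panel, so partial
#' agonists in the panel pin `Em`; `"per_curve"` fits an independent
#' `Em`/`bottom` per ligand. With `ka_policy = "fix_to_binding"` log K_A is
#' fixed to `-pKi` from competition binding for ligands present in
#' `binding`, with its SEM set to 0.
#'
#' Each independent experiment is fitted separately (duplicates averaged
#' first by default) and experiment-level estimates are pooled as mean +/-
#' SEM; the log tau / log K_A covariance of the pooled means is retained for
#' downstream error propagation.
#'
#' @param data Data frame with columns `ligand_id`, `concentration` (molar,
#'   0 = basal), `response`; optional `experiment_id`, `replicate_id`.
#' @param em_policy `"shared_per_pathway"` (default) or `"per_curve"`.
#' @param ka_policy `"fit"` (default) or `"fix_to_binding"`.
#' @param binding Named numeric vector of pKi per ligand_id, required for
#'   ligands constrained under `"fix_to_binding"`.
#' @param binding_sem Optional named SEMs of the pKi values. An error in
#'   the anchored log K_A displaces log tau by about `(tau+1)/tau` log
#'   units per log unit (the EC50 is data-determined while
#'   `EC50 = K_A/(tau+1)`), identically in every experiment, so this
#'   component is invisible to the between-experiment SEM; it is added to
#'   `sem_log_tau` in quadrature.
#' @param fix_bottom Optional fixed basal response (e.g. 0 for
#'   baseline-subtracted assays).
#' @param fix_em Optional fixed system maximum. Because the slope-1
#'   operational curve is exactly a logistic (plateau
#'   `(Em - bottom) tau/(tau+1)`, EC50 `K_A/(tau+1)`), Em, tau and K_A are
#'   not jointly identifiable from functional data alone: without either
#'   `fix_em` or `ka_policy = "fix_to_binding"`, fits report a point on the
#'   flat ridge (the transduction coefficient tau/K_A and the derived pEC50
#'   are still well determined).
#' @param near_full_threshold Under `"fix_to_binding"`, K_A is fixed for
#'   ligands whose plateau reaches at least this fraction of the panel's
#'   largest plateau; the rest keep a free K_A identified through the
#'   shared Em. The default 0 anchors every ligand with binding data —
#'   each anchored ligand stiffens the Em/tau ridge, and the classical
#'   operational-model assumption (functional K_A approximates binding
#'   affinity) is in fact safest for partial agonists.
#' @param average_duplicates Average technical replicates within an
#'   experiment before fitting.
#' @param noise_alpha Significance level of the flat-curve F-test used to
#'   call `no_response` per ligand.
#' @return A tibble of class `operational_fit`, one row per ligand:
#'   `ligand_id`, `log_tau`, `sem_log_tau`, `log_ka`, `sem_log_ka`,
#'   `cov_log_tau_log_ka`, `em`, `bottom`, `pec50_derived`
#'   (`-logKA + log10(tau + 1)`), `n_experiments`, `status` in
#'   ok/no_response/not_converged/ka_fixed. Experiment-level estimates are
#'   attached as `attr(, "per_experiment")`.
#' @export
fit_operational <- function(data,
                            em_policy = c("shared_per_pathway", "per_curve"),
                            ka_policy = c("fit", "fix_to_binding"),
                            binding = NULL, binding_sem = NULL,
                            fix_bottom = NULL,
                            fix_em = NULL, near_full_threshold = 0,
                            average_duplicates = TRUE, noise_alpha = 0.05) {
  em_policy <- match.arg(em_policy)
  ka_policy <- match.arg(ka_policy)
  stopifnot(all(c("ligand_id", "concentration", "response") %in% names(data)))
  if (!"experiment_id" %in% names(data)) data$experiment_id <- 1L
  data <- data[is.finite(data$response) & data$concentration >= 0, ]
  if (average_duplicates) {
    data <- dplyr::summarise(
      dplyr::group_by(data, .data$ligand_id, .data$experiment_id,
                      .data$concentration),
      response = mean(.data$response), .groups = "drop")
  }

  ligands <- sort(unique(data$ligand_id))
  flat <- vapply(ligands, function(l) {
    d <- data[data$ligand_id == l, ]
    flat_curve(d$concentration, d$response, noise_alpha)
  }, logical(1))
  active <- ligands[!flat]

  na_row <- function(l, status, n) tibble::tibble(
    ligand_id = l, log_tau = NA_real_, sem_log_tau = NA_real_,
    log_ka = NA_real_, sem_log_ka = NA_real_,
    cov_log_tau_log_ka = NA_real_, em = NA_real_, bottom = NA_real_,
    pec50_derived = NA_real_, n_experiments = n, status = status)

  n_exp_all <- length(unique(data$experiment_id))
  if (length(active) == 0) {
    out <- dplyr::bind_rows(lapply(ligands, na_row, status = "no_response",
                                   n = n_exp_all))
    return(new_operational_fit(out, empty_operational_pe()))
  }

  fixed_ka <- NULL
  if (ka_policy == "fix_to_binding") {
    if (is.null(binding)) stop("ka_policy = 'fix_to_binding' needs `binding`")
    tops <- vapply(active, function(l) {
      d <- data[data$ligand_id == l, ]
      fit_logistic_single(d$concentration, d$response)$top
    }, double(1))
    near_full <- active[tops >= near_full_threshold * max(tops)]
    fixed_ka <- -binding[names(binding) %in% near_full]
    fixed_ka <- fixed_ka[is.finite(fixed_ka)]
    if (length(fixed_ka) == 0) fixed_ka <- NULL
  }

  pe <- purrr::map(split(data, data$experiment_id), function(d) {
    fit_operational_single(d[d$ligand_id %in% active, ], active, em_policy,
                           fixed_ka, fix_bottom, fix_em)
  })
  pe_tbl <- dplyr::bind_rows(pe, .id = "experiment_id")

  rows <- lapply(ligands, function(l) {
    if (!l %in% active) return(na_row(l, "no_response", n_exp_all))
    d <- pe_tbl[pe_tbl$ligand_id == l & pe_tbl$converged, ]
    if (nrow(d) == 0) return(na_row(l, "not_converged", n_exp_all))
    n <- nrow(d)
    if (n >= 2) {
      s_tau <- sem(d$log_tau); s_ka <- sem(d$log_ka)
      cv <- stats::cov(d$log_tau, d$log_ka) / n
    } else {
      s_tau <- d$se_log_tau[1]; s_ka <- d$se_log_ka[1]
      cv <- d$cov_tau_ka[1]
    }
    ka_fixed <- !is.null(fixed_ka) && l %in% names(fixed_ka)
    at_bound <- mean(d$log_tau) >= 4 - 1e-3
    status <- if (at_bound) "not_converged"
              else if (ka_fixed) "ka_fixed" else "ok"
    if (ka_fixed && !is.null(binding_sem) && l %in% names(binding_sem) &&
        is.finite(binding_sem[[l]])) {
      tau_hat <- 10^mean(d$log_tau)
      s_anchor <- (tau_hat + 1) / tau_hat * binding_sem[[l]]
      s_tau <- sqrt(s_tau^2 + s_anchor^2)
    }
    tibble::tibble(
      ligand_id = l,
      log_tau = mean(d$log_tau), sem_log_tau = s_tau,
      log_ka = mean(d$log_ka),
      sem_log_ka = if (ka_fixed) 0 else s_ka,
      cov_log_tau_log_ka = if (ka_fixed) 0 else cv,
      em = mean(d$em), bottom = mean(d$bottom),
      pec50_derived = -mean(d$log_ka) + log10(10^mean(d$log_tau) + 1),
      n_experiments = n, status = status)
  })
  new_operational_fit(dplyr::bind_rows(rows), pe_tbl)
}

new_operational_fit <- function(tbl, pe) {
  attr(tbl, "per_experiment") <- pe
  class(tbl) <- c("operational_fit", class(tbl))
  tbl
}

empty_operational_pe <- function() {
  tibble::tibble(experiment_id = character(), ligand_id = character(),
                 log_tau = double(), log_ka = double(), em = double(),
                 bottom = double(), se_log_tau = double(),
                 se_log_ka = double(), cov_tau_ka = double(),
                 converged = logical())
}

#' @export
print.operational_fit <- function(x, ...) {
  cat("<operational_fit> ", nrow(x), " ligand(s)\n", sep = "")
  NextMethod()
}

# joint per-experiment fit over all active ligands of one construct x pathway
fit_operational_single <- function(d, ligands, em_policy, fixed_ka,
                                   fix_bottom, fix_em = NULL) {
  span <- diff(range(d$response))
  b0 <- if (is.null(fix_bottom)) min(d$response) else fix_bottom

  # data-driven starts from per-ligand logistic fits
  seed_fit <- lapply(ligands, function(l) {
    dl <- d[d$ligand_id == l, ]
    fit_logistic_single(dl$concentration, dl$response)
  })
  names(seed_fit) <- ligands
  top0 <- vapply(seed_fit, function(f) f$top, double(1))
  pec0 <- vapply(seed_fit, function(f) f$pec50, double(1))
  em0 <- if (is.null(fix_em)) max(top0) * 1.05 else fix_em
  r <- pmin((top0 - b0) / (em0 - b0), 0.95)
  r <- pmax(r, 0.002)
  ltau0 <- log10(r / (1 - r))
  lka0 <- pmin(pmax(log10(10^ltau0 + 1) - pec0, -12), -4)

  free_ka <- if (is.null(fixed_ka)) ligands else setdiff(ligands,
                                                         names(fixed_ka))
  par <- list(); lower <- c(); upper <- c()
  add_par <- function(name, value, lo, hi) {
    par[[name]] <<- value
    lower[name] <<- lo; upper[name] <<- hi
  }
  # Em can sit far above the largest observed plateau when every ligand in
  # the panel is weak (plateau = (Em-b) tau/(tau+1)), so the upper bound
  # must stay loose; identifiability comes from fixed K_A or fix_em
  em_hi <- b0 + 500 * span
  if (em_policy == "shared_per_pathway") {
    if (is.null(fix_em))
      add_par("em", em0, b0 + 0.25 * span, em_hi)
    if (is.null(fix_bottom))
      add_par("bottom", b0, b0 - span, b0 + 0.5 * span)
  } else {
    for (l in ligands) {
      if (is.null(fix_em))
        add_par(paste0("em.", l), em0, b0 + 0.25 * span, em_hi)
      if (is.null(fix_bottom))
        add_par(paste0("bottom.", l), b0, b0 - span, b0 + 0.5 * span)
    }
  }
  for (l in ligands) {
    add_par(paste0("ltau.", l), ltau0[[l]], -3, 4)
    if (l %in% free_ka) add_par(paste0("lka.", l), lka0[[l]], -12, -4)
  }

  # precompute per-ligand data and parameter indices so the residual
  # function stays cheap inside the optimizer
  par_vec <- unlist(par)
  pname <- names(par_vec)
  idx <- function(nm) match(nm, pname)
  lig_info <- lapply(ligands, function(l) {
    dl <- d[d$ligand_id == l, ]
    list(conc = dl$concentration, resp = dl$response,
         i_em = if (!is.null(fix_em)) NA_integer_
                else if (em_policy == "shared_per_pathway") idx("em")
                else idx(paste0("em.", l)),
         i_bot = if (!is.null(fix_bottom)) NA_integer_
                 else if (em_policy == "shared_per_pathway") idx("bottom")
                 else idx(paste0("bottom.", l)),
         i_tau = idx(paste0("ltau.", l)),
         i_ka = if (l %in% free_ka) idx(paste0("lka.", l)) else NA_integer_,
         ka_val = if (l %in% free_ka) NA_real_ else fixed_ka[[l]])
  })
  obs <- unlist(lapply(lig_info, function(x) x$resp))
  predict_panel <- function(p) {
    unlist(lapply(lig_info, function(x) {
      em <- if (is.na(x$i_em)) fix_em else p[[x$i_em]]
      bt <- if (is.na(x$i_bot)) fix_bottom else p[[x$i_bot]]
      lka <- if (is.na(x$i_ka)) x$ka_val else p[[x$i_ka]]
      operational_model(x$conc, p[[x$i_tau]], lka, em, bt)
    }))
  }

  fit <- minpack.lm::nls.lm(
    par = par_vec, fn = function(p) obs - predict_panel(p),
    lower = unname(lower[pname]), upper = unname(upper[pname]),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- as.list(stats::setNames(as.numeric(fit$par), pname))
  se <- tryCatch({
    co <- summary(fit)$coefficients
    stats::setNames(co[, "Std. Error"], rownames(co))
  }, error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                         names(cf)))
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)

  dplyr::bind_rows(lapply(ligands, function(l) {
    nt <- paste0("ltau.", l); nk <- paste0("lka.", l)
    lka <- if (l %in% free_ka) cf[[nk]] else fixed_ka[[l]]
    cov_tk <- if (!is.null(vc) && nt %in% rownames(vc) &&
                  nk %in% rownames(vc)) vc[nt, nk] else 0
    tibble::tibble(
      ligand_id = l,
      log_tau = cf[[nt]],
      log_ka = lka,
      em = if (!is.null(fix_em)) fix_em
           else if (em_policy == "shared_per_pathway") cf[["em"]]
           else cf[[paste0("em.", l)]],
      bottom = if (!is.null(fix_bottom)) fix_bottom
               else if (em_policy == "shared_per_pathway") cf[["bottom"]]
               else cf[[paste0("bottom.", l)]],
      se_log_tau = unname(se[nt]),
      se_log_ka = if (l %in% free_ka) unname(se[nk]) else 0,
      cov_tau_ka = cov_tk,
      converged = fit$info %in% 1:4)
  }))
}

#' Correct operational efficacy for cell-surface expression
#'
#' tau absorbs receptor density, so mutants expressed at a fraction of
#' wild-type levels show reduced tau even when per-receptor coupling is
#' intact. The expression-corrected efficacy divides tau by relative surface
#' expression: `log tau_c = log tau - log10(f_mut / f_wt)`. Expression SEMs
#' are moved to the log10 scale by the delta method
#' (`sem_log x = sem_x / (x ln 10)`) and combined with the tau SEM in
#' quadrature, assuming independence of the functional and expression
#' measurements.
#'
#' @param log_tau,sem_log_tau Operational efficacy estimate and SEM.
#' @param expr_fraction,expr_sem Construct surface expression as a fraction
#'   of wild-type, and its SEM (linear scale).
#' @param wt_fraction,wt_sem Wild-type reference expression (default 1, 0).
#' @return A tibble with `log_tau_c`, `sem_log_tau_c` and
#'   `expression_fraction_used`. Non-finite or non-positive expression gives
#'   an `NA` row (expression not determined).
#' @export
correct_tau <- function(log_tau, sem_log_tau, expr_fraction, expr_sem = 0,
                        wt_fraction = 1, wt_sem = 0) {
  n <- max(length(log_tau), length(expr_fraction))
  log_tau <- rep_len(log_tau, n); sem_log_tau <- rep_len(sem_log_tau, n)
  expr_fraction <- rep_len(expr_fraction, n)
  expr_sem <- rep_len(expr_sem, n)
  wt_fraction <- rep_len(wt_fraction, n); wt_sem <- rep_len(wt_sem, n)

  ok <- is.finite(expr_fraction) & expr_fraction > 0 &
    is.finite(wt_fraction) & wt_fraction > 0
  ltc <- ifelse(ok, log_tau - log10(expr_fraction / wt_fraction), NA_real_)
  s_ratio <- sqrt(sem_to_log10(expr_sem, expr_fraction)^2 +
                    sem_to_log10(wt_sem, wt_fraction)^2)
  stc <- ifelse(ok, sqrt(sem_log_tau^2 + s_ratio^2), NA_real_)
  tibble::tibble(log_tau_c = ltc, sem_log_tau_c = stc,
                 expression_fraction_used = ifelse(ok, expr_fraction,
                                                   NA_real_))
}

#' Apply the expression correction across an operational fit table
#'
#' @param fits A tibble with columns `construct_id`, `log_tau`,
#'   `sem_log_tau` (e.g. stacked [fit_operational()] results).
#' @param expression Expression table with `construct_id`,
#'   `expression_fraction`, `sem` (and optionally `status`;
#'   `"not_determined"` rows propagate `NA`).
#' @param wt_id Wild-type construct id supplying the reference fraction.
#' @return `fits` with `log_tau_c`, `sem_log_tau_c`,
#'   `expression_fraction_used` appended.
#' @export
correct_tau_table <- function(fits, expression, wt_id) {
  stopifnot(wt_id %in% expression$construct_id)
  if (!"status" %in% names(expression)) expression$status <- "ok"
  expression$expression_fraction[expression$status == "not_determined"] <-
    NA_real_
  wt <- expression[expression$construct_id == wt_id, ]
  m <- match(fits$construct_id, expression$construct_id)
  is_wt <- fits$construct_id == wt_id
  # the wild-type ratio is identically 1 (same measurement top and bottom),
  # so no expression error enters its own correction
  corr <- correct_tau(fits$log_tau, fits$sem_log_tau,
                      expression$expression_fraction[m],
                      ifelse(is_wt, 0, expression$sem[m]),
                      wt$expression_fraction[1],
                      ifelse(is_wt, 0, wt$sem[1]))
  dplyr::bind_cols(fits, corr)
}
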