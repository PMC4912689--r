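#' Fit a three-parameter logistic concentration-response curve
#'
#' Fits `Y = bottom + (top - bottom)/(1 + 10^(-pEC50 - log10 A))` (Hill slope
#' fixed to 1) by bounded least squares with three data-driven starts.
#' By default technical duplicates are averaged within each independent
#' experiment, each experiment is fitted separately, and the per-experiment
#' estimates are pooled as mean +/- SEM, mirroring the "n independent
#' experiments conducted in duplicate" design. Basal (zero-concentration)
#' wells anchor the bottom asymptote.
#'
#' @param data Data frame with columns `concentration` (molar, 0 = basal) and
#'   `response`; optional `experiment_id` and `replicate_id`.
#' @param fix_bottom,fix_top Optional fixed asymptote values.
#' @param average_duplicates Average replicates within an experiment before
#'   fitting (default `TRUE`).
#' @param pool Fit all experiments jointly instead of per experiment.
#' @param noise_alpha Significance level of the F-test against a flat model
#'   used to call `no_response` (default 0.05).
#' @return An object of class `logistic_fit`: a list with `pec50`, `top`,
#'   `bottom`, their SEMs, `n_experiments`, `converged`, `extrapolated`,
#'   `status` (`"ok"` or `"no_response"`), and a `per_experiment` tibble of
#'   experiment-level estimates.
#' @export
fit_logistic <- function(data, fix_bottom = NULL, fix_top = NULL,
                         average_duplicates = TRUE, pool = FALSE,
                         noise_alpha = 0.05) {
  data <- prep_curve_data(data, average_duplicates)
  rng <- range(-log10(data$concentration[data$concentration > 0]))

  if (flat_curve(data$concentration, data$response, noise_alpha)) {
    return(structure(list(
      pec50 = NA_real_, top = NA_real_, bottom = NA_real_,
      sem_pec50 = NA_real_, sem_top = NA_real_, sem_bottom = NA_real_,
      n_experiments = length(unique(data$experiment_id)),
      converged = FALSE, extrapolated = FALSE, status = "no_response",
      per_experiment = empty_logistic_pe()
    ), class = "logistic_fit"))
  }

  split_ids <- if (pool) list(all = data) else split(data, data$experiment_id)
  pe <- purrr::map(split_ids, function(d) {
    fit_logistic_single(d$concentration, d$response, fix_bottom, fix_top)
  })
  pe_tbl <- tibble::tibble(
    experiment_id = names(pe),
    pec50 = purrr::map_dbl(pe, "pec50"),
    top = purrr::map_dbl(pe, "top"),
    bottom = purrr::map_dbl(pe, "bottom"),
    converged = purrr::map_lgl(pe, "converged")
  )
  ok <- pe_tbl$converged & is.finite(pe_tbl$pec50)
  agg <- function(v, se_single) {
    if (sum(ok) >= 2) c(mean(v[ok]), sem(v[ok]))
    else c(unname(v[ok][1]), unname(se_single))
  }
  one <- pe[[which(ok)[1]]]
  p <- agg(pe_tbl$pec50, one$se["pec50"])
  t <- agg(pe_tbl$top, one$se["top"])
  b <- agg(pe_tbl$bottom, one$se["bottom"])

  structure(list(
    pec50 = p[1], top = t[1], bottom = b[1],
    sem_pec50 = p[2], sem_top = t[2], sem_bottom = b[2],
    n_experiments = nrow(pe_tbl),
    converged = all(pe_tbl$converged),
    extrapolated = p[1] < rng[1] - 1 || p[1] > rng[2] + 1,
    status = "ok",
    per_experiment = pe_tbl
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit>", x$status, "\n")
  if (x$status == "ok") {
    cat(sprintf("  pEC50 %.3f +/- %.3f  top %.2f  bottom %.2f  (n = %d)\n",
                x$pec50, x$sem_pec50 %||% NA, x$top, x$bottom,
                x$n_experiments))
    if (x$extrapolated) cat("  note: pEC50 outside tested range + 1 log\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

prep_curve_data <- function(data, average_duplicates) {
  stopifnot(all(c("concentration", "response") %in% names(data)))
  if (!"experiment_id" %in% names(data)) data$experiment_id <- 1L
  data <- data[is.finite(data$response) & data$concentration >= 0, ]
  if (average_duplicates) {
    data <- dplyr::summarise(
      dplyr::group_by(data, .data$experiment_id, .data$concentration),
      response = mean(.data$response), .groups = "drop")
  }
  n_conc <- length(unique(data$concentration[data$concentration > 0]))
  if (n_conc < 5) {
    stop("need >= 5 distinct non-zero concentrations, got ", n_conc)
  }
  data
}

empty_logistic_pe <- function() {
  tibble::tibble(experiment_id = character(), pec50 = double(),
                 top = double(), bottom = double(), converged = logical())
}

# F-test of the 3PL fit against a flat (intercept-only) model; degenerate
# residuals (both models exact) count as flat.
flat_curve <- function(conc, resp, alpha) {
  if (diff(range(resp)) == 0) return(TRUE)
  fit <- try(fit_logistic_single(conc, resp, NULL, NULL), silent = TRUE)
  if (inherits(fit, "try-error")) return(TRUE)
  sse1 <- fit$rss
  sse0 <- sum((resp - mean(resp))^2)
  df1 <- length(resp) - 3
  if (df1 <= 0) return(FALSE)
  if (sse1 <= .Machine$double.eps * sse0) return(FALSE)
  f <- ((sse0 - sse1) / 2) / (sse1 / df1)
  stats::pf(f, 2, df1, lower.tail = FALSE) > alpha
}

fit_logistic_single <- function(conc, resp, fix_bottom = NULL,
                                fix_top = NULL) {
  lg <- -log10(conc[conc > 0])
  span <- diff(range(resp))
  mid <- min(resp) + span / 2
  p0 <- lg[which.min(abs(resp[conc > 0] - mid))]
  starts <- c(p0, p0 - 1, p0 + 1)
  lower <- c(pec50 = min(lg) - 3, top = -Inf, bottom = -Inf)
  upper <- c(pec50 = max(lg) + 3, top = Inf, bottom = Inf)

  best <- NULL
  for (s in starts) {
    st <- list(pec50 = s)
    if (is.null(fix_top)) st$top <- max(resp)
    if (is.null(fix_bottom)) st$bottom <- min(resp)
    model <- function(p) {
      top <- if (is.null(fix_top)) p[["top"]] else fix_top
      bottom <- if (is.null(fix_bottom)) p[["bottom"]] else fix_bottom
      logistic3(conc, p[["pec50"]], top, bottom)
    }
    fit <- try(minpack.lm::nls.lm(
      par = st, fn = function(p) resp - model(p),
      lower = lower[names(st)], upper = upper[names(st)],
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("logistic fit failed for all starts")
  fit <- best$fit
  cf <- fit$par
  se <- tryCatch({
    s <- summary(fit)$coefficients[, "Std. Error"]
    stats::setNames(as.numeric(s), rownames(summary(fit)$coefficients))
  }, error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                         names(cf)))
  list(
    pec50 = cf[["pec50"]],
    top = if (is.null(fix_top)) cf[["top"]] else fix_top,
    bottom = if (is.null(fix_bottom)) cf[["bottom"]] else fix_bottom,
    se = se, rss = best$rss,
    converged = fit$info %in% 1:4
  )
}

#' Fit a one-site competition binding curve and derive pKi
#'
#' Fits `B = bottom + (top - bottom)/(1 + 10^(log10 A + pIC50))` to
#' competition radioligand-binding data (% specific binding versus log
#' competitor concentration), per independent experiment, then converts the
#' pooled pIC50 to pKi with the Cheng-Prusoff correction
#' `pKi = pIC50 + log10(1 + tracer_conc/tracer_kd)`.
#'
#' @param data Data frame with columns `log_conc` (log10 molar) and
#'   `specific_binding` (%); optional `experiment_id`.
#' @param tracer_kd,tracer_conc Tracer dissociation constant and assay
#'   concentration, molar.
#' @param min_displacement Minimum displacement (percentage points) over the
#'   tested range required to call binding (default 20).
#' @return An object of class `affinity_fit` with `pic50`, `pki`, `sem_pki`,
#'   `n_experiments`, `status` (`"ok"` or `"no_binding"`), `method`, and a
#'   `per_experiment` tibble.
#' @export
fit_competition <- function(data, tracer_kd, tracer_conc,
                            min_displacement = 20) {
  stopifnot(all(c("log_conc", "specific_binding") %in% names(data)),
            tracer_kd > 0, tracer_conc > 0)
  if (!"experiment_id" %in% names(data)) data$experiment_id <- 1L
  data <- data[is.finite(data$specific_binding), ]

  m <- dplyr::summarise(dplyr::group_by(data, .data$log_conc),
                        b = mean(.data$specific_binding), .groups = "drop")
  displacement <- m$b[which.min(m$log_conc)] - m$b[which.max(m$log_conc)]
  if (!is.finite(displacement) || displacement < min_displacement) {
    return(structure(list(
      pic50 = NA_real_, pki = NA_real_, sem_pki = NA_real_,
      sem_pic50 = NA_real_, n_experiments = length(unique(data$experiment_id)),
      status = "no_binding", method = "cheng_prusoff",
      per_experiment = tibble::tibble(experiment_id = character(),
                                      pic50 = double())
    ), class = "affinity_fit"))
  }

  pe <- purrr::map_dbl(split(data, data$experiment_id), function(d) {
    fit_competition_single(d$log_conc, d$specific_binding)
  })
  correction <- log10(1 + tracer_conc / tracer_kd)
  pic50 <- mean(pe)
  s <- if (length(pe) >= 2) sem(pe) else NA_real_
  structure(list(
    pic50 = pic50,
    pki = cheng_prusoff(pic50, tracer_conc, tracer_kd),
    sem_pic50 = s,
    sem_pki = s,  # the correction is a known constant offset
    n_experiments = length(pe),
    status = "ok", method = "cheng_prusoff",
    per_experiment = tibble::tibble(experiment_id = names(pe), pic50 = pe,
                                    pki = pe + correction)
  ), class = "affinity_fit")
}

#' @export
print.affinity_fit <- function(x, ...) {
  cat("<affinity_fit>", x$status, "\n")
  if (x$status == "ok") {
    cat(sprintf("  pIC50 %.3f  pKi %.3f +/- %.3f  (n = %d, Cheng-Prusoff)\n",
                x$pic50, x$pki, x$sem_pki, x$n_experiments))
  }
  invisible(x)
}

fit_competition_single <- function(log_conc, binding) {
  mid <- min(binding) + diff(range(binding)) / 2
  p0 <- -log_conc[which.min(abs(binding - mid))]
  best <- NULL
  for (s in c(p0, p0 - 1, p0 + 1)) {
    fit <- try(minpack.lm::nls.lm(
      par = list(pic50 = s, top = max(binding), bottom = min(binding)),
      fn = function(p) binding -
        competition1(log_conc, p$pic50, p$top, p$bottom),
      lower = c(-max(log_conc) - 3, -Inf, -Inf),
      upper = c(-min(log_conc) + 3, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit,
                                                             rss = rss)
  }
  if (is.null(best)) stop("competition fit failed")
  best$fit$par$pic50
}
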