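#' Three-parameter logistic concentration-response model
#'
#' Classical Hill-slope-1 logistic used to summarise agonist concentration-
#' response data: `Y = bottom + (top - bottom) / (1 + 10^(-pEC50 - log10 A))`.
#' Zero concentrations (basal wells) evaluate to `bottom`.
#'
#' @param conc Agonist concentration in molar (0 allowed for basal wells).
#' @param pec50 Negative log10 molar EC50.
#' @param top,bottom Upper and lower asymptotes in assay units.
#' @return Predicted response, same length as `conc`.
#' @export
logistic3 <- function(conc, pec50, top, bottom) {
  stopifnot(all(conc >= 0))
  out <- rep(bottom, length.out = length(conc))
  pos <- conc > 0
  out[pos] <- bottom + (top - bottom) / (1 + 10^(-pec50 - log10(conc[pos])))
  out
}

#' One-site competition binding model
#'
#' Displacement of a tracer by a competitor:
#' `B = bottom + (top - bottom) / (1 + 10^(log10 A + pIC50))`.
#'
#' @param log_conc log10 molar competitor concentration.
#' @param pic50 Negative log10 molar IC50.
#' @param top,bottom Binding plateaus (% specific binding).
#' @return Predicted specific binding.
#' @export
competition1 <- function(log_conc, pic50, top, bottom) {
  bottom + (top - bottom) / (1 + 10^(log_conc + pic50))
}

#' Operational model of agonism
#'
#' Black-Leff operational model in the logistic form used for receptor
#' mutagenesis analysis:
#' `Y = bottom + (Em - bottom) / (1 + (10^logKA + A) / (10^logtau * A))`
#' with agonist concentration `A` in molar. `tau` is the operational
#' efficacy (coupling of the occupied receptor to response, which also
#' absorbs receptor density) and `K_A` the functional agonist-receptor
#' dissociation constant. Zero concentrations evaluate to `bottom`.
#'
#' Useful identities: the plateau is `bottom + (Em - bottom) * tau/(tau+1)`
#' and the midpoint obeys `pEC50 = -logKA + log10(tau + 1)`.
#'
#' @param conc Agonist concentration in molar.
#' @param log_tau log10 operational efficacy.
#' @param log_ka log10 molar functional dissociation constant.
#' @param em Maximal system stimulation (assay units).
#' @param bottom Response in the absence of ligand.
#' @return Predicted response, same length as `conc`.
#' @export
operational_model <- function(conc, log_tau, log_ka, em, bottom) {
  stopifnot(all(conc >= 0))
  out <- rep(bottom, length.out = length(conc))
  pos <- conc > 0
  a <- conc[pos]
  out[pos] <- bottom + (em - bottom) /
    (1 + (10^log_ka + a) / (10^log_tau * a))
  out
}

#' Cheng-Prusoff conversion of pIC50 to pKi
#'
#' `Ki = IC50 / (1 + L/Kd)` for a competitive interaction with tracer
#' concentration `L` and tracer dissociation constant `Kd`, i.e.
#' `pKi = pIC50 + log10(1 + L/Kd)`.
#'
#' @param pic50 Negative log10 molar IC50 from a competition fit.
#' @param tracer_conc,tracer_kd Tracer concentration and Kd, molar.
#' @return pKi on the negative log10 molar scale.
#' @export
cheng_prusoff <- function(pic50, tracer_conc, tracer_kd) {
  stopifnot(tracer_conc > 0, tracer_kd > 0)
  pic50 + log10(1 + tracer_conc / tracer_kd)
}

# standard error of the mean
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# delta-method conversion of a linear-scale SEM to the log10 scale
sem_to_log10 <- function(sem_x, x) sem_x / (x * log(10))

# quadrature combination of independent SEMs
sem_quad <- function(...) sqrt(sum(c(...)^2))

# run code with a locally fixed RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
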