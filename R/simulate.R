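#' Default agonist concentration grid
#'
#' Ten-point 3-fold serial dilution from 1 uM down (1e-6 to ~5e-11 M,
#' spanning ~4.3 log units) plus a basal zero-concentration well.
#'
#' @param top Highest concentration, molar.
#' @param n Number of non-zero points.
#' @param dilution Serial dilution factor.
#' @param basal Include a zero-concentration basal well.
#' @return Numeric vector of molar concentrations.
#' @export
default_grid <- function(top = 1e-6, n = 10, dilution = 3, basal = TRUE) {
  g <- top / dilution^(seq_len(n) - 1)
  if (basal) c(0, rev(g)) else rev(g)
}

# wild-type ground truth shared by all scenarios; the reference peptide is
# a strong agonist in the reference pathway, the oxyntomodulin-like
# peptide a weak partial agonist with a built-in +1.0 log unit
# DeltaDelta log(tau/K_A) shift toward pERK, and the exendin-4-like
# peptide essentially unbiased. Functional log K_A equals -pKi throughout
# (the assumption behind fixing K_A to binding affinity), so the
# functional and binding truths are mutually consistent.
wt_functional_truth <- function() {
  tibble::tribble(
    ~ligand_id,      ~pathway_id, ~log_tau, ~log_ka,
    "GLP-1",         "cAMP",       0.70,    -8.2,
    "oxyntomodulin", "cAMP",      -0.20,    -7.0,
    "exendin-4",     "cAMP",       0.60,    -8.8,
    "GLP-1",         "pERK",       0.30,    -8.2,
    "oxyntomodulin", "pERK",       0.40,    -7.0,
    "exendin-4",     "pERK",       0.25,    -8.8,
    "GLP-1",         "iCa",        0.20,    -8.2,
    "oxyntomodulin", "iCa",       -0.60,    -7.0,
    "exendin-4",     "iCa",       -0.15,    -8.8) |>
    dplyr::mutate(construct_id = "WT", em = 100, bottom = 0,
                  .before = 1)
}

wt_binding_truth <- function() {
  tibble::tibble(
    construct_id = "WT",
    ligand_id = c("GLP-1", "oxyntomodulin", "exendin-4"),
    pki = c(8.2, 7.0, 8.8))
}

new_truth_panel <- function(functional, binding, expression, tags = list()) {
  structure(list(functional = functional, binding = binding,
                 expression = expression, tags = tags),
            class = "truth_panel")
}

#' @export
print.truth_panel <- function(x, ...) {
  cat("<truth_panel> ", length(unique(x$functional$construct_id)),
      " construct(s), ",
      length(unique(x$functional$ligand_id)), " ligand(s), ",
      length(unique(x$functional$pathway_id)), " pathway(s)\n", sep = "")
  invisible(x)
}

# derive a mutant's truth rows from wild-type by log-scale shifts; an
# affinity shift moves binding pKi and functional K_A together
mutant_truth <- function(wt_fun, wt_bind, id, d_log_tau = 0, d_pki = 0,
                         pathways = NULL, ligands = NULL) {
  f <- wt_fun
  sel <- rep(TRUE, nrow(f))
  if (!is.null(pathways)) sel <- sel & f$pathway_id %in% pathways
  if (!is.null(ligands)) sel <- sel & f$ligand_id %in% ligands
  f$log_tau[sel] <- f$log_tau[sel] + d_log_tau
  f$log_ka[sel] <- f$log_ka[sel] - d_pki
  f$construct_id <- id
  b <- wt_bind
  bsel <- if (is.null(ligands)) rep(TRUE, nrow(b)) else
    b$ligand_id %in% ligands
  b$pki[bsel] <- b$pki[bsel] + d_pki
  b$construct_id <- id
  list(functional = f, binding = b)
}

#' Bundled ground-truth scenarios
#'
#' Named `truth_panel` objects emulating the phenotype classes seen in
#' receptor alanine scans, each carrying its generative parameters as
#' ground truth:
#' \describe{
#'   \item{wild_type}{The reference construct alone: a strong agonist
#'     (GLP-1-like), a pERK-biased low-efficacy partial agonist
#'     (oxyntomodulin-like, true DeltaDelta log(tau/K_A) = +1.0 toward
#'     pERK), and an essentially unbiased strong agonist (exendin-4-like),
#'     across cAMP, pERK and iCa.}
#'   \item{bias_reference}{Same truths restricted to cAMP + pERK; tag
#'     `true_ddelta_perk` records the oxyntomodulin-like pERK bias (+1.0).}
#'   \item{mutant_classes}{Wild-type plus eight mutants with 4-, 7-, 18-
#'     and 50-fold losses in affinity (pKi; ECL1 positions) or efficacy
#'     (log tau, all pathways; ECL2 positions), one bin mid-point each.}
#'   \item{expression_deficit}{A mutant expressed at 30% of wild-type with
#'     intrinsic coupling untouched (observed tau scales with expression;
#'     tau_c should recover wild-type).}
#'   \item{enhanced_efficacy}{A mutant with +0.8 log tau for GLP-1 and
#'     exendin-4 in iCa but -0.7 for oxyntomodulin (mixed-direction
#'     pattern), plus +0.8 for GLP-1 in cAMP.}
#'   \item{dead_surface}{A mutant with no detectable surface expression:
#'     expression not_determined, flat curves, no binding.}
#'   \item{full_panel}{Wild-type plus 56 alanine mutants tiling ECL1
#'     (201-223), ECL2 (285-307) and a 10-residue stretch of ECL3
#'     (372-381), cycling deterministically through effect classes — used
#'     to exercise the whole pipeline and the structure heatmap.}
#' }
#'
#' @return Named list of `truth_panel` objects.
#' @export
scenario_library <- function() {
  wf <- wt_functional_truth(); wb <- wt_binding_truth()
  we <- tibble::tibble(construct_id = "WT", expression_fraction = 1,
                       sem = 0.05, status = "ok")
  lib <- list()

  lib$wild_type <- new_truth_panel(wf, wb, we,
                                   tags = list(scenario = "wild_type"))

  sub <- wf[wf$pathway_id %in% c("cAMP", "pERK"), ]
  lib$bias_reference <- new_truth_panel(
    sub, wb, we, tags = list(scenario = "bias_reference",
                             true_ddelta_perk = 1.0,
                             bias_ligand = "oxyntomodulin"))

  folds <- c(4, 7, 18, 50)
  aff_ids <- paste0(c("L", "K", "M", "V"), c(201, 202, 204, 206), "A")
  eff_ids <- paste0(c("G", "T", "Y", "E"), c(285, 286, 291, 294), "A")
  mc_fun <- list(wf); mc_bind <- list(wb)
  mc_expr <- list(we)
  for (i in seq_along(folds)) {
    m <- mutant_truth(wf, wb, aff_ids[i], d_pki = -log10(folds[i]))
    mc_fun <- c(mc_fun, list(m$functional)); mc_bind <- c(mc_bind,
                                                          list(m$binding))
    m <- mutant_truth(wf, wb, eff_ids[i], d_log_tau = -log10(folds[i]))
    mc_fun <- c(mc_fun, list(m$functional)); mc_bind <- c(mc_bind,
                                                          list(m$binding))
    mc_expr <- c(mc_expr, list(
      tibble::tibble(construct_id = c(aff_ids[i], eff_ids[i]),
                     expression_fraction = 1, sem = 0.05, status = "ok")))
  }
  lib$mutant_classes <- new_truth_panel(
    dplyr::bind_rows(mc_fun), dplyr::bind_rows(mc_bind),
    dplyr::bind_rows(mc_expr),
    tags = list(scenario = "mutant_classes", folds = folds,
                affinity_mutants = aff_ids, efficacy_mutants = eff_ids))

  frac <- 0.3
  m <- mutant_truth(wf, wb, "N210A", d_log_tau = log10(frac))
  lib$expression_deficit <- new_truth_panel(
    dplyr::bind_rows(wf, m$functional), dplyr::bind_rows(wb, m$binding),
    dplyr::bind_rows(we, tibble::tibble(
      construct_id = "N210A", expression_fraction = frac,
      sem = 0.05 * frac, status = "ok")),
    tags = list(scenario = "expression_deficit", mutant = "N210A",
                expression_fraction = frac))

  m <- mutant_truth(wf, wb, "T378A")
  m$functional$log_tau <- m$functional$log_tau + with(
    m$functional,
    ifelse(pathway_id == "iCa" & ligand_id != "oxyntomodulin", 0.8,
    ifelse(pathway_id == "iCa", -0.7,
    ifelse(pathway_id == "cAMP" & ligand_id == "GLP-1", 0.8, 0))))
  lib$enhanced_efficacy <- new_truth_panel(
    dplyr::bind_rows(wf, m$functional), dplyr::bind_rows(wb, m$binding),
    dplyr::bind_rows(we, tibble::tibble(
      construct_id = "T378A", expression_fraction = 1, sem = 0.05,
      status = "ok")),
    tags = list(scenario = "enhanced_efficacy", mutant = "T378A"))

  dead_fun <- wf
  dead_fun$construct_id <- "W306A"
  dead_fun$log_tau <- NA_real_  # no detectable response
  dead_bind <- wb
  dead_bind$construct_id <- "W306A"
  dead_bind$pki <- NA_real_
  lib$dead_surface <- new_truth_panel(
    dplyr::bind_rows(wf, dead_fun), dplyr::bind_rows(wb, dead_bind),
    dplyr::bind_rows(we, tibble::tibble(
      construct_id = "W306A", expression_fraction = NA_real_,
      sem = NA_real_, status = "not_determined")),
    tags = list(scenario = "dead_surface", mutant = "W306A"))

  lib$full_panel <- full_panel_truth(wf, wb, we)
  lib
}

# 56 mutants tiling the loops, cycling deterministically through effect
# classes so every heat category and summary class is represented
full_panel_truth <- function(wf, wb, we) {
  positions <- c(201:223, 285:307, 372:381)
  aa <- c("L", "K", "S", "M", "T", "V", "Q", "N", "D", "E", "Y", "W", "R")
  classes <- c("none", "aff_4", "eff_7", "aff_18", "eff_50", "none",
               "eff_4", "aff_50")
  ligs <- c("GLP-1", "oxyntomodulin", "exendin-4")
  funs <- list(wf); binds <- list(wb); exprs <- list(we)
  for (i in seq_along(positions)) {
    pos <- positions[i]
    id <- paste0(aa[(i - 1) %% length(aa) + 1], pos, "A")
    cls <- classes[(i - 1) %% length(classes) + 1]
    # alternate which ligands carry the effect to populate the
    # selective/shared/global summary classes
    lig_sel <- switch((i %% 3) + 1, ligs, ligs[1], ligs[1:2])
    m <- switch(cls,
      none = mutant_truth(wf, wb, id),
      aff_4 = mutant_truth(wf, wb, id, d_pki = -log10(4),
                           ligands = lig_sel),
      aff_18 = mutant_truth(wf, wb, id, d_pki = -log10(18),
                            ligands = lig_sel),
      aff_50 = mutant_truth(wf, wb, id, d_pki = -log10(50),
                            ligands = lig_sel),
      eff_4 = mutant_truth(wf, wb, id, d_log_tau = -log10(4),
                           ligands = lig_sel),
      eff_7 = mutant_truth(wf, wb, id, d_log_tau = -log10(7),
                           ligands = lig_sel),
      eff_50 = mutant_truth(wf, wb, id, d_log_tau = -log10(50),
                            ligands = lig_sel))
    funs <- c(funs, list(m$functional)); binds <- c(binds, list(m$binding))
    exprs <- c(exprs, list(tibble::tibble(
      construct_id = id, expression_fraction = 1, sem = 0.05,
      status = "ok")))
  }
  new_truth_panel(dplyr::bind_rows(funs), dplyr::bind_rows(binds),
                  dplyr::bind_rows(exprs),
                  tags = list(scenario = "full_panel",
                              positions = positions))
}

#' Generate a synthetic study dataset from a ground-truth panel
#'
#' Draws complete concentration-response, competition-binding and
#' cell-surface expression tables from a `truth_panel`, emulating the study
#' design: `n_experiments` independent experiments (4-6 in the emulated
#' study) conducted in `n_duplicates` technical duplicates, multiplicative
#' Gaussian measurement noise with constant coefficient of variation, and
#' small between-experiment random effects on the system maximum.
#' Functional responses are operational-model means; binding curves are
#' one-site competition curves whose true pIC50 derives from the true pKi
#' by the inverse Cheng-Prusoff relation; expression observations are
#' Gaussian around the true fraction. Fully deterministic under `seed`.
#'
#' @param truth A `truth_panel`, e.g. from [scenario_library()].
#' @param cv Fractional (multiplicative) response noise, default 0.05.
#' @param n_experiments Independent experiments per curve (default 5).
#' @param n_duplicates Technical replicates per experiment (default 2).
#' @param seed Integer seed; same seed, same tables.
#' @param grid Agonist concentration grid, molar ([default_grid()]).
#' @param binding_grid log10 molar competitor grid for binding curves.
#' @param tracer_kd,tracer_conc Tracer parameters (molar) used to translate
#'   true pKi into the generative pIC50.
#' @param exp_effect_sd SD of the between-experiment multiplicative shift
#'   in the system maximum (default 0.05).
#' @param binding_sd Additive SD of binding noise, percentage points.
#' @param noise `"multiplicative"` (default, constant CV) or `"additive"`
#'   (constant SD `cv * em`).
#' @return A list of class `synthetic_panel`: tibbles `response`,
#'   `binding`, `expression`, the `truth` panel, and the generation
#'   settings in `config`. Warns when the grid does not cover a curve's
#'   true EC50 +/- 1 log unit.
#' @export
generate_panel <- function(truth, cv = 0.05, n_experiments = 5,
                           n_duplicates = 2, seed = 1,
                           grid = default_grid(),
                           binding_grid = seq(-11.5, -5.5, by = 0.5),
                           tracer_kd = 1e-9, tracer_conc = 0.5e-9,
                           exp_effect_sd = 0.05, binding_sd = 5,
                           noise = c("multiplicative", "additive")) {
  noise <- match.arg(noise)
  stopifnot(inherits(truth, "truth_panel"), cv >= 0, n_experiments >= 1)
  set.seed(seed)
  f <- truth$functional
  pos_grid <- grid[grid > 0]
  if (length(pos_grid) < 6 ||
      diff(range(log10(pos_grid))) < 4) {
    stop("concentration grid must have >= 6 points spanning >= 4 log units")
  }

  active <- f[is.finite(f$log_tau), ]
  if (nrow(active) > 0) {
    ec50 <- -(-active$log_ka + log10(10^active$log_tau + 1))
    covered <- ec50 >= min(log10(pos_grid)) - 1 &
      ec50 <= max(log10(pos_grid)) + 1
    if (!all(covered)) {
      warning("grid does not cover true EC50 +/- 1 log for: ",
              paste(unique(paste(active$construct_id[!covered],
                                 active$ligand_id[!covered],
                                 active$pathway_id[!covered])),
                    collapse = "; "))
    }
  }

  design <- tidyr::expand_grid(
    f, experiment_id = seq_len(n_experiments),
    concentration = grid, replicate_id = seq_len(n_duplicates))
  # between-experiment shift in the system maximum (shared within a
  # construct x pathway x experiment)
  eff_key <- unique(design[c("construct_id", "pathway_id",
                             "experiment_id")])
  eff_key$em_mult <- 1 + stats::rnorm(nrow(eff_key), 0, exp_effect_sd)
  design <- dplyr::left_join(
    design, eff_key, by = c("construct_id", "pathway_id", "experiment_id"))
  mu <- ifelse(
    is.finite(design$log_tau),
    operational_model_v(design$concentration, design$log_tau,
                        design$log_ka, design$em * design$em_mult,
                        design$bottom),
    design$bottom)
  eps <- stats::rnorm(nrow(design))
  design$response <- if (noise == "multiplicative") mu * (1 + cv * eps)
    else mu + cv * design$em * eps
  response <- design[c("construct_id", "ligand_id", "pathway_id",
                       "experiment_id", "replicate_id", "concentration",
                       "response")]

  b <- truth$binding
  bdesign <- tidyr::expand_grid(
    b, experiment_id = seq_len(n_experiments), log_conc = binding_grid)
  pic50 <- bdesign$pki - log10(1 + tracer_conc / tracer_kd)
  bmu <- ifelse(is.finite(pic50),
                competition1(bdesign$log_conc, pic50, 100, 0),
                100)  # no displacement when the competitor does not bind
  bdesign$specific_binding <- bmu + stats::rnorm(nrow(bdesign), 0,
                                                 binding_sd)
  binding <- bdesign[c("construct_id", "ligand_id", "experiment_id",
                       "log_conc", "specific_binding")]

  e <- truth$expression
  obs <- rep(NA_real_, nrow(e))
  ok <- e$status == "ok"
  obs[ok] <- stats::rnorm(sum(ok), e$expression_fraction[ok], e$sem[ok])
  expression <- tibble::tibble(
    construct_id = e$construct_id,
    expression_fraction = pmax(obs, 0.01),
    sem = e$sem, status = e$status)
  # the wild-type anchors the relative scale
  wt <- expression$construct_id == "WT"

  structure(list(
    response = response, binding = binding, expression = expression,
    truth = truth,
    config = list(cv = cv, n_experiments = n_experiments,
                  n_duplicates = n_duplicates, seed = seed,
                  tracer_kd = tracer_kd, tracer_conc = tracer_conc,
                  exp_effect_sd = exp_effect_sd, binding_sd = binding_sd,
                  noise = noise)),
    class = "synthetic_panel")
}

# vectorised operational model (parameters vary per row)
operational_model_v <- function(conc, log_tau, log_ka, em, bottom) {
  out <- bottom
  pos <- conc > 0
  out[pos] <- bottom[pos] + (em[pos] - bottom[pos]) /
    (1 + (10^log_ka[pos] + conc[pos]) / (10^log_tau[pos] * conc[pos]))
  out
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("<synthetic_panel> ", nrow(x$response), " response rows, ",
      nrow(x$binding), " binding rows, seed ", x$config$seed, "\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic panel to disk
#'
#' Emits the three input CSVs (`response.csv`, `binding.csv`,
#' `expression.csv`) plus the serialized ground truth (`truth.json`) into a
#' directory, the on-disk contract of the `simulate` command-line verb.
#'
#' @param panel A `synthetic_panel` from [generate_panel()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(panel$response, file.path(dir, "response.csv"))
  readr::write_csv(panel$binding, file.path(dir, "binding.csv"))
  readr::write_csv(panel$expression, file.path(dir, "expression.csv"))
  jsonlite::write_json(
    list(functional = panel$truth$functional,
         binding = panel$truth$binding,
         expression = panel$truth$expression,
         tags = panel$truth$tags, config = panel$config),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
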