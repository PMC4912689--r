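#' Parse alanine-mutant construct identifiers
#'
#' Interprets ids like `"L201A"` (wild-type residue, position, mutant
#' residue); anything that does not match is treated as wild-type.
#'
#' @param ids Character construct ids.
#' @return Tibble `construct_id`, `kind`, `position`, `wt_residue`,
#'   `mut_residue`.
#' @export
parse_construct_id <- function(ids) {
  m <- regmatches(ids, regexec("^([A-Y])([0-9]+)([A-Y])$", ids))
  tibble::tibble(
    construct_id = ids,
    kind = ifelse(vapply(m, length, integer(1)) == 4, "point_mutant",
                  "wild_type"),
    position = vapply(m, function(x)
      if (length(x) == 4) as.integer(x[3]) else NA_integer_, integer(1)),
    wt_residue = vapply(m, function(x)
      if (length(x) == 4) x[2] else NA_character_, character(1)),
    mut_residue = vapply(m, function(x)
      if (length(x) == 4) x[4] else NA_character_, character(1)))
}

# ratio of the wild-type response window to replicate noise, used to
# decide whether a no-response mutant can be floored to the top heat bin
wt_window_ratio <- function(response, wt_id, pathway) {
  d <- response[response$construct_id == wt_id &
                  response$pathway_id == pathway, ]
  if (nrow(d) == 0) return(NA_real_)
  g <- dplyr::summarise(
    dplyr::group_by(d, .data$ligand_id, .data$experiment_id,
                    .data$concentration),
    m = mean(.data$response), s = stats::sd(.data$response),
    .groups = "drop")
  span <- max(g$m) - min(g$m)
  noise <- stats::median(g$s, na.rm = TRUE)
  if (!is.finite(noise) || noise == 0) return(Inf)
  span / noise
}

#' Run the full mutant-panel analysis
#'
#' End-to-end pipeline over a study dataset: operational-model fits per
#' construct x pathway ([fit_operational()]), expression correction
#' ([correct_tau_table()]), competition-binding fits per construct x ligand
#' ([fit_competition()]), mutant-versus-wild-type deltas with ANOVA +
#' Dunnett ([delta_vs_wildtype()]), heat classification ([classify_heat()]),
#' per-residue summary classes ([summarize_across_ligands()]), and bias
#' factors for the wild-type construct ([transduction_coefficients()],
#' [bias_factors()]).
#'
#' @param panel A `synthetic_panel`, or a list with tibbles `response`,
#'   `binding`, `expression` in the package's table schemas.
#' @param config A [run_config()].
#' @param wt_id Wild-type construct id (default `"WT"`).
#' @return A list with `operational` (fits + tau_c per
#'   construct/ligand/pathway), `affinity` (pKi per construct/ligand),
#'   `deltas` (classified `DeltaEstimate` rows for measures `pKi` and
#'   `log_tau_c`), `residue_summary` (per position x measure summary
#'   class), `bias` (wild-type bias table, `NULL` when the reference
#'   cells are not all measured), and `per_experiment` (experiment-level
#'   operational and affinity estimates behind the pooled values).
#' @export
analyze_panel <- function(panel, config = run_config(), wt_id = "WT") {
  response <- panel$response; binding <- panel$binding
  expression <- panel$expression
  stopifnot(wt_id %in% response$construct_id)

  # ---- binding fits per construct x ligand ----
  bkeys <- unique(binding[c("construct_id", "ligand_id")])
  aff <- purrr::map(seq_len(nrow(bkeys)), function(i) {
    d <- binding[binding$construct_id == bkeys$construct_id[i] &
                   binding$ligand_id == bkeys$ligand_id[i], ]
    f <- fit_competition(d, tracer_kd = config$tracer_kd,
                         tracer_conc = config$tracer_conc)
    pe <- f$per_experiment
    row <- tibble::tibble(
      construct_id = bkeys$construct_id[i],
      ligand_id = bkeys$ligand_id[i],
      pic50 = f$pic50, pki = f$pki, sem_pki = f$sem_pki,
      n_experiments = f$n_experiments, status = f$status)
    if (nrow(pe) > 0) {
      pe$construct_id <- bkeys$construct_id[i]
      pe$ligand_id <- bkeys$ligand_id[i]
    }
    list(row = row, pe = pe)
  })
  affinity <- dplyr::bind_rows(purrr::map(aff, "row"))
  aff_pe <- dplyr::bind_rows(purrr::map(aff, "pe"))

  # ---- operational fits per construct x pathway ----
  # Under em_policy = "shared_per_pathway" the system maximum is treated
  # as a property of the pathway in this cell background: Em is estimated
  # on the wild-type construct and fixed for the mutants. This keeps tau
  # for strongly impaired mutants plateau-determined instead of
  # amplifying the K_A anchor error by (tau+1)/tau.
  keys <- unique(response[c("construct_id", "pathway_id")])
  keys <- keys[order(keys$construct_id != wt_id, keys$construct_id), ]
  wt_em <- new.env(parent = emptyenv())
  fits <- purrr::map(seq_len(nrow(keys)), function(i) {
    d <- response[response$construct_id == keys$construct_id[i] &
                    response$pathway_id == keys$pathway_id[i], ]
    pki <- affinity[affinity$construct_id == keys$construct_id[i] &
                      affinity$status == "ok", ]
    is_wt <- keys$construct_id[i] == wt_id
    fix_em <- if (!is_wt && config$em_policy == "shared_per_pathway")
      get0(keys$pathway_id[i], envir = wt_em, ifnotfound = NULL)
    else NULL
    f <- fit_operational(d, em_policy = config$em_policy,
                         ka_policy = config$ka_policy,
                         binding = stats::setNames(pki$pki, pki$ligand_id),
                         binding_sem = stats::setNames(pki$sem_pki,
                                                       pki$ligand_id),
                         fix_em = fix_em)
    if (is_wt) {
      em_hat <- mean(f$em[is.finite(f$em)])
      if (is.finite(em_hat)) assign(keys$pathway_id[i], em_hat,
                                    envir = wt_em)
    }
    pe <- attr(f, "per_experiment")
    f$construct_id <- keys$construct_id[i]
    f$pathway_id <- keys$pathway_id[i]
    if (nrow(pe) > 0) {
      pe$construct_id <- keys$construct_id[i]
      pe$pathway_id <- keys$pathway_id[i]
    }
    list(fit = tibble::as_tibble(f), pe = pe)
  })
  operational <- dplyr::bind_rows(purrr::map(fits, "fit"))
  op_pe <- dplyr::bind_rows(purrr::map(fits, "pe"))
  operational <- correct_tau_table(operational, expression, wt_id)

  # per-experiment tau_c values: the expression correction is a constant
  # shift per construct, applied to each experiment's log tau
  shift <- operational$log_tau_c - operational$log_tau
  key <- paste(operational$construct_id, operational$ligand_id,
               operational$pathway_id)
  if (nrow(op_pe) > 0) {
    op_pe$log_tau_c <- op_pe$log_tau +
      shift[match(paste(op_pe$construct_id, op_pe$ligand_id,
                        op_pe$pathway_id), key)]
  }

  # ---- mutant vs wild-type: pKi families per ligand ----
  deltas <- list()
  if (nrow(affinity) > 0 && nrow(affinity[affinity$construct_id !=
                                            wt_id, ]) > 0) {
    if (nrow(aff_pe) > 0 && length(unique(aff_pe$construct_id)) > 1) {
      est <- tibble::tibble(construct_id = aff_pe$construct_id,
                            ligand_id = aff_pe$ligand_id,
                            value = aff_pe$pki)
      d <- delta_vs_wildtype(est, wt_id, "pKi", alpha = config$alpha)
      d$pathway_id <- NA_character_
    } else {
      d <- tibble::tibble()
    }
    deltas$pki <- append_missing_mutants(
      d, affinity[affinity$status != "ok" & affinity$construct_id !=
                    wt_id, ], "pKi")
  }

  # ---- mutant vs wild-type: log tau_c families per ligand x pathway ----
  for (pw in unique(operational$pathway_id)) {
    pe <- op_pe[op_pe$pathway_id == pw & is.finite(op_pe$log_tau_c), ]
    nr <- operational[operational$pathway_id == pw &
                        operational$status == "no_response" &
                        operational$construct_id != wt_id, ]
    if (nrow(pe) > 0 && length(unique(pe$construct_id)) >= 2) {
      est <- tibble::tibble(construct_id = pe$construct_id,
                            ligand_id = pe$ligand_id,
                            value = pe$log_tau_c)
      d <- delta_vs_wildtype(est, wt_id, "log_tau_c",
                             alpha = config$alpha)
      d$pathway_id <- pw
    } else {
      d <- tibble::tibble()  # only the wild-type responded
    }
    deltas[[paste0("tau_", pw)]] <- append_missing_mutants(d, nr,
                                                           "log_tau_c")
  }
  deltas <- dplyr::bind_rows(deltas)

  # ---- heat classification ----
  if (nrow(deltas) > 0) {
    window_ok <- vapply(seq_len(nrow(deltas)), function(i) {
      pw <- deltas$pathway_id[i]
      if (is.na(pw)) return(TRUE)  # binding windows span 0-100%
      r <- wt_window_ratio(response, wt_id, pw)
      is.finite(r) && r >= max(config$fold_bins)
    }, logical(1))
    deltas <- classify_heat(deltas, bins = config$fold_bins,
                            wt_window_ok = window_ok)
  }

  # ---- per-residue summary classes across ligands ----
  residue_summary <- NULL
  if (nrow(deltas) > 0) {
    info <- parse_construct_id(deltas$construct_id)
    dd <- deltas[info$kind == "point_mutant", ]
    dd$position <- info$position[info$kind == "point_mutant"]
    residue_summary <- dplyr::bind_rows(purrr::map(
      split(dd, paste(dd$measure, dd$pathway_id)), function(g) {
        s <- summarize_across_ligands(
          g[c("position", "ligand_id", "category")])
        s$measure <- g$measure[1]
        s$pathway_id <- g$pathway_id[1]
        s
      }))
  }

  # ---- wild-type bias factors ----
  wt_fit <- operational[operational$construct_id == wt_id, ]
  bias <- NULL
  ok_cells <- wt_fit[wt_fit$status %in% c("ok", "ka_fixed") &
                       is.finite(wt_fit$log_tau_c), ]
  ref_ok <- config$reference_pathway_id %in% ok_cells$pathway_id &&
    all(unique(ok_cells$pathway_id) %in%
          ok_cells$pathway_id[ok_cells$ligand_id ==
                                config$reference_ligand_id])
  if (ref_ok) {
    tc <- transduction_coefficients(ok_cells)
    bias <- bias_factors(tc, config$reference_ligand_id,
                         config$reference_pathway_id)
  }

  list(operational = operational, affinity = affinity, deltas = deltas,
       residue_summary = residue_summary, bias = bias,
       per_experiment = list(operational = op_pe, affinity = aff_pe))
}

# add NA-delta rows for mutants whose curves gave no usable estimate, so
# the report mirrors "no detectable response" table entries
append_missing_mutants <- function(d, missing_rows, measure) {
  if (nrow(missing_rows) == 0) return(d)
  extra <- unique(missing_rows[c("construct_id", "ligand_id")])
  if (nrow(d) > 0) {
    extra <- extra[!paste(extra$construct_id, extra$ligand_id) %in%
                     paste(d$construct_id, d$ligand_id), ]
  }
  if (nrow(extra) == 0) return(d)
  add <- tibble::tibble(
    construct_id = extra$construct_id, ligand_id = extra$ligand_id,
    measure = measure, delta = NA_real_, sem_delta = NA_real_,
    p_adj = NA_real_, significant = NA, fold_change = NA_real_,
    direction = NA_character_,
    pathway_id = if ("pathway_id" %in% names(missing_rows))
      missing_rows$pathway_id[match(extra$construct_id,
                                    missing_rows$construct_id)]
    else NA_character_)
  dplyr::bind_rows(d, add)
}
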