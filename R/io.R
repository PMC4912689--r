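#' Run configuration
#'
#' Validated analysis settings shared by the pipeline: the reference ligand
#' and pathway for bias normalization, tracer parameters for the
#' Cheng-Prusoff conversion, the Em and K_A fitting policies, the
#' family-wise significance level, and the fold-change bin thresholds of
#' the heat classification.
#'
#' @param reference_ligand_id,reference_pathway_id Bias references
#'   (defaults `"GLP-1"` and `"cAMP"`).
#' @param tracer_kd,tracer_conc Tracer dissociation constant and assay
#'   concentration, molar.
#' @param em_policy,ka_policy Operational-model policies; see
#'   [fit_operational()]. The pipeline default `"fix_to_binding"`
#'   constrains log K_A to the binding-derived `-pKi` for near-full
#'   agonists, which is what makes Em and tau identifiable (the slope-1
#'   operational curve is otherwise exactly a logistic and carries no
#'   information separating Em, tau and K_A).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param fold_bins Strictly increasing fold thresholds > 1, default
#'   `c(3, 5, 10, 30)`.
#' @param seed Integer seed for any stochastic step.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(reference_ligand_id = "GLP-1",
                       reference_pathway_id = "cAMP",
                       tracer_kd = 1e-9, tracer_conc = 0.5e-9,
                       em_policy = c("shared_per_pathway", "per_curve"),
                       ka_policy = c("fix_to_binding", "fit"),
                       alpha = 0.05, fold_bins = c(3, 5, 10, 30),
                       seed = 1L) {
  em_policy <- match.arg(em_policy)
  ka_policy <- match.arg(ka_policy)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (any(diff(fold_bins) <= 0) || any(fold_bins <= 1)) {
    stop("fold_bins must be strictly increasing and > 1")
  }
  if (tracer_kd <= 0 || tracer_conc <= 0) {
    stop("tracer parameters must be positive")
  }
  structure(list(
    reference_ligand_id = reference_ligand_id,
    reference_pathway_id = reference_pathway_id,
    tracer_kd = tracer_kd, tracer_conc = tracer_conc,
    em_policy = em_policy, ka_policy = ka_policy,
    alpha = alpha, fold_bins = fold_bins, seed = as.integer(seed)),
    class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with any subset of the [run_config()] fields;
#'   missing fields take the defaults.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

table_schemas <- list(
  response = list(
    required = c("construct_id", "ligand_id", "pathway_id",
                 "experiment_id", "replicate_id", "concentration",
                 "response"),
    numeric = c("concentration", "response")),
  binding = list(
    required = c("construct_id", "ligand_id", "experiment_id", "log_conc",
                 "specific_binding"),
    numeric = c("log_conc", "specific_binding")),
  expression = list(
    required = c("construct_id", "expression_fraction", "sem"),
    numeric = c("expression_fraction", "sem")))

#' Read and validate an input table
#'
#' Reads one of the three tabular inputs (comma-separated, UTF-8, `.`
#' decimal) and validates it against its schema. A missing required column
#' is a schema error naming the column. Row-level problems (negative
#' concentrations in response tables — zero is the basal well and is kept —
#' non-finite responses, non-positive expression fractions) do not abort:
#' offending rows are removed from the returned table and listed, with
#' reasons, in the validation report. Values are never silently altered.
#'
#' @param path CSV path.
#' @param schema One of `"response"`, `"binding"`, `"expression"`.
#' @return A tibble of valid rows with the report in
#'   `attr(, "validation_report")` (tibble `row`, `reason`).
#' @export
read_table <- function(path, schema = c("response", "binding",
                                        "expression")) {
  schema <- match.arg(schema)
  sc <- table_schemas[[schema]]
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(sc$required, names(x))
  if (length(missing) > 0) {
    stop("schema error: missing column(s) ", paste(missing,
                                                   collapse = ", "),
         " in ", schema, " table")
  }
  for (col in sc$numeric) {
    if (!is.numeric(x[[col]])) {
      stop("schema error: column '", col, "' does not parse as numeric")
    }
  }
  validate_rows(x, schema)
}

validate_rows <- function(x, schema) {
  bad <- character(nrow(x))
  if (schema == "response") {
    bad[!is.finite(x$response)] <- "non-finite response"
    bad[is.na(x$concentration) | x$concentration < 0] <-
      "negative concentration in non-basal row"
  } else if (schema == "binding") {
    bad[!is.finite(x$specific_binding)] <- "non-finite specific_binding"
    bad[!is.finite(x$log_conc)] <- "non-finite log_conc"
  } else if (schema == "expression") {
    nd <- if ("status" %in% names(x)) x$status == "not_determined"
          else rep(FALSE, nrow(x))
    bad[!nd & (!is.finite(x$expression_fraction) |
                 x$expression_fraction <= 0)] <-
      "non-positive expression fraction (use status not_determined)"
  }
  flagged <- which(bad != "")
  report <- tibble::tibble(row = flagged, reason = bad[flagged])
  out <- if (length(flagged) > 0) x[-flagged, ] else x
  attr(out, "validation_report") <- report
  out
}

#' Write a results table
#'
#' Writes any result tibble as CSV with full numeric precision, so that
#' `read(write(x))` round-trips numeric fields to better than 1e-9
#' relative error. Factor columns are written as their labels.
#'
#' @param x A data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  x <- as.data.frame(x)
  for (c in names(x)) if (is.factor(x[[c]])) x[[c]] <- as.character(x[[c]])
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}
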