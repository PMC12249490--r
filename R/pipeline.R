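# Dataset-level fitting pipelines tying enrichment extraction, de-biasing
# and the kinetic fits together.

.check_timecourse_columns <- function(data, require_neh = FALSE) {
  required <- c("protein_id", "peptide_sequence", "time_days", "i0")
  if (require_neh) required <- c(required, "n_eh")
  missing <- setdiff(required, names(data))
  if (length(missing))
    stop(sprintf("missing required column(s) %s; found: %s",
                 paste(missing, collapse = ", "),
                 paste(names(data), collapse = ", ")))
  invisible(TRUE)
}

#' Fit turnover rates for every peptide in a dataset
#'
#' Runs the classical pipeline (monoisotopic-RA decay fit per peptide),
#' the proposed pipeline (enrichment extraction, per-timepoint N_EH
#' de-biasing, N_EH-scaled fit), or both, over a long time-course table.
#'
#' @param data Long table with columns `protein_id`, `peptide_sequence`,
#'   `time_days`, `i0`, `n_eh` (and optionally `i0_natural`). If `n_eh` is
#'   absent it is computed from `peptide_sequence` with
#'   [compute_neh()] and `residue_table`.
#' @param params A [labeling_parameters()] object.
#' @param model `"classical"`, `"proposed"`, or `"both"`.
#' @param scope De-biasing scope for the proposed pipeline
#'   (see [debias_dataset()]).
#' @param extraction_mode Enrichment extraction mode
#'   (see [extract_enrichment()]).
#' @param reference I0(0) reference: `"observed"` (0-day measurement,
#'   default) or `"theoretical"` (`i0_natural` column).
#' @param residue_table Residue N_EH table used when `n_eh` is missing.
#' @param min_timepoints Minimum observations per peptide fit.
#' @param debias Apply the per-timepoint N_EH de-biasing before the
#'   N_EH-scaled fit (default `TRUE`; the proposed pipeline's step 1).
#' @return A list of class `fit_result`: `peptides` (one row per peptide:
#'   ids, `n_eh`, and per requested model `k_*`, `k_stderr_*`,
#'   `converged_*`, `status_*`) and `debias_audit` (per-timepoint
#'   regression audit, `NULL` for `model = "classical"`).
#' @export
fit_dataset <- function(data, params,
                        model = c("both", "classical", "proposed"),
                        scope = "protein",
                        extraction_mode = "verbatim",
                        reference = "observed",
                        residue_table = default_residue_table(),
                        min_timepoints = 4,
                        debias = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(params, "labeling_parameters"))
  .check_timecourse_columns(data)
  if (is.null(data$n_eh))
    data$n_eh <- compute_neh(data$peptide_sequence, table = residue_table)

  data <- add_enrichment(data, p_h = params$p_h, mode = extraction_mode,
                         reference = reference)
  audit <- NULL
  if (model %in% c("proposed", "both")) {
    if (debias) {
      db <- debias_dataset(data, scope = scope)
      data <- db$data
      audit <- db$regressions
    } else {
      data$px_adjusted <- data$px
    }
  }

  key <- paste(data$protein_id, data$peptide_sequence, sep = "\r")
  rows <- lapply(split(seq_len(nrow(data)), key), function(idx) {
    d <- data[idx, , drop = FALSE]
    d <- d[order(d$time_days), , drop = FALSE]
    out <- data.frame(protein_id = d$protein_id[1],
                      peptide_sequence = d$peptide_sequence[1],
                      n_eh = d$n_eh[1], stringsAsFactors = FALSE)
    if (model %in% c("classical", "both")) {
      f <- fit_classical_ra(d$time_days, d$i0, d$i0_reference[1], d$n_eh[1],
                            params, min_timepoints = min_timepoints)
      out$k_classical <- f$k; out$k_stderr_classical <- f$k_stderr
      out$converged_classical <- f$converged; out$status_classical <- f$status
    }
    if (model %in% c("proposed", "both")) {
      f <- fit_adjusted(d$time_days, d$px_adjusted, d$n_eh[1],
                        params, min_timepoints = min_timepoints)
      out$k_adjusted <- f$k; out$k_stderr_adjusted <- f$k_stderr
      out$converged_adjusted <- f$converged; out$status_adjusted <- f$status
    }
    out
  })
  peptides <- do.call(rbind, rows)
  peptides <- peptides[order(peptides$protein_id, peptides$peptide_sequence), ,
                       drop = FALSE]
  rownames(peptides) <- NULL
  structure(list(peptides = peptides, debias_audit = audit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit result: %d peptides", nrow(x$peptides)))
  if (!is.null(x$peptides$k_classical))
    cat(sprintf(", classical converged %d", sum(x$peptides$converged_classical)))
  if (!is.null(x$peptides$k_adjusted))
    cat(sprintf(", adjusted converged %d", sum(x$peptides$converged_adjusted)))
  cat("\n")
  invisible(x)
}
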