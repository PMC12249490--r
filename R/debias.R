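# Per-timepoint de-biasing of excess enrichment against N_EH: regress
# p_X(t) on N_EH at each labeling duration and remove the linear component
# while preserving the residual error.

#' Per-timepoint regression of enrichment on N_EH
#'
#' Ordinary least-squares regression of p_X values on N_EH at a single
#' labeling duration, with the slope's standard error, two-sided t-test
#' p-value and 95% confidence interval. This is the diagnostic (and first
#' step of the correction) for N_EH-dependent bias in the enrichment.
#'
#' @param px_values Excess enrichments at one timepoint (one per peptide).
#' @param neh_values Matching N_EH values.
#' @param time The labeling duration (days), carried into the result.
#' @param scope `"per_protein"` or `"global"` (annotation only).
#' @return An object of class `neh_regression`: `time`, `slope`,
#'   `intercept`, `slope_stderr`, `slope_ci95` (length-2), `p_value`,
#'   `n_peptides`, `neh_mean`, `scope`, `estimable`. When all N_EH are
#'   identical the regression is not estimable and `estimable` is `FALSE`.
#' @export
fit_neh_regression <- function(px_values, neh_values, time = NA_real_,
                               scope = c("per_protein", "global")) {
  scope <- match.arg(scope)
  stopifnot(length(px_values) == length(neh_values))
  ok <- is.finite(px_values) & is.finite(neh_values)
  px <- px_values[ok]; neh <- neh_values[ok]
  n <- length(px)
  base <- structure(list(time = time, slope = NA_real_, intercept = NA_real_,
                         slope_stderr = NA_real_,
                         slope_ci95 = c(NA_real_, NA_real_),
                         p_value = NA_real_, n_peptides = n,
                         neh_mean = if (n) mean(neh) else NA_real_,
                         scope = scope, estimable = FALSE),
                    class = "neh_regression")
  if (n < 3) return(base)
  if (length(unique(neh)) < 2) return(base)  # NotEstimable: no N_EH contrast
  fit <- stats::lm(px ~ neh)
  # a residual-free fit (noiseless simulated data) is a legitimate state,
  # not a modeling problem worth a warning per regression group
  sm <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  slope <- sm["neh", "Estimate"]
  se <- sm["neh", "Std. Error"]
  tcrit <- stats::qt(0.975, df = n - 2)
  base$slope <- slope
  base$intercept <- sm["(Intercept)", "Estimate"]
  base$slope_stderr <- se
  base$slope_ci95 <- c(slope - tcrit * se, slope + tcrit * se)
  base$p_value <- sm["neh", "Pr(>|t|)"]
  base$estimable <- TRUE
  base
}

#' @export
print.neh_regression <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("N_EH regression (t = %g d): not estimable (n = %d)\n",
                x$time, x$n_peptides))
  } else {
    cat(sprintf(
      "N_EH regression (t = %g d, %s): slope = %.3g (se %.2g, 95%% CI [%.3g, %.3g], p = %.3g), intercept = %.3g, n = %d\n",
      x$time, x$scope, x$slope, x$slope_stderr,
      x$slope_ci95[1], x$slope_ci95[2], x$p_value, x$intercept, x$n_peptides))
  }
  invisible(x)
}

#' Remove the N_EH-dependent component from enrichment values
#'
#' Subtracts the fitted linear N_EH component about the regression
#' centroid: `px - slope * (neh - neh_mean)`. Residuals (the original
#' model error) are preserved, the per-timepoint mean enrichment is
#' unchanged, and refitting the regression on the adjusted values yields a
#' zero slope to machine precision. With `anchor = "intercept"` the full
#' `slope * neh` term is subtracted instead (shifts the level; provided
#' for comparison only).
#'
#' @param px_values Enrichments to adjust.
#' @param neh_values Matching N_EH values.
#' @param regression An `neh_regression` fitted on the same (or a
#'   configured reference) peptide set. If not estimable, values are
#'   returned unchanged with a warning.
#' @param anchor `"centroid"` (default, mean-preserving) or `"intercept"`.
#' @return Adjusted enrichment values.
#' @export
adjust_enrichment <- function(px_values, neh_values, regression,
                              anchor = c("centroid", "intercept")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(regression, "neh_regression"),
            length(px_values) == length(neh_values))
  if (!isTRUE(regression$estimable)) {
    warning("N_EH regression not estimable; enrichment values returned unchanged")
    return(px_values)
  }
  center <- if (anchor == "centroid") regression$neh_mean else 0
  px_values - regression$slope * (neh_values - center)
}

#' De-bias a whole dataset's enrichments against N_EH
#'
#' At every labeling duration, fits the p_X-on-N_EH regression within each
#' group (all peptides of one protein, or the whole dataset) and removes
#' the linear component via [adjust_enrichment()]. Groups with fewer than
#' `min_group` peptides (or without N_EH contrast) at a timepoint are
#' passed through unchanged with a warning.
#'
#' @param data A long table with columns `protein_id`, `peptide_sequence`,
#'   `time_days`, `n_eh` and `px` (see [add_enrichment()]).
#' @param scope `"protein"`: one regression per (protein, timepoint), as in
#'   single-protein analyses; `"global"`: one regression per timepoint over
#'   all peptides, for proteome-wide runs.
#' @param min_group Minimum peptides per regression group (default 3).
#' @param anchor Passed to [adjust_enrichment()].
#' @return A list of class `debias_result`: `data` (input with column
#'   `px_adjusted` added) and `regressions` (audit data frame with one row
#'   per timepoint x group: time, scope, group, slope, stderr, ci_low,
#'   ci_high, p_value, n, estimable).
#' @export
debias_dataset <- function(data, scope = c("protein", "global"),
                           min_group = 3, anchor = "centroid") {
  scope <- match.arg(scope)
  .check_timecourse_columns(data, require_neh = TRUE)
  if (is.null(data$px)) stop("`data` must carry a `px` column; see add_enrichment()")
  grp <- if (scope == "protein") as.character(data$protein_id) else "all"
  key <- paste(data$time_days, grp, sep = "\r")
  data$px_adjusted <- data$px
  audits <- list()
  skipped <- 0L
  reg_scope <- if (scope == "protein") "per_protein" else "global"
  for (idx in split(seq_len(nrow(data)), key)) {
    t_i <- data$time_days[idx[1]]
    g_i <- grp[idx[1]]
    reg <- fit_neh_regression(data$px[idx], data$n_eh[idx],
                              time = t_i, scope = reg_scope)
    if (reg$estimable && reg$n_peptides >= min_group) {
      data$px_adjusted[idx] <- adjust_enrichment(data$px[idx], data$n_eh[idx],
                                                 reg, anchor = anchor)
    } else {
      skipped <- skipped + 1L
    }
    audits[[length(audits) + 1L]] <- data.frame(
      time = t_i, scope = reg_scope, group = g_i,
      slope = reg$slope, stderr = reg$slope_stderr,
      ci_low = reg$slope_ci95[1], ci_high = reg$slope_ci95[2],
      p_value = reg$p_value, n = reg$n_peptides,
      estimable = reg$estimable, stringsAsFactors = FALSE)
  }
  if (skipped > 0)
    warning(sprintf("%d regression group(s) too small or without N_EH contrast; values passed through", skipped))
  audit <- do.call(rbind, audits)
  audit <- audit[order(audit$time, audit$group), , drop = FALSE]
  rownames(audit) <- NULL
  structure(list(data = data, regressions = audit), class = "debias_result")
}

#' @export
print.debias_result <- function(x, ...) {
  est <- x$regressions[x$regressions$estimable, , drop = FALSE]
  cat(sprintf("de-biased dataset: %d rows, %d per-timepoint regressions (%d estimable)\n",
              nrow(x$data), nrow(x$regressions), nrow(est)))
  if (nrow(est))
    cat(sprintf("  |slope| range %.3g .. %.3g\n",
                min(abs(est$slope)), max(abs(est$slope))))
  invisible(x)
}

#' Write the de-biasing audit trail
#'
#' @param x A `debias_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_debias_audit <- function(x, path) {
  stopifnot(inherits(x, "debias_result"))
  out <- x$regressions
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
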