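# Protein-level aggregation of peptide kinetic fits and comparison
# statistics between the classical and N_EH-scaled pipelines.

#' Summarize a protein's peptide turnover rates
#'
#' Aggregates converged peptide-level kinetic fits of one protein into
#' protein-level statistics: mean, median and sample standard deviation
#' (n - 1 denominator) of the turnover rates.
#'
#' @param fits Either a list of `kinetic_fit` objects or a data frame with
#'   columns `k` and `converged` (and optionally `peptide`, `n_eh`).
#' @param protein_id Protein identifier carried into the summary.
#' @param n_eh Optional N_EH values matching `fits` when `fits` is a list.
#' @return An object of class `protein_summary`: `protein_id`,
#'   `n_peptides` (count of converged fits), `k_mean`, `k_median`, `k_sd`,
#'   `model`, `single_peptide` flag, and `per_peptide` (data frame of the
#'   converged peptides' `peptide`, `k`, `n_eh`). Zero converged fits yield
#'   a non-summarizable result (`n_peptides = 0`, statistics `NA`).
#' @export
summarize_protein <- function(fits, protein_id = NA_character_, n_eh = NULL) {
  if (is.data.frame(fits)) {
    df <- fits
    # exact-name access: `$` on data frames partial-matches (e.g. `peptide`
    # against `peptide_sequence`)
    if (is.null(df[["converged"]])) df$converged <- TRUE
    if (is.null(df[["peptide"]]))
      df$peptide <- if (!is.null(df[["peptide_sequence"]])) df[["peptide_sequence"]]
                    else paste0("pep", seq_len(nrow(df)))
    if (is.null(df[["n_eh"]])) df$n_eh <- NA_real_
    model <- if (!is.null(df[["model"]]) && nrow(df)) df[["model"]][1] else NA_character_
  } else {
    stopifnot(all(vapply(fits, inherits, logical(1), "kinetic_fit")))
    df <- data.frame(
      peptide = paste0("pep", seq_along(fits)),
      k = vapply(fits, `[[`, numeric(1), "k"),
      converged = vapply(fits, `[[`, logical(1), "converged"),
      n_eh = if (is.null(n_eh)) NA_real_ else n_eh,
      stringsAsFactors = FALSE)
    model <- if (length(fits)) fits[[1]]$model else NA_character_
  }
  conv <- df[isTRUE_vec(df[["converged"]]) & is.finite(df[["k"]]), , drop = FALSE]
  n <- nrow(conv)
  structure(list(
    protein_id = protein_id,
    n_peptides = n,
    k_mean = if (n) mean(conv$k) else NA_real_,
    k_median = if (n) stats::median(conv$k) else NA_real_,
    k_sd = if (n >= 2) stats::sd(conv$k) else if (n == 1) 0 else NA_real_,
    model = model,
    single_peptide = n == 1,
    per_peptide = conv[, c("peptide", "k", "n_eh"), drop = FALSE]
  ), class = "protein_summary")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.protein_summary <- function(x, ...) {
  if (x$n_peptides == 0) {
    cat(sprintf("protein %s: no converged peptide fits\n", x$protein_id))
  } else {
    cat(sprintf("protein %s [%s]: n = %d peptides, k mean %.4g, median %.4g, sd %.3g%s\n",
                x$protein_id, x$model, x$n_peptides, x$k_mean, x$k_median, x$k_sd,
                if (x$single_peptide) " (single peptide; sd not informative)" else ""))
  }
  invisible(x)
}

#' Regression of peptide turnover rates on N_EH
#'
#' Tests whether a protein's peptide-level turnover rates depend on the
#' number of exchangeable hydrogens — the diagnostic of residual N_EH bias
#' (an unbiased method should give a slope indistinguishable from zero).
#'
#' @param summary A `protein_summary` (with `n_eh` in `per_peptide`), or a
#'   data frame with columns `k` and `n_eh`.
#' @return An `neh_regression` of k on N_EH (see [fit_neh_regression()]).
#' @export
slope_test_k_vs_neh <- function(summary) {
  df <- if (inherits(summary, "protein_summary")) summary$per_peptide else summary
  stopifnot(is.data.frame(df), !is.null(df$k), !is.null(df$n_eh))
  fit_neh_regression(df$k, df$n_eh, time = NA_real_)
}

#' Compare turnover-rate dispersion between two pipelines
#'
#' For one protein quantified by both the classical (existing) and the
#' N_EH-scaled (proposed) pipeline, reports the two standard deviations of
#' peptide turnover rates and their relative difference
#' `(sd_existing - sd_proposed) / sd_existing` (positive when the proposed
#' pipeline is less dispersed).
#'
#' @param existing `protein_summary` from the classical pipeline.
#' @param proposed `protein_summary` from the proposed pipeline.
#' @return An object of class `method_comparison`: `protein_id`,
#'   `sd_existing`, `sd_proposed`, `relative_difference` (`NA` with a
#'   `degenerate` flag when `sd_existing` is 0).
#' @export
compare_methods <- function(existing, proposed) {
  stopifnot(inherits(existing, "protein_summary"),
            inherits(proposed, "protein_summary"))
  if (!identical(existing$protein_id, proposed$protein_id))
    stop("summaries refer to different proteins: ",
         existing$protein_id, " vs ", proposed$protein_id)
  if (existing$n_peptides == 0 || proposed$n_peptides == 0)
    stop("both summaries must contain converged fits")
  degenerate <- !is.na(existing$k_sd) && existing$k_sd == 0
  structure(list(
    protein_id = existing$protein_id,
    sd_existing = existing$k_sd,
    sd_proposed = proposed$k_sd,
    relative_difference = if (degenerate) NA_real_
                          else (existing$k_sd - proposed$k_sd) / existing$k_sd,
    degenerate = degenerate
  ), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("protein %s: sd existing %.4g, proposed %.4g, relative difference %s\n",
              x$protein_id, x$sd_existing, x$sd_proposed,
              if (x$degenerate) "undefined (sd_existing = 0)"
              else sprintf("%.3f", x$relative_difference)))
  invisible(x)
}

#' Two-condition comparison of peptide turnover rates
#'
#' Two-sample t-test on the peptide-level turnover rates of one protein
#' measured under two conditions (e.g. two tissues). Welch's unequal
#' variance test by default; set `var_equal = TRUE` for the pooled
#' (Student) variant.
#'
#' @param rates_a,rates_b Numeric vectors of peptide turnover rates
#'   (day^-1), at least 2 values each.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return A list: `t_statistic`, `p_value`, `df`, `mean_a`, `mean_b`,
#'   `sd_a`, `sd_b`, `method`.
#' @export
two_condition_test <- function(rates_a, rates_b, var_equal = FALSE) {
  rates_a <- rates_a[is.finite(rates_a)]
  rates_b <- rates_b[is.finite(rates_b)]
  if (length(rates_a) < 2 || length(rates_b) < 2)
    stop("not estimable: each group needs at least 2 finite rates")
  if (stats::sd(rates_a) == 0 && stats::sd(rates_b) == 0) {
    # degenerate but well-defined limits: identical groups -> no difference
    same <- mean(rates_a) == mean(rates_b)
    return(list(t_statistic = if (same) 0 else Inf * sign(mean(rates_a) - mean(rates_b)),
                p_value = if (same) 1 else 0,
                df = length(rates_a) + length(rates_b) - 2,
                mean_a = mean(rates_a), mean_b = mean(rates_b),
                sd_a = 0, sd_b = 0,
                method = if (var_equal) "student" else "welch"))
  }
  ht <- stats::t.test(rates_a, rates_b, var.equal = var_equal)
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter),
       mean_a = mean(rates_a), mean_b = mean(rates_b),
       sd_a = stats::sd(rates_a), sd_b = stats::sd(rates_b),
       method = if (var_equal) "student" else "welch")
}

#' Protein summary table across a fitted dataset
#'
#' Convenience: builds one `protein_summary` per protein from a peptide
#' fit table and returns a flat data frame (one row per protein) suitable
#' for export.
#'
#' @param fits Data frame with columns `protein_id`, `peptide`, `k`,
#'   `converged`, `n_eh`.
#' @return Data frame: `protein_id`, `n_peptides`, `k_mean`, `k_median`,
#'   `k_sd`, `slope_vs_neh`, `slope_p`.
#' @export
summarize_proteins <- function(fits) {
  stopifnot(is.data.frame(fits), !is.null(fits$protein_id))
  rows <- lapply(split(fits, fits$protein_id), function(df) {
    s <- summarize_protein(df, protein_id = df$protein_id[1])
    reg <- if (s$n_peptides >= 3) slope_test_k_vs_neh(s) else NULL
    data.frame(protein_id = s$protein_id, n_peptides = s$n_peptides,
               k_mean = s$k_mean, k_median = s$k_median, k_sd = s$k_sd,
               slope_vs_neh = if (!is.null(reg)) reg$slope else NA_real_,
               slope_p = if (!is.null(reg)) reg$p_value else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
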