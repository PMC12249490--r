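# Conversion between monoisotopic relative abundance I0(t) and excess
# deuterium enrichment p_X(t).

#' Excess deuterium enrichment from monoisotopic relative abundance
#'
#' Inverts the depletion of the monoisotopic relative abundance to recover
#' the excess deuterium enrichment p_X(t) of a peptide with `n_eh`
#' exchangeable hydrogens. Two modes are provided:
#'
#' * `"verbatim"` (default): `p_X = (1 - p_h) * (1 - (i0_t/i0_0)^(1/n_eh))`,
#'   the form conventionally used in heavy-water turnover software.
#' * `"exact_inversion"`: `p_X = 1 - (1 - p_h) * (i0_t/i0_0)^(1/n_eh)`,
#'   the exact algebraic inverse of [predict_monoisotope()].
#'
#' The two differ by at most `p_h` (about 1e-4), which matters only when
#' machine-precision roundtrips are required.
#'
#' Non-positive `i0_t` values are treated as missing observations and
#' returned as `NA` (with a warning), not as errors, so that batch
#' processing continues. Values of `i0_t` exceeding `i0_0` (possible under
#' measurement noise) yield slightly negative enrichments, which are
#' deliberately retained: clipping them would bias downstream per-timepoint
#' regressions near t = 0. Pass `clip = TRUE` to clamp at 0.
#'
#' @param i0_t Observed monoisotopic relative abundance at labeling time t.
#' @param i0_0 Reference (unlabeled) monoisotopic relative abundance, > 0.
#' @param n_eh Number of exchangeable hydrogens, > 0. Recycled against
#'   `i0_t`.
#' @param p_h Natural deuterium abundance.
#' @param mode `"verbatim"` or `"exact_inversion"`.
#' @param clip If `TRUE`, negative enrichments are clamped to 0.
#' @return Numeric vector of excess enrichments.
#' @seealso [predict_monoisotope()]
#' @export
extract_enrichment <- function(i0_t, i0_0, n_eh,
                               p_h = natural_deuterium_abundance(),
                               mode = c("verbatim", "exact_inversion"),
                               clip = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(i0_0) == 1L || length(i0_0) == length(i0_t))
  if (any(i0_0 <= 0)) stop("`i0_0` must be positive")
  if (any(n_eh <= 0)) stop("`n_eh` must be positive")
  missing_obs <- !is.na(i0_t) & i0_t <= 0
  if (any(missing_obs)) {
    warning(sprintf("%d non-positive i0 value(s) flagged as missing", sum(missing_obs)))
    i0_t[missing_obs] <- NA_real_
  }
  root <- (i0_t / i0_0)^(1 / n_eh)
  px <- switch(mode,
               verbatim = (1 - p_h) * (1 - root),
               exact_inversion = 1 - (1 - p_h) * root)
  if (clip) px <- pmax(px, 0)
  px
}

#' Predicted monoisotopic relative abundance at a given enrichment
#'
#' Forward model for the monoisotopic relative abundance of a peptide whose
#' exchangeable hydrogens are enriched in deuterium to excess level `p_x`:
#' `I0 = i0_0 * ((1 - p_x) / (1 - p_h))^n_eh`.
#'
#' @param p_x Excess deuterium enrichment (< 1).
#' @param n_eh Number of exchangeable hydrogens, > 0.
#' @param p_h Natural deuterium abundance.
#' @param i0_0 Natural (unlabeled) monoisotopic relative abundance.
#' @return Numeric vector of predicted monoisotopic relative abundances.
#' @seealso [extract_enrichment()]
#' @export
predict_monoisotope <- function(p_x, n_eh, p_h = natural_deuterium_abundance(),
                                i0_0 = 1) {
  if (any(p_x >= 1, na.rm = TRUE)) stop("`p_x` must be < 1")
  if (any(n_eh <= 0)) stop("`n_eh` must be positive")
  i0_0 * ((1 - p_x) / (1 - p_h))^n_eh
}

#' Enrichment time series for a whole dataset
#'
#' Adds a `px` column to a long peptide time-course table by extracting
#' excess enrichment per row. The per-peptide reference `i0_0` is the
#' observed 0-day measurement by default, or the `i0_natural` column when
#' `reference = "theoretical"`.
#'
#' @param data A time-course table as returned by
#'   [read_timecourse_table()] or [simulate_dataset()]: columns
#'   `protein_id`, `peptide_sequence`, `time_days`, `i0`, `n_eh`, and
#'   (for `reference = "theoretical"`) `i0_natural`.
#' @param p_h Natural deuterium abundance.
#' @param mode Extraction mode, see [extract_enrichment()].
#' @param reference `"observed"` (0-day measurement, default) or
#'   `"theoretical"` (`i0_natural` column).
#' @return The input data frame with columns `i0_reference` and `px` added.
#' @export
add_enrichment <- function(data, p_h = natural_deuterium_abundance(),
                           mode = c("verbatim", "exact_inversion"),
                           reference = c("observed", "theoretical")) {
  mode <- match.arg(mode)
  reference <- match.arg(reference)
  .check_timecourse_columns(data, require_neh = TRUE)
  key <- paste(data$protein_id, data$peptide_sequence, sep = "\r")
  ref <- if (reference == "theoretical") {
    if (is.null(data$i0_natural))
      stop("reference = \"theoretical\" needs an `i0_natural` column")
    data$i0_natural
  } else {
    ref_by_pep <- vapply(split(seq_len(nrow(data)), key), function(i) {
      at0 <- i[data$time_days[i] == min(data$time_days[i])]
      mean(data$i0[at0], na.rm = TRUE)
    }, numeric(1))
    unname(ref_by_pep[key])
  }
  data$i0_reference <- ref
  data$px <- extract_enrichment(data$i0, ref, data$n_eh, p_h = p_h, mode = mode)
  data
}
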