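# Kinetic models for heavy-water labeling: classical monoisotopic-RA decay,
# classical enrichment growth, and the N_EH-scaled reformulation, plus the
# analytic half-life diagnostics.

#' Labeling parameters
#'
#' Bundles the precursor-pool (body water) deuterium enrichment `p_w` and
#' the natural deuterium abundance `p_h`.
#'
#' @param p_w Body-water enrichment in deuterium, a fraction in (0, 0.1)
#'   (typically 0.02-0.05 in rodent experiments).
#' @param p_h Natural deuterium abundance, `0 <= p_h < p_w`.
#' @return An object of class `labeling_parameters`.
#' @export
labeling_parameters <- function(p_w, p_h = natural_deuterium_abundance()) {
  stopifnot(is.numeric(p_w), length(p_w) == 1L, is.numeric(p_h), length(p_h) == 1L)
  if (!(p_w > 0 && p_w < 0.1)) stop("`p_w` must lie in (0, 0.1)")
  if (!(p_h >= 0 && p_h < p_w)) stop("`p_h` must satisfy 0 <= p_h < p_w")
  structure(list(p_w = p_w, p_h = p_h), class = "labeling_parameters")
}

#' @export
print.labeling_parameters <- function(x, ...) {
  cat(sprintf("labeling parameters: p_w = %g, p_h = %g\n", x$p_w, x$p_h))
  invisible(x)
}

#' Plateau monoisotopic relative abundance under classical kinetics
#'
#' The asymptotic monoisotopic relative abundance reached at labeling
#' equilibrium: `i0_0 * ((1 - p_w) / (1 - p_h))^n_eh`. Non-zero because the
#' body-water enrichment is far below 1.
#'
#' @param i0_0 Natural monoisotopic relative abundance.
#' @param params A [labeling_parameters()] object.
#' @param n_eh Number of exchangeable hydrogens.
#' @return The plateau relative abundance (vectorized over `n_eh`/`i0_0`).
#' @export
asymptote_classical <- function(i0_0, params, n_eh) {
  stopifnot(inherits(params, "labeling_parameters"))
  i0_0 * ((1 - params$p_w) / (1 - params$p_h))^n_eh
}

# --- kinetic_fit container -------------------------------------------------

new_kinetic_fit <- function(k, model, p_w_used, n_points,
                            k_stderr = NA_real_, residual_sse = NA_real_,
                            converged = FALSE, status = "ok") {
  structure(list(
    k = k, model = model,
    k_stderr = k_stderr, residual_sse = residual_sse,
    n_points = n_points, converged = converged,
    p_w_used = p_w_used,
    half_life = if (is.finite(k) && k > 0) log(2) / k else NA_real_,
    status = status
  ), class = "kinetic_fit")
}

not_fittable <- function(model, p_w_used, n_points, status) {
  new_kinetic_fit(NA_real_, model, p_w_used, n_points,
                  converged = FALSE, status = status)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("kinetic fit [%s]: ", x$model))
  if (isTRUE(x$converged)) {
    cat(sprintf("k = %.5g /day (se %.3g), t1/2 = %.4g d, n = %d, SSE = %.3g\n",
                x$k, x$k_stderr, x$half_life, x$n_points, x$residual_sse))
  } else {
    cat(sprintf("not fitted (%s), n = %d\n", x$status, x$n_points))
  }
  invisible(x)
}

# One-parameter bounded exponential-approach fit: y ~ A + (1 - A) exp(-k t)
# with A known. Initial k from a log-linear regression through the interior
# points; stats::nls(port) with an optimize() fallback on the 1-D SSE.
fit_transformed <- function(times, y, A, model, p_w_used,
                            min_timepoints = 4, k_bounds = c(1e-6, 10)) {
  ok <- is.finite(times) & is.finite(y)
  times <- times[ok]; y <- y[ok]
  n <- length(y)
  if (n < min_timepoints)
    return(not_fittable(model, p_w_used, n, "insufficient_points"))
  if (abs(1 - A) < 1e-12)
    return(not_fittable(model, p_w_used, n, "degenerate_asymptote"))

  z <- (y - A) / (1 - A)
  interior <- which(times > 0 & z > 1e-8 & z < 1)
  k0 <- if (length(interior) >= 2) {
    slope <- sum(times[interior] * (-log(z[interior]))) / sum(times[interior]^2)
    min(max(slope, k_bounds[1] * 2), k_bounds[2] / 2)
  } else {
    tpos <- times[times > 0]
    if (length(tpos)) min(max(1 / stats::median(tpos), k_bounds[1] * 2), k_bounds[2] / 2)
    else sqrt(prod(k_bounds))
  }

  pred <- function(k) A + (1 - A) * exp(-k * times)
  sse <- function(k) sum((y - pred(k))^2)

  k_hat <- NA_real_
  fit <- tryCatch(
    stats::nls(y ~ A + (1 - A) * exp(-k * times),
               start = list(k = k0), algorithm = "port",
               lower = k_bounds[1], upper = k_bounds[2],
               control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                            minFactor = 1e-12,
                                            warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) k_hat <- stats::coef(fit)[["k"]]
  # refine (or recover) with golden-section search on the 1-D SSE
  opt <- stats::optimize(sse, lower = k_bounds[1], upper = k_bounds[2],
                         tol = .Machine$double.eps^0.5)
  if (!is.finite(k_hat) || opt$objective < sse(k_hat) - 1e-18) k_hat <- opt$minimum
  # local polish around the current optimum
  lo <- max(k_bounds[1], k_hat * 0.8); hi <- min(k_bounds[2], k_hat * 1.25)
  if (hi > lo) {
    opt2 <- stats::optimize(sse, lower = lo, upper = hi,
                            tol = .Machine$double.eps^0.6)
    if (opt2$objective <= sse(k_hat)) k_hat <- opt2$minimum
  }

  rss <- sse(k_hat)
  grad <- (1 - A) * (-times) * exp(-k_hat * times)
  jtj <- sum(grad^2)
  k_se <- if (jtj > 0 && n > 1) sqrt(rss / (n - 1) / jtj) else NaN
  at_bound <- k_hat <= k_bounds[1] * (1 + 1e-6) || k_hat >= k_bounds[2] * (1 - 1e-6)
  new_kinetic_fit(k_hat, model, p_w_used, n,
                  k_stderr = k_se, residual_sse = rss,
                  converged = !at_bound,
                  status = if (at_bound) "k_at_bound" else "ok")
}

#' Fit the classical monoisotopic-RA decay model
#'
#' Fits the single-exponential depletion of the monoisotopic relative
#' abundance, `I0(t) = I0_asymp + (I0(0) - I0_asymp) exp(-k t)`, with the
#' plateau `I0_asymp` fixed by [asymptote_classical()]. The fit is performed
#' on `I0(t) / i0_reference`, making it invariant to uniform rescaling of
#' the abundances.
#'
#' @param times Labeling durations in days.
#' @param i0_values Observed monoisotopic relative abundances.
#' @param i0_reference The reference I0(0) used for normalization and the
#'   plateau.
#' @param n_eh Number of exchangeable hydrogens of the peptide.
#' @param params A [labeling_parameters()] object.
#' @param min_timepoints Minimum number of valid observations (default 4);
#'   fewer yields a non-fittable result, not an error.
#' @param k_bounds Search bounds for the rate, day^-1.
#' @return A `kinetic_fit` object with elements `k` (day^-1), `k_stderr`,
#'   `residual_sse` (in normalized-abundance space), `n_points`,
#'   `converged`, `p_w_used`, `half_life` (`log(2)/k`), `status`.
#' @export
fit_classical_ra <- function(times, i0_values, i0_reference, n_eh, params,
                             min_timepoints = 4, k_bounds = c(1e-6, 10)) {
  stopifnot(inherits(params, "labeling_parameters"),
            length(times) == length(i0_values), i0_reference > 0, n_eh > 0)
  A <- ((1 - params$p_w) / (1 - params$p_h))^n_eh
  fit_transformed(times, i0_values / i0_reference, A,
                  model = "classical_ra", p_w_used = params$p_w,
                  min_timepoints = min_timepoints, k_bounds = k_bounds)
}

#' Fit the classical enrichment-growth model
#'
#' Fits the excess-enrichment form of the classical kinetics: the
#' transformed observable `((1 - p_X(t)) / (1 - p_h))^n_eh` is fitted to
#' `A + (1 - A) exp(-k t)` with `A = ((1 - p_w) / (1 - p_h))^n_eh`.
#' Algebraically equivalent to [fit_classical_ra()] (identical k on exact
#' data).
#'
#' @param times Labeling durations in days.
#' @param px_values Excess deuterium enrichments p_X(t).
#' @param n_eh Number of exchangeable hydrogens of the peptide.
#' @inheritParams fit_classical_ra
#' @return A `kinetic_fit` object (model `"classical_px"`).
#' @export
fit_classical_px <- function(times, px_values, n_eh, params,
                             min_timepoints = 4, k_bounds = c(1e-6, 10)) {
  stopifnot(inherits(params, "labeling_parameters"),
            length(times) == length(px_values), n_eh > 0)
  y <- ((1 - px_values) / (1 - params$p_h))^n_eh
  A <- ((1 - params$p_w) / (1 - params$p_h))^n_eh
  fit_transformed(times, y, A,
                  model = "classical_px", p_w_used = params$p_w,
                  min_timepoints = min_timepoints, k_bounds = k_bounds)
}

#' Fit the N_EH-scaled kinetic model
#'
#' The reformulated kinetics in which the enrichment enters scaled by the
#' number of exchangeable hydrogens: the observable
#' `((1 - p_X(t)/n_eh) / (1 - p_h))^n_eh` is fitted to
#' `A' + (1 - A') exp(-k t)` with
#' `A' = ((1 - p_w/n_eh) / (1 - p_h))^n_eh`. Because the leading N_EH
#' dependence cancels, the fitted rate is practically independent of N_EH
#' whenever `n_eh * p_w^2 << 1` (satisfied for all peptides in practice).
#'
#' @param times Labeling durations in days.
#' @param px_values Excess deuterium enrichments (raw or de-biased).
#' @param n_eh Number of exchangeable hydrogens of the peptide.
#' @inheritParams fit_classical_ra
#' @return A `kinetic_fit` object (model `"adjusted_px"`).
#' @export
fit_adjusted <- function(times, px_values, n_eh, params,
                         min_timepoints = 4, k_bounds = c(1e-6, 10)) {
  stopifnot(inherits(params, "labeling_parameters"),
            length(times) == length(px_values), n_eh > 0)
  y <- ((1 - px_values / n_eh) / (1 - params$p_h))^n_eh
  A <- ((1 - params$p_w / n_eh) / (1 - params$p_h))^n_eh
  fit_transformed(times, y, A,
                  model = "adjusted_px", p_w_used = params$p_w,
                  min_timepoints = min_timepoints, k_bounds = k_bounds)
}

#' Half-life diagnostic ratio of the classical model
#'
#' The normalized excess of the monoisotopic RA over its plateau, evaluated
#' at the protein half-life under the classical model with enrichment
#' `p_w/2`. If the model were free of N_EH dependence this ratio would be
#' exactly 1/2 for every (`n_eh`, `p_w`); its drift with `n_eh` quantifies
#' the N_EH bias of the classical formulation.
#'
#' @param n_eh Number of exchangeable hydrogens (vectorized).
#' @param params A [labeling_parameters()] object. Note: the commonly
#'   quoted numeric values of this ratio (e.g. 0.43 at `n_eh = 15`,
#'   `p_w = 0.04`) correspond to `p_h = 0`.
#' @return The ratio, in (0, 1).
#' @export
half_life_ratio_classical <- function(n_eh, params) {
  stopifnot(inherits(params, "labeling_parameters"))
  p_w <- params$p_w; p_h <- params$p_h
  half <- ((1 - p_w / 2) / (1 - p_h))^n_eh
  plateau <- ((1 - p_w) / (1 - p_h))^n_eh
  denom <- 1 - plateau
  if (any(abs(denom) < 1e-14))
    stop("ratio undefined: p_w equals p_h (no labeling contrast)")
  (half - plateau) / denom
}

#' Half-life diagnostic ratio of the N_EH-scaled model
#'
#' Analogue of [half_life_ratio_classical()] for the reformulated kinetics
#' (enrichment scaled by `n_eh`). Practically independent of `n_eh` and
#' close to 1/2 for realistic parameters.
#'
#' @inheritParams half_life_ratio_classical
#' @return The ratio, close to 1/2.
#' @export
half_life_ratio_adjusted <- function(n_eh, params) {
  stopifnot(inherits(params, "labeling_parameters"))
  p_w <- params$p_w; p_h <- params$p_h
  half <- ((1 - p_w / (2 * n_eh)) / (1 - p_h))^n_eh
  plateau <- ((1 - p_w / n_eh) / (1 - p_h))^n_eh
  denom <- 1 - plateau
  if (any(abs(denom) < 1e-14))
    stop("ratio undefined: p_w equals p_h (no labeling contrast)")
  (half - plateau) / denom
}

#' Fractional synthesis from monoisotopic relative abundances
#'
#' The proportion of newly synthesized protein implied by an observed
#' monoisotopic RA: `f = 1 - (i0_t - i0_asymp) / (i0_0 - i0_asymp)`, so
#' that `f = 0` before labeling and `f = 1` at the plateau. Under
#' first-order kinetics `f(t) = 1 - exp(-k t)`.
#'
#' @param i0_t Observed monoisotopic RA.
#' @param i0_0 Unlabeled (natural) monoisotopic RA.
#' @param i0_asymp Plateau monoisotopic RA (see [asymptote_classical()]).
#' @return The newly synthesized fraction (the old-protein fraction is
#'   `1 -` the returned value).
#' @export
fractional_synthesis <- function(i0_t, i0_0, i0_asymp) {
  if (any(abs(i0_0 - i0_asymp) < 1e-14))
    stop("degenerate: i0_0 equals i0_asymp (no labeling contrast)")
  1 - (i0_t - i0_asymp) / (i0_0 - i0_asymp)
}

#' First-order (Taylor-limit) enrichment curve
#'
#' The small-enrichment limit of the labeling kinetics, in which the excess
#' deuterium enrichment is independent of N_EH:
#' `p_X(t) = p_w * (1 - exp(-k t))`. Valid to first order whenever
#' `n_eh * p_w^2 << 1` for the N_EH-scaled model (up to N_EH of several
#' hundred), but only when `n_eh * p_w << 1` for the classical model.
#'
#' @param p_w Body-water enrichment.
#' @param k Turnover rate, day^-1.
#' @param t Labeling duration(s), days.
#' @return Enrichment values in `[0, p_w)`.
#' @export
taylor_limit_enrichment <- function(p_w, k, t) {
  stopifnot(k > 0, all(t >= 0))
  p_w * (1 - exp(-k * t))
}
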