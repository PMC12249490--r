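---
title: "Turnover kinetics from heavy-water labeling and the exchangeable-hydrogen bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turnover kinetics from heavy-water labeling and the exchangeable-hydrogen bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deuteRate)
```

## The model

`deuteRate` estimates first-order protein turnover rates k (day⁻¹) from
heavy-water labeling time courses of peptide monoisotopic relative
abundance (RA). The one-pool model assumes: (i) protein replacement is
first order, so the fraction of newly synthesized molecules is
f(t) = 1 − e^(−kt); (ii) the precursor pool equilibrates fast relative to
protein turnover, so the body-water enrichment p_W is a known constant
over the experiment; (iii) each of a peptide's N_EH exchangeable hydrogen
sites is deuterated independently with probability p_W in new molecules.
Under these assumptions the monoisotopic RA decays as

$$I_0(t) = I_0^{asymp} + (I_0(0) - I_0^{asymp})\,e^{-kt}, \qquad
  I_0^{asymp} = I_0(0)\Big(\frac{1-p_W}{1-p_H}\Big)^{N_{EH}},$$

and the excess enrichment extracted per timepoint is
$p_X(t) = (1-p_H)\,(1 - (I_0(t)/I_0(0))^{1/N_{EH}})$.

### Why the classical estimate depends on N_EH

Turnover is a protein property: all peptides of a protein should report
the same k, and the enrichment p_X(t) should likewise be peptide
independent. But the classical observable raises (1 − p_X) to the power
N_EH, and the exponential-decay form is only the first-order expansion of
that power — accurate when N_EH·p_W ≪ 1. At rodent enrichment levels
(p_W ≈ 0.03–0.05) and N_EH up to 60, N_EH·p_W reaches 2–3 and the
truncation error becomes an N_EH-dependent rate bias. A closed-form
diagnostic is the normalized RA excess at the half-life
(`half_life_ratio_classical`), which would equal 1/2 for an unbiased
model but drifts with N_EH:

```{r ratios}
p04 <- labeling_parameters(p_w = 0.04, p_h = 0)
half_life_ratio_classical(c(15, 25), p04)
half_life_ratio_adjusted(c(15, 25), p04)
```

### The N_EH-scaled model

The package's corrected estimator replaces p_X(t) by p_X(t)/N_EH inside
the kinetic equation (`fit_adjusted`):

$$\Big(\frac{1-p_X(t)/N_{EH}}{1-p_H}\Big)^{N_{EH}}
  = A' + (1-A')e^{-kt}, \qquad
  A' = \Big(\frac{1-p_W/N_{EH}}{1-p_H}\Big)^{N_{EH}}.$$

Expanding each power to first order yields
p_X(t) = p_W(1 − e^(−kt)) with no N_EH dependence; the expansion is valid
when N_EH·p_W² ≪ 1, which holds to N_EH ≈ 400 — i.e. for every real
peptide. The residual second-order deviation of the model-implied
enrichment from p_W(1 − e^(−kt)) is bounded by p_W²/8 (attained near
f = 1/2), which the test suite checks on a grid up to N_EH = 400.

### Step 1: per-timepoint de-biasing

Real data show an additional, noise-amplified linear trend of extracted
p_X(t) against N_EH. `debias_dataset` removes it without touching the raw
RA values: at each labeling duration, p_X is regressed on N_EH by
ordinary least squares within a group (all peptides of one protein, or
the whole dataset), and the fitted linear component is subtracted
*about the regression centroid*:

$$p_{X,adj,i} = p_{X,i} - \hat\beta\,(N_{EH,i} - \bar N_{EH}).$$

Anchoring at the centroid (rather than subtracting β·N_EH outright) is a
deliberate choice: it preserves the per-timepoint mean enrichment and the
individual residuals, so late-time adjusted p_X still sits at the
body-water enrichment level and the correction is idempotent — refitting
the regression on adjusted values returns a slope of zero to machine
precision. An intercept-anchored variant is available behind the
`anchor` argument for comparison. The unlabeled (0-day) timepoint is
included without special-casing; its slope is expected to be ≈ 0. The
regression is plain unweighted OLS; robust or weighted variants are out
of scope, as outlier handling belongs upstream.

## Numerical conventions

**Fit space.** All three fits (`fit_classical_ra`, `fit_classical_px`,
`fit_adjusted`) minimize least squares in the transformed observable
written above — the N_EH-power expressions — not in p_X space, and the RA
fit normalizes by the reference I₀(0) first, which makes all fits
invariant to uniform rescaling of the abundances. On exact data the RA
and enrichment forms of the classical fit are algebraically identical
objectives, and the test suite requires agreement to 10⁻⁶ relative in k
(achieved at ~10⁻¹⁵). That equivalence requires extracting p_X with the
`exact_inversion` mode: the conventional ("verbatim") extraction formula
is not the exact algebraic inverse of the forward model — the two differ
by O(p_H) — so with verbatim extraction the two fits can differ by
O(N_EH·p_H) relative in k, ~0.6% at N_EH = 60. Both modes are
implemented; verbatim is the default for fidelity to field practice, and
negative enrichments from noisy I₀(t) > I₀(0) are retained (not clipped)
so that the per-timepoint regressions see unbiased noise.

**The p_H convention.** The natural deuterium abundance
(p_H = 1.15·10⁻⁴) matters in two places with very different weight:

* In the *chemistry* (natural monoisotopic abundance of a composition),
  where it is used at its physical value.
* Inside the *kinetic equations*, where the (1 − p_H)^(−N_EH)
  factors are cosmetic for the classical observable (relative effect
  N_EH·p_H ≈ 0.7% against a dynamic range of order 1) but **not** for the
  N_EH-scaled observable, whose dynamic range is only ~p_W: carrying
  p_H = 1.15·10⁻⁴ verbatim creates a t = 0 model-vs-data offset of
  N_EH·p_H (0.007 at N_EH = 60) — a double-digit percentage rate bias.
  The printed reference values of the half-life ratios (0.43/0.38,
  0.48/0.47, 0.4953/0.4952) are reproducible *only* with p_H = 0, which
  identifies the convention in actual use: when rates are fitted from the
  measured ratio I₀(t)/I₀(0), natural deuterium is already absorbed in
  the reference, and the appropriate in-model value is p_H = 0. The
  packaged benchmark and the acceptance report therefore fit with
  p_H = 0 (the `fit_p_h` argument of `make_benchmark_bias_study`), while
  the simulator still *generates* data at the physical p_H, so the
  realistic mismatch is exercised. Every function still accepts any p_H
  for users who want the verbatim behavior.

**Optimizer.** Each fit is a one-parameter bounded nonlinear least
squares on k ∈ [10⁻⁶, 10] day⁻¹: `stats::nls` (algorithm `"port"`,
loss tolerance 10⁻¹⁰) started from a log-linear regression of
−log((y − A)/(1 − A)) on t through the interior points, followed by a
golden-section polish of the one-dimensional SSE (which also serves as
the fallback when `nls` fails, e.g. on zero-residual data). The standard
error of k comes from the Jacobian-based covariance,
`sqrt(SSE/(n−1)/Σg²)` with g = ∂ŷ/∂k, reported as `NaN` when the
curvature vanishes. Peptides with fewer than 4 valid timepoints
(configurable) return a structured non-fittable result rather than an
error, and a fitted k pinned at a bound (e.g. a constant series at the
plateau) is flagged `k_at_bound` with `converged = FALSE`.

## The simulator: what it emulates and what it does not

`simulate_dataset` emulates peptide-level time-course tables as exported
by isotope-profile quantification software: one row per
peptide-timepoint with I₀, at ten labeling durations 0–21 days. Defaults
(chosen once; see `labeling_design`):

| parameter | default | rationale |
|---|---|---|
| true k | lognormal, median 0.1 day⁻¹, sdlog 0.5 | fast-turnover tissue (liver/kidney) scale |
| N_EH | uniform integers 10–60 | the span observed for tryptic peptides |
| p_W | 0.04 | typical rodent body-water enrichment |
| p_H | 1.15·10⁻⁴ | physical natural abundance (generation only) |
| I₀ noise | additive Gaussian, SD 0.002 | small technical noise on a relative abundance |
| I₀(0) | uniform 0.2–0.7 | natural monoisotopic RA of 800–2500 Da peptides |

Two truth models are provided: `neh_independent_enrichment` treats
enrichment as a protein property, p_X(t) = p_W(1 − e^(−kt)), and maps it
to I₀ through the forward power model; `classical_eq4` makes I₀ itself
single-exponential. Noise is added in observation space (on I₀), matching
the attribution of the empirical bias to instrument-level inaccuracies.
Both a theoretical I₀(0) and the noisy observed 0-day value are emitted;
pipelines default to the noisy observation.

The simulator does **not** emulate raw spectra, isotope-profile
truncation, co-elution, or quantification artifacts. This matters for
interpreting the benchmark:

### Direction of the classical bias

In the simulated `neh_independent_enrichment` world, the classical fit's
N_EH dependence is **positive**: the true I₀(t) decays faster than a
single exponential at early times (convexity of (1 − x)^N), so the
classical estimator overshoots k, increasingly with N_EH:

```{r bias-direction}
p0 <- labeling_parameters(0.04, 0)
tt <- c(0, 0.5, 1, 2, 3, 5, 7, 10.5, 15, 21)
sapply(c(10, 30, 60), function(n_eh) {
  px <- taylor_limit_enrichment(0.04, 0.1, tt)      # true k = 0.1
  i0 <- predict_monoisotope(px, n_eh, 0, 0.4)
  fit_classical_ra(tt, i0, 0.4, n_eh, p0)$k
})
```

This is consistent with the half-life diagnostic (0.43 → 0.38 as N_EH
goes 15 → 25: labeling *appears* further advanced for larger N_EH). In
real murine data, however, the observed trend of both p_X(t) and fitted k
against N_EH is *negative* — a measurement artifact of isotope-profile
quantification that plain additive Gaussian noise does not reproduce (the
Jensen-type extraction bias it does produce is of order σ²/2N_EH,
negligible at realistic noise). A green benchmark therefore establishes
that the pipeline *removes whatever N_EH dependence is present and
recovers the true rates* — not that the simulator reproduces the
empirical sign of the artifact. One acceptance criterion encodes the
empirical (negative) sign and is accordingly expected to fail in this
synthetic world; the package reports the measured slope either way. For
the same reason, the simulated variance-reduction figure (≈ 0.93 mean
relative SD difference at default settings, where the classical
dispersion is dominated by the structural N_EH spread) is larger than
what is observed on real data (≈ 0.5), where part of the dispersion is
N_EH-independent technical error that no N_EH correction can remove.

## Protein-level statistics

`summarize_protein` aggregates converged peptide rates (mean and median
are both reported; the mean is the protein-level rate, the aggregator
being otherwise unspecified in the field). Dispersion uses the sample
(n − 1) SD throughout; a single-peptide protein reports SD 0 with a
flag. `compare_methods` reports
(σ_existing − σ_proposed)/σ_existing, `two_condition_test` defaults to
Welch's unequal-variance t-test (`var_equal = TRUE` for the pooled
variant), and `slope_test_k_vs_neh` reuses the p_X-on-N_EH regression
machinery for fitted rates. Raw p-values are emitted without
multiple-testing correction — proteome-wide users should correct
downstream.

## Known limitations

* One-pool kinetics with known, constant p_W; no two-compartment
  precursor delay, no per-peptide p_W estimation beyond late-timepoint
  plateaus.
* The de-biasing removes only the *linear* N_EH component, by design.
* The N_EH-scaled model is an empirical reformulation, not a mechanistic
  one: its fitted rate inherits the interpretation of the classical k,
  but intermediate quantities (e.g. its half-life ratio) are diagnostic
  constructs.
* N_EH tables are literature values and tissue/organism dependent; the
  packaged table is overridable everywhere.
* General (N_EH-independent) technical error passes through the
  correction untouched.
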