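# deuteRate

Protein turnover rates from deuterated-water (²H₂O) metabolic labeling
time courses, with explicit treatment of the exchangeable-hydrogen bias.

## The problem

In heavy-water labeling experiments, animals drink ²H₂O and deuterium is
incorporated into newly synthesized proteins. For each tryptic peptide,
LC-MS tracks the depletion of the monoisotopic relative abundance (RA),
I₀(t), over labeling durations t, and a first-order rate constant k
(day⁻¹) — the protein turnover rate — is obtained by nonlinear least
squares from

    I₀(t) = I₀^asymp + (I₀(0) − I₀^asymp) · exp(−k t),
    I₀^asymp = I₀(0) · ((1 − p_W) / (1 − p_H))^N_EH,

where p_W is the body-water deuterium enrichment (typically 0.02–0.05),
p_H the natural deuterium abundance, and N_EH the peptide's number of
exchangeable hydrogens (summed over residues from a literature table).
Equivalently, the excess deuterium enrichment extracted from the RA,

    p_X(t) = (1 − p_H) · (1 − (I₀(t)/I₀(0))^(1/N_EH)),

can be fitted to the matching growth model. Although turnover is a
property of the protein, rates estimated this way correlate with the
peptides' N_EH — a systematic artifact that inflates the dispersion of
peptide-level rates within a protein and weakens downstream statistics.

`deuteRate` implements both the classical estimators and a two-step
correction:

1. **De-biasing** — at every labeling duration, ordinary least-squares
   regression of p_X(t) on N_EH; the fitted linear component is removed
   about the regression centroid, preserving the residual error and the
   per-timepoint mean.
2. **N_EH-scaled kinetics** — the enrichment enters the kinetic model
   divided by N_EH:

       ((1 − p_X(t)/N_EH)/(1 − p_H))^N_EH
         = A′ + (1 − A′)·exp(−k t),  A′ = ((1 − p_W/N_EH)/(1 − p_H))^N_EH,

   whose solution is practically independent of N_EH whenever
   N_EH·p_W² ≪ 1 (valid to N_EH ≈ 400, i.e. all real peptides), in
   contrast to the classical model which requires N_EH·p_W ≪ 1.

A diagnostic for the bias is the model's normalized RA excess at the
half-life: it should equal 1/2 for any (N_EH, p_W). Classically it is
0.43 (N_EH = 15) and 0.38 (N_EH = 25) at p_W = 0.04; under the scaled
model it is 0.4953 and 0.4952.

The package also ships a synthetic-data simulator (peptide time-course
tables with configurable truth model and measurement noise), protein-level
aggregation and comparison statistics (SD reduction, two-condition Welch
tests), CSV readers/writers, and a command-line interface.

## Worked example

```r
library(deuteRate)

path <- system.file("extdata", "example_timecourse_synthetic.csv",
                    package = "deuteRate")   # simulated CH60-like peptides
tc <- read_timecourse_table(path)
params <- labeling_parameters(p_w = 0.04, p_h = 0)
fits <- fit_dataset(tc, params, model = "both")
fits$peptides[, c("peptide_sequence", "n_eh", "k_classical", "k_adjusted")]
```

```
       peptide_sequence  n_eh k_classical k_adjusted
1     AAVEEGIVLGGGCALLR 37.11      0.1233     0.0758
2 ALMLQGVDLLADAVAVTMGPK 37.50      0.1297     0.0777
3          TVIIEQSWGSPK 21.15      0.0984     0.0756
4              VGEVIVTK  9.43      0.0847     0.0771
```

The four peptides come from one simulated protein with true
k = 0.075 day⁻¹. The classical rates climb from 0.085 to 0.130 day⁻¹ as
N_EH grows from 9 to 38 — the N_EH artifact; the proposed pipeline
(de-biasing + scaled fit) returns ≈ 0.076 day⁻¹ for all of them.

```r
summarize_proteins(transform(fits$peptides,
                             k = k_adjusted, converged = converged_adjusted))
#   protein_id n_peptides k_mean k_median    k_sd slope_vs_neh slope_p
# 1 CH60_SYNTH          4 0.0765   0.0765 0.00103      3.2e-06   0.958
```

The k-vs-N_EH slope of the adjusted rates is statistically
indistinguishable from zero (p = 0.958). The analytic diagnostics:

```r
p04 <- labeling_parameters(0.04, 0)
half_life_ratio_classical(c(15, 25), p04)   # 0.43, 0.38  (drifts with N_EH)
half_life_ratio_adjusted(c(15, 25), p04)    # 0.4953, 0.4952
```

And the packaged end-to-end benchmark (simulated world where enrichment
is a protein property, plus additive I₀ noise):

```r
study <- make_benchmark_bias_study(
  labeling_design(n_proteins = 10, peptides_per_protein = 12, seed = 42))
study
# bias-reproduction benchmark
#   peptides fitted: 120 (classical), 120 (adjusted)
#   pooled k-vs-N_EH slope, classical: 0.00292 (p = 6.76e-06)
#   pooled k-vs-N_EH slope, adjusted:  -0.000202 (p = 0.604)
#   mean relative SD difference across 10 proteins: 0.936
#   median |k_hat - k|/k: classical 0.642, adjusted 0.014
```

## Command line

```sh
Rscript inst/exec/deuterate simulate --seed 1 --out sim/
Rscript inst/exec/deuterate fit --input sim/observations.csv \
    --pw 0.04 --ph 0 --model both --out fit/
Rscript inst/exec/deuterate adjust --input sim/observations.csv --pw 0.04 --out adj/
Rscript inst/exec/deuterate compare --input fitA/fits.csv --input fitB/fits.csv --out cmp/
Rscript inst/exec/deuterate benchmark --seed 1 --out bench/
```

Flags: `--input, --residue-table, --pw, --ph, --model
{classical|proposed|both}, --scope {protein|global}, --min-timepoints,
--seed, --out, --exact-inversion, --config` (key = value file; explicit
flags win).

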