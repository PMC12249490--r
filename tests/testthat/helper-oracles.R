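# Independent closed-form / brute-force oracles used against the package's
# implementations, plus small dataset builders.

# OLS slope/intercept/stderr/p by the textbook normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tstat <- slope / se
  list(slope = slope, intercept = intercept, stderr = se,
       p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Welch two-sample t statistic and p computed stepwise.
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df = df))
}

# Two-pass textbook sample standard deviation.
sd_oracle <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# x^n by explicit repeated multiplication (integer n).
pow_loop <- function(x, n) {
  out <- 1
  for (i in seq_len(n)) out <- out * x
  out
}

default_times <- function() c(0, 0.5, 1, 2, 3, 5, 7, 10.5, 15, 21)

# Noiseless classical (single-exponential) monoisotopic RA time course.
make_classical_i0 <- function(k, n_eh, params, i0_0 = 0.4,
                              times = default_times()) {
  A <- asymptote_classical(i0_0, params, n_eh)
  A + (i0_0 - A) * exp(-k * times)
}

# Enrichment implied by the N_EH-scaled kinetic model at rate k.
make_eq7_px <- function(k, n_eh, params, times = default_times()) {
  A <- ((1 - params$p_w / n_eh) / (1 - params$p_h))^n_eh
  y <- A + (1 - A) * exp(-k * times)
  n_eh * (1 - (1 - params$p_h) * y^(1 / n_eh))
}

# Small long-format time-course table for io/debias tests.
make_tiny_table <- function() {
  tt <- c(0, 1, 3, 7, 14)
  p <- labeling_parameters(0.04, 0)
  rows <- list()
  for (i in 1:4) {
    n_eh <- c(12, 20, 35, 50)[i]
    i0 <- make_classical_i0(0.15, n_eh, p, i0_0 = 0.5, times = tt)
    rows[[i]] <- data.frame(protein_id = "P1",
                            peptide_sequence = sprintf("PEP%02d", i),
                            time_days = tt, i0 = i0,
                            i0_natural = 0.5, n_eh = n_eh,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
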