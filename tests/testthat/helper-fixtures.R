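# Shared fixture builders; everything is generated in code, nothing stored.

# default titration grid: 7 points, 1.5 nM to 46 uM, geometric
conc7 <- function() exp(seq(log(0.0015), log(46), length.out = 7))

# noise-free screen configuration (all CVs zero, no planted compounds
# unless asked for)
quiet_config <- function(n_compounds = 8, seed = 1, ...) {
  screen_config(n_compounds = n_compounds, dmso_cv = 0, pos_control_cv = 0,
                fraction_true_antagonists = 0, fraction_cytotoxic = 0,
                rng_seed = seed, ...)
}

# a truth table planting one known antagonist among inert compounds
one_antagonist_truth <- function(n = 8, ic50 = 0.2, efficacy = -90,
                                 hill_n = 1.3) {
  data.frame(
    compound_id = sprintf("CMP%05d", seq_len(n)),
    true_ic50 = c(ic50, rep(NA_real_, n - 1)),
    true_efficacy = c(efficacy, rep(0, n - 1)),
    true_hill_n = c(hill_n, rep(1, n - 1)),
    cytotoxic_ic50 = NA_real_,
    cluster_id = "k01", stringsAsFactors = FALSE)
}

# percent-activity series with multiplicative noise applied on the raw
# signal scale, independently of the screen generator (used as an oracle
# path for fit-recovery properties)
noisy_series <- function(conc, ic50, efficacy, hill_n, cv,
                         mu_v = 3540, s_b = 3.54) {
  mu_p <- mu_v / s_b
  a <- efficacy / (1 + (ic50 / conc)^hill_n)
  v <- (mu_p + (mu_v - mu_p) * (1 + a / 100)) * (1 + rnorm(length(conc), 0, cv))
  (v - mu_v) / (mu_v - mu_p) * 100
}

# brute-force one-sided enrichment p: upper hypergeometric tail by direct
# summation over the support
hyper_tail_p <- function(a, cluster_size, lib_active, lib_size) {
  x <- a:min(cluster_size, lib_active)
  sum(dhyper(x, lib_active, lib_size - lib_active, cluster_size))
}
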