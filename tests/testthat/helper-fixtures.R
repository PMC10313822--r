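# Shared fixtures: all synthetic, built in code at test time.

# Asymmetric 150/15 mM KCl with anion:cation permeability p_cl : 1.
kcl_conditions <- function(p_cl = 100, cis = 150, trans = 15) {
  ionic_conditions(
    list(ion_species("K", +1, 1), ion_species("Cl", -1, p_cl)),
    conc_cis = c(cis, cis), conc_trans = c(trans, trans)
  )
}

# Bi-ionic pair: reference anion in cis, test anion in trans, equal charge.
biionic_conditions <- function(test_name, p_test, conc = 150) {
  ionic_conditions(
    list(ion_species("Cl", -1, 1), ion_species(test_name, -1, p_test)),
    conc_cis = c(conc, 0), conc_trans = c(0, conc)
  )
}

# Square trace: piecewise-constant current from (level, duration_ms) pairs,
# sampled at `fs` Hz with no noise and no filtering.
square_trace <- function(levels, durations_ms, fs = 10000) {
  n_per <- round(durations_ms * fs / 1000)
  current <- rep(levels, n_per)
  tm <- (seq_along(current) - 1) * 1000 / fs
  trace(tm, current, metadata = list(sampling_rate = fs, noise_sd = 0))
}

# Amplitude levels object with known parameters, bypassing the EM fit.
fixed_levels <- function(closed, open, sd = 0.05) {
  structure(
    list(means = c(closed, open), sds = c(sd, sd), weights = c(0.5, 0.5),
         se = c(sd, sd) / 100, separation = open - closed,
         loglik = NA_real_, converged = TRUE),
    class = "blm_levels"
  )
}

# Standard short acquisition used across simulator tests.
quick_acq <- function(duration = 1, seed = 1, noise_sd = 0.45) {
  acquisition_params(sampling_rate = 10000, filter_cutoff = 1000,
                     noise_sd = noise_sd, duration = duration, seed = seed)
}
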