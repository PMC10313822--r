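# Seeded generators for everything the analysis pipeline consumes: gated
# current traces, Ca2+ dose-response tables, and SPR sensorgrams.

#' Two-state gating rates
#'
#' Opening and closing rates of a closed <-> open two-state Markov gating
#' scheme. The stationary open probability is `k_open / (k_open + k_close)`
#' and mean dwell times are `1/k_close` (open) and `1/k_open` (closed).
#'
#' @param k_open,k_close Transition rates in s^-1, both >= 0.
#' @return A list of class `gating_params`.
#' @examples
#' gating_params(50, 50) # stationary Po = 0.5, 20 ms mean dwells
#' @export
gating_params <- function(k_open, k_close) {
  if (!is.finite(k_open) || k_open < 0 || !is.finite(k_close) || k_close < 0) {
    stop("gating rates must be finite and non-negative", call. = FALSE)
  }
  structure(list(k_open = k_open, k_close = k_close), class = "gating_params")
}

#' Stationary open probability of a gating scheme
#' @param gating A [gating_params()] object.
#' @return `k_open / (k_open + k_close)`, or 0 when both rates are zero.
#' @export
stationary_po <- function(gating) {
  stopifnot(inherits(gating, "gating_params"))
  if (gating$k_open + gating$k_close == 0) return(0)
  gating$k_open / (gating$k_open + gating$k_close)
}

#' Channel model for trace simulation
#'
#' Combines a linear i-V model, two-state gating rates, a channel count, and
#' optional modulator parameters: luminal Ca2+ inhibition (which scales
#' `k_open` by `1 / (1 + (ca / ic50)^hill)`, reducing Po but leaving the
#' open-level amplitude unchanged) and a PIP2 preset (a discrete alternative
#' (i-V, gating) pair engaged with `use_pip2 = TRUE` in [simulate_trace()]).
#'
#' @param iv A [linear_iv()] object.
#' @param gating A [gating_params()] object.
#' @param n_channels Number of independent channels in the bilayer (>= 1).
#' @param ca_inhibition Optional `list(ic50 = <mM>, hill = <dimensionless>)`.
#' @param pip2_preset Optional `list(iv = <linear_iv>, gating = <gating_params>)`.
#' @return A list of class `channel_model`.
#' @seealso [wt_channel_model()] for the wild-type anion-channel preset.
#' @export
channel_model <- function(iv, gating, n_channels = 1L,
                          ca_inhibition = NULL, pip2_preset = NULL) {
  stopifnot(inherits(iv, "linear_iv"), inherits(gating, "gating_params"))
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1L) {
    stop("n_channels must be a positive integer", call. = FALSE)
  }
  if (!is.null(ca_inhibition)) {
    stopifnot(is.list(ca_inhibition),
              all(c("ic50", "hill") %in% names(ca_inhibition)))
    if (ca_inhibition$ic50 <= 0 || ca_inhibition$hill <= 0) {
      stop("ca_inhibition ic50 and hill must be positive", call. = FALSE)
    }
  }
  if (!is.null(pip2_preset)) {
    stopifnot(is.list(pip2_preset), inherits(pip2_preset$iv, "linear_iv"),
              inherits(pip2_preset$gating, "gating_params"))
  }
  structure(
    list(iv = iv, gating = gating, n_channels = n_channels,
         ca_inhibition = ca_inhibition, pip2_preset = pip2_preset),
    class = "channel_model"
  )
}

#' Wild-type anion-channel simulator preset
#'
#' The default stated world of the simulator: 39.9 pS slope conductance with
#' a +56.8 mV reversal (asymmetric 150/15 mM KCl, anion-selective), symmetric
#' 50/50 s^-1 gating (stationary Po 0.5, 20 ms mean dwells, comfortably above
#' the 1 kHz filter rise time), luminal Ca2+ inhibition with IC50 1.09 mM and
#' Hill slope 1, and a PIP2 preset that raises the conductance to 80.1 pS.
#'
#' @param n_channels Number of independent channels (default 1).
#' @return A [channel_model()].
#' @examples
#' wt_channel_model()
#' @export
wt_channel_model <- function(n_channels = 1L) {
  channel_model(
    iv = linear_iv(39.9, 56.8),
    gating = gating_params(50, 50),
    n_channels = n_channels,
    ca_inhibition = list(ic50 = 1.09, hill = 1),
    pip2_preset = list(iv = linear_iv(80.1, 56.8),
                       gating = gating_params(100, 50))
  )
}

#' Acquisition parameters for trace simulation
#'
#' @param sampling_rate Sampling rate in Hz; must exceed twice the filter
#'   cutoff. Default 10 kHz (10x the 1 kHz recording filter).
#' @param filter_cutoff Low-pass -3 dB cutoff in Hz (default 1000).
#' @param noise_sd Baseline white-noise SD in pA added before filtering.
#'   Default 0.45 pA, i.e. SNR ~ 5 at the 2.27 pA wild-type open level.
#' @param duration Recording duration in seconds.
#' @param seed Integer RNG seed recorded in the trace metadata.
#' @return A list of class `acquisition_params`.
#' @export
acquisition_params <- function(sampling_rate = 10000, filter_cutoff = 1000,
                               noise_sd = 0.45, duration = 10, seed = 1L) {
  if (!is.finite(duration) || duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be non-negative", call. = FALSE)
  }
  if (!is.finite(sampling_rate) || sampling_rate <= 2 * filter_cutoff) {
    stop("sampling_rate must exceed twice the filter cutoff", call. = FALSE)
  }
  structure(
    list(sampling_rate = sampling_rate, filter_cutoff = filter_cutoff,
         noise_sd = noise_sd, duration = duration, seed = as.integer(seed)),
    class = "acquisition_params"
  )
}

#' Construct a current trace
#'
#' @param time_ms Uniform, strictly increasing time grid in ms.
#' @param current_pa Current samples in pA, same length as `time_ms`.
#' @param metadata List of acquisition and provenance metadata; must contain
#'   `sampling_rate` (Hz) or it is inferred from the time grid.
#' @return A list of class `blm_trace` with `time`, `current`, `metadata`.
#' @export
trace <- function(time_ms, current_pa, metadata = list()) {
  stopifnot(is.numeric(time_ms), is.numeric(current_pa))
  if (length(time_ms) != length(current_pa)) {
    stop("time and current must have equal length", call. = FALSE)
  }
  if (length(time_ms) >= 2L) {
    dt <- diff(time_ms)
    if (any(dt <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
    if (diff(range(dt)) > 1e-6 * stats::median(dt)) {
      stop("time grid must be uniform", call. = FALSE)
    }
    if (is.null(metadata$sampling_rate)) {
      metadata$sampling_rate <- 1000 / stats::median(dt)
    }
  }
  structure(list(time = time_ms, current = current_pa, metadata = metadata),
            class = "blm_trace")
}

#' @export
print.blm_trace <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<blm_trace> %d samples, %.3g s at %g Hz\n",
              length(x$time), length(x$time) / md$sampling_rate,
              md$sampling_rate))
  if (!is.null(md$filter_cutoff)) {
    cat(sprintf("  filtered at %g Hz", md$filter_cutoff))
    if (!is.null(md$voltage)) cat(sprintf(", V = %g mV", md$voltage))
    cat("\n")
  }
  invisible(x)
}

# Exact continuous-time sampling of one two-state channel: exponential
# holding times with alternating rates, then state lookup on the sample grid.
# Returns a 0/1 open indicator per sample.
.sim_channel_path <- function(k_open, k_close, t_s) {
  duration <- t_s[length(t_s)]
  if (k_open <= 0) return(integer(length(t_s)))
  if (k_close <= 0) return(rep(1L, length(t_s)))
  p_open <- k_open / (k_open + k_close)
  s0 <- as.integer(stats::runif(1) < p_open)
  change_times <- 0
  total <- 0
  dwells <- numeric(0)
  # grow the dwell sequence in blocks until the recording is covered
  block <- max(64L, ceiling(duration * (k_open + k_close) / 2))
  state_first <- s0
  repeat {
    n_have <- length(dwells)
    first <- if (n_have %% 2L == 0L) state_first else 1L - state_first
    rates <- rep_len(if (first == 1L) c(k_close, k_open) else c(k_open, k_close),
                     block)
    dwells <- c(dwells, stats::rexp(block, rate = rates))
    total <- sum(dwells)
    if (total >= duration) break
  }
  change_times <- c(0, cumsum(dwells))
  states <- rep_len(c(s0, 1L - s0), length(change_times))
  idx <- findInterval(t_s, change_times, rightmost.closed = FALSE)
  states[idx]
}

#' Simulate a gated single- or multi-channel current trace
#'
#' Each channel follows a continuous-time two-state Markov path sampled
#' exactly (exponential holding times); the independent channels are summed,
#' converted to current through the linear i-V model, Gaussian baseline noise
#' is added, and the result is low-pass filtered at the acquisition cutoff.
#' Identical seed and parameters reproduce the trace bit-for-bit.
#'
#' @param model A [channel_model()].
#' @param acq An [acquisition_params()] object (its `seed` drives all
#'   randomness in the call).
#' @param voltage Holding potential in mV.
#' @param luminal_ca Luminal (cis) Ca2+ concentration in mM; with an active
#'   `ca_inhibition` block the effective opening rate is scaled by
#'   `1 / (1 + (ca/ic50)^hill)`.
#' @param use_pip2 Use the model's PIP2 preset (i-V and gating) if present.
#' @param return_states Attach the per-sample open-channel count (pre-noise)
#'   as attribute `"n_open"`; used by oracle tests.
#' @return A [trace()] with full provenance metadata.
#' @examples
#' tr <- simulate_trace(wt_channel_model(),
#'                      acquisition_params(duration = 0.2, seed = 7),
#'                      voltage = 0)
#' @export
simulate_trace <- function(model, acq, voltage, luminal_ca = 0,
                           use_pip2 = FALSE, return_states = FALSE) {
  stopifnot(inherits(model, "channel_model"),
            inherits(acq, "acquisition_params"), is.numeric(voltage))
  iv <- model$iv
  gating <- model$gating
  if (use_pip2) {
    if (is.null(model$pip2_preset)) {
      stop("model has no pip2_preset", call. = FALSE)
    }
    iv <- model$pip2_preset$iv
    gating <- model$pip2_preset$gating
  }
  k_open <- gating$k_open
  if (luminal_ca > 0 && !is.null(model$ca_inhibition)) {
    k_open <- k_open /
      (1 + (luminal_ca / model$ca_inhibition$ic50)^model$ca_inhibition$hill)
  }
  set.seed(acq$seed)
  n <- floor(acq$duration * acq$sampling_rate)
  t_s <- (seq_len(n) - 1L) / acq$sampling_rate
  n_open <- integer(n)
  for (ch in seq_len(model$n_channels)) {
    n_open <- n_open + .sim_channel_path(k_open, gating$k_close, t_s)
  }
  i1 <- linear_iv_current(iv, voltage)
  current <- i1 * n_open
  if (acq$noise_sd > 0) current <- current + stats::rnorm(n, 0, acq$noise_sd)
  current <- .lowpass_bessel4(current, acq$sampling_rate, acq$filter_cutoff)
  md <- list(
    sampling_rate = acq$sampling_rate, filter_cutoff = acq$filter_cutoff,
    noise_sd = acq$noise_sd, duration = acq$duration, seed = acq$seed,
    voltage = voltage, n_channels = model$n_channels,
    conductance = iv$conductance, reversal = iv$reversal,
    k_open = k_open, k_close = gating$k_close, luminal_ca = luminal_ca,
    use_pip2 = use_pip2, unit_current = i1,
    stationary_po = if (k_open + gating$k_close > 0)
      k_open / (k_open + gating$k_close) else 0,
    units = list(time = "ms", current = "pA", voltage = "mV")
  )
  out <- trace(t_s * 1000, current, md)
  if (return_states) attr(out, "n_open") <- n_open
  out
}

#' Simulate square step-like multi-channel currents
#'
#' Superposition of `N >= 2` independent channels: the noiseless level set is
#' `{k * i1 : k = 0..N}` and the instantaneous open count is Binomial(N, Po)
#' at stationarity. Thin wrapper around [simulate_trace()] kept as the
#' documented entry point for multi-channel records.
#'
#' @inheritParams simulate_trace
#' @return A [trace()].
#' @export
simulate_multichannel_steps <- function(model, acq, voltage,
                                        return_states = FALSE) {
  if (model$n_channels < 2L) {
    stop("simulate_multichannel_steps expects n_channels >= 2; ",
         "use simulate_trace for a single channel", call. = FALSE)
  }
  simulate_trace(model, acq, voltage, return_states = return_states)
}

#' Default concentration series
#'
#' `ca_dose_series()` is the package's default Ca2+ dose grid for
#' dose-response generation: 12 log-spaced doses from 0.03 to 30 mM,
#' bracketing the 1-20 mM IC50 range of interest. `spr_conc_series()` is the
#' standard 12-point two-fold SPR analyte series from 9.76 uM to 20 mM.
#'
#' @return Numeric vector of concentrations in mM.
#' @export
ca_dose_series <- function() {
  10^seq(log10(0.03), log10(30), length.out = 12)
}

#' @rdname ca_dose_series
#' @export
spr_conc_series <- function() {
  20 / 2^(11:0)
}

#' Generate a relative-Po dose-response table
#'
#' Draws replicate relative open probabilities (Po after treatment divided by
#' Po before) around the Hill inhibition curve
#' `1 / (1 + (dose / ic50)^hill)`, with additive Gaussian noise truncated
#' at zero.
#'
#' @param ic50 Half-inhibition concentration in mM (> 0).
#' @param hill Hill coefficient (> 0, default 1).
#' @param doses Vector of doses in mM (>= 0); must be non-empty. Defaults to
#'   [ca_dose_series()].
#' @param replicates Replicates per dose (default 6).
#' @param noise_sd SD of the additive noise on the relative-Po scale
#'   (default 0.1, i.e. 10\% of the untreated level).
#' @param seed Optional integer seed.
#' @return A data.frame of class `dose_response` with columns `dose`,
#'   `replicate`, `relative_po`.
#' @examples
#' generate_dose_response(1.09, doses = 10^seq(-1.5, 1.5, 0.5), seed = 1)
#' @export
generate_dose_response <- function(ic50, hill = 1, doses = ca_dose_series(),
                                   replicates = 6L,
                                   noise_sd = 0.1, seed = NULL) {
  if (!is.finite(ic50) || ic50 <= 0) stop("ic50 must be positive", call. = FALSE)
  if (!is.finite(hill) || hill <= 0) stop("hill must be positive", call. = FALSE)
  if (length(doses) == 0L) stop("doses must be non-empty", call. = FALSE)
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates), dose = doses)
  mu <- 1 / (1 + (grid$dose / ic50)^hill)
  y <- mu
  if (noise_sd > 0) y <- pmax(0, mu + stats::rnorm(length(mu), 0, noise_sd))
  out <- data.frame(dose = grid$dose, replicate = grid$replicate,
                    relative_po = y)
  class(out) <- c("dose_response", "data.frame")
  attr(out, "truth") <- list(ic50 = ic50, hill = hill, noise_sd = noise_sd)
  out
}

#' Simulate a 1:1 Langmuir SPR sensorgram
#'
#' Association phase `R(t) = R_eq (1 - exp(-(ka C + kd) t))` with
#' `R_eq = C Rmax / (C + kd/ka)`, followed by dissociation
#' `R(t) = R(t_assoc) exp(-kd (t - t_assoc))`. Default phase lengths are
#' 90 s each, matching a Biacore protocol with 90 s association and 90 s
#' dissociation.
#'
#' @param ka Association rate constant in mM^-1 s^-1 (> 0).
#' @param kd Dissociation rate constant in s^-1 (> 0).
#' @param rmax Saturating response in RU (> 0).
#' @param conc Analyte concentration in mM (>= 0; 0 yields a flat record).
#' @param t_assoc,t_dissoc Phase durations in s (defaults 90 and 90).
#' @param noise_sd Additive Gaussian noise SD in RU.
#' @param seed Optional integer seed.
#' @param sampling_rate Samples per second (default 10).
#' @return A list of class `blm_sensorgram` with `time` (s), `response` (RU),
#'   `analyte_conc` (mM) and `t_assoc` (s).
#' @examples
#' sg <- simulate_sensorgram(ka = 0.0125, kd = 0.1, rmax = 100, conc = 8)
#' @export
simulate_sensorgram <- function(ka, kd, rmax, conc, t_assoc = 90,
                                t_dissoc = 90, noise_sd = 0, seed = NULL,
                                sampling_rate = 10) {
  if (!is.finite(ka) || ka <= 0 || !is.finite(kd) || kd <= 0 ||
      !is.finite(rmax) || rmax <= 0) {
    stop("kinetic parameters ka, kd, rmax must all be positive", call. = FALSE)
  }
  if (conc < 0) stop("analyte concentration must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, t_assoc + t_dissoc, by = 1 / sampling_rate)
  r <- langmuir_response(t, ka, kd, rmax, conc, t_assoc)
  if (noise_sd > 0) r <- r + stats::rnorm(length(r), 0, noise_sd)
  structure(
    list(time = t, response = r, analyte_conc = conc, t_assoc = t_assoc,
         truth = list(ka = ka, kd = kd, rmax = rmax, noise_sd = noise_sd)),
    class = "blm_sensorgram"
  )
}

# Noiseless 1:1 Langmuir response; shared by the simulator and the kinetic
# fitting routine so the model is defined in exactly one place.
langmuir_response <- function(t, ka, kd, rmax, conc, t_assoc) {
  req <- conc * rmax / (conc + kd / ka)
  rate <- ka * conc + kd
  r_end <- req * (1 - exp(-rate * t_assoc))
  ifelse(t <= t_assoc,
         req * (1 - exp(-rate * t)),
         r_end * exp(-kd * (t - t_assoc)))
}
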