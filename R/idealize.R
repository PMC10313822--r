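# Reduction of a raw trace to amplitude levels, idealized events, open
# probability and dwell-time statistics.

# Weighted EM for a 1-D Gaussian mixture on binned data. Operating on the
# all-points histogram keeps the fit O(bins) per iteration regardless of
# trace length.
.gmm_em_binned <- function(x, w, k, max_iter = 500, tol = 1e-10) {
  sd_floor <- max(diff(range(x)) / length(x), 1e-6)
  # init: histogram peak-picking on lightly smoothed counts; quantile
  # fallback when fewer than k separated peaks exist
  sm <- stats::filter(w, rep(1 / 11, 11), sides = 2)
  sm[is.na(sm)] <- 0
  peaks <- which(diff(sign(diff(c(-Inf, sm, -Inf)))) < 0)
  peaks <- peaks[order(sm[peaks], decreasing = TRUE)]
  # greedy pick with an exclusion zone so all k starts sit in distinct modes
  min_sep <- diff(range(x)) / (3 * k)
  chosen <- numeric(0)
  for (p in peaks) {
    if (all(abs(x[p] - chosen) > min_sep)) chosen <- c(chosen, x[p])
    if (length(chosen) == k) break
  }
  if (length(chosen) == k) {
    mu <- sort(chosen)
  } else {
    cdf <- cumsum(w) / sum(w)
    mu <- vapply((seq_len(k) - 0.5) / k,
                 function(q) x[which.min(abs(cdf - q))], numeric(1))
    mu <- sort(mu)
  }
  sigma <- rep(max(sd_floor, if (k > 1) min(diff(mu)) / 4 else
    diff(range(x)) / 4), k)
  pi_k <- rep(1 / k, k)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) pi_k[j] * stats::dnorm(x, mu[j], sigma[j]),
                   numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    resp <- dens / tot
    nk <- colSums(w * resp)
    nk[nk < 1e-12] <- 1e-12
    mu <- colSums(w * resp * x) / nk
    sigma <- sqrt(pmax(
      colSums(w * resp * (outer(x, mu, "-"))^2) / nk, sd_floor^2))
    pi_k <- nk / sum(w)
    ll <- sum(w * log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(means = mu, sds = sigma, weights = pi_k, n_eff = nk,
       loglik = ll, converged = converged)
}

#' Fit amplitude levels to the all-points histogram
#'
#' Gaussian-mixture fit of the all-points current histogram, the standard way
#' to estimate single-channel amplitudes ("fitting to Gaussian functions").
#' The fit runs a deterministic EM on the binned histogram, initialised by
#' histogram peak-picking, so identical traces always give identical levels.
#'
#' The closed level is taken as the component mean closest to 0 pA (baseline
#' drift beyond a constant offset is out of scope); remaining levels are
#' sorted by absolute deviation from it.
#'
#' @param trace A [trace()] object.
#' @param n_levels Number of mixture components (>= 2).
#' @param n_bins Number of histogram bins (default 512).
#' @return A list of class `blm_levels`: `means`, `sds`, `weights` (summing
#'   to 1), `se` (standard errors of the means), `separation` (open minus
#'   closed mean), `converged`.
#' @examples
#' tr <- simulate_trace(wt_channel_model(),
#'                      acquisition_params(duration = 1, seed = 2), voltage = 0)
#' fit_amplitude_levels(tr, 2)
#' @export
fit_amplitude_levels <- function(trace, n_levels = 2L, n_bins = 512L) {
  stopifnot(inherits(trace, "blm_trace"))
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be >= 2", call. = FALSE)
  x <- trace$current
  if (length(x) < 100L * n_levels) {
    stop("trace too short for a ", n_levels, "-level fit (need >= ",
         100L * n_levels, " samples)", call. = FALSE)
  }
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-1, 1) * 1e-6
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  fit <- .gmm_em_binned(h$mids, h$counts, n_levels)
  if (!fit$converged) {
    # single-level data makes overlapping components drift without the
    # log-likelihood settling; report the merged levels with a warning
    if (diff(range(fit$means)) < max(fit$sds)) {
      warning("degenerate data: the ", n_levels,
              " requested levels merged into one; means nearly coincide",
              call. = FALSE)
    } else {
      stop("amplitude-level EM did not converge (log-likelihood ",
           format(fit$loglik), ")", call. = FALSE)
    }
  }
  # order: closed level (mean nearest 0) first, then by |deviation|
  closed_idx <- which.min(abs(fit$means))
  ord <- order(abs(fit$means - fit$means[closed_idx]))
  means <- fit$means[ord]
  sds <- fit$sds[ord]
  weights <- fit$weights[ord]
  n_eff <- fit$n_eff[ord]
  separation <- means[2] - means[1]
  if (abs(separation) < 2 * max(sds)) {
    warning("amplitude levels poorly separated (|separation| = ",
            format(abs(separation), digits = 3), " pA < 2 SD); ",
            "levels may be merged", call. = FALSE)
  }
  structure(
    list(means = means, sds = sds, weights = weights,
         se = sds / sqrt(pmax(n_eff, 1)), separation = separation,
         loglik = fit$loglik, converged = fit$converged),
    class = "blm_levels"
  )
}

#' @export
print.blm_levels <- function(x, ...) {
  cat("<blm_levels>\n")
  df <- data.frame(mean_pA = round(x$means, 4), sd_pA = round(x$sds, 4),
                   weight = round(x$weights, 4))
  rownames(df) <- c("closed", paste0("open", seq_len(nrow(df) - 1L)))
  print(df)
  invisible(x)
}

#' Construct an event list by hand
#'
#' Mainly for tests and for reading event tables back from disk: builds the
#' contiguous open/closed interval representation that [open_probability()]
#' and [dwell_summary()] consume.
#'
#' @param states Character vector, each `"open"` or `"closed"`.
#' @param durations_ms Event durations in ms, same length as `states`.
#' @param min_duration_applied Minimum open duration that was enforced (ms).
#' @param sample_period_ms Sample period of the source trace (ms).
#' @return A data.frame of class `event_list` with `state`, `start_ms`,
#'   `duration_ms` and attributes `total_time_ms`, `min_duration_applied`.
#' @export
event_list <- function(states, durations_ms, min_duration_applied = 0,
                       sample_period_ms = NA_real_) {
  stopifnot(length(states) == length(durations_ms),
            all(states %in% c("open", "closed")), all(durations_ms > 0))
  starts <- if (length(durations_ms)) {
    cumsum(c(0, durations_ms[-length(durations_ms)]))
  } else {
    numeric(0)
  }
  out <- data.frame(
    state = states,
    start_ms = starts,
    duration_ms = durations_ms,
    stringsAsFactors = FALSE
  )
  class(out) <- c("event_list", "data.frame")
  attr(out, "total_time_ms") <- sum(durations_ms)
  attr(out, "min_duration_applied") <- min_duration_applied
  attr(out, "sample_period_ms") <- sample_period_ms
  out
}

#' Half-amplitude threshold idealization
#'
#' Converts a trace into contiguous open/closed events by thresholding at the
#' midpoint between the closed and open level means. Open events shorter than
#' `min_open_ms` are ignored (merged into the flanking closed state), per the
#' convention that opening times below 0.5-1.0 ms are discarded; closed gaps
#' are deliberately not filtered.
#'
#' @param trace A [trace()] object.
#' @param levels A [fit_amplitude_levels()] result (closed level first).
#' @param min_open_ms Minimum accepted open duration in ms. Default 0.5, the
#'   lower bound of the conventional 0.5-1.0 ms range; values outside that
#'   range are allowed with a warning.
#' @return An [event_list()] spanning the full trace.
#' @examples
#' tr <- simulate_trace(wt_channel_model(),
#'                      acquisition_params(duration = 1, seed = 3), voltage = 0)
#' lv <- fit_amplitude_levels(tr, 2)
#' ev <- idealize_half_amplitude(tr, lv)
#' open_probability(ev)
#' @export
idealize_half_amplitude <- function(trace, levels, min_open_ms = 0.5) {
  stopifnot(inherits(trace, "blm_trace"), inherits(levels, "blm_levels"))
  if (min_open_ms < 0.5 || min_open_ms > 1.0) {
    warning("min_open_ms = ", min_open_ms,
            " ms is outside the conventional 0.5-1.0 ms range", call. = FALSE)
  }
  closed <- levels$means[1]
  open <- levels$means[2]
  if (abs(open - closed) < 2 * max(levels$sds)) {
    stop("levels unresolved: |separation| = ",
         format(abs(open - closed), digits = 3), " pA is below 2 x max SD (",
         format(2 * max(levels$sds), digits = 3),
         " pA); refusing to idealize", call. = FALSE)
  }
  thr <- (closed + open) / 2
  is_open <- if (open > closed) trace$current >= thr else trace$current <= thr
  dt_ms <- 1000 / trace$metadata$sampling_rate
  r <- rle(is_open)
  short <- r$values & (r$lengths * dt_ms < min_open_ms)
  if (any(short)) {
    r$values[short] <- FALSE
    is_open <- inverse.rle(r)
    r <- rle(is_open)
  }
  event_list(
    states = ifelse(r$values, "open", "closed"),
    durations_ms = r$lengths * dt_ms,
    min_duration_applied = min_open_ms,
    sample_period_ms = dt_ms
  )
}

#' Open probability from an event list
#'
#' `Po = t / T`: total open time divided by total recording time.
#'
#' @param events An [event_list()].
#' @return Open probability in `[0, 1]`.
#' @export
open_probability <- function(events) {
  stopifnot(inherits(events, "event_list"))
  if (nrow(events) == 0L) stop("empty event list", call. = FALSE)
  total <- attr(events, "total_time_ms")
  if (!is.finite(total) || total <= 0) {
    stop("total recording time must be positive", call. = FALSE)
  }
  sum(events$duration_ms[events$state == "open"]) / total
}

#' Dwell-time summary
#'
#' Arithmetic mean dwell times and event counts per state. A state with no
#' events has its mean reported as `NA` (undefined), not zero.
#'
#' @param events An [event_list()].
#' @return A list with `mean_open_ms`, `mean_closed_ms`, `n_open`, `n_closed`.
#' @export
dwell_summary <- function(events) {
  stopifnot(inherits(events, "event_list"))
  open_d <- events$duration_ms[events$state == "open"]
  closed_d <- events$duration_ms[events$state == "closed"]
  list(
    mean_open_ms = if (length(open_d)) mean(open_d) else NA_real_,
    mean_closed_ms = if (length(closed_d)) mean(closed_d) else NA_real_,
    n_open = length(open_d),
    n_closed = length(closed_d)
  )
}
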