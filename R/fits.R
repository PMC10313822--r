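# Parameter-estimation layer: i-V lines, Hill IC50 inhibition, and 1:1
# Langmuir binding (steady-state and kinetic).

#' Generic fit-result container
#'
#' @param parameters Named numeric vector of estimates.
#' @param se Named numeric vector of standard errors (same names), or `NULL`;
#'   standard errors are only attached when the fit converged.
#' @param units Named character vector of units per parameter.
#' @param residual_norm Euclidean norm of the residuals.
#' @param converged Logical convergence flag.
#' @param n Number of data points used.
#' @param method Short description of the fitting method.
#' @param details Optional list of extra metadata (starting points, modes).
#' @return A list of class `fit_result`.
#' @export
fit_result <- function(parameters, se = NULL, units = NULL,
                       residual_norm = NA_real_, converged = TRUE,
                       n = NA_integer_, method = "", details = list()) {
  stopifnot(is.numeric(parameters), !is.null(names(parameters)))
  if (!converged) se <- NULL
  structure(
    list(parameters = parameters, se = se, units = units,
         residual_norm = residual_norm, converged = converged,
         n = as.integer(n), method = method, details = details),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$method, "\n")
  for (p in names(x$parameters)) {
    cat(sprintf("  %-8s %12.6g", p, x$parameters[[p]]))
    if (!is.null(x$se) && p %in% names(x$se)) {
      cat(sprintf(" +/- %.3g", x$se[[p]]))
    }
    if (!is.null(x$units) && p %in% names(x$units)) cat(" ", x$units[[p]])
    cat("\n")
  }
  cat(sprintf("  n = %d, residual norm = %.4g, converged = %s\n",
              x$n, x$residual_norm, x$converged))
  invisible(x)
}

# Multi-start weighted least squares on an unconstrained parameterisation
# (callers log-transform positive parameters). model_fn(theta) returns fitted
# values for the full dataset. Standard errors come from the Gauss-Newton
# approximation sigma^2 (J' W J)^-1 with a central-difference Jacobian.
.ls_multistart <- function(y, model_fn, starts, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(y))
  obj <- function(theta) {
    f <- model_fn(theta)
    if (any(!is.finite(f))) return(1e300)
    sum(weights * (y - f)^2)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best)) stop("all fit starts failed", call. = FALSE)
  theta <- best$par
  p <- length(theta)
  n <- length(y)
  eps <- pmax(abs(theta), 1) * 1e-6
  jac <- vapply(seq_len(p), function(j) {
    up <- theta; up[j] <- up[j] + eps[j]
    dn <- theta; dn[j] <- dn[j] - eps[j]
    (model_fn(up) - model_fn(dn)) / (2 * eps[j])
  }, numeric(n))
  rss <- best$value
  sigma2 <- if (n > p) rss / (n - p) else 0
  jtj <- crossprod(jac * sqrt(weights))
  se <- tryCatch(sqrt(pmax(diag(sigma2 * solve(jtj)), 0)),
                 error = function(e) rep(NA_real_, p))
  names(se) <- names(theta)
  list(theta = theta, se = se, rss = rss, n = n,
       converged = best$convergence == 0)
}

#' Fit a linear current-voltage relationship
#'
#' Weighted least-squares line `i = g (V - E_rev)` through single-channel
#' amplitudes. The slope in pA/mV equals the conductance in nS, so `g` in pS
#' is 1000 x slope; `E_rev = -intercept/slope`, with its standard error
#' propagated by the delta method from the coefficient covariance.
#'
#' @param data A data.frame with columns `voltage` (mV), `amplitude` (pA) and
#'   optionally `uncertainty` (pA SD, used as inverse-variance weights).
#' @return A [fit_result()] with parameters `g` (pS) and `E_rev` (mV).
#' @examples
#' v <- c(-60, -30, 0, 30, 60, 90)
#' d <- data.frame(voltage = v,
#'                 amplitude = linear_iv_current(linear_iv(39.9, 56.8), v))
#' fit_iv(d)
#' @export
fit_iv <- function(data) {
  stopifnot(is.data.frame(data), all(c("voltage", "amplitude") %in% names(data)))
  if (length(unique(data$voltage)) < 2L) {
    stop("need >= 2 distinct voltages to fit an i-V line", call. = FALSE)
  }
  w <- if ("uncertainty" %in% names(data) && all(data$uncertainty > 0)) {
    1 / data$uncertainty^2
  } else {
    NULL
  }
  fit <- stats::lm(amplitude ~ voltage, data = data, weights = w)
  cf <- stats::coef(fit)
  a <- cf[["voltage"]]    # slope, pA/mV = nS
  b <- cf[["(Intercept)"]]
  if (!is.finite(a) || a == 0) {
    stop("degenerate i-V data: zero or undefined slope", call. = FALSE)
  }
  vc <- stats::vcov(fit)
  g <- 1000 * a
  e_rev <- -b / a
  se_g <- 1000 * sqrt(vc["voltage", "voltage"])
  # delta method for E_rev = -b/a
  grad <- c(-1 / a, b / a^2)  # d/db, d/da
  se_e <- sqrt(drop(t(grad) %*% vc[c("(Intercept)", "voltage"),
                                   c("(Intercept)", "voltage")] %*% grad))
  fit_result(
    parameters = c(g = g, E_rev = e_rev),
    se = c(g = se_g, E_rev = se_e),
    units = c(g = "pS", E_rev = "mV"),
    residual_norm = sqrt(sum(stats::residuals(fit)^2)),
    converged = TRUE, n = nrow(data),
    method = "weighted least-squares line i = g (V - E_rev)"
  )
}

#' Relative open probability
#'
#' Ratio of the open probability after a treatment to that before it
#' (`Po_post / Po_pre`), the standard normalisation for modulator effects.
#'
#' @param po_pre Open probability before treatment (> 0).
#' @param po_post Open probability after treatment (>= 0).
#' @return `po_post / po_pre`.
#' @examples
#' relative_po(0.4, 0.2) # 0.5
#' @export
relative_po <- function(po_pre, po_post) {
  if (!is.finite(po_pre) || po_pre <= 0) {
    stop("po_pre must be positive", call. = FALSE)
  }
  if (po_post < 0) stop("po_post must be non-negative", call. = FALSE)
  po_post / po_pre
}

#' Fit a Hill inhibition curve for IC50
#'
#' Least-squares fit of mean relative Po per dose to
#' `1 / (1 + (C / IC50)^h)`. The dose at half response under the fitted model
#' is IC50. Fitting is on the mean per dose, with inverse-variance weights
#' when replicate SDs are available, and uses three log-spaced IC50 starts to
#' guard against local minima. The Hill coefficient is free by default;
#' `fix_hill = 1` reproduces a fixed-slope fit.
#'
#' @param table A [generate_dose_response()] table, or any data.frame with
#'   columns `dose` (mM) and `relative_po`.
#' @param fix_hill Optional fixed Hill coefficient; `NULL` (default) fits it.
#' @return A [fit_result()] with parameters `ic50` (mM) and `hill`.
#' @examples
#' tab <- generate_dose_response(1.09, doses = 10^seq(-1.5, 1.5, 0.25),
#'                               noise_sd = 0, seed = 1)
#' fit_hill_inhibition(tab)
#' @export
fit_hill_inhibition <- function(table, fix_hill = NULL) {
  stopifnot(is.data.frame(table),
            all(c("dose", "relative_po") %in% names(table)))
  agg <- stats::aggregate(relative_po ~ dose, data = table,
                          FUN = function(v) c(m = mean(v), s = stats::sd(v),
                                              n = length(v)))
  doses <- agg$dose
  y <- agg$relative_po[, "m"]
  sds <- agg$relative_po[, "s"]
  ns <- agg$relative_po[, "n"]
  if (length(doses) < 3L) {
    stop("need >= 3 distinct doses to fit an inhibition curve", call. = FALSE)
  }
  if (min(y) > 0.8 || max(y) < 0.2) {
    stop("doses lie on one plateau (mean responses span [",
         format(min(y), digits = 3), ", ", format(max(y), digits = 3),
         "]); IC50 is not identifiable", call. = FALSE)
  }
  weights <- NULL
  if (all(ns >= 2L) && all(is.finite(sds))) {
    floor_sd <- stats::median(sds) / 3
    if (floor_sd > 0) weights <- ns / pmax(sds, floor_sd)^2
  }
  # start: dose whose mean response is nearest half-inhibition
  ic50_0 <- doses[which.min(abs(y - 0.5))]
  if (ic50_0 <= 0) ic50_0 <- stats::median(doses[doses > 0])
  hill_fixed <- !is.null(fix_hill)
  if (hill_fixed && fix_hill <= 0) stop("fix_hill must be positive", call. = FALSE)
  model_fn <- if (hill_fixed) {
    function(theta) 1 / (1 + (doses / exp(theta[["lic50"]]))^fix_hill)
  } else {
    function(theta) {
      1 / (1 + (doses / exp(theta[["lic50"]]))^exp(theta[["lhill"]]))
    }
  }
  starts <- lapply(c(1 / 3, 1, 3), function(f) {
    if (hill_fixed) c(lic50 = log(ic50_0 * f)) else
      c(lic50 = log(ic50_0 * f), lhill = 0)
  })
  ls <- .ls_multistart(y, model_fn, starts, weights)
  ic50 <- exp(ls$theta[["lic50"]])
  hill <- if (hill_fixed) fix_hill else exp(ls$theta[["lhill"]])
  se <- c(ic50 = ic50 * ls$se[["lic50"]],
          hill = if (hill_fixed) 0 else hill * ls$se[["lhill"]])
  fit_result(
    parameters = c(ic50 = ic50, hill = hill),
    se = se, units = c(ic50 = "mM", hill = ""),
    residual_norm = sqrt(ls$rss), converged = ls$converged, n = ls$n,
    method = "Hill inhibition 1/(1 + (C/IC50)^h), mean per dose",
    details = list(hill_fixed = hill_fixed, weighted = !is.null(weights),
                   start_ic50 = ic50_0)
  )
}

#' Steady-state response of a sensorgram
#'
#' Biacore-style plateau estimate: the mean response over the final fraction
#' (default 10\%) of the association phase.
#'
#' @param sensorgram A [simulate_sensorgram()] object.
#' @param frac Final fraction of the association phase to average.
#' @return Steady-state response in RU.
#' @export
steady_state_response <- function(sensorgram, frac = 0.1) {
  stopifnot(inherits(sensorgram, "blm_sensorgram"), frac > 0, frac <= 1)
  ta <- sensorgram$t_assoc
  sel <- sensorgram$time >= ta * (1 - frac) & sensorgram$time <= ta
  mean(sensorgram$response[sel])
}

#' Build a concentration/steady-response binding series
#'
#' @param sensorgrams List of [simulate_sensorgram()] objects at distinct
#'   analyte concentrations.
#' @param frac Passed to [steady_state_response()].
#' @return A data.frame with columns `conc` (mM) and `response` (RU).
#' @export
binding_series <- function(sensorgrams, frac = 0.1) {
  stopifnot(is.list(sensorgrams), length(sensorgrams) >= 1L)
  data.frame(
    conc = vapply(sensorgrams, `[[`, numeric(1), "analyte_conc"),
    response = vapply(sensorgrams, steady_state_response, numeric(1),
                      frac = frac)
  )
}

#' Steady-state Langmuir 1:1 affinity fit
#'
#' Least-squares fit of the binding isotherm
#' `R_eq = C R_max / (C + K_D)` to a concentration/steady-response series.
#'
#' @param series A data.frame with columns `conc` (mM, strictly positive and
#'   distinct) and `response` (RU), e.g. from [binding_series()].
#' @return A [fit_result()] with parameters `K_D` (mM) and `R_max` (RU). A
#'   warning is issued when the series does not approach saturation
#'   (max concentration below the fitted K_D), in which case the reported
#'   uncertainties are wide.
#' @examples
#' conc <- 20 / 2^(11:0)
#' series <- data.frame(conc = conc, response = conc * 100 / (conc + 7.99))
#' fit_langmuir_steady(series)
#' @export
fit_langmuir_steady <- function(series) {
  stopifnot(is.data.frame(series), all(c("conc", "response") %in% names(series)))
  conc <- series$conc
  y <- series$response
  if (length(unique(conc)) < 3L) {
    stop("need >= 3 distinct concentrations", call. = FALSE)
  }
  if (any(conc <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (any(y <= 0)) stop("responses must be positive", call. = FALSE)
  rmax_0 <- max(y) * 1.5
  kd_0 <- conc[which.min(abs(y - max(y) / 2))]
  model_fn <- function(theta) {
    conc * exp(theta[["lrmax"]]) / (conc + exp(theta[["lkd"]]))
  }
  starts <- lapply(c(1 / 3, 1, 3), function(f) {
    c(lkd = log(kd_0 * f), lrmax = log(rmax_0))
  })
  ls <- .ls_multistart(y, model_fn, starts)
  kd <- exp(ls$theta[["lkd"]])
  rmax <- exp(ls$theta[["lrmax"]])
  if (max(conc) < kd) {
    warning("binding series is non-saturating (max concentration ",
            format(max(conc)), " mM < fitted K_D ", format(kd, digits = 3),
            " mM); confidence in K_D and R_max is poor", call. = FALSE)
  }
  fit_result(
    parameters = c(K_D = kd, R_max = rmax),
    se = c(K_D = kd * ls$se[["lkd"]], R_max = rmax * ls$se[["lrmax"]]),
    units = c(K_D = "mM", R_max = "RU"),
    residual_norm = sqrt(ls$rss), converged = ls$converged, n = ls$n,
    method = "steady-state Langmuir 1:1 isotherm R = C Rmax / (C + K_D)"
  )
}

#' Global kinetic Langmuir 1:1 fit of a sensorgram set
#'
#' Global least-squares fit of the closed-form association/dissociation
#' exponentials across all concentrations, sharing `ka`, `kd` and `R_max`
#' (the 1:1 Biacore convention). Starting values are derived from the data:
#' `kd` from the log-linear slope of the largest dissociation phase, `K_D`
#' and `R_max` from a steady-state fit of the plateau responses, and
#' `ka = kd / K_D`.
#'
#' @param sensorgrams List of [simulate_sensorgram()] objects at two or more
#'   distinct analyte concentrations.
#' @return A [fit_result()] with parameters `ka` (mM^-1 s^-1), `kd` (s^-1),
#'   `R_max` (RU) and the derived `K_D = kd/ka` (mM).
#' @export
fit_langmuir_kinetic <- function(sensorgrams) {
  stopifnot(is.list(sensorgrams), length(sensorgrams) >= 2L)
  ok <- vapply(sensorgrams, inherits, logical(1), "blm_sensorgram")
  if (!all(ok)) stop("sensorgrams must be blm_sensorgram objects", call. = FALSE)
  concs <- vapply(sensorgrams, `[[`, numeric(1), "analyte_conc")
  if (length(unique(concs)) < 2L) {
    stop("all analyte concentrations identical: ka is not identifiable",
         call. = FALSE)
  }
  t_all <- unlist(lapply(sensorgrams, `[[`, "time"))
  y_all <- unlist(lapply(sensorgrams, `[[`, "response"))
  c_all <- rep(concs, vapply(sensorgrams, function(s) length(s$time), 1L))
  ta_all <- rep(vapply(sensorgrams, `[[`, numeric(1), "t_assoc"),
                vapply(sensorgrams, function(s) length(s$time), 1L))
  # kd start: log-linear decay of the dissociation phase of the biggest curve
  big <- sensorgrams[[which.max(concs)]]
  sel <- big$time > big$t_assoc & big$response > 0
  kd_0 <- if (sum(sel) >= 3L) {
    sl <- stats::coef(stats::lm(log(big$response[sel]) ~ big$time[sel]))[[2]]
    max(-sl, 1e-4)
  } else {
    0.01
  }
  steady <- tryCatch(fit_langmuir_steady(binding_series(sensorgrams)),
                     error = function(e) NULL, warning = function(w) {
                       suppressWarnings(fit_langmuir_steady(binding_series(sensorgrams)))
                     })
  kd_eq_0 <- if (!is.null(steady)) steady$parameters[["K_D"]] else stats::median(concs)
  rmax_0 <- if (!is.null(steady)) steady$parameters[["R_max"]] else max(y_all) * 1.5
  model_fn <- function(theta) {
    langmuir_response(t_all, exp(theta[["lka"]]), exp(theta[["lkd"]]),
                      exp(theta[["lrmax"]]), c_all, ta_all)
  }
  starts <- lapply(c(1 / 3, 1, 3), function(f) {
    c(lka = log(kd_0 * f / kd_eq_0), lkd = log(kd_0 * f), lrmax = log(rmax_0))
  })
  ls <- .ls_multistart(y_all, model_fn, starts)
  ka <- exp(ls$theta[["lka"]])
  kd <- exp(ls$theta[["lkd"]])
  rmax <- exp(ls$theta[["lrmax"]])
  fit_result(
    parameters = c(ka = ka, kd = kd, R_max = rmax, K_D = kd / ka),
    se = c(ka = ka * ls$se[["lka"]], kd = kd * ls$se[["lkd"]],
           R_max = rmax * ls$se[["lrmax"]],
           K_D = (kd / ka) * sqrt(ls$se[["lka"]]^2 + ls$se[["lkd"]]^2)),
    units = c(ka = "mM^-1 s^-1", kd = "s^-1", R_max = "RU", K_D = "mM"),
    residual_norm = sqrt(ls$rss), converged = ls$converged, n = ls$n,
    method = "global kinetic Langmuir 1:1 fit (shared ka, kd, R_max)",
    details = list(start_kd = kd_0, start_KD = kd_eq_0)
  )
}
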