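# Pipeline driver and command-line surface. Subcommands: simulate, idealize,
# iv, dose, spr, report. Every stochastic run records its seed, and each
# stage's output JSON carries enough metadata to regenerate it.

.log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

.num <- function(params, key, default = NULL) {
  if (is.null(params[[key]])) return(default)
  as.numeric(params[[key]])
}

.stage_simulate <- function(params) {
  seed <- as.integer(params$seed %||% 1L)
  acq <- acquisition_params(
    sampling_rate = .num(params, "sampling_rate", 10000),
    filter_cutoff = .num(params, "filter_cutoff", 1000),
    noise_sd = .num(params, "noise_sd", 0.45),
    duration = .num(params, "duration", 10),
    seed = seed
  )
  model <- channel_model(
    iv = linear_iv(.num(params, "conductance", 39.9),
                   .num(params, "reversal", 56.8)),
    gating = gating_params(.num(params, "k_open", 50),
                           .num(params, "k_close", 50)),
    n_channels = .num(params, "n_channels", 1),
    ca_inhibition = if (!is.null(params$ic50)) {
      list(ic50 = .num(params, "ic50"), hill = .num(params, "hill", 1))
    }
  )
  tr <- simulate_trace(model, acq, voltage = .num(params, "voltage", 0),
                       luminal_ca = .num(params, "luminal_ca", 0))
  out <- params$out %||% "trace.csv"
  write_trace(tr, out)
  .log_msg("INFO", "simulate: wrote ", out, " (seed ", seed, ")")
  out
}

.stage_idealize <- function(params) {
  if (is.null(params$input)) stop("idealize needs an input trace file")
  tr <- read_trace(params$input)
  lv <- fit_amplitude_levels(tr, n_levels = .num(params, "n_levels", 2))
  ev <- idealize_half_amplitude(tr, lv,
                                min_open_ms = .num(params, "min_open_ms", 0.5))
  out <- params$out %||% "events.csv"
  write_events(ev, out)
  dw <- dwell_summary(ev)
  summary_rec <- list(
    type = "idealization_summary",
    po = open_probability(ev),
    level_means_pA = lv$means, level_sds_pA = lv$sds,
    mean_open_ms = dw$mean_open_ms, mean_closed_ms = dw$mean_closed_ms,
    n_open = dw$n_open, n_closed = dw$n_closed,
    min_open_ms = attr(ev, "min_duration_applied"),
    input = params$input
  )
  write_results(summary_rec, paste0(out, ".summary.json"))
  .log_msg("INFO", "idealize: Po = ", format(summary_rec$po, digits = 4),
           ", wrote ", out)
  out
}

.stage_iv <- function(params) {
  if (is.null(params$input)) stop("iv needs an input CSV (voltage, amplitude)")
  d <- utils::read.csv(params$input)
  names(d)[1:2] <- c("voltage", "amplitude")
  res <- fit_iv(d)
  out <- params$out %||% "iv_fit.json"
  write_results(res, out)
  .log_msg("INFO", "iv: g = ", format(res$parameters[["g"]], digits = 4),
           " pS, E_rev = ", format(res$parameters[["E_rev"]], digits = 4),
           " mV")
  out
}

.stage_dose <- function(params) {
  if (is.null(params$input)) stop("dose needs an input CSV (dose, relative_po)")
  d <- utils::read.csv(params$input)
  names(d)[1:2] <- c("dose", "relative_po")
  res <- fit_hill_inhibition(d, fix_hill = .num(params, "fix_hill"))
  out <- params$out %||% "dose_fit.json"
  write_results(res, out)
  .log_msg("INFO", "dose: IC50 = ",
           format(res$parameters[["ic50"]], digits = 4), " mM")
  out
}

.stage_spr <- function(params) {
  if (is.null(params$input)) {
    stop("spr needs an input CSV (time_s, response_RU, conc_mM[, t_assoc_s])")
  }
  d <- utils::read.csv(params$input)
  names(d)[1:3] <- c("time_s", "response_RU", "conc_mM")
  ta <- if ("t_assoc_s" %in% names(d)) d$t_assoc_s[1] else 90
  sgs <- lapply(split(d, d$conc_mM), function(g) {
    structure(list(time = g$time_s, response = g$response_RU,
                   analyte_conc = g$conc_mM[1], t_assoc = ta),
              class = "blm_sensorgram")
  })
  mode <- params$mode %||% "both"
  rec <- list(type = "spr_fit", mode = mode, input = params$input)
  if (mode %in% c("steady", "both")) {
    rec$steady <- .result_record(fit_langmuir_steady(binding_series(sgs)))
  }
  if (mode %in% c("kinetic", "both")) {
    rec$kinetic <- .result_record(fit_langmuir_kinetic(sgs))
  }
  out <- params$out %||% "spr_fit.json"
  write_results(rec, out)
  .log_msg("INFO", "spr: wrote ", out)
  out
}

.stage_report <- function(params) {
  dir <- params$input %||% "."
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  files <- files[!grepl("report\\.json$", files)]
  rec <- list(type = "report",
              results = lapply(files, function(f) {
                list(file = f, record = read_results(f))
              }))
  out <- params$out %||% file.path(dir, "report.json")
  write_results(rec, out)
  .log_msg("INFO", "report: indexed ", length(files), " result files")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a pipeline stage from a configuration
#'
#' Executes one subcommand of the simulate -> filter -> idealize -> fit chain
#' and writes its outputs. All parameters, seeds and the package version are
#' logged and embedded in the outputs, so a run can be reproduced from its
#' files alone. Errors in any stage are reported with the stage name and turn
#' into a non-zero exit status; no partial outputs are kept on error.
#'
#' @param config A list with `subcommand` (one of `"simulate"`, `"idealize"`,
#'   `"iv"`, `"dose"`, `"spr"`, `"report"`) and the stage parameters
#'   (`input`, `out`, `seed`, plus stage-specific fields; see the stage
#'   functions' documentation).
#' @return Exit status, invisibly: 0 on success, 1 on any stage error.
#' @examples
#' out <- file.path(tempdir(), "tr.csv")
#' status <- run_pipeline(list(subcommand = "simulate", duration = 0.1,
#'                             seed = 1, out = out))
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$subcommand))
  sub <- config$subcommand
  stage <- switch(sub,
    simulate = .stage_simulate,
    idealize = .stage_idealize,
    iv = .stage_iv,
    dose = .stage_dose,
    spr = .stage_spr,
    report = .stage_report,
    stop("unknown subcommand: ", sub, call. = FALSE)
  )
  status <- tryCatch({
    stage(config)
    0L
  }, error = function(e) {
    .log_msg("ERROR", "stage '", sub, "' failed: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

# Parse "--key value" / "--key=value" flags after the subcommand.
.parse_cli_args <- function(args) {
  if (length(args) == 0L) stop("usage: <subcommand> [--key value ...]",
                               call. = FALSE)
  config <- list(subcommand = args[[1]])
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    a <- rest[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    a <- substring(a, 3)
    if (grepl("=", a, fixed = TRUE)) {
      kv <- strsplit(a, "=", fixed = TRUE)[[1]]
      key <- kv[1]
      val <- paste(kv[-1], collapse = "=")
    } else {
      key <- a
      if (i == length(rest)) stop("flag --", key, " needs a value", call. = FALSE)
      i <- i + 1L
      val <- rest[[i]]
    }
    num <- suppressWarnings(as.numeric(val))
    config[[key]] <- if (!is.na(num)) num else val
    i <- i + 1L
  }
  if (!is.null(config$config)) {
    file_cfg <- jsonlite::fromJSON(config$config, simplifyVector = TRUE)
    config <- utils::modifyList(file_cfg, config)
  }
  config
}

#' Command-line entry point
#'
#' `blm_main(c("simulate", "--seed", "3", "--out", "tr.csv"))` etc. Shared
#' flags: `--seed`, `--config <json>`, `--out`. Intended to be called from an
#' Rscript wrapper; see `system.file("cli", "bilayertools", package =
#' "bilayertools")`.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status integer, invisibly.
#' @export
blm_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  config <- tryCatch(.parse_cli_args(args), error = function(e) {
    .log_msg("ERROR", conditionMessage(e))
    NULL
  })
  if (is.null(config)) return(invisible(2L))
  run_pipeline(config)
}
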