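# Plain-text I/O: traces and event tables as CSV with unit-tagged headers,
# results and configs as JSON. All numeric I/O is in the package's fixed
# units (ms, pA, mV, pS, mM, RU; s for sensorgrams).

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a trace to disk
#'
#' Two-column CSV (`time_ms`, `current_pA`) plus a JSON metadata sidecar at
#' `<path>.json` carrying the acquisition parameters, seed and package
#' version, enough to regenerate a simulated trace exactly.
#'
#' @param trace A [trace()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "blm_trace"))
  data.table::fwrite(
    data.table::data.table(time_ms = trace$time, current_pA = trace$current),
    path
  )
  meta <- trace$metadata
  meta$package_version <- as.character(utils::packageVersion("bilayertools"))
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "string", pretty = TRUE)
  invisible(path)
}

#' Read a trace from disk
#'
#' Accepts two numeric columns (`time_ms`, `current_pA`) with an optional
#' header; a `<path>.json` sidecar, if present, is merged into the metadata.
#' The time grid must be uniform to within 1e-6 relative; non-numeric rows
#' are rejected with their line number.
#'
#' @param path Input CSV path.
#' @return A [trace()] with inferred sampling rate.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = "auto", colClasses = "character")
  if (ncol(dt) < 2L) stop("expected two columns (time_ms, current_pA) in ",
                          path, call. = FALSE)
  tm <- suppressWarnings(as.numeric(dt[[1]]))
  cur <- suppressWarnings(as.numeric(dt[[2]]))
  bad <- which(is.na(tm) | is.na(cur))
  if (length(bad)) {
    stop("non-numeric data in ", path, " at line ", bad[1] + 1L,
         " (counting the header)", call. = FALSE)
  }
  if (length(tm) >= 3L) {
    dts <- diff(tm)
    if (any(dts <= 0) || diff(range(dts)) > 1e-6 * stats::median(dts)) {
      stop("non-uniform time grid in ", path,
           " (jitter exceeds 1e-6 relative)", call. = FALSE)
    }
  }
  meta <- list(source = path)
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    meta <- utils::modifyList(jsonlite::fromJSON(sc, simplifyVector = TRUE),
                              meta)
  }
  trace(tm, cur, meta)
}

#' Write an event list as tabular text
#' @param events An [event_list()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_list"))
  data.table::fwrite(
    data.table::data.table(state = events$state, start_ms = events$start_ms,
                           duration_ms = events$duration_ms),
    path
  )
  invisible(path)
}

# Attach unit tags to a fit_result for JSON serialisation; NaN/NA become the
# string "NA" rather than being dropped.
.result_record <- function(x) {
  if (inherits(x, "fit_result")) {
    params <- lapply(names(x$parameters), function(p) {
      rec <- list(value = x$parameters[[p]])
      if (!is.null(x$units) && p %in% names(x$units)) {
        rec$unit <- x$units[[p]]
      }
      if (!is.null(x$se) && p %in% names(x$se)) rec$se <- x$se[[p]]
      rec
    })
    names(params) <- names(x$parameters)
    list(type = "fit_result", method = x$method, parameters = params,
         residual_norm = x$residual_norm, converged = x$converged, n = x$n,
         details = x$details)
  } else {
    x
  }
}

#' Write a result record as JSON
#'
#' Fit results are serialised with a unit tag on every parameter and with
#' deterministic key order; `NaN`/`NA` values are written explicitly as
#' strings rather than dropped.
#'
#' @param record A [fit_result()] or any serialisable list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_results <- function(record, path) {
  rec <- .result_record(record)
  rec$package_version <- as.character(utils::packageVersion("bilayertools"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       na = "string", pretty = TRUE)
  invisible(path)
}

#' Read a result record written by [write_results()]
#' @param path JSON path.
#' @return The deserialised record (a list).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
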