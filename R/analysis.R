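# Post-processing: EPSC normalization, percentage plasticity, boundary
# extraction, and run reports.

#' Normalize an EPSC series onto the 100-150 display scale
#'
#' Affine map sending the series minimum to 100 and its maximum to 150:
#' 100 + (EPSC - EPSC_min) (150 - 100) / (EPSC_max - EPSC_min).  Invariant
#' to affine rescaling of the raw units.
#'
#' @param amp raw EPSC amplitudes (pA); must not be constant
#' @return normalized amplitudes
#' @export
normalize_epsc <- function(amp) {
  rng <- range(amp)
  if (diff(rng) == 0) stop("EPSC series is constant: normalization undefined")
  100 + (amp - rng[1]) * (150 - 100) / (rng[2] - rng[1])
}

#' Relative EPSC change from 5 to 30 min after a pairing window
#'
#' Given the relative increases over baseline at 5 min (\code{pct5}) and
#' 30 min (\code{pct30}) after the window end, the 5-to-30-min change is
#' (pct30 - pct5) / (100 + pct5) * 100.
#'
#' @param pct5,pct30 percent increases over baseline
#' @return percent change from 5 to 30 min
#' @export
percentage_change_5_30 <- function(pct5, pct30) {
  (pct30 - pct5) / (100 + pct5) * 100
}

#' Percentage plasticity of a simulated EPSC series
#'
#' Computes the relative EPSC increases over the pre-window baseline at 5
#' and 30 min after the window end and their 5-to-30-min relative change
#' (the quantity used to judge whether a disinhibition response keeps its
#' shape: small for long windows that stay potentiated, large for short
#' windows that decay).
#'
#' @param time_min EPSC pulse times (min); \code{amp} amplitudes (pA)
#' @param amp EPSC amplitudes (pA)
#' @param window_end_min end of the pairing/disinhibition window (min)
#' @param window_start_min start of the window; used for the baseline mean
#' @param baseline optional explicit baseline amplitude (pA)
#' @return list with \code{pct_5}, \code{pct_30}, \code{pct_30_5}
#' @export
percentage_plasticity <- function(time_min, amp, window_end_min,
                                  window_start_min = NULL, baseline = NULL) {
  stopifnot(length(time_min) == length(amp))
  if (max(time_min) < window_end_min + 30) {
    stop("series must span at least 30 min past the window end")
  }
  if (is.null(baseline)) {
    if (is.null(window_start_min)) stop("need window_start_min or baseline")
    baseline <- mean(amp[time_min < window_start_min])
  }
  at <- function(tq) amp[which.min(abs(time_min - tq))]
  pct5 <- (at(window_end_min + 5) / baseline - 1) * 100
  pct30 <- (at(window_end_min + 30) / baseline - 1) * 100
  list(pct_5 = pct5, pct_30 = pct30,
       pct_30_5 = percentage_change_5_30(pct5, pct30))
}

#' Zero crossings of a scanned response
#'
#' Linear-interpolated abscissae where the sign of \code{y} changes; one
#' entry per sign change, empty if the table never changes sign.
#'
#' @param x sorted abscissae; \code{y} responses
#' @param y responses at \code{x}
#' @return numeric vector of crossing locations
#' @export
extract_boundaries <- function(x, y) {
  stopifnot(length(x) == length(y), !is.unsorted(x))
  s <- sign(y)
  out <- numeric(0)
  for (i in seq_len(length(x) - 1)) {
    if (s[i] != s[i + 1] && s[i] != 0) {
      out <- c(out, x[i] + (x[i + 1] - x[i]) * (0 - y[i]) / (y[i + 1] - y[i]))
    }
  }
  out
}

#' Write protocol outputs to disk
#'
#' Writes the numeric endpoint report as JSON, every supplied trace as CSV
#' (comma-separated, '.' decimal, UTF-8) and the full configuration as a
#' YAML sidecar, so a run can be reproduced from its artifacts.  Reports
#' containing non-finite endpoints are refused.
#'
#' @param report named list of scalar endpoints (protocol name, preset,
#'   seeds, endpoint numbers, ...)
#' @param traces named list of data.frames to write as CSV
#' @param params the \code{\link{circuit_params}} used
#' @param dir output directory (created if missing)
#' @return invisibly, the vector of files written
#' @export
write_outputs <- function(report, traces = list(), params = NULL,
                          dir = ".") {
  num <- vapply(report, is.numeric, logical(1))
  bad <- vapply(report[num], function(x) any(!is.finite(x)), logical(1))
  if (any(bad)) {
    stop("refusing to write report with non-finite endpoint(s): ",
         paste(names(report[num])[bad], collapse = ", "))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  for (nm in names(traces)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    write.csv(traces[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(params)) {
    f <- file.path(dir, "config.yaml")
    write_config(params, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Serialize a parameter set to a YAML config file
#'
#' One section per component, keys named as in the parameter constructors.
#'
#' @param params a \code{\link{circuit_params}} object
#' @param path output file path
#' @return invisibly, \code{path}
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "circuit_params"))
  yaml::write_yaml(lapply(unclass(params), function(x)
    if (is.list(x)) unclass(x) else x), path)
  invisible(path)
}

#' Read a parameter set from a YAML config file
#'
#' @param path config file path
#' @return a \code{\link{circuit_params}} object
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  preset <- y$preset %||% "disinhibition"
  comps <- setdiff(names(y), "preset")
  do.call(circuit_params, c(list(preset = preset), y[comps]))
}
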