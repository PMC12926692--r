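# SpectrumRun: the in-memory representation of one LC-MS acquisition.

#' Construct a spectrum run
#'
#' A time-ordered collection of mass spectra. Each scan is a list with `rt`
#' (minutes), `mz` (ascending), and `intensity` (non-negative, same length).
#'
#' @param scans List of scans.
#' @param mode `"centroid"` or `"profile"`.
#' @param metadata Named list of acquisition metadata (instrument, `mz_range`,
#'   `scan_rate`, optionally `quad_low_mass`).
#' @return Object of class `spectrum_run`.
#' @export
spectrum_run <- function(scans, mode = c("centroid", "profile"),
                         metadata = list()) {
  mode <- match.arg(mode)
  rts <- vapply(scans, `[[`, numeric(1), "rt")
  if (length(rts) > 1 && any(diff(rts) <= 0))
    stop("scan retention times must be strictly increasing")
  for (s in scans) {
    if (length(s$mz) != length(s$intensity))
      stop("mz and intensity arrays must have equal length")
    if (length(s$mz) > 1 && is.unsorted(s$mz))
      stop("mz must be ascending within a scan")
    if (any(s$intensity < 0)) stop("intensities must be non-negative")
  }
  structure(list(scans = scans, mode = mode, metadata = metadata),
            class = "spectrum_run")
}

#' Number of scans in a run
#' @param run A `spectrum_run`.
#' @return Integer scan count.
#' @export
n_scans <- function(run) length(run$scans)

#' Scan retention times
#' @param run A `spectrum_run`.
#' @return Numeric vector of retention times in minutes.
#' @export
scan_times <- function(run) vapply(run$scans, `[[`, numeric(1), "rt")

#' @export
print.spectrum_run <- function(x, ...) {
  rts <- scan_times(x)
  np <- sum(vapply(x$scans, function(s) length(s$mz), integer(1)))
  cat(sprintf("<spectrum_run> %d %s scans, rt %.2f-%.2f min, %d peaks\n",
              n_scans(x), x$mode,
              if (length(rts)) min(rts) else NA, if (length(rts)) max(rts) else NA,
              np))
  invisible(x)
}

# Coerce assorted peak-list representations to list(mz, intensity).
.as_peaklist <- function(x) {
  if (inherits(x, "averaged_spectrum")) return(list(mz = x$mz, intensity = x$intensity))
  if (is.list(x) && !is.null(x$mz)) return(list(mz = x$mz, intensity = x$intensity))
  if (is.matrix(x)) return(list(mz = x[, 1], intensity = x[, 2]))
  if (is.data.frame(x)) return(list(mz = x[[1]], intensity = x[[2]]))
  stop("cannot interpret object as a peak list")
}
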