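# Retention-time spectrum averaging, extracted ion chromatograms, and AUC.

#' Average spectra over a retention-time window
#'
#' Centroid mode: peaks from all scans in the window are pooled, clustered
#' (adjacent peaks within `cluster_tol` m/z belong to one cluster), and each
#' cluster reports the intensity-weighted mean m/z and the mean intensity
#' over the scans in the window (a scan without the peak contributes zero).
#' Profile mode: scans are linearly resampled to the first scan's grid and
#' averaged.
#'
#' @param run A [spectrum_run()].
#' @param rt_window Numeric `c(lo, hi)` in minutes (inclusive).
#' @param cluster_tol Centroid clustering tolerance in m/z (default 0.01,
#'   about FWHM/1.7 at m/z 1000 and resolving power 60000).
#' @return Object of class `averaged_spectrum`: list with `mz`, `intensity`,
#'   `mode`, `rt_window`, `n_scans`.
#' @export
average_spectra <- function(run, rt_window, cluster_tol = 0.01) {
  stopifnot(inherits(run, "spectrum_run"), length(rt_window) == 2)
  rts <- scan_times(run)
  sel <- which(rts >= rt_window[1] & rts <= rt_window[2])
  if (!length(sel))
    stop(sprintf("rt window [%.3f, %.3f] overlaps no scan (run spans %.3f-%.3f min)",
                 rt_window[1], rt_window[2],
                 if (length(rts)) min(rts) else NA_real_,
                 if (length(rts)) max(rts) else NA_real_))
  nsc <- length(sel)
  if (run$mode == "profile") {
    grid <- run$scans[[sel[1]]]$mz
    acc <- numeric(length(grid))
    for (i in sel) {
      s <- run$scans[[i]]
      if (length(s$mz) == 0) next
      acc <- acc + stats::approx(s$mz, s$intensity, xout = grid,
                                 yleft = 0, yright = 0)$y
    }
    return(structure(list(mz = grid, intensity = acc / nsc, mode = "profile",
                          rt_window = rt_window, n_scans = nsc),
                     class = "averaged_spectrum"))
  }
  mz <- unlist(lapply(sel, function(i) run$scans[[i]]$mz))
  it <- unlist(lapply(sel, function(i) run$scans[[i]]$intensity))
  if (!length(mz))
    return(structure(list(mz = numeric(0), intensity = numeric(0),
                          mode = "centroid", rt_window = rt_window,
                          n_scans = nsc), class = "averaged_spectrum"))
  ord <- order(mz)
  mz <- mz[ord]
  it <- it[ord]
  cl <- cumsum(c(1L, as.integer(diff(mz) > cluster_tol)))
  itc <- as.numeric(tapply(it, cl, sum))
  wmz <- as.numeric(tapply(mz * it, cl, sum)) / pmax(itc, .Machine$double.xmin)
  zero <- itc == 0  # all-zero clusters keep their plain mean m/z
  if (any(zero)) wmz[zero] <- as.numeric(tapply(mz, cl, mean))[zero]
  structure(list(mz = wmz, intensity = itc / nsc, mode = "centroid",
                 rt_window = rt_window, n_scans = nsc),
            class = "averaged_spectrum")
}

#' @export
print.averaged_spectrum <- function(x, ...) {
  cat(sprintf("<averaged_spectrum> %d peaks, %s, rt %.2f-%.2f min (%d scans)\n",
              length(x$mz), x$mode, x$rt_window[1], x$rt_window[2], x$n_scans))
  invisible(x)
}

# normalize windows input to a 2-column matrix and merge overlaps
.normalize_windows <- function(windows) {
  if (is.list(windows) && !is.data.frame(windows))
    windows <- do.call(rbind, lapply(windows, function(w) c(w[1], w[2])))
  windows <- matrix(as.numeric(as.matrix(windows)), ncol = 2)
  if (any(windows[, 1] >= windows[, 2]))
    stop("each m/z window must satisfy lo < hi")
  windows <- windows[order(windows[, 1]), , drop = FALSE]
  if (nrow(windows) > 1) {
    merged <- list(windows[1, ])
    overlap <- FALSE
    for (i in 2:nrow(windows)) {
      last <- merged[[length(merged)]]
      if (windows[i, 1] < last[2]) {
        overlap <- TRUE
        merged[[length(merged)]] <- c(last[1], max(last[2], windows[i, 2]))
      } else merged[[length(merged) + 1]] <- windows[i, ]
    }
    if (overlap) {
      warning("overlapping m/z windows merged (no double counting)")
      windows <- do.call(rbind, merged)
    }
  }
  windows
}

#' Extract an ion chromatogram
#'
#' Per scan, sums all peak intensities whose m/z falls in any of the given
#' half-open windows `[lo, hi)`. Overlapping windows are merged with a
#' warning so no peak is counted twice.
#'
#' @param run A [spectrum_run()].
#' @param windows Two-column matrix, data frame, or list of `c(lo, hi)` m/z
#'   windows.
#' @param label Trace label (e.g. the isoform name).
#' @return Object of class `chromatogram_trace`: `rt` (minutes), `intensity`,
#'   `windows`, `label`.
#' @export
extract_eic <- function(run, windows, label = "") {
  stopifnot(inherits(run, "spectrum_run"))
  windows <- .normalize_windows(windows)
  intensity <- vapply(run$scans, function(s) {
    if (!length(s$mz)) return(0)
    tot <- 0
    for (i in seq_len(nrow(windows))) {
      j1 <- findInterval(windows[i, 1], s$mz, left.open = TRUE) + 1L
      j2 <- findInterval(windows[i, 2], s$mz, left.open = TRUE)
      if (j2 >= j1) tot <- tot + sum(s$intensity[j1:j2])
    }
    tot
  }, numeric(1))
  structure(list(rt = scan_times(run), intensity = intensity,
                 windows = windows, label = label),
            class = "chromatogram_trace")
}

#' @export
as.data.frame.chromatogram_trace <- function(x, ...) {
  data.frame(rt_min = x$rt, intensity = x$intensity,
             label = rep(x$label, length(x$rt)), stringsAsFactors = FALSE)
}

#' @export
print.chromatogram_trace <- function(x, ...) {
  cat(sprintf("<chromatogram_trace> '%s': %d points, %d window(s), apex %.3g\n",
              x$label, length(x$rt), nrow(x$windows),
              if (length(x$intensity)) max(x$intensity) else NA))
  invisible(x)
}

#' Area under a chromatogram
#'
#' Trapezoidal integral of the trace intensity over retention time, in
#' intensity x minutes. Defaults to the full trace; optional bounds restrict
#' the integration to `[lo, hi]` (points at the bounds included).
#'
#' @param trace A `chromatogram_trace` from [extract_eic()], or any list with
#'   `rt` and `intensity`.
#' @param rt_bounds Optional `c(lo, hi)` in minutes.
#' @return Non-negative area.
#' @examples
#' auc(list(rt = c(0, 1, 2), intensity = c(0, 10, 0)))  # 10
#' @export
auc <- function(trace, rt_bounds = NULL) {
  rt <- trace$rt
  y <- trace$intensity
  if (!is.null(rt_bounds)) {
    keep <- rt >= rt_bounds[1] & rt <= rt_bounds[2]
    rt <- rt[keep]
    y <- y[keep]
  }
  if (length(rt) < 2)
    stop("need at least 2 points within the integration bounds")
  sum(diff(rt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
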