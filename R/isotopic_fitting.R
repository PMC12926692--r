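# Validation of deconvoluted masses by fitting theoretical averagine isotopic
# distributions to observed clusters: calculated vs experimental mass, signed
# ppm error, and a scale-free fit score.

#' Fit a theoretical isotopic pattern to an observed cluster
#'
#' Aligns the averagine isotope distribution of `candidate_mass` to an
#' observed mass-domain cluster by optimizing a single mass offset within
#' +/- `search_window` Da (0.001 Da grid followed by parabolic refinement)
#' and a free intensity scale. The fit score is 100 x the cosine similarity
#' between the theoretical probabilities and the matched observed
#' intensities (theoretical peaks with no observed partner count as zeros;
#' matched intensities are softly weighted by a Gaussian of the residual
#' distance so the score is smooth in the offset). The experimental mass is
#' the offset-corrected monoisotopic mass, additionally refined as the
#' intensity-weighted mean matched-peak residual.
#'
#' @param observed Data frame / list with `mass` (Da) and `intensity`, or a
#'   two-column matrix; at least 3 points. See [cluster_mass_domain()].
#' @param candidate_mass Candidate (calculated) monoisotopic mass, Da.
#' @param search_window Alignment half-window in Da (default 0.5, i.e. less
#'   than one isotopologue spacing so off-by-one candidates cannot
#'   re-align).
#' @param grid_step Offset search grid in Da (default 0.001).
#' @param match_tol Peak-matching tolerance in Da (default 0.3).
#' @param sigma_match Gaussian width (Da) of the soft distance weighting
#'   (default 0.1).
#' @param truncate_at Averagine truncation threshold.
#' @return Object of class `isotopic_fit`: list with `calculated_mass`,
#'   `experimental_mass`, `ppm`, `fit_score` (percent in `[0, 100]`), and
#'   `scale`.
#' @examples
#' d <- averagine_isotope_distribution(12000)
#' fit <- fit_isotopic_pattern(data.frame(mass = d$mass, intensity = d$prob),
#'                             candidate_mass = 12000)
#' fit$fit_score  # 100
#' @export
fit_isotopic_pattern <- function(observed, candidate_mass,
                                 search_window = 0.5, grid_step = 0.001,
                                 match_tol = 0.3, sigma_match = 0.1,
                                 truncate_at = 1e-4) {
  if (is.matrix(observed)) observed <- list(mass = observed[, 1],
                                            intensity = observed[, 2])
  om <- as.numeric(observed$mass)
  oi <- as.numeric(observed$intensity)
  if (length(om) < 3) stop("need at least 3 observed points to fit")
  if (candidate_mass <= 0) stop("candidate_mass must be positive")
  ord <- order(om)
  om <- om[ord]
  oi <- oi[ord]
  theo <- averagine_isotope_distribution(candidate_mass, truncate_at)
  tm <- theo$mass
  tp <- theo$prob
  nobs <- length(om)

  score_at <- function(off) {
    pos <- tm + off
    near <- findInterval(pos, om)
    lowd <- ifelse(near >= 1, pos - om[pmax(near, 1)], Inf)
    highd <- ifelse(near < nobs, om[pmin(near + 1L, nobs)] - pos, Inf)
    pick <- ifelse(lowd <= highd, pmax(near, 1L), pmin(near + 1L, nobs))
    dist <- pmin(lowd, highd)
    v <- ifelse(dist <= match_tol,
                oi[pick] * exp(-0.5 * (dist / sigma_match)^2), 0)
    den <- sqrt(sum(v^2) * sum(tp^2))
    if (den == 0) return(list(score = 0, v = v, pick = pick, dist = dist))
    list(score = sum(v * tp) / den, v = v, pick = pick, dist = dist)
  }

  offsets <- seq(-search_window, search_window, by = grid_step)
  scores <- vapply(offsets, function(o) score_at(o)$score, numeric(1))
  bi <- which.max(scores)
  best_off <- offsets[bi]
  # parabolic refinement on the smooth score surface
  if (bi > 1 && bi < length(offsets)) {
    y1 <- scores[bi - 1]; y2 <- scores[bi]; y3 <- scores[bi + 1]
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && den < 0)
      best_off <- best_off + 0.5 * grid_step * (y1 - y3) / den
  }
  at <- score_at(best_off)
  if (all(at$v == 0)) {
    return(structure(list(calculated_mass = candidate_mass,
                          experimental_mass = NA_real_, ppm = NA_real_,
                          fit_score = 0, scale = NA_real_),
                     class = "isotopic_fit"))
  }
  # offset-corrected experimental mass, refined from matched residuals
  matched <- at$v > 0
  resid <- om[at$pick[matched]] - tm[matched]
  w <- at$v[matched]
  off_final <- sum(resid * w) / sum(w)
  experimental <- candidate_mass + off_final
  scale <- sum(oi[at$pick[matched]] * tp[matched]) / sum(tp[matched]^2)
  structure(list(calculated_mass = candidate_mass,
                 experimental_mass = experimental,
                 ppm = ppm_error(experimental, candidate_mass),
                 fit_score = 100 * max(min(at$score, 1), 0),
                 scale = scale),
            class = "isotopic_fit")
}

#' @export
print.isotopic_fit <- function(x, ...) {
  cat(sprintf("C: %.4f Da  E: %.4f Da  error: %+.2f ppm  fit score: %.1f%%\n",
              x$calculated_mass, x$experimental_mass, x$ppm, x$fit_score))
  invisible(x)
}

#' Isotopic fit report for a set of assigned proteoforms
#'
#' Runs [fit_isotopic_pattern()] for each supplied cluster/candidate pair and
#' returns the tabular report (calculated mass, experimental mass, ppm, fit
#' score).
#'
#' @param clusters List of observed clusters (each with `mass`, `intensity`),
#'   e.g. from [cluster_mass_domain()].
#' @param candidate_masses Numeric vector, one candidate per cluster.
#' @param ids Optional character labels.
#' @return Data frame with `proteoform_id`, `calculated_mass_da`,
#'   `experimental_mass_da`, `ppm`, `fit_score_pct`.
#' @export
fit_report <- function(clusters, candidate_masses, ids = NULL) {
  stopifnot(length(clusters) == length(candidate_masses))
  if (is.null(ids)) ids <- sprintf("cluster%02d", seq_along(clusters))
  rows <- lapply(seq_along(clusters), function(i) {
    f <- fit_isotopic_pattern(clusters[[i]], candidate_masses[i])
    data.frame(proteoform_id = ids[i],
               calculated_mass_da = f$calculated_mass,
               experimental_mass_da = f$experimental_mass,
               ppm = f$ppm, fit_score_pct = f$fit_score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
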