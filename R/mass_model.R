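# Fundamental mass / charge / isotope arithmetic shared by all pipeline stages.

# Stable-isotope masses (Da) and natural abundances for the averagine elements.
.element_isotopes <- list(
  C = list(mass = c(12.0000000, 13.0033548378),
           abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.0078250319, 2.0141017779),
           abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.0030740052, 15.0001088984),
           abundance = c(0.99632, 0.00368)),
  O = list(mass = c(15.9949146221, 16.9991315, 17.9991604),
           abundance = c(0.99757, 0.00038, 0.00205)),
  # S has no stable A+3 isotope; that bin carries zero abundance.
  S = list(mass = c(31.97207069, 32.97145850, 33.96786683, 34.96903, 35.96708088),
           abundance = c(0.9493, 0.0076, 0.0429, 0.0, 0.0002))
)

.const <- list(
  proton_mass = 1.007276466,
  averagine_monomer_mass = 111.1254,
  averagine_composition = c(C = 4.9384, H = 7.7583, N = 1.3577,
                            O = 1.4773, S = 0.0417),
  mod_deltas = c(phospho = 79.96633, oxidation = 15.99491, acetyl = 42.01057),
  avg_isotope_spacing = 1.00235
)

#' Physical and model constants
#'
#' Returns the fixed constants used throughout the package: the proton mass,
#' the Senko averagine monomer mass and fractional elemental composition, the
#' supported post-translational modification mass deltas (phospho, oxidation,
#' acetyl), and the average isotopologue spacing.
#'
#' @return Named list of constants (masses in Da).
#' @examples
#' mass_constants()$proton_mass
#' @export
mass_constants <- function() .const

#' Convert a neutral mass to m/z at a given charge
#'
#' Assumes protonation: `(M + z * m_p) / z` with `m_p` the proton mass.
#'
#' @param neutral_mass Neutral (monoisotopic) mass in Da, positive.
#' @param charge Positive integer charge state (vectorized).
#' @return m/z value(s).
#' @seealso [mass_from_mz()] for the inverse.
#' @examples
#' mz_from_mass(20000, 20)
#' @export
mz_from_mass <- function(neutral_mass, charge) {
  if (any(neutral_mass <= 0)) stop("neutral_mass must be positive")
  if (any(charge < 1)) stop("charge must be a positive integer")
  (neutral_mass + charge * .const$proton_mass) / charge
}

#' Convert an m/z value back to neutral mass
#'
#' @param mz Observed m/z.
#' @param charge Positive integer charge state.
#' @return Neutral mass in Da.
#' @export
mass_from_mz <- function(mz, charge) {
  if (any(charge < 1)) stop("charge must be a positive integer")
  charge * (mz - .const$proton_mass)
}

#' Signed mass error in parts per million
#'
#' @param experimental Experimental mass (Da).
#' @param calculated Calculated (theoretical) mass (Da), positive.
#' @return Signed ppm error `(experimental - calculated) / calculated * 1e6`.
#' @examples
#' ppm_error(1000.001, 1000)
#' @export
ppm_error <- function(experimental, calculated) {
  if (any(calculated <= 0)) stop("calculated mass must be positive")
  (experimental - calculated) / calculated * 1e6
}

# Convolve two aggregated isotope distributions (per-nucleon bins carrying
# probability and probability-weighted mean mass). Standard aggregated
# (unit-neutron grid) approximation.
.iso_convolve <- function(a, b, prune = 1e-15) {
  na <- length(a$prob)
  nb <- length(b$prob)
  prob <- numeric(na + nb - 1)
  msum <- numeric(na + nb - 1)
  for (i in seq_len(na)) {
    if (a$prob[i] <= 0) next
    idx <- i:(i + nb - 1L)
    contrib <- a$prob[i] * b$prob
    prob[idx] <- prob[idx] + contrib
    msum[idx] <- msum[idx] + contrib * (a$mass[i] + b$mass)
  }
  mass <- ifelse(prob > 0, msum / pmax(prob, .Machine$double.xmin), NA_real_)
  keep <- which(prob > prune * max(prob))
  lo <- keep[1L]
  hi <- keep[length(keep)]
  prob <- prob[lo:hi]
  mass <- mass[lo:hi]
  # interior zero-probability bins (possible with S) get interpolated masses so
  # the grid stays monotone; they carry no probability.
  if (anyNA(mass)) {
    ok <- which(!is.na(mass))
    mass <- stats::approx(ok, mass[ok], xout = seq_along(mass), rule = 2)$y
  }
  list(prob = prob, mass = mass)
}

.iso_power <- function(base, n, prune = 1e-15) {
  result <- list(prob = 1, mass = 0)
  while (n > 0) {
    if (n %% 2 == 1) result <- .iso_convolve(result, base, prune)
    n <- n %/% 2
    if (n > 0) base <- .iso_convolve(base, base, prune)
  }
  result
}

#' Averagine elemental composition for a neutral mass
#'
#' Rounds the fractional averagine element counts scaled to the target mass;
#' the hydrogen count absorbs the rounding residual so the monoisotopic mass
#' of the composition tracks the target.
#'
#' @param neutral_mass Target monoisotopic mass (Da).
#' @return Named integer vector of element counts (C, H, N, O, S).
#' @export
averagine_composition <- function(neutral_mass) {
  n <- neutral_mass / .const$averagine_monomer_mass
  comp <- .const$averagine_composition
  counts <- round(n * comp[c("C", "N", "O", "S")])
  mono <- vapply(names(counts), function(el) .element_isotopes[[el]]$mass[1],
                 numeric(1))
  h <- max(round((neutral_mass - sum(counts * mono)) /
                   .element_isotopes$H$mass[1]), 1)
  out <- c(C = unname(counts["C"]), H = h, N = unname(counts["N"]),
           O = unname(counts["O"]), S = unname(counts["S"]))
  storage.mode(out) <- "integer"
  out
}

#' Theoretical averagine isotope distribution
#'
#' Builds the aggregated isotopic distribution of the averagine model protein
#' at the requested monoisotopic mass, by elemental convolution (binary
#' exponentiation of per-element isotope distributions on a unit-neutron
#' grid). The distribution is shifted by a constant so its monoisotopic peak
#' sits exactly at `neutral_mass`; peaks below `truncate_at` of the maximum
#' are dropped and the remainder renormalized to sum to one.
#'
#' @param neutral_mass Monoisotopic mass in Da, in `[500, 500000]`.
#' @param truncate_at Relative abundance threshold in (0, 1); default `1e-4`.
#' @return Object of class `isotope_distribution`: list with `mass` (ascending
#'   Da), `prob` (sums to 1), `neutral_mass`, `composition`, and
#'   `most_abundant_index`.
#' @examples
#' d <- averagine_isotope_distribution(10000)
#' sum(d$prob)
#' @export
averagine_isotope_distribution <- function(neutral_mass, truncate_at = 1e-4) {
  if (length(neutral_mass) != 1 || neutral_mass < 500 || neutral_mass > 5e5)
    stop("neutral_mass must lie in [500, 500000] Da")
  if (truncate_at <= 0 || truncate_at >= 1)
    stop("truncate_at must lie in (0, 1)")
  comp <- averagine_composition(neutral_mass)
  dist <- list(prob = 1, mass = 0)
  for (el in names(comp)) {
    if (comp[[el]] == 0) next
    base <- list(prob = .element_isotopes[[el]]$abundance,
                 mass = .element_isotopes[[el]]$mass)
    dist <- .iso_convolve(dist, .iso_power(base, comp[[el]]))
  }
  # constant shift: first (monoisotopic) bin pinned to the requested mass
  dist$mass <- dist$mass - dist$mass[1] + neutral_mass
  keep <- dist$prob >= truncate_at * max(dist$prob)
  lo <- which(keep)[1]
  hi <- max(which(keep))
  mass <- dist$mass[lo:hi]
  prob <- dist$prob[lo:hi]
  prob <- prob / sum(prob)
  structure(list(mass = mass, prob = prob, neutral_mass = neutral_mass,
                 composition = comp,
                 most_abundant_index = which.max(prob)),
            class = "isotope_distribution")
}

#' Most abundant isotopologue mass of a distribution
#'
#' @param dist An `isotope_distribution`.
#' @return Mass (Da) of the most abundant isotopologue.
#' @export
most_abundant_mass <- function(dist) {
  stopifnot(inherits(dist, "isotope_distribution"))
  dist$mass[dist$most_abundant_index]
}

#' @export
print.isotope_distribution <- function(x, ...) {
  cat(sprintf(
    "Averagine isotope distribution: mono %.4f Da, %d isotopologues, apex +%.3f Da\n",
    x$neutral_mass, length(x$prob), most_abundant_mass(x) - x$neutral_mass))
  invisible(x)
}
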