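# Synthetic single-fiber LC-MS run generator. Emulates the QTOF acquisition
# regime (centroid spectra, 300-3000 m/z, 1 Hz scans, resolving power 60000,
# optional quadrupole low-mass transmission floor) over co-eluting fast/slow
# sarcomeric proteoforms, and records a ground-truth manifest against which
# every downstream stage can be checked.

#' Auto charge-envelope model
#'
#' Heuristic electrospray charge envelope for an intact protein of a given
#' mass: center `round(sqrt(M) / 4.5)`, spread `max(1.5, center / 6)`.
#' Yields QTOF-plausible envelopes over 5-60 kDa.
#'
#' @param neutral_mass Neutral mass in Da.
#' @return List with `z_center` and `z_sigma`.
#' @export
auto_charge_envelope <- function(neutral_mass) {
  zc <- round(sqrt(neutral_mass) / 4.5)
  list(z_center = zc, z_sigma = max(1.5, zc / 6))
}

#' Configure a synthetic LC-MS run
#'
#' @param proteoforms Data frame with one row per simulated proteoform:
#'   columns `id`, `protein`, `family`, `neutral_mass` (monoisotopic Da,
#'   including any modifications), `n_phospho` (integer sites occupied),
#'   `abundance` (fraction; must sum to 1 within each `family`), `rt_center`
#'   and `rt_sigma` (minutes), and optionally `z_center` / `z_sigma`
#'   (NA = auto envelope from mass).
#' @param family_scale Named numeric vector scaling total signal per family
#'   (default 1 for every family).
#' @param resolving_power Instrument resolving power (m/dm FWHM).
#' @param mz_range Acquisition m/z window, default `c(300, 3000)`.
#' @param quad_low_mass Optional quadrupole transmission floor (m/z); charge
#'   states below it are not transmitted (surviving envelope renormalized).
#' @param scan_rate Scans per second (Hz).
#' @param rt_range Run retention-time span in minutes.
#' @param noise List with `baseline_level` (mean intensity of baseline /
#'   spurious peaks), `intensity_cv` (multiplicative log-normal CV),
#'   `spurious_peak_rate` (Poisson mean spurious peaks per scan), and
#'   optionally `mz_jitter_ppm` (default 0).
#' @param mode `"centroid"` (default) or `"profile"`.
#' @param base_intensity Apex intensity scale of a family at abundance 1.
#' @param truncate_at Isotope-distribution truncation threshold.
#' @param seed Integer seed; the same config generates identical output bytes.
#' @return Object of class `synthetic_run_config`.
#' @seealso [generate_run()], [fiber_fixture()]
#' @export
synthetic_run_config <- function(proteoforms,
                                 family_scale = NULL,
                                 resolving_power = 60000,
                                 mz_range = c(300, 3000),
                                 quad_low_mass = NULL,
                                 scan_rate = 1,
                                 rt_range = c(0, 6),
                                 noise = list(baseline_level = 0,
                                              intensity_cv = 0,
                                              spurious_peak_rate = 0),
                                 mode = c("centroid", "profile"),
                                 base_intensity = 1e6,
                                 truncate_at = 1e-4,
                                 seed = 1L) {
  mode <- match.arg(mode)
  req <- c("id", "protein", "family", "neutral_mass", "n_phospho",
           "abundance", "rt_center", "rt_sigma")
  missing <- setdiff(req, names(proteoforms))
  if (length(missing))
    stop("proteoforms missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(proteoforms$id)) stop("duplicate proteoform id")
  if (!("z_center" %in% names(proteoforms))) proteoforms$z_center <- NA_real_
  if (!("z_sigma" %in% names(proteoforms))) proteoforms$z_sigma <- NA_real_
  if (mz_range[1] >= mz_range[2]) stop("mz_range lower bound must be < upper")
  fam_sums <- tapply(proteoforms$abundance, proteoforms$family, sum)
  if (any(abs(fam_sums - 1) > 1e-9))
    stop("relative abundances must sum to 1 within each family; offending: ",
         paste(names(fam_sums)[abs(fam_sums - 1) > 1e-9], collapse = ", "))
  if (is.null(family_scale)) {
    fams <- unique(proteoforms$family)
    family_scale <- stats::setNames(rep(1, length(fams)), fams)
  }
  noise <- utils::modifyList(list(baseline_level = 0, intensity_cv = 0,
                                  spurious_peak_rate = 0, mz_jitter_ppm = 0),
                             noise)
  structure(list(proteoforms = proteoforms, family_scale = family_scale,
                 resolving_power = resolving_power, mz_range = mz_range,
                 quad_low_mass = quad_low_mass, scan_rate = scan_rate,
                 rt_range = rt_range, noise = noise, mode = mode,
                 base_intensity = base_intensity, truncate_at = truncate_at,
                 seed = as.integer(seed)),
            class = "synthetic_run_config")
}

# Transmitted charge states and normalized envelope weights for one species.
.charge_envelope_weights <- function(mass, z_center, z_sigma, mz_range,
                                     quad_low_mass, span = 3.5) {
  z <- seq(max(1, floor(z_center - span * z_sigma)),
           ceiling(z_center + span * z_sigma))
  mz <- mz_from_mass(mass, z)
  lo <- if (is.null(quad_low_mass)) mz_range[1] else max(mz_range[1], quad_low_mass)
  keep <- mz >= lo & mz <= mz_range[2]
  z <- z[keep]
  if (!length(z)) return(NULL)
  w <- stats::dnorm(z, z_center, z_sigma)
  list(z = z, w = w / sum(w))
}

#' Generate a synthetic LC-MS run with ground truth
#'
#' Renders every configured proteoform as a Gaussian elution profile spread
#' over a discretized Gaussian charge envelope, each charge carrying the
#' averagine isotope distribution of the proteoform's mass. In centroid mode
#' each isotopologue is emitted at its exact theoretical m/z; in profile mode
#' it is rendered as a Gaussian of FWHM `mz / resolving_power` on a local
#' grid. Multiplicative log-normal intensity noise, spurious baseline peaks
#' and optional m/z jitter are applied under the config seed, so the same
#' config always produces identical output.
#'
#' @param config A [synthetic_run_config()].
#' @return List with elements `run` (a [spectrum_run()]) and `manifest`
#'   (class `run_manifest`): per-proteoform truth (mass, abundance, retention
#'   profile, charge envelope), per-family isoform fractions, and per-protein
#'   total phosphorylation.
#' @export
generate_run <- function(config) {
  stopifnot(inherits(config, "synthetic_run_config"))
  pf <- config$proteoforms
  if (nrow(pf) < 1) stop("config must contain at least one proteoform")

  # deterministic RNG scope
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  species <- vector("list", nrow(pf))
  excluded <- logical(nrow(pf))
  for (i in seq_len(nrow(pf))) {
    m <- pf$neutral_mass[i]
    env <- if (is.na(pf$z_center[i])) auto_charge_envelope(m)
           else list(z_center = pf$z_center[i], z_sigma = pf$z_sigma[i])
    cw <- .charge_envelope_weights(m, env$z_center, env$z_sigma,
                                   config$mz_range, config$quad_low_mass)
    if (is.null(cw)) {
      warning("proteoform ", pf$id[i],
              " falls entirely outside the m/z range; excluded")
      excluded[i] <- TRUE
      species[[i]] <- list(env = env)
      next
    }
    iso <- averagine_isotope_distribution(m, config$truncate_at)
    mz <- as.vector(outer(iso$mass, cw$z, function(M, z) (M + z * .const$proton_mass) / z))
    w <- as.vector(outer(iso$prob, cw$w))
    ord <- order(mz)
    amp <- config$base_intensity * config$family_scale[[pf$family[i]]] *
      pf$abundance[i]
    species[[i]] <- list(mz = mz[ord], w = w[ord], amp = amp,
                         rt_center = pf$rt_center[i], rt_sigma = pf$rt_sigma[i],
                         env = env, charges = cw$z, charge_weights = cw$w,
                         iso = iso)
  }

  rts <- seq(config$rt_range[1], config$rt_range[2],
             by = 1 / (config$scan_rate * 60))
  nz <- config$noise
  scans <- vector("list", length(rts))
  for (si in seq_along(rts)) {
    t <- rts[si]
    mz_all <- numeric(0)
    it_all <- numeric(0)
    for (i in seq_len(nrow(pf))) {
      if (excluded[i]) next
      sp <- species[[i]]
      g <- exp(-0.5 * ((t - sp$rt_center) / sp$rt_sigma)^2)
      if (g < 1e-5) next
      mz_all <- c(mz_all, sp$mz)
      it_all <- c(it_all, sp$amp * g * sp$w)
    }
    if (nz$spurious_peak_rate > 0) {
      nspur <- stats::rpois(1, nz$spurious_peak_rate)
      if (nspur > 0) {
        smz <- stats::runif(nspur, config$mz_range[1], config$mz_range[2])
        sint <- if (nz$baseline_level > 0)
          stats::rexp(nspur, 1 / nz$baseline_level) else rep(0, nspur)
        mz_all <- c(mz_all, smz)
        it_all <- c(it_all, sint)
      }
    }
    if (nz$intensity_cv > 0 && length(it_all)) {
      sdlog <- sqrt(log(1 + nz$intensity_cv^2))
      it_all <- it_all * stats::rlnorm(length(it_all), -sdlog^2 / 2, sdlog)
    }
    if (nz$mz_jitter_ppm > 0 && length(mz_all))
      mz_all <- mz_all * (1 + stats::rnorm(length(mz_all), 0, nz$mz_jitter_ppm * 1e-6))
    ord <- order(mz_all)
    mz_all <- mz_all[ord]
    it_all <- it_all[ord]
    if (config$mode == "profile" && length(mz_all)) {
      prof <- .render_profile(mz_all, it_all, config$resolving_power)
      mz_all <- prof$mz
      it_all <- prof$intensity
    }
    scans[[si]] <- list(rt = t, mz = mz_all, intensity = it_all)
  }

  run <- spectrum_run(scans, mode = config$mode,
                      metadata = list(instrument = "synthetic QTOF",
                                      mz_range = config$mz_range,
                                      scan_rate = config$scan_rate,
                                      quad_low_mass = config$quad_low_mass,
                                      resolving_power = config$resolving_power))
  manifest <- .build_manifest(config, species, excluded)
  list(run = run, manifest = manifest)
}

# Sum of per-centroid Gaussians sampled on a union of local grids.
.render_profile <- function(mz, intensity, resolving_power, step_frac = 2.5,
                            extent = 2.5) {
  sigma <- mz / (resolving_power * 2.3548)
  grids <- lapply(seq_along(mz), function(i)
    seq(mz[i] - extent * sigma[i], mz[i] + extent * sigma[i],
        by = sigma[i] / step_frac))
  grid <- sort(unique(round(unlist(grids), 6)))
  y <- numeric(length(grid))
  for (i in seq_along(mz)) {
    idx <- which(grid >= mz[i] - extent * sigma[i] &
                 grid <= mz[i] + extent * sigma[i])
    y[idx] <- y[idx] + intensity[i] *
      exp(-0.5 * ((grid[idx] - mz[i]) / sigma[i])^2)
  }
  list(mz = grid, intensity = y)
}

.build_manifest <- function(config, species, excluded) {
  pf <- config$proteoforms
  prot_tot <- tapply(pf$abundance, pf$protein, sum)
  pdf <- data.frame(
    id = pf$id, protein = pf$protein, family = pf$family,
    neutral_mass = pf$neutral_mass,
    most_abundant_mass = vapply(seq_len(nrow(pf)), function(i) {
      if (excluded[i]) return(NA_real_)
      most_abundant_mass(species[[i]]$iso)
    }, numeric(1)),
    n_phospho = pf$n_phospho,
    abundance = pf$abundance,
    fraction_within_protein = pf$abundance / as.numeric(prot_tot[pf$protein]),
    rt_center = pf$rt_center, rt_sigma = pf$rt_sigma,
    z_center = vapply(species, function(s) s$env$z_center, numeric(1)),
    z_sigma = vapply(species, function(s) s$env$z_sigma, numeric(1)),
    excluded = excluded,
    stringsAsFactors = FALSE
  )
  pdf$charges <- lapply(species, function(s) s$charges)
  pdf$charge_weights <- lapply(species, function(s) s$charge_weights)
  fam <- stats::aggregate(abundance ~ family + protein, data = pf, FUN = sum)
  names(fam)[names(fam) == "abundance"] <- "fraction"
  fam <- fam[order(fam$family, fam$protein), ]
  rownames(fam) <- NULL
  ptot <- vapply(split(pf, pf$protein), function(d)
    sum(d$n_phospho * d$abundance) / sum(d$abundance), numeric(1))
  phos <- data.frame(protein = names(ptot), p_total = as.numeric(ptot),
                     stringsAsFactors = FALSE)
  rownames(phos) <- NULL
  structure(list(proteoforms = pdf, isoform_fractions = fam,
                 total_phosphorylation = phos, seed = config$seed),
            class = "run_manifest")
}

#' Write a ground-truth manifest as JSON
#' @param manifest A `run_manifest` from [generate_run()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d proteoforms, %d proteins, seed %d\n",
              nrow(x$proteoforms),
              length(unique(x$proteoforms$protein)), x$seed))
  invisible(x)
}
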