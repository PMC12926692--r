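# Conversion of multiply-charged m/z spectra into zero-charge neutral-mass
# spectra: (a) SNAP-style isotopically resolved charge inference with
# averagine pattern scoring, and (b) iterative nonnegative (Richardson-Lucy)
# charge-envelope deconvolution on a logarithmic mass grid.

.empty_decon <- function(method, resolving_power = NA_real_, diagnostic = NULL) {
  d <- data.frame(neutral_mass = numeric(0), intensity = numeric(0),
                  n_isotopologues = integer(0))
  d$charges <- list()
  structure(d, class = c("deconvoluted_spectrum", "data.frame"),
            method = method, resolving_power = resolving_power,
            diagnostic = diagnostic)
}

.make_decon <- function(mass, intensity, charges, n_iso, method,
                        resolving_power = NA_real_) {
  ord <- order(mass)
  d <- data.frame(neutral_mass = mass[ord], intensity = intensity[ord],
                  n_isotopologues = as.integer(n_iso[ord]))
  d$charges <- charges[ord]
  structure(d, class = c("deconvoluted_spectrum", "data.frame"),
            method = method, resolving_power = resolving_power)
}

#' @export
print.deconvoluted_spectrum <- function(x, ...) {
  cat(sprintf("<deconvoluted_spectrum> %d peaks (method: %s)\n",
              nrow(x), attr(x, "method")))
  if (nrow(x)) print.data.frame(utils::head(
    data.frame(neutral_mass = x$neutral_mass, intensity = x$intensity,
               charges = vapply(x$charges, function(z)
                 paste(z, collapse = ","), character(1))), 10))
  invisible(x)
}

# cache of averagine distributions keyed by a 200 Da mass ladder; pattern
# shape varies slowly with mass, offsets are taken from the cached rung
.iso_cache <- new.env(parent = emptyenv())
.iso_ladder <- function(mass, truncate_at = 1e-4) {
  key <- sprintf("%d_%g", as.integer(round(mass / 200)), truncate_at)
  got <- .iso_cache[[key]]
  if (is.null(got)) {
    rung <- max(500, round(mass / 200) * 200)
    got <- averagine_isotope_distribution(rung, truncate_at)
    .iso_cache[[key]] <- got
  }
  got
}

# best alignment (shift) of an observed intensity ladder onto theoretical
# probabilities; returns shift index (0-based) and cosine score against the
# full theoretical vector with unmatched positions as zeros
.align_pattern <- function(obs, theo_prob) {
  L <- length(obs)
  nt <- length(theo_prob)
  nobs <- sqrt(sum(obs^2))
  ntheo <- sqrt(sum(theo_prob^2))
  shifts <- (-(L - 1L)):(nt - 1L)
  scores <- vapply(shifts, function(s) {
    tix <- s + seq_len(L)
    ok <- tix >= 1 & tix <= nt
    if (!any(ok)) return(0)
    sum(obs[ok] * theo_prob[tix[ok]]) / (nobs * ntheo)
  }, numeric(1))
  best <- which.max(scores)
  list(shift = shifts[best], score = scores[best])
}

#' SNAP-style monoisotopic mass determination
#'
#' Groups centroided peaks into isotopic clusters of near-uniform spacing,
#' infers the charge from the spacing (`round(avg_isotope_spacing /
#' observed_spacing)`), fits the cluster intensities against the averagine
#' distribution for the implied mass, and reports the monoisotopic mass and
#' a cosine pattern score per cluster. Seeds are visited in decreasing
#' intensity; candidate charges for a seed come from the spacings to its
#' nearest neighbours. Peaks assignable to no cluster are returned in a
#' remainder list.
#'
#' @param spectrum An `averaged_spectrum`, or any peak list with `mz` and
#'   `intensity` (must be centroided).
#' @param charge_range Integer `c(zmin, zmax)`, default `c(5, 50)`.
#' @param spacing_tol Relative spacing tolerance (default 0.05): a peak is
#'   accepted into a cluster if its spacing deviates from
#'   `avg_isotope_spacing / z` by at most this fraction.
#' @param min_score Minimum cosine score to accept a cluster (default 0.6).
#' @param min_peaks Minimum isotopologues per cluster (default 3).
#' @param intensity_floor Absolute seed intensity floor; default
#'   `1e-3 * max(intensity)`.
#' @param truncate_at Averagine truncation threshold used for scoring.
#' @return Object of class `isotopic_clusters`: list with `clusters` (each a
#'   list with `mzs`, `intensities`, `inferred_charge`, `monoisotopic_mass`,
#'   `cluster_score`, `apex_intensity`, `n_peaks`) and `remainder` (data
#'   frame of unassigned peaks).
#' @export
snap_monoisotopic <- function(spectrum, charge_range = c(5, 50),
                              spacing_tol = 0.05, min_score = 0.6,
                              min_peaks = 3, intensity_floor = NULL,
                              truncate_at = 1e-4) {
  pk <- .as_peaklist(spectrum)
  n <- length(pk$mz)
  if (n == 0)
    return(structure(list(clusters = list(),
                          remainder = data.frame(mz = numeric(0),
                                                 intensity = numeric(0))),
                     class = "isotopic_clusters"))
  ord <- order(pk$mz)
  mz <- pk$mz[ord]
  it <- pk$intensity[ord]
  if (is.null(intensity_floor)) intensity_floor <- 1e-3 * max(it)
  used <- logical(n)
  tried <- logical(n)
  spacing <- .const$avg_isotope_spacing
  clusters <- list()

  near_target <- function(target, tol) {
    j1 <- findInterval(target - tol, mz) + 1L
    j2 <- findInterval(target + tol, mz)
    if (j2 < j1) return(integer(0))
    cand <- j1:j2
    cand[!used[cand]]
  }
  walk <- function(seed, z) {
    d <- spacing / z
    # adaptive: the spacing of charge z +/- 1 differs by ~1/z relative, so the
    # per-step tolerance must shrink with z to keep charges distinguishable
    tol <- min(spacing_tol, 0.45 / z) * d
    step_dir <- function(start, dir) {
      idx <- integer(0)
      cur_mz <- mz[start]
      repeat {
        nxt <- integer(0)
        for (k in 1:2) {  # allow bridging one corrupted/missing position
          nxt <- near_target(cur_mz + dir * k * d, tol)
          if (length(nxt)) break
        }
        if (!length(nxt)) break
        target <- cur_mz + dir * k * d
        cur <- nxt[which.min(abs(mz[nxt] - target))]
        idx <- c(idx, cur)
        cur_mz <- mz[cur]
        if (length(idx) > 200) break
      }
      idx
    }
    sort(unique(c(step_dir(seed, 1), seed, step_dir(seed, -1))))
  }

  repeat {
    seedable <- which(!used & !tried & it >= intensity_floor)
    if (!length(seedable)) break
    seed <- seedable[which.max(it[seedable])]
    tried[seed] <- TRUE
    # candidate charges from spacings to nearest unused neighbours
    free <- which(!used)
    pos <- match(seed, free)
    nb <- free[setdiff(pmax(pmin(pos + (-2:2), length(free)), 1), pos)]
    gaps <- abs(mz[nb] - mz[seed])
    gaps <- gaps[gaps > 1e-6]
    zc <- unique(as.integer(round(spacing / gaps)))
    zc <- unique(c(zc, zc + 1L, zc - 1L))
    zc <- zc[zc >= charge_range[1] & zc <= charge_range[2]]
    if (!length(zc)) next
    best <- NULL
    for (z in sort(zc)) {
      idx <- walk(seed, z)
      if (length(idx) < min_peaks) next
      d <- spacing / z
      # integer ladder positions (bridged gaps leave holes)
      rel <- as.integer(round((mz[idx] - mz[idx[1]]) / d))
      sp <- diff(mz[idx])
      ksteps <- pmax(diff(rel), 1L)
      step_tol <- min(spacing_tol, 0.45 / z)
      if (any(abs(sp / ksteps - d) / d > step_tol)) next
      # the mean spacing discriminates z from z +/- 1 (which differ by ~1/z)
      if (abs(mean(sp / ksteps) - d) / d > 0.15 / z) next
      m0 <- mass_from_mz(mz[idx[1]], z)
      if (m0 < 500) next
      theo <- .iso_ladder(m0, truncate_at)
      padded <- numeric(max(rel) + 1L)
      padded[rel + 1L] <- it[idx]
      al <- .align_pattern(padded, theo$prob)
      # theoretical index of each observed peak (1-based into theo)
      tix <- al$shift + rel + 1L
      ok <- tix >= 1 & tix <= length(theo$prob)
      if (sum(ok) < min_peaks) next
      offsets <- theo$mass[pmax(pmin(tix, length(theo$mass)), 1)] - theo$neutral_mass
      mono_est <- mass_from_mz(mz[idx], z) - offsets
      mono <- sum(mono_est[ok] * it[idx][ok]) / sum(it[idx][ok])
      cand <- list(idx = idx, z = z, score = al$score, mono = mono,
                   n_eff = length(idx))
      if (is.null(best) || cand$score > best$score + 1e-12) best <- cand
    }
    # short clusters carry little pattern evidence: hold them to a stricter
    # score so stray fragments of longer ladders are not promoted
    eff_min <- if (!is.null(best) && length(best$idx) < 8)
      max(min_score, 0.9) else min_score
    if (!is.null(best) && best$score >= eff_min) {
      used[best$idx] <- TRUE
      clusters[[length(clusters) + 1]] <- list(
        mzs = mz[best$idx], intensities = it[best$idx],
        inferred_charge = best$z, monoisotopic_mass = best$mono,
        cluster_score = best$score,
        apex_intensity = max(it[best$idx]),
        n_peaks = length(best$idx))
    }
  }
  remainder <- data.frame(mz = mz[!used], intensity = it[!used])
  structure(list(clusters = clusters, remainder = remainder),
            class = "isotopic_clusters")
}

#' @export
print.isotopic_clusters <- function(x, ...) {
  cat(sprintf("<isotopic_clusters> %d clusters, %d peaks unassigned\n",
              length(x$clusters), nrow(x$remainder)))
  invisible(x)
}

#' Isotopic cluster in the neutral-mass domain
#'
#' Converts a cluster's m/z ladder to neutral masses (for isotopic-pattern
#' fitting against a candidate mass).
#'
#' @param cluster One element of `snap_monoisotopic()$clusters`.
#' @return Data frame with `mass` and `intensity`.
#' @export
cluster_mass_domain <- function(cluster) {
  data.frame(mass = mass_from_mz(cluster$mzs, cluster$inferred_charge),
             intensity = cluster$intensities)
}

#' Merge per-charge isotopic clusters into a zero-charge spectrum
#'
#' Clusters whose monoisotopic masses agree within `merge_tol_ppm` are merged
#' (single linkage on the sorted masses); the merged peak carries the
#' intensity-weighted mean mass, the summed cluster apex intensities, and the
#' sorted list of supporting charges.
#'
#' Additionally, weak peaks lying within `absorb_window` Da of a peak at
#' least `absorb_ratio` times stronger are absorbed into it: such satellites
#' are almost always misaligned fragments of the stronger peak's own charge
#' ladders (one-neutron misassignments from envelope overlap), so their
#' intensity is returned to the parent. Genuine modification satellites
#' (phospho +80, oxidation +16, acetyl +42) lie outside the default window.
#'
#' @param clusters An `isotopic_clusters` object or plain list of clusters.
#' @param merge_tol_ppm Merge tolerance in ppm (default 10).
#' @param absorb_window Absorption window in Da (default 10).
#' @param absorb_ratio Minimum intensity ratio for absorption (default 3).
#' @return A `deconvoluted_spectrum` (method `"isotopic"`).
#' @export
merge_charge_evidence <- function(clusters, merge_tol_ppm = 10,
                                  absorb_window = 10, absorb_ratio = 3) {
  if (inherits(clusters, "isotopic_clusters")) clusters <- clusters$clusters
  if (!length(clusters)) return(.empty_decon("isotopic"))
  mono <- vapply(clusters, `[[`, numeric(1), "monoisotopic_mass")
  apex <- vapply(clusters, `[[`, numeric(1), "apex_intensity")
  z <- vapply(clusters, `[[`, numeric(1), "inferred_charge")
  npk <- vapply(clusters, `[[`, numeric(1), "n_peaks")
  ord <- order(mono)
  grp <- cumsum(c(1L, as.integer(diff(mono[ord]) >
                                   merge_tol_ppm * 1e-6 * mono[ord][-length(ord)])))
  gl <- split(ord, grp)
  mass <- vapply(gl, function(i) sum(mono[i] * apex[i]) / sum(apex[i]), numeric(1))
  intensity <- vapply(gl, function(i) sum(apex[i]), numeric(1))
  niso <- vapply(gl, function(i) sum(npk[i]), numeric(1))
  chg <- lapply(gl, function(i) sort(unique(as.integer(z[i]))))
  # absorb weak nearby satellites into their dominant parent
  if (length(mass) > 1 && absorb_window > 0) {
    repeat {
      changed <- FALSE
      for (i in order(intensity)) {
        if (is.na(mass[i])) next
        near <- which(!is.na(mass) & seq_along(mass) != i &
                        abs(mass - mass[i]) <= absorb_window &
                        intensity >= absorb_ratio * intensity[i])
        if (length(near)) {
          j <- near[which.max(intensity[near])]
          intensity[j] <- intensity[j] + intensity[i]
          chg[[j]] <- sort(unique(c(chg[[j]], chg[[i]])))
          niso[j] <- niso[j] + niso[i]
          mass[i] <- NA_real_
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    keep <- !is.na(mass)
    mass <- mass[keep]; intensity <- intensity[keep]
    niso <- niso[keep]; chg <- chg[keep]
  }
  .make_decon(mass, intensity, chg, niso, "isotopic")
}

#' Charge-envelope deconvolution by iterative nonnegative inversion
#'
#' Richardson-Lucy-style multiplicative deconvolution of a centroided m/z
#' spectrum onto a logarithmic neutral-mass grid (step `M / (2 R)`). Each
#' candidate (mass, charge) column renders the averagine isotope envelope of
#' that mass at that charge; columns are normalized so iteration conserves
#' flux, with unmatched probability routed to a zero-intensity miss bin that
#' suppresses masses the observed spectrum does not support. Local maxima of
#' the converged mass-domain intensity above `report_threshold` of the
#' maximum are reported as peaks; each reported mass is refined from its
#' matched observed centroids, and supporting charges are those contributing
#' more than 5% of the peak's rendered intensity.
#'
#' @param spectrum Averaged (centroid) spectrum or peak list.
#' @param mass_range `c(lo, hi)` neutral-mass search range in Da.
#' @param charge_range `c(zmin, zmax)`, default `c(5, 50)`.
#' @param resolving_power Peak-width model and grid-step parameter (default
#'   60000).
#' @param max_iter Maximum iterations (default 500).
#' @param tol Convergence threshold on the relative residual change
#'   (default 1e-4).
#' @param report_threshold Reporting threshold relative to the strongest
#'   mass peak (default 1e-3).
#' @param entropy_weight Optional entropy regularization weight (default 0).
#' @param prune_frac Columns whose matched probability mass is below this
#'   fraction are dropped before iterating (default 0.3).
#' @param min_mass_sep Minimum separation (Da) between reported masses;
#'   candidates closer than this are chained into a one-neutron isotope-alias
#'   group resolved by envelope-shape score (default 3.2).
#' @param truncate_at Averagine truncation threshold for the kernel.
#' @return A `deconvoluted_spectrum` (method `"envelope"`).
#' @export
envelope_deconvolute <- function(spectrum, mass_range,
                                 charge_range = c(5, 50),
                                 resolving_power = 60000,
                                 max_iter = 500, tol = 1e-4,
                                 report_threshold = 1e-3,
                                 entropy_weight = 0,
                                 prune_frac = 0.3,
                                 min_mass_sep = 3.2,
                                 truncate_at = 1e-3) {
  pk <- .as_peaklist(spectrum)
  if (!length(pk$mz) || all(pk$intensity == 0))
    return(.empty_decon("envelope", resolving_power))
  if (mass_range[1] >= mass_range[2]) stop("mass_range lo must be < hi")
  if (charge_range[1] > charge_range[2]) stop("zmin must be <= zmax")
  ord <- order(pk$mz)
  omz <- pk$mz[ord]
  oit <- pk$intensity[ord]
  nobs <- length(omz)

  r <- 1 + 1 / (2 * resolving_power)
  K <- ceiling(log(mass_range[2] / mass_range[1]) / log(r))
  grid <- mass_range[1] * r^(0:K)

  zs <- charge_range[1]:charge_range[2]
  entries_row <- list(); entries_col <- list(); entries_val <- list()
  col_meta_mass <- list(); col_meta_z <- list()
  ncol_total <- 0L
  for (zi in seq_along(zs)) {
    z <- zs[zi]
    theo <- .iso_ladder(mean(mass_range), truncate_at)
    offs <- theo$mass - theo$neutral_mass
    probs <- theo$prob
    nj <- length(offs)
    # mz of isotopologue j for every grid mass at this charge
    base_mz <- (grid + z * .const$proton_mass) / z
    for (j in seq_len(nj)) {
      mzj <- base_mz + offs[j] / z
      sig <- mzj / (resolving_power * 2.3548)
      near <- findInterval(mzj, omz)
      lowd <- ifelse(near >= 1, mzj - omz[pmax(near, 1)], Inf)
      highd <- ifelse(near < nobs, omz[pmin(near + 1L, nobs)] - mzj, Inf)
      pick <- ifelse(lowd <= highd, pmax(near, 1L), pmin(near + 1L, nobs))
      dist <- pmin(lowd, highd)
      g <- exp(-0.5 * (dist / sig)^2)
      hit <- dist <= 2 * sig
      w <- probs[j] * ifelse(hit, g, 0)
      keep <- w > 0
      if (any(keep)) {
        entries_row[[length(entries_row) + 1]] <- pick[keep]
        entries_col[[length(entries_col) + 1]] <- ncol_total + which(keep)
        entries_val[[length(entries_val) + 1]] <- w[keep]
      }
    }
    col_meta_mass[[zi]] <- grid
    col_meta_z[[zi]] <- rep(z, length(grid))
    ncol_total <- ncol_total + length(grid)
  }
  if (!length(entries_row))
    return(.empty_decon("envelope", resolving_power,
                        diagnostic = "no charge state explains any observed peak"))
  row_i <- unlist(entries_row)
  col_i <- unlist(entries_col)
  val <- unlist(entries_val)
  col_mass <- unlist(col_meta_mass)
  col_z <- unlist(col_meta_z)

  matched <- numeric(ncol_total)
  agg <- tapply(val, col_i, sum)
  matched[as.integer(names(agg))] <- as.numeric(agg)
  live <- which(matched >= prune_frac)
  if (!length(live))
    return(.empty_decon("envelope", resolving_power,
                        diagnostic = "no charge state explains any observed peak"))
  remap <- integer(ncol_total)
  remap[live] <- seq_along(live)
  sel <- col_i %in% live
  row_i <- row_i[sel]
  col_i <- remap[col_i[sel]]
  val <- val[sel]
  col_mass <- col_mass[live]
  col_z <- col_z[live]
  ncols <- length(live)

  # dense kernel with a final miss row keeping column sums at 1;
  # duplicate (row, col) pairs are accumulated via a linear index
  A <- matrix(0, nrow = nobs + 1L, ncol = ncols)
  lin <- (col_i - 1L) * (nobs + 1L) + row_i
  aggv <- tapply(val, lin, sum)
  A[as.integer(names(aggv))] <- as.numeric(aggv)
  A[nobs + 1L, ] <- pmax(1 - colSums(A[seq_len(nobs), , drop = FALSE]), 0)
  y <- c(oit, 0)

  h <- rep(sum(oit) / ncols, ncols)
  prev_res <- Inf
  for (iter in seq_len(max_iter)) {
    yhat <- as.numeric(A %*% h)
    ratio <- ifelse(yhat > 0, y / yhat, 0)
    h <- h * as.numeric(crossprod(A, ratio))
    if (entropy_weight > 0) {
      hm <- mean(h[h > 0])
      h <- h * exp(-entropy_weight * log(pmax(h / hm, 1e-12)))
    }
    res <- sqrt(sum((y[seq_len(nobs)] - yhat[seq_len(nobs)])^2))
    if (is.finite(prev_res) && prev_res > 0 &&
        abs(prev_res - res) / prev_res < tol) break
    prev_res <- res
  }

  # collapse to the mass domain: total h per grid mass
  mass_idx <- match(col_mass, grid)
  hm <- numeric(length(grid))
  aggh <- tapply(h, mass_idx, sum)
  hm[as.integer(names(aggh))] <- as.numeric(aggh)

  thr <- report_threshold * max(hm)
  is_max <- hm > thr &
    hm >= c(-Inf, hm[-length(hm)]) & hm >= c(hm[-1], -Inf)
  apexes <- which(is_max)
  if (!length(apexes))
    return(.empty_decon("envelope", resolving_power))
  # candidate masses: contiguous grid region around each apex, intensity
  # centroid, then refinement from the matched observed centroids
  match_cols <- function(m, z, theo) {
    offs <- theo$mass - theo$neutral_mass
    mzj <- (m + offs + z * .const$proton_mass) / z
    sig <- mzj / (resolving_power * 2.3548)
    near <- findInterval(mzj, omz)
    lowd <- ifelse(near >= 1, mzj - omz[pmax(near, 1)], Inf)
    highd <- ifelse(near < nobs, omz[pmin(near + 1L, nobs)] - mzj, Inf)
    pick <- ifelse(lowd <= highd, pmax(near, 1L), pmin(near + 1L, nobs))
    dist <- pmin(lowd, highd)
    okj <- dist <= 2 * sig
    g <- exp(-0.5 * (dist / sig)^2)
    list(row = pick[okj], w = (theo$prob * g)[okj], j = which(okj),
         offs = offs)
  }
  cand <- list()
  taken <- logical(length(grid))
  for (a in apexes[order(hm[apexes], decreasing = TRUE)]) {
    if (taken[a]) next
    loi <- a
    while (loi > 1 && hm[loi - 1] > 0.05 * hm[a] && hm[loi - 1] <= hm[loi] &&
           !taken[loi - 1]) loi <- loi - 1
    hii <- a
    while (hii < length(grid) && hm[hii + 1] > 0.05 * hm[a] &&
           hm[hii + 1] <= hm[hii] && !taken[hii + 1]) hii <- hii + 1
    taken[loi:hii] <- TRUE
    region <- loi:hii
    m_centroid <- sum(grid[region] * hm[region]) / sum(hm[region])
    cand[[length(cand) + 1]] <- list(mass = m_centroid,
                                     weight = sum(hm[region]))
  }
  # one-neutron isotope-alias resolution: masses ~k x 1.00235 Da apart render
  # nearly identical m/z ladders (shifted by k isotopologue indices), so the
  # inversion alone cannot separate them. Candidates closer than min_mass_sep
  # are chained into an alias group and the member whose averagine envelope
  # SHAPE best matches the observed index-aligned intensities wins.
  cw <- vapply(cand, `[[`, numeric(1), "weight")
  cm <- vapply(cand, `[[`, numeric(1), "mass")
  ordm <- order(cm)
  cm <- cm[ordm]; cw <- cw[ordm]
  gid <- cumsum(c(1L, as.integer(diff(cm) >= min_mass_sep)))
  shape_score <- function(m) {
    theo <- .iso_ladder(m, truncate_at)
    obsvec <- numeric(length(theo$prob))
    for (z in zs) {
      mc <- match_cols(m, z, theo)
      if (length(mc$row)) obsvec[mc$j] <- obsvec[mc$j] + oit[mc$row]
    }
    if (!any(obsvec > 0)) return(0)
    sum(obsvec * theo$prob) / sqrt(sum(obsvec^2) * sum(theo$prob^2))
  }
  refine_mass <- function(m) {
    theo <- .iso_ladder(m, truncate_at)
    ests <- numeric(0); wts <- numeric(0)
    for (z in zs) {
      mc <- match_cols(m, z, theo)
      if (!length(mc$row)) next
      ests <- c(ests, mass_from_mz(omz[mc$row], z) - mc$offs[mc$j])
      wts <- c(wts, oit[mc$row] * mc$w)
    }
    if (length(ests)) sum(ests * wts) / sum(wts) else NA_real_
  }
  accepted <- vapply(split(seq_along(cm), gid), function(ix) {
    m0 <- cm[ix][which.max(cw[ix])]
    cands <- unique(c(cm[ix], m0 + (-3:3) * .const$avg_isotope_spacing))
    refined <- vapply(cands, refine_mass, numeric(1))
    refined <- unique(round(refined[!is.na(refined)], 4))
    if (!length(refined)) return(m0)
    sc <- vapply(refined, shape_score, numeric(1))
    refined[which.max(sc)]
  }, numeric(1))
  accepted <- sort(unname(accepted))

  # restricted multiplicative refit over the accepted masses only: exact
  # averagine envelopes at the refined masses, all charges; yields the final
  # intensity split and supporting charges
  # refine each accepted mass from its matched observed centroids
  refined <- vapply(accepted, refine_mass, numeric(1))
  refined[is.na(refined)] <- accepted[is.na(refined)]

  nacc <- length(refined)
  B <- matrix(0, nrow = nobs + 1L, ncol = nacc * length(zs))
  bz <- integer(nacc * length(zs))
  bm <- integer(nacc * length(zs))
  niso <- integer(nacc)
  cc <- 0L
  for (mi in seq_len(nacc)) {
    theo <- .iso_ladder(refined[mi], truncate_at)
    niso[mi] <- length(theo$prob)
    for (z in zs) {
      cc <- cc + 1L
      bz[cc] <- z
      bm[cc] <- mi
      mc <- match_cols(refined[mi], z, theo)
      if (length(mc$row)) {
        col <- numeric(nobs + 1L)
        for (k in seq_along(mc$row)) col[mc$row[k]] <- col[mc$row[k]] + mc$w[k]
        col[nobs + 1L] <- max(1 - sum(col), 0)
        B[, cc] <- col
      } else B[nobs + 1L, cc] <- 1
    }
  }
  hb <- rep(sum(oit) / ncol(B), ncol(B))
  prev_res <- Inf
  for (iter in seq_len(max_iter)) {
    yhat <- as.numeric(B %*% hb)
    ratio <- ifelse(yhat > 0, y / yhat, 0)
    hb <- hb * as.numeric(crossprod(B, ratio))
    res <- sqrt(sum((y[seq_len(nobs)] - yhat[seq_len(nobs)])^2))
    if (is.finite(prev_res) && prev_res > 0 &&
        abs(prev_res - res) / prev_res < tol) break
    prev_res <- res
  }
  mass_int <- as.numeric(tapply(hb, bm, sum))
  charges <- lapply(seq_len(nacc), function(mi) {
    sel <- bm == mi
    zshare <- hb[sel]
    sort(bz[sel][zshare > 0.05 * sum(zshare)])
  })
  keep <- mass_int > report_threshold * max(mass_int)
  .make_decon(refined[keep], mass_int[keep], charges[keep], niso[keep],
              "envelope", resolving_power)
}

#' Export a deconvoluted peak list as CSV
#' @param decon A `deconvoluted_spectrum`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decon_csv <- function(decon, path) {
  df <- data.frame(neutral_mass_da = decon$neutral_mass,
                   intensity = decon$intensity,
                   charges = vapply(decon$charges, function(z)
                     paste(z, collapse = ";"), character(1)),
                   n_isotopologues = decon$n_isotopologues,
                   method = attr(decon, "method"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
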