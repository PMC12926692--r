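# Per-fiber quantification: top-charge-state EIC selection, isoform relative
# abundance from AUC ratios, proteoform relative abundance from deconvoluted
# peak intensities, and site-weighted total phosphorylation.

#' Select the top charge-state EIC windows of a proteoform
#'
#' Ranks the proteoform's charge states by the observed apex intensity near
#' the most abundant isotopologue m/z and returns the top 5-7 (fewer, with a
#' warning, when fewer are detected), each with an m/z window of
#' `+/- eic_halfwidth` around the apex isotopologue.
#'
#' @param averaged_spectrum An `averaged_spectrum` containing the proteoform.
#' @param neutral_mass Monoisotopic mass of the proteoform (Da).
#' @param charge_range Charges to consider, default `c(5, 50)`.
#' @param n_range `c(min, max)` charge states to select, default `c(5, 7)`.
#' @param eic_halfwidth EIC window half-width in m/z (default 0.2).
#' @param detection_floor Minimum apex intensity for a charge state to count
#'   as detected (default 0, i.e. any signal).
#' @param truncate_at Averagine truncation threshold.
#' @param label Proteoform name used in error messages.
#' @return Data frame with `charge`, `mz_apex`, `mz_lo`, `mz_hi`,
#'   `apex_intensity`, sorted by decreasing apex intensity.
#' @export
select_top_charge_states <- function(averaged_spectrum, neutral_mass,
                                     charge_range = c(5, 50),
                                     n_range = c(5, 7),
                                     eic_halfwidth = 0.2,
                                     detection_floor = 0,
                                     truncate_at = 1e-4,
                                     label = NULL) {
  pk <- .as_peaklist(averaged_spectrum)
  if (is.null(label)) label <- sprintf("%.1f Da", neutral_mass)
  iso <- averagine_isotope_distribution(neutral_mass, truncate_at)
  m_apex <- most_abundant_mass(iso)
  zs <- charge_range[1]:charge_range[2]
  apex_mz <- mz_from_mass(m_apex, zs)
  apex_int <- vapply(seq_along(zs), function(k) {
    lo <- apex_mz[k] - eic_halfwidth
    hi <- apex_mz[k] + eic_halfwidth
    j1 <- findInterval(lo, pk$mz, left.open = TRUE) + 1L
    j2 <- findInterval(hi, pk$mz, left.open = TRUE)
    if (j2 < j1) return(0)
    max(pk$intensity[j1:j2])
  }, numeric(1))
  det <- apex_int > detection_floor
  if (!any(det)) stop("proteoform not detected in averaged spectrum: ", label)
  ndet <- sum(det)
  n <- min(n_range[2], ndet)
  if (ndet < n_range[1])
    warning(sprintf("only %d charge states detected for %s (requested %d-%d)",
                    ndet, label, n_range[1], n_range[2]))
  ord <- order(apex_int, decreasing = TRUE)
  sel <- ord[seq_len(n)]
  data.frame(charge = zs[sel], mz_apex = apex_mz[sel],
             mz_lo = apex_mz[sel] - eic_halfwidth,
             mz_hi = apex_mz[sel] + eic_halfwidth,
             apex_intensity = apex_int[sel])
}

#' Isoform relative abundance from EIC AUCs
#'
#' Fractional abundance of each isoform as its AUC over the summed AUC, plus
#' all pairwise AUC ratios (e.g. MLC3F/MLC1F).
#'
#' @param aucs Named numeric vector of per-isoform EIC AUCs; at least one
#'   must be positive.
#' @return List with `fractions` (named, sums to 1) and `ratios` (data frame
#'   `numerator`, `denominator`, `ratio` over all ordered pairs with a
#'   positive denominator).
#' @examples
#' isoform_relative_abundance(c(MLC1F = 100, MLC3F = 5))
#' @export
isoform_relative_abundance <- function(aucs) {
  if (!length(aucs) || is.null(names(aucs)))
    stop("aucs must be a named vector")
  if (all(aucs == 0)) stop("all AUCs are zero")
  if (any(aucs < 0)) stop("AUCs must be non-negative")
  fractions <- aucs / sum(aucs)
  pairs <- expand.grid(numerator = names(aucs), denominator = names(aucs),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$numerator != pairs$denominator, ]
  pairs <- pairs[aucs[pairs$denominator] > 0, ]
  pairs$ratio <- as.numeric(aucs[pairs$numerator] / aucs[pairs$denominator])
  rownames(pairs) <- NULL
  list(fractions = fractions, ratios = pairs)
}

#' Proteoform relative abundance within a protein
#'
#' Each proteoform's apex peak intensity over the summed intensities of all
#' proteoforms of that protein.
#'
#' @param series A proteoform series data frame (see [proteoform_series()])
#'   with `label` and `intensity` columns, or a named numeric vector of
#'   intensities.
#' @return Named fractions summing to 1.
#' @export
proteoform_relative_abundance <- function(series) {
  if (is.numeric(series)) {
    int <- series
    if (is.null(names(int))) stop("intensities must be named")
  } else {
    if (!nrow(series)) stop("series is empty")
    int <- stats::setNames(series$intensity, series$label)
  }
  tot <- sum(int)
  if (tot <= 0) stop("total series intensity is zero")
  int / tot
}

#' Site-weighted total phosphorylation (mol Pi / mol protein)
#'
#' `sum(k_j * I_j) / sum(I_j)` over the protein's proteoform series, where
#' `k_j` is the integer number of occupied phosphosites of proteoform `j`
#' and `I_j` its peak intensity. Bounded by the maximum site count.
#'
#' @param series A proteoform series data frame with `intensity` and
#'   `n_phospho` columns.
#' @param intensities,n_phospho Alternatively, plain vectors.
#' @return Total phosphorylation in `[0, max(n_phospho)]`.
#' @examples
#' total_phosphorylation(intensities = c(50, 30, 20), n_phospho = c(0, 1, 2))
#' @export
total_phosphorylation <- function(series = NULL, intensities = NULL,
                                  n_phospho = NULL) {
  if (!is.null(series)) {
    if (!nrow(series)) stop("series is empty")
    intensities <- series$intensity
    n_phospho <- series$n_phospho
  }
  if (is.null(intensities) || is.null(n_phospho))
    stop("provide a series or both intensities and n_phospho")
  if (anyNA(n_phospho)) stop("phospho site counts must be known")
  tot <- sum(intensities)
  if (tot <= 0) stop("total series intensity is zero")
  sum(n_phospho * intensities) / tot
}

#' Analysis configuration for [fiber_report()]
#'
#' @param families Named character vector mapping protein name to isoform
#'   family (proteins absent from the map form their own family).
#' @param ppm_tol Assignment tolerance in ppm.
#' @param max_unknown_shift Largest unexplained shift to flag (Da).
#' @param eic_halfwidth EIC window half-width (m/z).
#' @param rt_halfwidth Averaging window half-width around the detected
#'   elution apex (minutes).
#' @param charge_range Charges considered by deconvolution and EIC selection.
#' @param n_range Top charge states used for EICs, default `c(5, 7)`.
#' @param pool_mod_states Pool the EIC windows of all modification states of
#'   an isoform (default TRUE; FALSE uses the unmodified proteoform only).
#' @param eic_efficiency_correction Normalize each proteoform's EIC AUC by
#'   the measured fraction of its total charge-ladder signal captured by the
#'   selected windows, so isoforms with differently shaped or clipped charge
#'   envelopes remain comparable (default FALSE: raw AUC ratios, matching
#'   the conventional reading of isoform EIC ratios).
#' @param integrate Either `"window"` (default): integrate each EIC over the
#'   protein's averaging window, which is robust when isoform pairs co-elute
#'   closely; or `"peak"`: integrate only the chromatographic peak containing
#'   the isoform's elution apex (delimited by the surrounding valleys),
#'   which excludes species sharing an m/z window at a different retention
#'   time but can truncate unresolved co-eluting pairs.
#' @param snap Additional arguments passed to [snap_monoisotopic()].
#' @param cluster_tol Centroid averaging tolerance (m/z).
#' @return List of class `fiber_analysis_config`.
#' @export
fiber_analysis_config <- function(families = character(),
                                  ppm_tol = 10,
                                  max_unknown_shift = 100,
                                  eic_halfwidth = 0.2,
                                  rt_halfwidth = 0.45,
                                  charge_range = c(5, 70),
                                  n_range = c(5, 7),
                                  pool_mod_states = TRUE,
                                  eic_efficiency_correction = FALSE,
                                  integrate = c("window", "peak"),
                                  snap = list(),
                                  cluster_tol = 0.01) {
  integrate <- match.arg(integrate)
  structure(list(families = families, ppm_tol = ppm_tol,
                 max_unknown_shift = max_unknown_shift,
                 eic_halfwidth = eic_halfwidth, rt_halfwidth = rt_halfwidth,
                 charge_range = charge_range, n_range = n_range,
                 pool_mod_states = pool_mod_states,
                 eic_efficiency_correction = eic_efficiency_correction,
                 integrate = integrate,
                 snap = snap, cluster_tol = cluster_tol),
            class = "fiber_analysis_config")
}

# rt bounds of the chromatographic peak containing apex_rt: extend outward
# from the apex until the (lightly smoothed) trace stops falling, i.e. the
# valley before any neighbouring peak, or drops below 1% of the apex
.peak_bounds <- function(trace, apex_rt) {
  y <- trace$intensity
  n <- length(y)
  if (n >= 3) y <- (c(y[1], y[-n]) + y + c(y[-1], y[n])) / 3
  i0 <- which.min(abs(trace$rt - apex_rt))
  # snap to the local maximum within a few scans of the nominal apex
  nb <- max(1, i0 - 5):min(n, i0 + 5)
  i0 <- nb[which.max(y[nb])]
  apex <- y[i0]
  floor_y <- 0.01 * apex
  rise <- 0.02 * apex
  lo <- i0
  while (lo > 1 && y[lo - 1] > floor_y && y[lo - 1] <= y[lo] + rise) lo <- lo - 1
  hi <- i0
  while (hi < n && y[hi + 1] > floor_y && y[hi + 1] <= y[hi] + rise) hi <- hi + 1
  c(trace$rt[lo], trace$rt[hi])
}

# summed intensity of a peak list inside a set of [lo, hi) windows
.sum_in_windows <- function(spectrum, windows) {
  pk <- .as_peaklist(spectrum)
  if (!length(pk$mz)) return(0)
  tot <- 0
  for (i in seq_len(nrow(windows))) {
    j1 <- findInterval(windows[i, 1], pk$mz, left.open = TRUE) + 1L
    j2 <- findInterval(windows[i, 2], pk$mz, left.open = TRUE)
    if (j2 >= j1) tot <- tot + sum(pk$intensity[j1:j2])
  }
  tot
}

# detect the elution apex of a target protein from an EIC at its predicted
# top charge-state windows
.detect_rt_apex <- function(run, base_mass, config) {
  env <- auto_charge_envelope(base_mass)
  md <- run$metadata
  mz_range <- if (!is.null(md$mz_range)) md$mz_range else c(300, 3000)
  cw <- .charge_envelope_weights(base_mass, env$z_center, env$z_sigma,
                                 mz_range, md$quad_low_mass)
  if (is.null(cw)) return(NA_real_)
  keep <- cw$z >= config$charge_range[1] & cw$z <= config$charge_range[2]
  if (!any(keep)) return(NA_real_)
  # use up to 10 candidate charges: when the acquisition's transmission
  # floor is not recorded in the metadata the top of the nominal envelope
  # may be absent from the data, and deeper candidates still locate the apex
  zs <- cw$z[keep][order(cw$w[keep], decreasing = TRUE)]
  zs <- zs[seq_len(min(10, length(zs)))]
  iso <- averagine_isotope_distribution(base_mass)
  apex_mz <- mz_from_mass(most_abundant_mass(iso), zs)
  win <- cbind(apex_mz - config$eic_halfwidth, apex_mz + config$eic_halfwidth)
  eic <- suppressWarnings(extract_eic(run, win, label = "rt-detect"))
  if (all(eic$intensity == 0)) return(NA_real_)
  eic$rt[which.max(eic$intensity)]
}

#' Full per-fiber quantification report
#'
#' Orchestrates the MS1 pipeline for one LC-MS run: per target protein the
#' elution apex is located from an EIC at predicted charge-state windows,
#' spectra are averaged across the protein's elution window, the averaged
#' spectrum is deconvoluted (SNAP-style isotopic clustering + charge-evidence
#' merging), peaks are assigned to the target table, and the three statistics
#' are computed: isoform relative abundances per family from top-charge-state
#' EIC AUC ratios (integrated over the protein's elution window), proteoform
#' relative abundances from deconvoluted apex intensities, and site-weighted
#' total phosphorylation. Deterministic: identical inputs give identical
#' reports.
#'
#' @param run A [spectrum_run()] (or path to an mzML file).
#' @param targets A `target_table`.
#' @param config A [fiber_analysis_config()].
#' @param fiber_id Identifier recorded in the report.
#' @return Object of class `quant_report`: list with `fiber_id`,
#'   `isoform_ratios` (per family: protein, AUC, fraction, detected flag),
#'   `pairwise_ratios`, `proteoform_abundances`, `total_phosphorylation`,
#'   `fit_table` (isotopic fit validation per assigned proteoform), and
#'   `provenance` (rt windows, charge states, tolerances).
#' @export
fiber_report <- function(run, targets, config = fiber_analysis_config(),
                         fiber_id = "fiber1") {
  if (is.character(run)) run <- read_mzml(run)
  stopifnot(inherits(run, "spectrum_run"))
  prot_df <- as.data.frame(targets)
  proteins <- unique(prot_df$protein_name)
  fam_map <- config$families
  fam_of <- function(p) if (p %in% names(fam_map)) fam_map[[p]] else p

  series_list <- list()
  auc_by_protein <- stats::setNames(numeric(length(proteins)), proteins)
  detected <- stats::setNames(logical(length(proteins)), proteins)
  prov_windows <- list()
  prov_charges <- list()
  fit_rows <- list()
  clusters_by_protein <- list()

  for (p in proteins) {
    base_mass <- min(prot_df$base_neutral_mass_da[prot_df$protein_name == p])
    apex_rt <- tryCatch(.detect_rt_apex(run, base_mass, config),
                        error = function(e) NA_real_)
    if (is.na(apex_rt)) {
      series_list[[p]] <- NULL
      next
    }
    rt_win <- c(apex_rt - config$rt_halfwidth, apex_rt + config$rt_halfwidth)
    prov_windows[[p]] <- rt_win
    avg <- average_spectra(run, rt_win, cluster_tol = config$cluster_tol)
    cl <- do.call(snap_monoisotopic,
                  c(list(avg, charge_range = config$charge_range),
                    config$snap))
    dec <- merge_charge_evidence(cl)
    if (!nrow(dec)) next
    asn <- assign_peaks(dec, targets, ppm_tol = config$ppm_tol,
                        max_unknown_shift = config$max_unknown_shift)
    ser <- proteoform_series(asn, p, targets)
    if (!nrow(ser)) next
    series_list[[p]] <- ser
    detected[p] <- TRUE
    clusters_by_protein[[p]] <- cl

    # isotopic fit validation for the apex proteoform
    apex_i <- which.max(ser$intensity)
    best_cl <- NULL
    for (c0 in cl$clusters) {
      m <- mass_from_mz(c0$mzs[1], c0$inferred_charge)
      if (abs(m - ser$neutral_mass[apex_i]) < 30 &&
          (is.null(best_cl) || c0$apex_intensity > best_cl$apex_intensity))
        best_cl <- c0
    }
    if (!is.null(best_cl)) {
      ft <- fit_isotopic_pattern(cluster_mass_domain(best_cl),
                                 ser$neutral_mass[apex_i])
      fit_rows[[p]] <- data.frame(
        protein = p, proteoform = ser$label[apex_i],
        calculated_mass_da = ft$calculated_mass,
        experimental_mass_da = ft$experimental_mass,
        ppm = ft$ppm, fit_score_pct = ft$fit_score,
        stringsAsFactors = FALSE)
    }

    # EIC quantification over the top charge states of each mod state. The
    # selected windows capture only part of each species' total signal (a
    # part that depends on its charge envelope and any transmission
    # clipping), so each AUC is normalized by the capture efficiency
    # measured from the averaged spectrum: (intensity inside the selected
    # windows) / (intensity across the species' full charge-state ladders).
    members <- if (config$pool_mod_states) seq_len(nrow(ser))
               else which(ser$mods == "" & ser$status == "matched")
    if (!length(members)) members <- seq_len(nrow(ser))
    charge_sel <- list()
    md <- run$metadata
    mz_lim <- if (!is.null(md$mz_range)) md$mz_range else c(-Inf, Inf)
    mz_floor <- if (!is.null(md$quad_low_mass)) md$quad_low_mass else mz_lim[1]
    total_auc <- 0
    for (k in members) {
      tc <- suppressWarnings(tryCatch(
        select_top_charge_states(avg, ser$neutral_mass[k],
                                 charge_range = config$charge_range,
                                 n_range = config$n_range,
                                 eic_halfwidth = config$eic_halfwidth,
                                 label = ser$label[k]),
        error = function(e) NULL))
      if (is.null(tc)) next
      charge_sel[[ser$label[k]]] <- tc$charge
      windows <- cbind(tc$mz_lo, tc$mz_hi)
      eff <- 1
      if (config$eic_efficiency_correction) {
        # capture efficiency measured from the species' own isotopic
        # clusters (window intensity at the selected charges over total
        # ladder intensity at all detected charges)
        M <- ser$neutral_mass[k]
        tolm <- max(10e-6 * M, 0.3)
        selcl <- Filter(function(c0)
          abs(c0$monoisotopic_mass - M) <= tolm, cl$clusters)
        if (length(selcl)) {
          ladder_tot <- sum(vapply(selcl, function(c0)
            sum(c0$intensities), numeric(1)))
          win_tot <- 0
          for (c0 in selcl) {
            wi <- which(tc$charge == c0$inferred_charge)
            if (!length(wi)) next
            inwin <- c0$mzs >= tc$mz_lo[wi[1]] & c0$mzs < tc$mz_hi[wi[1]]
            win_tot <- win_tot + sum(c0$intensities[inwin])
          }
          if (ladder_tot > 0 && win_tot > 0)
            eff <- min(win_tot / ladder_tot, 1)
        }
      }
      eic <- suppressWarnings(extract_eic(run, windows, label = ser$label[k]))
      bounds <- if (config$integrate == "peak") .peak_bounds(eic, apex_rt)
                else rt_win
      total_auc <- total_auc + auc(eic, rt_bounds = bounds) / eff
    }
    auc_by_protein[p] <- total_auc
    prov_charges[[p]] <- charge_sel
  }

  # family tables
  fams <- vapply(proteins, fam_of, character(1))
  iso_rows <- list()
  ratio_rows <- list()
  for (f in unique(fams)) {
    members <- proteins[fams == f]
    aucs <- auc_by_protein[members]
    if (all(aucs == 0)) {
      iso_rows[[f]] <- data.frame(family = f, protein = members,
                                  auc = 0, fraction = NA_real_,
                                  detected = FALSE, stringsAsFactors = FALSE)
      next
    }
    ira <- isoform_relative_abundance(aucs)
    iso_rows[[f]] <- data.frame(family = f, protein = members,
                                auc = as.numeric(aucs),
                                fraction = as.numeric(ira$fractions),
                                detected = detected[members],
                                stringsAsFactors = FALSE)
    if (nrow(ira$ratios)) {
      ira$ratios$family <- f
      ratio_rows[[f]] <- ira$ratios
    }
  }
  isoform_ratios <- do.call(rbind, iso_rows)
  rownames(isoform_ratios) <- NULL
  pairwise <- if (length(ratio_rows)) do.call(rbind, ratio_rows) else
    data.frame(numerator = character(0), denominator = character(0),
               ratio = numeric(0), family = character(0))
  rownames(pairwise) <- NULL

  # proteoform abundances and total phosphorylation
  pa_rows <- list()
  ptot_rows <- list()
  for (p in names(series_list)) {
    ser <- series_list[[p]]
    fr <- proteoform_relative_abundance(ser)
    pa_rows[[p]] <- data.frame(protein = p, label = names(fr),
                               neutral_mass = ser$neutral_mass,
                               intensity = ser$intensity,
                               fraction = as.numeric(fr),
                               n_phospho = ser$n_phospho,
                               status = ser$status,
                               shift_da = ser$shift_da,
                               stringsAsFactors = FALSE)
    sites_max <- max(vapply(targets, function(s)
      if (s$protein_name == p) s$phospho_sites_max else 0L, integer(1)))
    if (sites_max > 0)
      ptot_rows[[p]] <- data.frame(protein = p,
                                   p_total = total_phosphorylation(ser),
                                   sites_max = sites_max,
                                   stringsAsFactors = FALSE)
  }
  proteoform_abundances <- if (length(pa_rows)) do.call(rbind, pa_rows) else
    data.frame()
  rownames(proteoform_abundances) <- NULL
  phospho <- if (length(ptot_rows)) do.call(rbind, ptot_rows) else
    data.frame(protein = character(0), p_total = numeric(0),
               sites_max = integer(0))
  rownames(phospho) <- NULL
  fit_table <- if (length(fit_rows)) do.call(rbind, fit_rows) else data.frame()
  rownames(fit_table) <- NULL

  structure(list(
    fiber_id = fiber_id,
    isoform_ratios = isoform_ratios,
    pairwise_ratios = pairwise,
    proteoform_abundances = proteoform_abundances,
    total_phosphorylation = phospho,
    fit_table = fit_table,
    provenance = list(rt_windows = prov_windows,
                      charge_states = prov_charges,
                      ppm_tol = config$ppm_tol,
                      eic_halfwidth = config$eic_halfwidth,
                      rt_halfwidth = config$rt_halfwidth,
                      charge_range = config$charge_range,
                      pool_mod_states = config$pool_mod_states)
  ), class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat(sprintf("<quant_report> fiber '%s'\n", x$fiber_id))
  cat("Isoform fractions by family:\n")
  print.data.frame(x$isoform_ratios[, c("family", "protein", "fraction",
                                        "detected")])
  if (nrow(x$total_phosphorylation)) {
    cat("Total phosphorylation (mol Pi / mol protein):\n")
    print.data.frame(x$total_phosphorylation)
  }
  invisible(x)
}

#' Write a quantification report (JSON + CSV tables)
#'
#' Writes `report.json` plus `isoform_ratios.csv`,
#' `proteoform_abundance.csv` and `phospho_stoichiometry.csv` into `dir`.
#' Output is deterministic (no timestamps).
#'
#' @param report A `quant_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_quant_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$isoform_ratios,
                   file.path(dir, "isoform_ratios.csv"), row.names = FALSE)
  utils::write.csv(report$proteoform_abundances,
                   file.path(dir, "proteoform_abundance.csv"),
                   row.names = FALSE)
  utils::write.csv(report$total_phosphorylation,
                   file.path(dir, "phospho_stoichiometry.csv"),
                   row.names = FALSE)
  invisible(dir)
}
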