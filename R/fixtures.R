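# Built-in mock sarcomeric protein library and single-fiber fixture configs.
# Masses are synthetic placeholders in the plausible 5-60 kDa range for the
# twelve sarcomeric proteins tracked by the pipeline; they are NOT database
# masses and are flagged as mock throughout.

.sarcomere_mock <- data.frame(
  protein = c("ssTnI", "fsTnI", "MLC1V", "MLC1F", "MLC3F", "MLC2S",
              "MLC2F", "aTpm", "bTpm", "ssTnC", "fsTnC", "saActin"),
  gene = c("TNNI1", "TNNI2", "MYL3", "MYL1", "MYL1", "MYL2",
           "MYL11", "TPM1", "TPM2", "TNNC1", "TNNC2", "ACTA1"),
  family = c("TnI", "TnI", "ELC", "ELC", "ELC", "RLC",
             "RLC", "Tpm", "Tpm", "TnC", "TnC", "Actin"),
  class = c("slow", "fast", "slow", "fast", "fast", "slow",
            "fast", "both", "both", "slow", "fast", "both"),
  mass = c(21600, 21200, 21800, 20900, 16400, 18650,
           18950, 32680, 32830, 18380, 18100, 41350),
  phospho_sites_max = c(0L, 0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L, 0L, 0L, 0L),
  rt_center = c(1.20, 1.35, 3.80, 3.95, 4.40, 2.40,
                2.55, 3.25, 3.10, 1.80, 1.90, 4.80),
  stringsAsFactors = FALSE
)

.family_scale_default <- c(TnI = 0.3, Tpm = 0.8, ELC = 0.6, RLC = 0.6,
                           TnC = 0.2, Actin = 1.0)

#' Mock sarcomeric protein library
#'
#' The twelve fast/slow sarcomeric proteins tracked by the fixtures, with
#' synthetic (mock) monoisotopic masses, family grouping, fast/slow class and
#' default retention-time centers used by the simulator.
#'
#' @return Data frame with columns `protein`, `gene`, `family`, `class`,
#'   `mass`, `phospho_sites_max`, `rt_center`.
#' @export
sarcomere_library <- function() .sarcomere_mock

#' Proteoform target table for the mock sarcomeric library
#'
#' @return A [target_table()] with one unmodified base entry per protein.
#' @export
sarcomere_targets <- function() {
  lib <- .sarcomere_mock
  target_table(lapply(seq_len(nrow(lib)), function(i)
    proteoform_spec(lib$protein[i], lib$protein[i], lib$gene[i], lib$mass[i],
                    phospho_sites_max = lib$phospho_sites_max[i])))
}

#' Protein-to-family map of the mock library
#' @return Named character vector, protein name to family.
#' @export
sarcomere_families <- function()
  stats::setNames(.sarcomere_mock$family, .sarcomere_mock$protein)

#' Fast/slow class map of the mock library
#' @return Named character vector (`"fast"`, `"slow"`, or `"both"`).
#' @export
sarcomere_classes <- function()
  stats::setNames(.sarcomere_mock$class, .sarcomere_mock$protein)

# per-kind isoform fractions within each family, and per-protein phospho split
.fixture_fractions <- function(kind, include_mlc2s_shift) {
  frac <- switch(kind,
    slow_fiber = c(ssTnI = 0.95, fsTnI = 0.05,
                   aTpm = 0.45, bTpm = 0.55,
                   MLC1V = 0.92, MLC1F = 0.06, MLC3F = 0.02,
                   MLC2S = 0.93, MLC2F = 0.07,
                   ssTnC = 0.95, fsTnC = 0.05,
                   saActin = 1.0),
    fast_fiber = c(ssTnI = 0.04, fsTnI = 0.96,
                   aTpm = 0.65, bTpm = 0.35,
                   MLC1V = 0.03, MLC1F = 0.898, MLC3F = 0.072,
                   MLC2S = 0.05, MLC2F = 0.95,
                   ssTnC = 0.05, fsTnC = 0.95,
                   saActin = 1.0),
    hybrid_fiber = c(ssTnI = 0.50, fsTnI = 0.50,
                     aTpm = 0.55, bTpm = 0.45,
                     MLC1V = 0.46, MLC1F = 0.50, MLC3F = 0.04,
                     MLC2S = 0.50, MLC2F = 0.50,
                     ssTnC = 0.50, fsTnC = 0.50,
                     saActin = 1.0),
    stop("unknown fixture kind: ", kind)
  )
  # mono-phospho share within each phosphorylatable protein (P_total values)
  ptot <- switch(kind,
    slow_fiber = c(aTpm = 0.08, MLC2S = 0.10, MLC2F = 0.10),
    fast_fiber = c(aTpm = 0.10, MLC2S = 0.12, MLC2F = 0.12),
    hybrid_fiber = c(aTpm = 0.15, MLC2S = 0.10, MLC2F = 0.12)
  )
  list(frac = frac, ptot = ptot,
       mlc2s_shift_frac = if (include_mlc2s_shift) 0.10 else 0)
}

#' Single-fiber fixture configurations
#'
#' Builds a [synthetic_run_config()] over the mock sarcomeric library
#' emulating the fiber compositions seen in human vastus lateralis:
#' `"slow_fiber"` weights the slow isoforms (ssTnI, MLC1V, MLC2S, ssTnC)
#' high, `"fast_fiber"` the fast isoforms (fsTnI, MLC2F, MLC3F, fsTnC), and
#' `"hybrid_fiber"` mixes both. Mono-phosphorylated satellites of the
#' tropomyosins' alpha isoform and both myosin regulatory light chains are
#' included, plus (by default in the hybrid fiber) a +29.0 Da MLC2S variant
#' satellite.
#'
#' @param kind One of `"slow_fiber"`, `"fast_fiber"`, `"hybrid_fiber"`.
#' @param seed Integer seed for the generated run.
#' @param noise Noise settings passed to [synthetic_run_config()]; defaults
#'   emulate modest QTOF noise (baseline 200 counts, 10% intensity CV,
#'   5 spurious peaks per scan).
#' @param include_mlc2s_shift Include the +29 Da MLC2S satellite (default
#'   only in the hybrid fiber).
#' @param mode `"centroid"` (default) or `"profile"`.
#' @return A `synthetic_run_config`.
#' @examples
#' cfg <- fiber_fixture("hybrid_fiber", seed = 7)
#' @export
fiber_fixture <- function(kind = c("slow_fiber", "fast_fiber", "hybrid_fiber"),
                          seed = 1L,
                          noise = list(baseline_level = 200,
                                       intensity_cv = 0.1,
                                       spurious_peak_rate = 5),
                          include_mlc2s_shift = NULL,
                          mode = "centroid") {
  kind <- match.arg(kind)
  if (is.null(include_mlc2s_shift))
    include_mlc2s_shift <- kind == "hybrid_fiber"
  fx <- .fixture_fractions(kind, include_mlc2s_shift)
  lib <- .sarcomere_mock
  rows <- list()
  for (i in seq_len(nrow(lib))) {
    p <- lib$protein[i]
    f <- fx$frac[[p]]
    if (f <= 0) next
    p1 <- if (p %in% names(fx$ptot)) fx$ptot[[p]] else 0
    shift_frac <- if (p == "MLC2S") fx$mlc2s_shift_frac else 0
    f0 <- f * (1 - p1 - shift_frac)
    rows[[length(rows) + 1]] <- data.frame(
      id = p, protein = p, family = lib$family[i],
      neutral_mass = lib$mass[i], n_phospho = 0L, abundance = f0,
      rt_center = lib$rt_center[i], rt_sigma = 0.15,
      stringsAsFactors = FALSE)
    if (p1 > 0)
      rows[[length(rows) + 1]] <- data.frame(
        id = paste0(p, "_1P"), protein = p, family = lib$family[i],
        neutral_mass = proteoform_mass(lib$mass[i], c(phospho = 1)),
        n_phospho = 1L, abundance = f * p1,
        rt_center = lib$rt_center[i], rt_sigma = 0.15,
        stringsAsFactors = FALSE)
    if (shift_frac > 0)
      rows[[length(rows) + 1]] <- data.frame(
        id = paste0(p, "_m29"), protein = p, family = lib$family[i],
        neutral_mass = lib$mass[i] + 29.0,
        n_phospho = 0L, abundance = f * shift_frac,
        rt_center = lib$rt_center[i], rt_sigma = 0.15,
        stringsAsFactors = FALSE)
  }
  pf <- do.call(rbind, rows)
  synthetic_run_config(
    proteoforms = pf,
    family_scale = .family_scale_default,
    resolving_power = 60000,
    mz_range = c(300, 3000),
    quad_low_mass = 650,
    scan_rate = 1,
    rt_range = c(0, 6),
    noise = noise,
    mode = mode,
    seed = seed
  )
}
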