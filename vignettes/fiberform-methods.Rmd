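---
title: "Methods: MS1 proteoform quantification in single muscle fibers"
author: "fiberform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MS1 proteoform quantification in single muscle fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`fiberform` implements an MS1-level top-down proteomics pipeline for single
skeletal muscle fibers: intact sarcomeric proteins are electrosprayed as
multiply-protonated charge-state envelopes, acquired on a QTOF instrument,
and quantified at the proteoform level without digestion or MS/MS. The
package covers the full desk-side analysis chain — simulation of realistic
runs with ground truth, mzML input/output, retention-time spectrum
averaging, charge-state deconvolution to zero-charge mass spectra,
averagine isotopic-pattern validation, accurate-mass proteoform assignment,
and per-fiber quantification — and is organized so that every stage can be
verified against the simulator's manifest.

# The measurement model

An intact protein of monoisotopic mass $M$ observed at charge $z$ appears at

$$ m/z = \frac{M + z\,m_p}{z}, \qquad m_p = 1.007276466\ \mathrm{Da}, $$

and carries an isotopologue ladder spaced by $\approx 1.00235/z$ m/z. With
no sequence available at MS1, the isotope pattern of a mass $M$ is modelled
by the standard averagine pseudo-residue (monomer 111.1254 Da; fractional
composition C 4.9384, H 7.7583, N 1.3577, O 1.4773, S 0.0417). The element
counts are `round(M / 111.1254 × composition)` with hydrogen absorbing the
rounding residual, and the aggregated isotope distribution is computed by
exact per-element convolution on a unit-neutron grid (binary
exponentiation; bins below `truncate_at` of the apex are dropped and the
rest renormalized). `truncate_at = 1e-4` bounds the ladder length with no
visible effect on quantification. Internally every mass is monoisotopic;
the most abundant isotopologue mass is derived from the distribution when a
display convention calls for it, and both are labelled in outputs because
vendor reports are ambiguous on this point.

# The synthetic-data generator

`generate_run()` renders each configured proteoform as

* a Gaussian elution profile (default `rt_sigma` 0.15 min — a typical
  sharpness for a short reversed-phase gradient at 5 µL/min),
* spread over a discretized Gaussian charge envelope. When no envelope is
  given, `z_center = round(sqrt(M)/4.5)` and
  `z_sigma = max(1.5, z_center/6)`, which gives plausible QTOF envelopes
  over 5–60 kDa (about +20 for 9 kDa, +30 for 18 kDa, +45 for 41 kDa),
* each transmitted charge carrying the averagine ladder of the proteoform's
  total mass. Charges whose apex falls below the quadrupole low-mass
  setting (650 m/z in the fixtures, emulating the acquisition regime) or
  outside 300–3000 m/z are clipped and the surviving envelope is
  renormalized, so configured abundances are defined over *transmitted*
  ions.

Scans are emitted at 1 Hz. In centroid mode each isotopologue appears at
its exact theoretical m/z; in profile mode it is rendered as a Gaussian of
FWHM $= m/z / R$ with $R$ = 60 000 by default. Noise consists of
multiplicative log-normal intensity noise (`intensity_cv`), Poisson-count
spurious peaks with exponential intensities (`spurious_peak_rate`,
`baseline_level`), and optional m/z jitter (`mz_jitter_ppm`, default 0).
All randomness is drawn under the config seed in a fixed order, so the same
config yields byte-identical mzML.

The built-in single-fiber fixtures place twelve sarcomeric proteins
(troponin I/C fast and slow isoforms, essential and regulatory myosin light
chains, both tropomyosins, sarcomeric actin) at *synthetic mock masses* in
the 5–60 kDa range — they are deliberately not database masses. Slow,
fast and hybrid fiber compositions weight the slow-program and fast-program
isoforms the way heterogeneous vastus lateralis fibers do; tropomyosin and
actin are treated as present in every fiber type. Mono-phosphorylated
satellites of the alpha tropomyosin and both regulatory light chains are
included at stoichiometries of 0.08–0.15 mol Pi/mol, and the hybrid fiber
carries a +29.0 Da MLC2S variant satellite at 10% of the MLC2S pool.
Within-family abundances sum to one; family-to-family dynamic range is set
by a fixed scale vector (actin 1.0 down to troponin C 0.2), an
order-of-magnitude spread chosen as realistic in the absence of printed
values. The manifest records, per proteoform, the true mass, abundance,
elution profile and transmitted envelope, and per protein the isoform
fractions and total phosphorylation recomputable by the quantification
formulas — it is the oracle for every end-to-end test.

What the generator does *not* emulate: chromatographic tailing, detector
saturation, ion-mobility effects, m/z-dependent calibration drift
(`mz_jitter` is white, not systematic), and electrospray response
differences between proteins. Passing tests therefore demonstrate
correctness of the computational chain under a known instrument model, not
robustness to every artefact of real data.

# Spectrum averaging, EICs, and AUC

Averaging over a retention-time window pools centroid peaks from all scans
in the window, clusters them with a 0.01 m/z tolerance (about FWHM/1.7 at
m/z 1000 and $R$ = 60 000), and reports the intensity-weighted mean m/z and
the mean intensity over window scans (a scan without the peak contributes
zero). EIC windows are half-open $[lo, hi)$; overlapping windows are merged
with a warning so no peak is double-counted. AUC is the trapezoidal
integral over retention time, exactly additive over a shared endpoint, and
within 1% of the closed-form Gaussian area at 1 Hz sampling and
`rt_sigma` 0.15 min.

# Deconvolution

Two routes produce zero-charge spectra:

**Isotopically resolved (SNAP-style), the default.** Peaks are grouped
into ladders of near-uniform spacing by walking from intensity-ordered
seeds; the charge is `round(1.00235 / spacing)`. Two details matter in
crowded spectra. First, the per-step spacing tolerance is
`min(0.05, 0.45/z)` relative — at high charge the ladders of $z$ and
$z \pm 1$ differ by only $\sim 1/z$, so a fixed 5% tolerance would let a
ladder be walked with the wrong charge; the mean spacing is additionally
required to match to $0.15/z$. Second, when two species' ladders approach
within the averaging tolerance, the merged centroid is displaced and would
break the walk; the walk may therefore bridge one corrupted position, and
alignment works on integer ladder positions with holes. Each cluster is
aligned against the averagine pattern for its implied mass (cosine score;
clusters shorter than 8 peaks must score ≥ 0.9, others ≥ 0.6), and the
monoisotopic mass is the intensity-weighted mean of
$z\,(m/z - m_p) - \delta_j$ over matched isotopologues, where $\delta_j$ is
the theoretical offset of isotopologue $j$ from the monoisotopic peak —
this stays correct even when the monoisotopic bin itself is below the
rendering threshold, as it is above ~35 kDa. `merge_charge_evidence()`
merges per-charge masses agreeing within 10 ppm (intensity = summed cluster
apexes, mass = intensity-weighted mean) and then absorbs weak satellites
within ±10 Da of a ≥3× stronger peak back into it: such satellites are
almost always misaligned fragments of the parent's own ladders
(one-neutron misassignments caused by envelope overlap), while the genuine
modification deltas handled here (+15.99, +42.01, +79.97 Da) and the
+29 Da variant lie outside the window. The package therefore does not claim
to resolve two distinct proteoforms closer than ~10 Da — at these masses
the isotope envelopes themselves overlap almost completely.

**Charge-envelope inversion.** `envelope_deconvolute()` is an iterative
nonnegative (Richardson–Lucy-type) inversion on a logarithmic mass grid of
step $M / (2R)$ — the stated resolving power sets both the peak-width model
and the grid step, which is how a "deconvolution resolving power" parameter
is interpreted here. Unknowns are (mass, charge) pairs; each column renders
the averagine ladder of its mass at its charge onto the observed centroids
(Gaussian-weighted within 2σ of the predicted position), normalized so
multiplicative updates conserve flux, with unmatched probability routed to
a zero-intensity miss bin that suppresses unsupported masses. Columns with
under 30% matched probability are pruned before iterating; iteration stops
when the relative residual change falls below $10^{-4}$ (or 500
iterations). An optional entropy regularizer (weight 0 by default) damps
the update. Because a mass shifted by $k \times 1.00235$ Da renders a
nearly identical m/z ladder, local maxima of the converged solution closer
than 3.2 Da are chained into an alias group; the member whose envelope
*shape* best matches the index-aligned observed intensities wins, its mass
is refined from the matched centroids, and intensities are re-fit by a
restricted multiplicative inversion over the accepted masses only. The
initialization is uniform and nothing is drawn at random, so the result is
deterministic.

# Isotopic fit validation

`fit_isotopic_pattern()` aligns the averagine distribution of a candidate
mass to an observed mass-domain cluster by a single offset (±0.5 Da — less
than one isotopologue spacing, so an off-by-one candidate cannot re-align)
searched on a 1 mDa grid with parabolic refinement, plus a free scale. The
fit score is 100 × the cosine between theoretical probabilities and matched
observed intensities, with unmatched theoretical peaks counted as zeros and
matched intensities softly weighted by a Gaussian (σ = 0.1 Da) of the
residual distance — the weighting makes the score smooth in the offset;
because the cosine is invariant to a common factor, the score itself is
exactly scale-free and a self-match scores 100. The reported experimental
mass is refined as the intensity-weighted mean matched-peak residual added
to the candidate, which is what makes sub-ppm reporting possible at 30 kDa
on a 1 mDa search grid. The score formula used by vendor software is not
public; only the contract (100 for a perfect match, scale-free, strictly
decreasing under pattern distortion) is asserted.

# Assignment and shift flagging

For each deconvoluted peak, all targets' base masses plus allowed
modification combinations (phospho up to the target's site count, ≤2
oxidations, ≤1 acetyl — caps exposed in the API) are enumerated; the best
match minimizes |ppm| within a 10 ppm tolerance (QTOF-appropriate; the
caps bound the search so the tolerance cannot be satisfied by stacking
implausible modifications). Ties break by fewest added modifications, then
lexicographic id, making assignment a total order and hence deterministic.
A peak matching nothing but lying within 100 Da of a target's series is
reported `shifted`, with the shift quoted relative to the target's
*unmodified* state and rounded to 0.1 Da — unexplained deltas are surfaced,
never silently absorbed into the mass error, which is precisely how a
+29 Da variant satellite becomes visible. Interpretation of such shifts is
out of scope.

# Per-fiber quantification

`fiber_report()` orchestrates, per target protein: elution-apex detection
from an EIC at up to ten predicted charge-state windows (the charge prior
is the same envelope model the simulator documents; on real data it is an
approximation), averaging over apex ± 0.45 min (±3 elution sigmas),
SNAP deconvolution, assignment, and then the three statistics:

* **Isoform relative abundance** — the top 5–7 most intense charge states
  of each proteoform give ±0.2 m/z EIC windows around the most abundant
  isotopologue (±0.2 covers the apex cluster at $R$ = 60 000 without
  bridging adjacent charges for $z \le 40$); the AUC ratio across family
  members is the isoform fraction. Modification states are pooled into the
  isoform's windows by default, since isoform-level EICs trace the protein
  rather than its modification states. AUCs are integrated over the
  protein's elution window (recorded in provenance) rather than the full
  trace, because an m/z window can coincide with another protein's ladder
  at a different retention time. A `"peak"` integration mode (valley-bounded)
  and an optional capture-efficiency normalization are available; both are
  off by default because valley-bounding truncates closely co-eluting
  isoform pairs and the efficiency estimate inherits cluster noise —
  measured on the fixtures, plain window integration recovers isoform
  fractions with the smallest error.
* **Proteoform relative abundance** — each series member's apex intensity
  over the series total (apex rather than integrated cluster intensity by
  default; both conventions are defensible and the choice is recorded).
* **Total phosphorylation** — $\sum_j k_j I_j / \sum_j I_j$ with $k_j$ the
  occupied site count, algebraically identical to the fraction-weighted
  mean of $k_j$ and bounded by the site maximum.

Undetected family members are reported as zero-fraction rows with a
detection flag rather than dropped, keeping cross-fiber tables rectangular.
No cross-fiber normalization or inferential statistics are computed — the
reports are descriptive, per fiber.

# Numerical choices and degenerate inputs

Empty spectra deconvolve to empty results; an all-zero AUC family reports
`NA` fractions; a window overlapping no scan, an empty series, and an
unknown modification name are errors that name the offending input. Merge
and assignment tie-breaks are total orders. The averaged-spectrum
clustering tolerance (0.01 m/z), EIC half-width (0.2 m/z), SNAP score
thresholds (0.6 / 0.9), absorption window (10 Da) and alias-group span
(3.2 Da) are all config-exposed with the defaults above.

# Problem sizes used in the shipped tests

The test suite simulates short runs (0.6–1 min at 1 Hz) for unit-level
checks and full 6-min twelve-protein fiber runs for end-to-end checks; the
seed-robustness study uses 20 hybrid-fiber seeds at 10% intensity CV.
These sizes were chosen so the whole chain — including deconvolution at
60 000 resolving power — exercises realistic peak densities while a full
run of the suite stays comfortably within a coffee break.

# Known limitations

* Averagine is an approximation: true elemental compositions (especially
  cysteine-poor or phospho-heavy proteins) shift isotope patterns slightly;
  no sequence-based composition is attempted.
* Charge-state behaviour on real instruments depends on solvent and source
  conditions; the square-root envelope prior is a reasonable default, not
  a law.
* Species closer than ~10 Da in mass, or co-eluting within a scan or two
  with overlapping envelopes at low m/z, are quantified with reduced
  accuracy; the satellite-absorption step trades resolution below 10 Da for
  robustness against one-neutron misassignment.
* The isoform AUC ratio inherits any ionization-efficiency difference
  between isoforms; on synthetic data this appears as a small bias for
  species with strongly clipped envelopes (the smallest light chain), and
  on real data it is unknowable at MS1.
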