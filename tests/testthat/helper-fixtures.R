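# Shared synthetic fixtures, generated once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- maker()
  .fx_cache[[name]]
}

# one 18 kDa proteoform plus its mono-phospho satellite, short run, no noise
two_proteoform_config <- function(seed = 3, noise = list()) {
  pf <- data.frame(
    id = c("P1", "P1_1P"), protein = "P1", family = "F1",
    neutral_mass = c(18000, 18000 + mass_constants()$mod_deltas[["phospho"]]),
    n_phospho = c(0L, 1L), abundance = c(0.8, 0.2),
    rt_center = 0.5, rt_sigma = 0.15, stringsAsFactors = FALSE)
  synthetic_run_config(pf, rt_range = c(0, 1), seed = seed, noise = noise)
}

# three co-eluting proteoforms with an envelope confined to charges 12-25
three_proteoform_config <- function(seed = 7, noise = list()) {
  pf <- data.frame(
    id = c("A", "B", "C"), protein = c("A", "B", "C"),
    family = c("FA", "FB", "FC"),
    neutral_mass = c(17800, 18000, 18450),
    n_phospho = 0L, abundance = 1,
    rt_center = 0.5, rt_sigma = 0.15,
    z_center = 18.5, z_sigma = 2.0, stringsAsFactors = FALSE)
  synthetic_run_config(pf, family_scale = c(FA = 0.5, FB = 1, FC = 0.25),
                       rt_range = c(0, 1), seed = seed, noise = noise)
}

noise_free <- list(baseline_level = 0, intensity_cv = 0,
                   spurious_peak_rate = 0)

two_proteoform_run <- function()
  cached("two_run", function() generate_run(two_proteoform_config()))

three_proteoform_run <- function()
  cached("three_run", function() generate_run(three_proteoform_config()))

hybrid_noise_free_run <- function()
  cached("hybrid_nf", function()
    generate_run(fiber_fixture("hybrid_fiber", seed = 11,
                               noise = noise_free)))

# averaged spectrum across the full elution peak of the small runs
avg_of <- function(runout, lo = 0.35, hi = 0.65)
  average_spectra(runout$run, c(lo, hi))
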