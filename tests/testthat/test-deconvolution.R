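# Charge-state deconvolution: SNAP-style isotopic clustering, charge-evidence
# merging, and iterative envelope inversion.

test_that("cluster spacing determines the charge", {
  # a clean ladder spaced at exactly 1.00235/10 m/z implies charge 10
  spacing <- mass_constants()$avg_isotope_spacing
  iso <- averagine_isotope_distribution(12000)
  mzs <- 1201.2 + (seq_along(iso$prob) - 1) * spacing / 10
  cl <- snap_monoisotopic(list(mz = mzs, intensity = iso$prob))
  expect_equal(length(cl$clusters), 1)
  expect_equal(cl$clusters[[1]]$inferred_charge, 10)
})

test_that("single isolated peaks go to the remainder, not a cluster", {
  cl <- snap_monoisotopic(list(mz = c(800, 950.3, 1204.77),
                               intensity = c(10, 5, 2)))
  expect_equal(length(cl$clusters), 0)
  expect_equal(nrow(cl$remainder), 3)
})

test_that("noise-free clusters recover the monoisotopic mass to 2 ppm", {
  out <- two_proteoform_run()
  cl <- snap_monoisotopic(avg_of(out))
  mono <- vapply(cl$clusters, `[[`, numeric(1), "monoisotopic_mass")
  sc <- vapply(cl$clusters, `[[`, numeric(1), "cluster_score")
  main <- which(abs(mono - 18000) < 1)
  expect_gt(length(main), 5)
  expect_lt(max(abs(ppm_error(mono[main], 18000))), 2)
  expect_true(all(sc[main] > 0.99))
})

test_that("charge inference is exact on noise-free isotopically resolved data", {
  for (mass in c(8000, 20000, 35000)) {
    pf <- data.frame(id = "p", protein = "p", family = "f",
                     neutral_mass = mass, n_phospho = 0L, abundance = 1,
                     rt_center = 0.3, rt_sigma = 0.1, stringsAsFactors = FALSE)
    out <- generate_run(synthetic_run_config(pf, rt_range = c(0, 0.6),
                                             seed = 2))
    avg <- average_spectra(out$run, c(0.2, 0.4))
    cl <- snap_monoisotopic(avg, charge_range = c(5, 70))
    true_z <- out$manifest$proteoforms$charges[[1]]
    for (c0 in cl$clusters) {
      # every cluster's charge must be one the generator actually rendered,
      # and its implied mass must be the true mass
      expect_true(c0$inferred_charge %in% true_z)
      expect_lt(abs(ppm_error(c0$monoisotopic_mass, mass)), 5)
    }
    # all central (high-weight) charges are recovered
    w <- out$manifest$proteoforms$charge_weights[[1]]
    central <- true_z[w > 0.25 * max(w)]
    found_z <- vapply(cl$clusters, `[[`, numeric(1), "inferred_charge")
    expect_true(all(central %in% found_z))
  }
})

test_that("merging combines charge evidence and keeps distinct masses apart", {
  mk <- function(mono, z, apex) list(mzs = mz_from_mass(mono, z) + 0:4 * 1.00235 / z,
                                     intensities = rep(apex, 5),
                                     inferred_charge = z,
                                     monoisotopic_mass = mono,
                                     cluster_score = 0.99,
                                     apex_intensity = apex, n_peaks = 5L)
  two_same <- list(mk(15000.00, 14, 100), mk(15000.02, 15, 50))
  dec <- merge_charge_evidence(two_same)
  expect_equal(nrow(dec), 1)
  expect_equal(dec$charges[[1]], c(14L, 15L))
  expect_equal(dec$intensity, 150)
  expect_equal(dec$neutral_mass, (15000 * 100 + 15000.02 * 50) / 150,
               tolerance = 1e-9)
  # two clusters 100 ppm apart stay separate (comparable intensity)
  apart <- list(mk(15000, 14, 100), mk(15001.5, 15, 90))
  expect_equal(nrow(merge_charge_evidence(apart)), 2)
  # weak satellites within the absorption window collapse into the parent
  ghost <- list(mk(15000, 14, 1000), mk(15001.0, 15, 20))
  absorbed <- merge_charge_evidence(ghost)
  expect_equal(nrow(absorbed), 1)
  expect_equal(absorbed$intensity, 1020)
})

test_that("the merged mass list matches the manifest one-to-one", {
  out <- three_proteoform_run()
  dec <- merge_charge_evidence(snap_monoisotopic(avg_of(out),
                                                 charge_range = c(10, 30)))
  truth <- sort(out$manifest$proteoforms$neutral_mass)
  main <- dec[dec$intensity > 0.01 * max(dec$intensity), ]
  expect_equal(nrow(main), 3)
  expect_lt(max(abs(ppm_error(sort(main$neutral_mass), truth))), 5)
})

test_that("envelope deconvolution recovers masses and intensity ratios", {
  out <- two_proteoform_run()
  dec <- envelope_deconvolute(avg_of(out), mass_range = c(17500, 18500),
                              charge_range = c(12, 48))
  expect_equal(nrow(dec), 2)
  expect_lt(max(abs(ppm_error(dec$neutral_mass,
                              c(18000, 18079.96633)))), 5)
  frac <- dec$intensity / sum(dec$intensity)
  expect_lt(max(abs(frac - c(0.8, 0.2))), 0.05)
  # intensity conservation against the observed spectrum
  avg <- avg_of(out)
  expect_lt(abs(sum(dec$intensity) - sum(avg$intensity)) /
              sum(avg$intensity), 0.10)
  # supporting charges are the rendered ones
  expect_true(all(dec$charges[[1]] %in%
                    out$manifest$proteoforms$charges[[1]]))
})

test_that("degenerate envelope inputs give empty results", {
  empty <- envelope_deconvolute(list(mz = numeric(0), intensity = numeric(0)),
                                mass_range = c(1000, 2000))
  expect_equal(nrow(empty), 0)
  zeros <- envelope_deconvolute(list(mz = c(500, 600),
                                     intensity = c(0, 0)),
                                mass_range = c(1000, 2000))
  expect_equal(nrow(zeros), 0)
  # no charge in range explains the data
  none <- envelope_deconvolute(list(mz = c(500.1, 500.2),
                                    intensity = c(5, 5)),
                               mass_range = c(40000, 41000),
                               charge_range = c(5, 6))
  expect_equal(nrow(none), 0)
})

test_that("a brute-force grid search reproduces the SNAP peak set", {
  pf <- data.frame(id = c("a", "b"), protein = c("a", "b"), family = "f",
                   neutral_mass = c(9000, 9500), n_phospho = 0L,
                   abundance = c(0.6, 0.4), rt_center = 0.3, rt_sigma = 0.1,
                   z_center = 9, z_sigma = 1.0, stringsAsFactors = FALSE)
  out <- generate_run(synthetic_run_config(pf, rt_range = c(0, 0.6), seed = 4))
  avg <- average_spectra(out$run, c(0.2, 0.4))
  dec <- merge_charge_evidence(snap_monoisotopic(avg, charge_range = c(7, 11)))
  main <- dec$neutral_mass[dec$intensity > 0.05 * max(dec$intensity)]
  oracle <- oracle_grid_deconvolute(avg$mz, avg$intensity, charges = 7:11)
  expect_equal(length(main), 2)
  for (m in main)
    expect_lt(min(abs(oracle - m)), 10e-6 * m + 0.02)
})

test_that("mass error grows monotonically with m/z noise", {
  jitters <- c(0, 3, 12)
  med_err <- vapply(jitters, function(j) {
    errs <- vapply(1:6, function(s) {
      pf <- data.frame(id = "p", protein = "p", family = "f",
                       neutral_mass = 12000, n_phospho = 0L, abundance = 1,
                       rt_center = 0.3, rt_sigma = 0.1,
                       stringsAsFactors = FALSE)
      cfg <- synthetic_run_config(pf, rt_range = c(0, 0.6), seed = s,
                                  noise = list(intensity_cv = 0.05,
                                               mz_jitter_ppm = j,
                                               baseline_level = 0,
                                               spurious_peak_rate = 0))
      out <- generate_run(cfg)
      avg <- average_spectra(out$run, c(0.2, 0.4))
      dec <- merge_charge_evidence(snap_monoisotopic(avg))
      abs(ppm_error(dec$neutral_mass[which.max(dec$intensity)], 12000))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) >= 0))
})
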