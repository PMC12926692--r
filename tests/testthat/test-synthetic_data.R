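# Synthetic LC-MS run generator: construction guarantees, determinism, and
# manifest consistency.

test_that("noise-free centroids land exactly on theoretical isotopologue m/z", {
  out <- two_proteoform_run()
  manifest <- out$manifest
  # predicted m/z set from the generator's own inputs
  pred <- c()
  for (i in 1:2) {
    iso <- averagine_isotope_distribution(manifest$proteoforms$neutral_mass[i])
    for (z in manifest$proteoforms$charges[[i]])
      pred <- c(pred, mz_from_mass(iso$mass, z))
  }
  pred <- sort(pred)
  scan <- out$run$scans[[31]]  # at the elution apex
  expect_gt(length(scan$mz), 100)
  nearest <- vapply(scan$mz, function(x) min(abs(pred - x)), numeric(1))
  expect_lt(max(nearest), 1e-6)
})

test_that("same config and seed give byte-identical mzML", {
  cfg <- two_proteoform_config(seed = 9,
                               noise = list(baseline_level = 50,
                                            intensity_cv = 0.2,
                                            spurious_peak_rate = 3))
  f1 <- withr::local_tempfile(fileext = ".mzML")
  f2 <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(generate_run(cfg)$run, f1)
  write_mzml(generate_run(cfg)$run, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed changes the bytes
  cfg2 <- two_proteoform_config(seed = 10,
                                noise = list(baseline_level = 50,
                                             intensity_cv = 0.2,
                                             spurious_peak_rate = 3))
  f3 <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(generate_run(cfg2)$run, f3)
  expect_false(unname(tools::md5sum(f1)) == unname(tools::md5sum(f3)))
})

test_that("rendered intensity is conserved in the configured proportions", {
  pf <- data.frame(id = c("X", "Y"), protein = c("X", "Y"), family = "F",
                   neutral_mass = c(15000, 21000), n_phospho = 0L,
                   abundance = c(0.7, 0.3), rt_center = 0.5, rt_sigma = 0.15,
                   stringsAsFactors = FALSE)
  out <- generate_run(synthetic_run_config(pf, rt_range = c(0, 1), seed = 1))
  # noise-free construction: each species' total equals its single-species
  # rendering scaled by its abundance
  pf1 <- pf[1, ]; pf1$abundance <- 1
  pf2 <- pf[2, ]; pf2$abundance <- 1
  one <- generate_run(synthetic_run_config(pf1, rt_range = c(0, 1), seed = 1))
  two <- generate_run(synthetic_run_config(pf2, rt_range = c(0, 1), seed = 1))
  sum_run <- function(o) sum(vapply(o$run$scans, function(s)
    sum(s$intensity), numeric(1)))
  mixed <- sum_run(out)
  expect_equal(0.7 * sum_run(one) + 0.3 * sum_run(two), mixed,
               tolerance = 1e-6)
  # and the in-mix ratio matches 0.7 : 0.3
  expect_equal(0.7 * sum_run(one) / mixed, 0.7, tolerance = 1e-6)
})

test_that("proteoforms whose envelope falls outside the m/z range are excluded", {
  pf <- data.frame(id = "far", protein = "far", family = "F",
                   neutral_mass = 18000, n_phospho = 0L, abundance = 1,
                   rt_center = 0.3, rt_sigma = 0.1,
                   z_center = 3, z_sigma = 0.5, stringsAsFactors = FALSE)
  cfg <- synthetic_run_config(pf, rt_range = c(0, 0.6), seed = 1)
  expect_warning(out <- generate_run(cfg), "outside")
  expect_true(out$manifest$proteoforms$excluded[1])
  expect_true(all(vapply(out$run$scans, function(s) length(s$mz),
                         integer(1)) == 0))
})

test_that("fixture kinds encode the intended fiber compositions", {
  classes <- sarcomere_classes()
  for (kind in c("slow_fiber", "fast_fiber", "hybrid_fiber")) {
    cfg <- fiber_fixture(kind, seed = 1)
    pf <- cfg$proteoforms
    fam_sums <- tapply(pf$abundance, pf$family, sum)
    expect_true(all(abs(fam_sums - 1) < 1e-9))
    # total phosphorylation of the tropomyosin alpha isoform stays in range
    a <- pf[pf$protein == "aTpm", ]
    ptot <- sum(a$n_phospho * a$abundance) / sum(a$abundance)
    expect_gte(ptot, 0)
    expect_lte(ptot, 2)
  }
  slow <- fiber_fixture("slow_fiber")$proteoforms
  by_fam <- split(slow, slow$family)
  fast_share <- vapply(by_fam, function(d)
    sum(d$abundance[classes[d$protein] == "fast"]), numeric(1))
  fast_share <- fast_share[!names(fast_share) %in% c("Actin", "Tpm")]
  expect_lt(mean(fast_share), 0.1)
  hyb <- fiber_fixture("hybrid_fiber")$proteoforms
  expect_gt(sum(hyb$abundance[hyb$protein == "ssTnI"]), 0.1)
  expect_gt(sum(hyb$abundance[hyb$protein == "fsTnI"]), 0.1)
  expect_true("MLC2S_m29" %in% hyb$id)
  expect_false("MLC2S_m29" %in% fiber_fixture("slow_fiber")$proteoforms$id)
  expect_error(fiber_fixture("medium_fiber"), "arg")
})

test_that("manifest quantities are self-consistent with the formulas", {
  out <- hybrid_noise_free_run()
  man <- out$manifest
  pf <- man$proteoforms
  for (p in unique(pf$protein)) {
    d <- pf[pf$protein == p, ]
    expect_equal(sum(d$fraction_within_protein), 1, tolerance = 1e-9)
    ptruth <- man$total_phosphorylation$p_total[
      man$total_phosphorylation$protein == p]
    expect_equal(sum(d$n_phospho * d$abundance) / sum(d$abundance), ptruth,
                 tolerance = 1e-12)
  }
  fam <- man$isoform_fractions
  expect_true(all(abs(tapply(fam$fraction, fam$family, sum) - 1) < 1e-9))
})
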