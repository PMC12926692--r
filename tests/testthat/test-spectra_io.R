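# mzML round trips, spectrum averaging, EIC extraction and AUC integration.

test_that("mzML round trip preserves centroid data and metadata", {
  scans <- list(list(rt = 0.10, mz = c(500.123456, 600.5, 700.25),
                     intensity = c(10, 20, 30)),
                list(rt = 0.20, mz = c(501.1, 601.2),
                     intensity = c(5.5, 6.5)))
  run <- spectrum_run(scans, "centroid")
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(run, path)
  back <- read_mzml(path)
  expect_equal(n_scans(back), 2)
  expect_equal(back$mode, "centroid")
  expect_equal(scan_times(back), c(0.10, 0.20), tolerance = 1e-6)
  for (i in 1:2) {
    expect_equal(back$scans[[i]]$mz, scans[[i]]$mz, tolerance = 1e-9)
    # intensities are stored as 32-bit floats
    expect_equal(back$scans[[i]]$intensity, scans[[i]]$intensity,
                 tolerance = 1e-6)
  }
})

test_that("empty and profile runs survive the round trip", {
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(spectrum_run(list(), "centroid"), path)
  expect_equal(n_scans(read_mzml(path)), 0)

  grid <- seq(500, 502, by = 0.005)
  prof <- spectrum_run(list(list(rt = 0.5, mz = grid,
                                 intensity = dnorm(grid, 501, 0.05))),
                       "profile")
  path2 <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(prof, path2)
  back <- read_mzml(path2)
  expect_equal(back$mode, "profile")
  expect_equal(back$scans[[1]]$mz, grid, tolerance = 1e-9)
  expect_error(read_mzml(withr::local_tempfile(fileext = ".mzML")),
               "not found")
})

test_that("spectrum averaging follows the clustering contract", {
  scans <- list(
    list(rt = 0.1, mz = c(1000, 1100), intensity = c(10, 7)),
    list(rt = 0.2, mz = c(1000.001, 1100.002), intensity = c(30, 9)),
    list(rt = 0.9, mz = c(555), intensity = c(1))
  )
  run <- spectrum_run(scans, "centroid")
  # a window covering one scan returns that scan's peaks unchanged
  one <- average_spectra(run, c(0.05, 0.15))
  expect_equal(one$mz, c(1000, 1100))
  expect_equal(one$intensity, c(10, 7))
  # identical peak at 10 and 30 averages to 20 over a two-scan window
  avg <- average_spectra(run, c(0.05, 0.25))
  expect_equal(length(avg$mz), 2)
  expect_equal(avg$intensity[1], 20)
  # intensity-weighted mean m/z
  expect_equal(avg$mz[1], (1000 * 10 + 1000.001 * 30) / 40, tolerance = 1e-9)
  expect_error(average_spectra(run, c(2, 3)), "overlaps no scan")
})

test_that("averaging a noise-free elution peak leaves isotopologue m/z intact", {
  out <- two_proteoform_run()
  avg <- avg_of(out)
  iso <- averagine_isotope_distribution(18000)
  pred <- sort(as.vector(vapply(out$manifest$proteoforms$charges[[1]],
                                function(z) mz_from_mass(iso$mass, z),
                                numeric(length(iso$mass)))))
  near <- vapply(pred, function(p) min(abs(avg$mz - p)), numeric(1))
  expect_lt(max(near), 1e-6)
})

test_that("EIC extraction sums peaks in half-open windows", {
  scans <- lapply(1:5, function(i)
    list(rt = i / 60, mz = c(700, 800, 900), intensity = c(5, 2, 1)))
  run <- spectrum_run(scans, "centroid")
  flat <- extract_eic(run, list(c(699.9, 700.1)), "flat")
  expect_equal(flat$intensity, rep(5, 5))
  none <- extract_eic(run, list(c(1000, 1001)), "none")
  expect_equal(none$intensity, rep(0, 5))
  # half-open [lo, hi): a peak exactly at hi is excluded, at lo included
  edge <- extract_eic(run, list(c(700, 800)), "edge")
  expect_equal(edge$intensity, rep(5, 5))
  # overlapping windows merge with a warning and no double counting
  expect_warning(both <- extract_eic(run, list(c(699, 801), c(750, 850)),
                                     "both"), "merged")
  expect_equal(both$intensity, rep(7, 5))
})

test_that("EIC over the whole m/z range reproduces the TIC", {
  out <- two_proteoform_run()
  tic <- extract_eic(out$run, list(c(0, 1e5)), "tic")
  per_scan <- vapply(out$run$scans, function(s) sum(s$intensity), numeric(1))
  expect_equal(tic$intensity, per_scan, tolerance = 1e-12)
})

test_that("AUC integrates trapezoidally and additively", {
  tri <- list(rt = c(0, 1, 2), intensity = c(0, 10, 0))
  expect_equal(auc(tri), 10)
  expect_equal(auc(list(rt = 0:5, intensity = rep(0, 6))), 0)
  expect_error(auc(list(rt = 1, intensity = 5)), "2 points")
  # exact additivity over a shared endpoint
  set.seed(7)
  tr <- list(rt = seq(0, 3, by = 0.05), intensity = runif(61))
  expect_identical(auc(tr, c(0, 1.5)) + auc(tr, c(1.5, 3)), auc(tr, c(0, 3)))
})

test_that("trapezoidal AUC of a sampled Gaussian matches the closed form", {
  sigma <- 0.15
  rt <- seq(0, 2, by = 1 / 60)  # 1 Hz sampling
  A <- 1000
  tr <- list(rt = rt, intensity = A * exp(-0.5 * ((rt - 1) / sigma)^2))
  expect_equal(auc(tr), oracle_gaussian_area(A, sigma, 1, 0, 2),
               tolerance = 0.01)
})
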