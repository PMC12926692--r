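# Mass/charge arithmetic and averagine isotope modelling.

test_that("m/z conversion is exact and invertible", {
  expect_equal(mz_from_mass(20000, 20), 1001.007276466, tolerance = 1e-9)
  expect_equal(mz_from_mass(1000, 1), 1001.007276466, tolerance = 1e-9)
  set.seed(42)
  M <- runif(200, 600, 60000)
  z <- sample(1:50, 200, replace = TRUE)
  expect_equal(mass_from_mz(mz_from_mass(M, z), z), M, tolerance = 1e-9)
  # strictly decreasing in charge for fixed mass
  mzs <- mz_from_mass(18000, 1:50)
  expect_true(all(diff(mzs) < 0))
  expect_error(mz_from_mass(-5, 3), "positive")
  expect_error(mz_from_mass(1000, 0), "charge")
})

test_that("ppm error is signed and zero on identity", {
  expect_equal(ppm_error(1000.001, 1000), 1, tolerance = 1e-9)
  expect_equal(ppm_error(999.999, 1000), -1, tolerance = 1e-9)
  expect_equal(ppm_error(12345.6, 12345.6), 0)
  expect_error(ppm_error(10, -1), "positive")
})

test_that("proteoform mass adds modification deltas", {
  expect_equal(proteoform_mass(10000, c(phospho = 1)), 10079.96633)
  expect_equal(proteoform_mass(10000), 10000)
  expect_equal(proteoform_mass(10000, c(phospho = 2, oxidation = 1)),
               10175.92757)
  expect_error(proteoform_mass(10000, c(sumoylation = 1)), "sumoylation")
  sp <- proteoform_spec("x", "X", "GX", 20000, c(phospho = 1),
                        phospho_sites_max = 2)
  expect_equal(proteoform_mass(sp), 20079.96633)
  expect_error(proteoform_spec("y", "Y", "GY", 20000, c(phospho = 3),
                               phospho_sites_max = 2), "phospho")
})

test_that("averagine distribution matches the exact enumeration oracle", {
  for (mass in c(2000, 5000)) {
    d <- averagine_isotope_distribution(mass, truncate_at = 1e-9)
    orc <- oracle_isotope_distribution(averagine_composition(mass))
    n <- min(length(d$prob), nrow(orc))
    expect_lt(max(abs(d$prob[1:n] / sum(d$prob[1:n]) -
                        orc$p[1:n] / sum(orc$p[1:n]))), 1e-6)
  }
  # most abundant isotopologue index and mass offset at 20 kDa
  d20 <- averagine_isotope_distribution(20000, truncate_at = 1e-7)
  orc20 <- oracle_isotope_distribution(averagine_composition(20000))
  expect_equal(d20$most_abundant_index - 1L, orc20$dn[which.max(orc20$p)])
  off_pkg <- most_abundant_mass(d20) - d20$neutral_mass
  off_orc <- orc20$m[which.max(orc20$p)] - orc20$m[1]
  expect_lt(abs(off_pkg - off_orc), 0.001)
})

test_that("small-mass distributions put the monoisotopic peak on top", {
  d <- averagine_isotope_distribution(1000)
  expect_equal(d$most_abundant_index, 1L)
  orc <- oracle_isotope_distribution(averagine_composition(1000))
  expect_equal(which.max(orc$p), 1L)
})

test_that("isotope distributions are normalized, unimodal, evenly spaced", {
  for (mass in c(1000, 5000, 12000, 33000, 60000)) {
    d <- averagine_isotope_distribution(mass)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    sp <- diff(d$mass)
    expect_true(all(sp >= 1.0 & sp <= 1.007))
    # at most one local maximum after 3-point smoothing
    y <- stats::filter(d$prob, rep(1 / 3, 3), sides = 2)
    y <- y[!is.na(y)]
    n_max <- sum(diff(sign(diff(y))) < 0)
    expect_lte(n_max, 1)
  }
  expect_error(averagine_isotope_distribution(100), "500")
  expect_error(averagine_isotope_distribution(10000, truncate_at = 2), "0, 1")
})

test_that("target tables round-trip through TSV", {
  tt <- target_table(list(
    proteoform_spec("aTpm", "aTpm", "TPM1", 32680, phospho_sites_max = 2),
    proteoform_spec("MLC2S_1P", "MLC2S", "MYL2", 18650, c(phospho = 1),
                    phospho_sites_max = 2)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_target_table(tt, path)
  tt2 <- read_target_table(path)
  expect_equal(as.data.frame(tt2), as.data.frame(tt))
  expect_equal(proteoform_mass(tt2[[2]]), 18650 + 79.96633)
  # duplicate ids rejected
  df <- as.data.frame(tt)
  df$id <- "same"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_target_table(path2), "duplicate")
})
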