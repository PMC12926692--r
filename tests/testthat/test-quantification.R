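# Quantification statistics and the per-fiber pipeline orchestration.

test_that("total phosphorylation is the site-weighted intensity fraction", {
  expect_equal(total_phosphorylation(intensities = 100, n_phospho = 0), 0)
  expect_equal(total_phosphorylation(intensities = c(80, 20),
                                     n_phospho = c(0, 1)), 0.20)
  expect_equal(total_phosphorylation(intensities = c(50, 30, 20),
                                     n_phospho = c(0, 1, 2)), 0.70)
  expect_error(total_phosphorylation(intensities = c(0, 0),
                                     n_phospho = c(0, 1)), "zero")
})

test_that("proteoform fractions normalize and identities hold", {
  fr <- proteoform_relative_abundance(c("0P" = 60, "1P" = 40))
  expect_equal(as.numeric(fr), c(0.6, 0.4))
  expect_equal(sum(fr), 1)
  expect_equal(as.numeric(proteoform_relative_abundance(c(only = 12))), 1)
  # P_total equals the fraction-weighted mean of the site counts (exact)
  set.seed(11)
  for (i in 1:20) {
    I <- runif(4, 1, 100)
    k <- sample(0:3, 4, replace = TRUE)
    fr <- I / sum(I)
    expect_equal(total_phosphorylation(intensities = I, n_phospho = k),
                 sum(k * fr), tolerance = 1e-12)
  }
})

test_that("isoform abundance fractions and pairwise ratios are consistent", {
  ira <- isoform_relative_abundance(c(MLC1F = 100, MLC3F = 5))
  expect_equal(as.numeric(ira$fractions), c(100 / 105, 5 / 105))
  r <- ira$ratios
  expect_equal(r$ratio[r$numerator == "MLC3F" & r$denominator == "MLC1F"],
               0.05)
  expect_equal(as.numeric(isoform_relative_abundance(c(A = 50, B = 50))$fractions),
               c(0.5, 0.5))
  expect_equal(as.numeric(isoform_relative_abundance(c(A = 7))$fractions), 1)
  expect_error(isoform_relative_abundance(c(A = 0, B = 0)), "zero")
  # ratio(A/B) * fraction(B) = fraction(A) exactly
  set.seed(3)
  for (i in 1:10) {
    v <- stats::setNames(runif(4, 0.1, 10), letters[1:4])
    ira <- isoform_relative_abundance(v)
    r <- ira$ratios
    lhs <- r$ratio * as.numeric(ira$fractions[r$denominator])
    expect_equal(lhs, as.numeric(ira$fractions[r$numerator]),
                 tolerance = 1e-9)
  }
})

test_that("top charge-state selection returns 5-7 windows when available", {
  out <- two_proteoform_run()
  avg <- avg_of(out)
  tc <- select_top_charge_states(avg, 18000, charge_range = c(5, 60))
  expect_equal(nrow(tc), 7)
  expect_true(all(diff(tc$apex_intensity) <= 0))
  expect_equal(tc$mz_hi - tc$mz_lo, rep(0.4, 7), tolerance = 1e-12)
  # the selected charges sit at the top of the simulated envelope
  w <- out$manifest$proteoforms$charge_weights[[1]]
  zt <- out$manifest$proteoforms$charges[[1]]
  top7 <- zt[order(w, decreasing = TRUE)][1:7]
  expect_true(all(tc$charge %in% top7))
  # fewer detected charges: as many windows as exist, with a warning
  sub <- list(mz = avg$mz[avg$mz < 660], intensity = avg$intensity[avg$mz < 660])
  expect_warning(tc3 <- select_top_charge_states(sub, 18000,
                                                 charge_range = c(27, 29)),
                 "charge states")
  expect_lte(nrow(tc3), 3)
  expect_error(select_top_charge_states(avg, 55000, charge_range = c(5, 10),
                                        label = "ghost"), "ghost")
})

test_that("fiber reports recover the simulated truth on clean fixtures", {
  out <- two_proteoform_run()
  tt <- target_table(list(
    proteoform_spec("P1", "P1", "G1", 18000, phospho_sites_max = 2)))
  rep <- fiber_report(out$run, tt, fiber_analysis_config())
  pa <- rep$proteoform_abundances
  expect_equal(nrow(pa), 2)
  expect_equal(pa$fraction, c(0.8, 0.2), tolerance = 1e-3)
  expect_lt(abs(rep$total_phosphorylation$p_total - 0.2), 2e-3)
  expect_equal(rep$isoform_ratios$fraction, 1)
  # deterministic: identical runs give identical serialized reports
  rep2 <- fiber_report(out$run, tt, fiber_analysis_config())
  expect_identical(jsonlite::toJSON(unclass(rep), auto_unbox = TRUE, digits = NA),
                   jsonlite::toJSON(unclass(rep2), auto_unbox = TRUE, digits = NA))
})

test_that("slow fibers report low fast-isoform fractions end to end", {
  out <- cached("slow_nf", function()
    generate_run(fiber_fixture("slow_fiber", seed = 21, noise = noise_free)))
  rep <- fiber_report(out$run, sarcomere_targets(),
                      fiber_analysis_config(families = sarcomere_families()))
  ir <- rep$isoform_ratios
  classes <- sarcomere_classes()
  fast <- ir[classes[ir$protein] == "fast" & !is.na(ir$fraction), ]
  expect_true(all(fast$fraction < 0.1))
  # every family's detected fractions sum to one
  sums <- tapply(ir$fraction[!is.na(ir$fraction)],
                 ir$family[!is.na(ir$fraction)], sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("report files are written completely and reproducibly", {
  out <- two_proteoform_run()
  tt <- target_table(list(
    proteoform_spec("P1", "P1", "G1", 18000, phospho_sites_max = 2)))
  rep <- fiber_report(out$run, tt, fiber_analysis_config())
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_quant_report(rep, d1)
  write_quant_report(rep, d2)
  files <- c("report.json", "isoform_ratios.csv", "proteoform_abundance.csv",
             "phospho_stoichiometry.csv")
  expect_true(all(file.exists(file.path(d1, files))))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})
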