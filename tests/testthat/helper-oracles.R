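# Independent oracles used to freeze expected values: an exact isotope
# distribution built by direct multinomial enumeration over heavy-isotope
# counts (a different construction from the package's iterated convolution),
# and a brute-force (mass, charge) grid-search deconvolution.

.oracle_iso_tables <- list(
  C = data.frame(dn = c(0, 1), m = c(12.0, 13.0033548378),
                 p = c(0.9893, 0.0107)),
  H = data.frame(dn = c(0, 1), m = c(1.0078250319, 2.0141017779),
                 p = c(0.999885, 0.000115)),
  N = data.frame(dn = c(0, 1), m = c(14.0030740052, 15.0001088984),
                 p = c(0.99632, 0.00368)),
  O = data.frame(dn = c(0, 1, 2), m = c(15.9949146221, 16.9991315, 17.9991604),
                 p = c(0.99757, 0.00038, 0.00205)),
  S = data.frame(dn = c(0, 1, 2, 4),
                 m = c(31.97207069, 32.9714585, 33.96786683, 35.96708088),
                 p = c(0.9493, 0.0076, 0.0429, 0.0002))
)

# distribution of one element: exact multinomial over heavy-isotope counts
oracle_element_distribution <- function(el, n, kmax = 60) {
  tab <- .oracle_iso_tables[[el]]
  if (n == 0) return(data.frame(dn = 0L, m = 0, p = 1))
  heavy <- tab[-1, , drop = FALSE]
  grid <- expand.grid(lapply(seq_len(nrow(heavy)),
                             function(i) 0:min(n, kmax)))
  grid <- grid[rowSums(grid) <= n, , drop = FALSE]
  p <- apply(grid, 1, function(k) stats::dmultinom(c(n - sum(k), k),
                                                   prob = tab$p))
  dn <- as.vector(as.matrix(grid) %*% heavy$dn)
  m <- (n - rowSums(grid)) * tab$m[1] +
    as.vector(as.matrix(grid) %*% heavy$m)
  keep <- p > 0
  d <- data.frame(dn = dn[keep], m = m[keep], p = p[keep])
  agg_p <- tapply(d$p, d$dn, sum)
  agg_m <- tapply(d$p * d$m, d$dn, sum) / agg_p
  data.frame(dn = as.integer(names(agg_p)), m = as.numeric(agg_m),
             p = as.numeric(agg_p))
}

# exact aggregated isotope distribution of an elemental composition
oracle_isotope_distribution <- function(counts, prune = 1e-13) {
  res <- data.frame(dn = 0L, m = 0, p = 1)
  for (el in names(counts)) {
    if (counts[[el]] == 0) next
    d <- oracle_element_distribution(el, counts[[el]])
    comb_dn <- outer(res$dn, d$dn, `+`)
    comb_m <- outer(res$m, d$m, `+`)
    comb_p <- outer(res$p, d$p)
    agg_p <- tapply(as.vector(comb_p), as.vector(comb_dn), sum)
    agg_m <- tapply(as.vector(comb_p * comb_m), as.vector(comb_dn), sum) /
      agg_p
    res <- data.frame(dn = as.integer(names(agg_p)), m = as.numeric(agg_m),
                      p = as.numeric(agg_p))
    res <- res[res$p > prune * max(res$p), ]
  }
  res <- res[order(res$dn), ]
  rownames(res) <- NULL
  res
}

# brute-force deconvolution: enumerate candidate monoisotopic masses from
# every (peak, charge, isotopologue index) triple, score each candidate by
# matched ladder intensity over all charges, and greedily pick
# non-overlapping candidates
oracle_grid_deconvolute <- function(mz, intensity, charges, kmax = 25,
                                    tol = 0.01, min_frac = 0.05) {
  proton <- mass_constants()$proton_mass
  spacing <- mass_constants()$avg_isotope_spacing
  ord <- order(mz)
  mz <- mz[ord]
  intensity <- intensity[ord]
  cand <- unique(round(as.vector(
    outer(as.vector(outer(mz, charges, function(x, z) z * (x - proton))),
          0:kmax * spacing, `-`)), 2))
  cand <- cand[cand > 500]
  matched_peaks <- function(m, avail) {
    pred <- as.vector(outer(m + 0:kmax * spacing, charges,
                            function(M, z) (M + z * proton) / z))
    near <- findInterval(pred, mz)
    c1 <- pmax(near, 1L)
    c2 <- pmin(near + 1L, length(mz))
    d1 <- abs(mz[c1] - pred)
    d2 <- abs(mz[c2] - pred)
    pick <- ifelse(d1 <= d2, c1, c2)
    ok <- pmin(d1, d2) < tol & avail[pick]
    unique(pick[ok])
  }
  avail <- rep(TRUE, length(mz))
  found <- numeric(0)
  repeat {
    scores <- vapply(cand, function(m)
      sum(intensity[matched_peaks(m, avail)]), numeric(1))
    if (!length(scores) || max(scores) < min_frac * sum(intensity)) break
    best <- cand[which.max(scores)]
    found <- c(found, best)
    avail[matched_peaks(best, avail)] <- FALSE
    if (length(found) >= 6) break
  }
  sort(found)
}

# closed-form area of a Gaussian elution peak A * exp(-(t-mu)^2 / 2 sigma^2)
oracle_gaussian_area <- function(A, sigma, mu, lo = -Inf, hi = Inf) {
  A * sigma * sqrt(2 * pi) * (stats::pnorm(hi, mu, sigma) -
                                stats::pnorm(lo, mu, sigma))
}
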