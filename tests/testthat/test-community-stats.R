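# Mock-community ratios, distances, ordination, dispersion, diversity and
# qPCR-anchored absolute abundance.

test_that("observed/expected ratios point in the right direction", {
  expect_equal(observed_expected_ratio(6.25, 6.25), 100)
  expect_equal(observed_expected_ratio(0.2575, 6.25), 4.12)
  expect_equal(observed_expected_ratio(0, 6.25), 0)
  expect_error(observed_expected_ratio(1, 0), "> 0")
  # replicate matrix: mean and sd across rows
  obs <- rbind(c(5, 10), c(7, 10))
  r <- observed_expected_ratio(obs, c(6.25, 6.25))
  expect_equal(unname(r$mean), c(96, 160))
  expect_equal(unname(r$sd), c(sd(c(80, 112)), 0))
})

test_that("Bray-Curtis follows its formula and bounds", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 3, 0)), 1)
  expect_equal(bray_curtis(c(1, 1, 0), c(0, 1, 1)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  # symmetry, bounds and identity-of-indiscernibles on random vectors,
  # cross-checked against the community ecology reference implementation
  set.seed(7)
  for (i in 1:20) {
    x <- rpois(8, 20); y <- rpois(8, 20)
    d <- bray_curtis(x, y)
    expect_equal(d, bray_curtis(y, x))
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, as.numeric(vegan::vegdist(rbind(x, y), "bray")))
  }
})

test_that("principal coordinates reproduce known geometry", {
  # 2-point matrix: one axis, separation equal to the distance
  d <- matrix(c(0, 3, 3, 0), 2)
  p <- pcoa(d)
  expect_equal(abs(diff(p$points[, 1])), 3)
  # Euclidean distances of known points are recovered (up to rotation)
  set.seed(11)
  pts <- matrix(rnorm(20), 10, 2)
  rec <- pcoa(dist(pts), k = 2)
  expect_equal(as.numeric(dist(rec$points)), as.numeric(dist(pts)),
               tolerance = 1e-8)
  expect_equal(rec$correction, 0)
  # all-zero matrix: degenerate zero coordinates
  z <- pcoa(matrix(0, 3, 3))
  expect_true(all(z$points == 0))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("beta dispersion separates tight from wide groups", {
  # identical samples: zero dispersion
  m <- rbind(c(5, 5, 0), c(5, 5, 0), c(5, 5, 0), c(1, 1, 8), c(1, 1, 8))
  rownames(m) <- paste0("s", 1:5)
  bd <- beta_dispersion(vegan::vegdist(m, "bray"), c("a", "a", "a", "b", "b"))
  expect_equal(unname(bd$dispersions["a"]), 0, tolerance = 1e-10)
  # sigma vs 4 sigma: detected at alpha = 0.05 in >= 80% of seeds
  detected <- vapply(1:15, function(seed) {
    set.seed(seed)
    tight <- matrix(rnorm(20, sd = 1), 10, 2)
    wide <- matrix(rnorm(20, sd = 4), 10, 2)
    d <- dist(rbind(tight, wide))
    bd <- beta_dispersion(d, rep(c("t", "w"), each = 10))
    bd$dispersions["w"] > bd$dispersions["t"] && bd$p_value < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.8)
  # relabelling within a group leaves its dispersion unchanged
  set.seed(3)
  x <- matrix(rnorm(24), 12, 2)
  g <- rep(c("a", "b"), each = 6)
  d <- dist(x)
  b1 <- beta_dispersion(d, g)
  perm <- c(3, 1, 2, 6, 4, 5, 7:12)  # permute group a members among themselves
  b2 <- beta_dispersion(stats::as.dist(as.matrix(d)[perm, perm]), g[perm])
  expect_equal(sort(unname(b1$dispersions)), sort(unname(b2$dispersions)))
  # singleton group in a two-group comparison is rejected
  expect_error(beta_dispersion(dist(x[1:4, ]), c("a", "b", "b", "b")),
               "singleton")
})

test_that("Mann-Whitney U matches enumeration and the reference test", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 2 * 1 / 6)  # 1/C(4,2) each tail, doubled
  # identical samples: exact permutation p = 1 despite full ties
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # tie-free cases agree with the standard exact implementation
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(8)
    got <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
  }
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("large-sample path uses the tie-corrected normal approximation", {
  set.seed(17)
  a <- round(rnorm(25), 1); b <- round(rnorm(25, mean = 0.8), 1)
  got <- mann_whitney_u(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_match(got$method, "normal")
})

test_that("NMDS embeds exactly embeddable configurations and is seeded", {
  set.seed(19)
  pts <- matrix(rnorm(24), 12, 2)
  d <- dist(pts)
  fit <- nmds(d, k = 2, restarts = 5, seed = 42)
  expect_lt(fit$stress, 0.01)   # a perfect embedding exists
  fit2 <- nmds(d, k = 2, restarts = 5, seed = 42)
  expect_identical(fit$points, fit2$points)
  expect_identical(fit$stress, fit2$stress)
  # nested model: more axes can only fit better
  set.seed(23)
  comm <- matrix(rpois(10 * 12, 12), 10, 12)
  db <- vegan::vegdist(comm, "bray")
  s2 <- nmds(db, k = 2, restarts = 10, seed = 1)$stress
  s3 <- nmds(db, k = 3, restarts = 10, seed = 1)$stress
  expect_lte(s3, s2 + 1e-6)
  expect_error(nmds(d, k = 12, seed = 1), "smaller")
})

test_that("Chao1 uses the bias-corrected singleton/doubleton form", {
  expect_equal(chao1(c(4, 5, 6)), 3)           # no singletons
  expect_equal(chao1(c(1, 1, 2, 2)), 4 + 2 * 1 / (2 * 3))
  expect_equal(chao1(c(3, 3, 7, 9)), 4)        # everything >= 3 reads
  expect_error(chao1(c(1.5, 2)), "integers")
  # always >= observed richness; equality iff F1 * (F1 - 1) = 0
  set.seed(29)
  for (i in 1:20) {
    cts <- rpois(15, 2)
    est <- chao1(cts)
    s_obs <- sum(cts > 0)
    f1 <- sum(cts == 1)
    expect_gte(est, s_obs)
    expect_equal(est == s_obs, f1 * (f1 - 1) == 0)
  }
})

test_that("rarefaction expectation matches the hypergeometric form and MC", {
  counts <- c(5, 5)
  expect_equal(rarefaction_curve(counts, 2)$richness,
               2 * (1 - choose(5, 2) / choose(10, 2)))
  expect_equal(rarefaction_curve(counts, 10)$richness, 2)  # full depth
  expect_equal(rarefaction_curve(c(4, 0, 9), 1)$richness, 1)
  expect_error(rarefaction_curve(counts, 11), "exceeds")
  # Monte-Carlo agreement within 3 SE at 10,000 draws
  counts <- c(12, 7, 3, 1, 1)
  depth <- 8
  analytic <- rarefaction_curve(counts, depth)$richness
  set.seed(31)
  pool <- rep(seq_along(counts), counts)
  draws <- replicate(10000, length(unique(sample(pool, depth))))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - analytic), 3 * se)
})

test_that("qPCR curve fitting recovers slope, R2 and efficiency", {
  # collinear points: R2 = 1 and exact slope
  lq <- 3:8
  ct <- 38 - 3.4 * lq
  fit <- qpcr_standard_curve(lq, ct)
  expect_equal(fit$slope, -3.4)
  expect_equal(fit$r_squared, 1)
  # slope -1/log10(2): exact doubling, 100% efficiency
  expect_equal(qpcr_efficiency(-1 / log10(2)), 100)
  # efficiency/slope round-trip identity
  for (e in c(80, 100, 174.5)) {
    expect_equal(qpcr_efficiency(qpcr_slope_for_efficiency(e)), e,
                 tolerance = 1e-9)
  }
  expect_error(qpcr_standard_curve(c(1, 1.5, 2), c(30, 28, 26)), "2 log")
  expect_error(qpcr_standard_curve(c(3, 5), c(30, 24)), "3 points")
})

test_that("absolute abundance is total load times relative fraction", {
  expect_equal(absolute_abundance(2e8, 50), 1e8)
  expect_equal(absolute_abundance(5e7, 0), 0)
  expect_error(absolute_abundance(1e8, 120), "\\[0, 100\\]")
  expect_error(absolute_abundance(-1, 10), "nonnegative")
})

test_that("correlation matches a hand computation", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  # hand oracle: cov / (sd x sd)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate(x, y), hand)
  expect_equal(correlate(x, 2 * x), 1)
  expect_equal(correlate(x, -x), -1)
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "variance")
})
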