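test_that("cosine basis is orthonormal with the stated normalisation", {
  expect_equal(basis_eval("cosine", 0, 3.7, c(0, 10)), 1 / sqrt(10))
  expect_equal(basis_eval("cosine", 1, 0, c(0, 10)), sqrt(2 / 10))
  # orthogonality / unit norm by independent Simpson quadrature
  for (pair in list(c(1, 2), c(0, 3), c(2, 5))) {
    ip <- oracle_simpson(function(t) {
      basis_eval("cosine", pair[1], t, c(0, 10)) *
        basis_eval("cosine", pair[2], t, c(0, 10))
    }, 0, 10)
    expect_equal(ip, 0, tolerance = 1e-8)
  }
  for (i in 0:3) {
    nrm <- oracle_simpson(function(t) basis_eval("cosine", i, t, c(0, 10))^2, 0, 10)
    expect_equal(nrm, 1, tolerance = 1e-8)
  }
  expect_error(basis_eval("fourier", 0, 1, c(0, 10)), "unknown basis")
})

test_that("intensity evaluation clamps at the floor and respects the region", {
  const <- nhpp_intensity(3, c(0, 10), basis = "constant")
  expect_equal(intensity_at(const, c(0, 5, 10)), c(3, 3, 3))
  # coefficients making the raw expansion -1 everywhere
  neg <- nhpp_intensity(-1 * sqrt(10), c(0, 10), basis = "cosine")
  expect_equal(intensity_at(neg, 4.2), 1e-8)
  s1 <- scenario_intensities("S1")
  expect_equal(intensity_at(s1[[1]], 0), 6)
  expect_error(intensity_at(const, 11), "outside region")
})

test_that("cumulative intensity matches closed forms and quadrature oracle", {
  const <- nhpp_intensity(2, c(0, 10), basis = "constant")
  expect_equal(cumulative(const, 0, 10), 20)
  expect_equal(cumulative(const, 5, 5), 0)
  expect_error(cumulative(const, 6, 4), "a <= b")
  s1c1 <- scenario_intensities("S1")[[1]]
  expect_equal(cumulative(s1c1, 0, 10), 30, tolerance = 1e-6)
  expect_equal(cumulative(s1c1, 1, 4),
               oracle_simpson(function(t) 3 * cos(2 * pi * t / 10) + 3, 1, 4),
               tolerance = 1e-8)
  # clamped (partly negative) intensity falls back to clamped quadrature
  s2c3 <- scenario_intensities("S2")[[3]]
  raw <- nhpp_intensity(s2c3$coef - 2 * sqrt(10) * c(1, rep(0, 4)), c(0, 10))
  expect_equal(cumulative(raw, 0, 10),
               oracle_simpson(function(t) pmax(intensity_at(raw, t), 0), 0, 10),
               tolerance = 1e-4)
})

test_that("cumulative is additive over adjacent intervals", {
  s1 <- scenario_intensities("S1")
  for (intensity in s1) {
    expect_equal(cumulative(intensity, 0, 3.3) + cumulative(intensity, 3.3, 10),
                 cumulative(intensity, 0, 10), tolerance = 1e-9)
  }
})

test_that("path log-likelihood matches hand and oracle computations", {
  one <- nhpp_intensity(1, c(0, 10), basis = "constant")
  two <- nhpp_intensity(2, c(0, 10), basis = "constant")
  expect_equal(path_log_lik(numeric(0), one), -10)
  expect_equal(path_log_lik(c(1, 4, 7), two), -20 + 3 * log(2))
  # Scenario 1 cluster 1 intensity at sites {1,2,3}: frozen oracle value
  s1c1 <- scenario_intensities("S1")[[1]]
  expect_equal(path_log_lik(c(1, 2, 3), s1c1), -26.211743, tolerance = 1e-5)
  expect_error(path_log_lik(c(1, 11), s1c1), "outside region")
})

test_that("joint log-likelihood is additive over paths", {
  s1c1 <- scenario_intensities("S1")[[1]]
  p <- list(a = c(1, 2, 3))
  expect_equal(joint_log_lik(p, s1c1), path_log_lik(c(1, 2, 3), s1c1))
  expect_equal(joint_log_lik(c(p, list(b = c(1, 2, 3))), s1c1),
               2 * path_log_lik(c(1, 2, 3), s1c1))
  one <- nhpp_intensity(1, c(0, 10), basis = "constant")
  expect_equal(joint_log_lik(list(a = c(1, 2), b = numeric(0), c = 5), one), -30)
  expect_equal(joint_log_lik(list(), one), 0)
})

test_that("thinning simulator reproduces the Poisson mean", {
  three <- nhpp_intensity(3, c(0, 10), basis = "constant")
  counts <- withr::with_seed(42, replicate(2000, length(simulate_nhpp(three))))
  se <- sqrt(30 / 2000)
  expect_lt(abs(mean(counts) - 30), 3 * se)
  # zero-rate intensity yields (essentially) no events
  tiny <- nhpp_intensity(1e-8, c(0, 10), basis = "constant")
  expect_length(simulate_nhpp(tiny, seed = 1), 0)
  # reproducibility
  s1c1 <- scenario_intensities("S1")[[1]]
  expect_identical(simulate_nhpp(s1c1, seed = 7), simulate_nhpp(s1c1, seed = 7))
})

test_that("simulated counts from a cosine intensity pass a Poisson GOF test", {
  s1c1 <- scenario_intensities("S1")[[1]]  # total mass 30
  lm <- nhppclust:::dominating_rate(s1c1)
  counts <- withr::with_seed(11, replicate(
    2000, length(simulate_nhpp(s1c1, lambda_max = lm))))
  breaks <- c(-Inf, seq(18, 42, by = 4), Inf)
  obs <- table(cut(counts, breaks))
  p <- diff(ppois(c(-Inf, seq(18, 42, by = 4), Inf), lambda = 30))
  gof <- chisq.test(as.vector(obs), p = p)
  expect_gt(gof$p.value, 0.01)
})

test_that("superposition of independent simulations matches the summed rate", {
  a <- nhpp_intensity(2, c(0, 10), basis = "constant")
  b <- scenario_intensities("S1")[[2]]  # mass 30
  withr::with_seed(5, {
    merged <- replicate(1000, length(simulate_nhpp(a)) + length(simulate_nhpp(b)))
    summed <- nhpp_intensity(b$coef + c(2 * sqrt(10), 0, 0, 0, 0), c(0, 10))
    direct <- replicate(1000, length(simulate_nhpp(summed)))
    ks <- suppressWarnings(ks.test(merged, direct))
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("simulator increments over disjoint intervals are uncorrelated", {
  s1c1 <- scenario_intensities("S1")[[1]]
  lm <- nhppclust:::dominating_rate(s1c1)
  reps <- 1000
  counts <- withr::with_seed(9, replicate(reps, {
    p <- simulate_nhpp(s1c1, lambda_max = lm)
    c(sum(p <= 5), sum(p > 5))
  }))
  expect_lt(abs(cor(counts[1, ], counts[2, ])), 3 / sqrt(reps))
})

test_that("L2 distance: identity, closed form vs quadrature, region check", {
  s4 <- scenario_intensities("S4")
  expect_equal(l2_distance(s4[[1]], s4[[1]]), 0)
  quad <- sqrt(oracle_simpson(function(t) {
    ((5 * cos(2 * pi * t / 10) + 5) -
       (2.5 * cos(2 * pi * t / 10) + 3.75 * cos(4 * pi * t / 10) + 3.75))^2
  }, 0, 10))
  expect_equal(l2_distance(s4[[1]], s4[[2]]), quad, tolerance = 1e-6)
  other <- nhpp_intensity(1, c(0, 5), basis = "constant")
  expect_error(l2_distance(s4[[1]], other), "different regions")
})

test_that("sample-path serialization round-trips", {
  sites <- paths_to_sites(list(Oct4 = c(1.25, 3.5), Sox2 = 7.125))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sites(sites, f)
  back <- read_sites(f)
  expect_equal(as.character(back$tf), as.character(sites$tf))
  expect_equal(back$position, sites$position)
})
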