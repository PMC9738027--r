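test_that("the k=1 objective equals the pooled joint log-likelihood", {
  scn <- generate_scenario("S4", seed = 2)
  p <- nlk_cluster(scn$sites, scn$region, 1, nlk_control(n_init = 1), seed = 1)
  pooled <- fit_intensity_mle(scn$sites, scn$region,
                              nlk_control()$fit, seed = 1)
  expect_equal(p$objective, nlk_objective(scn$sites, p))
  expect_equal(p$objective, pooled$log_lik, tolerance = 1e-4)
  expect_true(all(p$assignments == 1))
})

test_that("the true split of well-separated homogeneous paths beats every bipartition", {
  # brute-force oracle: score all 2-cluster partitions of 4 paths with the
  # closed-form homogeneous MLE and log-likelihood
  paths <- withr::with_seed(13, list(
    a = runif_path(rpois(1, 10)), b = runif_path(rpois(1, 10)),
    c = runif_path(rpois(1, 200)), d = runif_path(rpois(1, 200))))
  counts <- lengths(paths)
  score <- function(assign) {
    sum(sapply(1:2, function(g) {
      n <- sum(assign == g)
      if (n == 0) return(0)
      tot <- sum(counts[assign == g])
      rate <- max(tot / (n * 10), 1e-8)
      sum(sapply(which(assign == g), function(i) {
        oracle_homog_ll(rate, 10, counts[i])
      }))
    }))
  }
  parts <- oracle_bipartitions(4)
  scores <- sapply(parts, score)
  truth <- c(1, 1, 2, 2)
  best <- parts[[which.max(scores)]]
  expect_equal(mcr(truth, best), 0)
  # package objective agrees with the oracle ranking on the true split
  ctrl <- fit_control(basis = "constant")
  part_true <- list(assignments = truth, intensities = list(
    fit_intensity_mle(paths[1:2], c(0, 10), ctrl)$intensity,
    fit_intensity_mle(paths[3:4], c(0, 10), ctrl)$intensity))
  expect_equal(nlk_objective(paths, part_true), max(scores), tolerance = 1e-4)
  expect_error(nlk_objective(paths, list(assignments = c(1, 1, 2, 5),
                                         intensities = part_true$intensities)),
               "out of range")
})

test_that("assignment goes to the likelihood-dominant intensity with ties to the lower index", {
  s4 <- scenario_intensities("S4")
  # sites under the peak of lambda_1 (t ~ 0), in the trough of lambda_3
  paths <- list(a = c(0.2, 0.5, 9.6, 9.9))
  expect_equal(assign_step(paths, list(s4[[3]], s4[[1]])), 2L)
  expect_equal(assign_step(paths, list(s4[[1]], s4[[3]])), 1L)
  expect_equal(assign_step(paths, list(s4[[1]], s4[[1]])), 1L)  # tie -> lowest
})

test_that("oracle-centroid assignment recovers Scenario 1 labels", {
  hits <- sapply(1:50, function(s) {
    scn <- generate_scenario("S1", seed = s)
    labels <- assign_step(scn$sites, scn$intensities)
    mcr(scn$truth$cluster, labels) == 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("NLK separates homogeneous rate-1 vs rate-20 paths", {
  perfect <- sapply(1:20, function(s) {
    paths <- withr::with_seed(s, c(
      setNames(lapply(1:10, function(i) runif_path(rpois(1, 10))),
               paste0("lo", 1:10)),
      setNames(lapply(1:10, function(i) runif_path(rpois(1, 200))),
               paste0("hi", 1:10))))
    p <- nlk_cluster(paths, c(0, 10), 2,
                     nlk_control(n_init = 4, fit = fast_fit(2)), seed = s)
    mcr(rep(1:2, each = 10), p$assignments) == 0
  })
  expect_gte(mean(perfect), 0.99)
})

test_that("the NLK objective is monotone within every run", {
  for (s in 1:5) {
    scn <- generate_scenario("S2", seed = s)
    p <- nlk_cluster(scn$sites, scn$region, 3,
                     nlk_control(n_init = 2, fit = fast_fit(4)), seed = s)
    # monotone up to the quadrature resolution of the refit objective
    expect_true(all(diff(p$objective_trace) >= -1e-3))
  }
})

test_that("permuting path order permutes assignments identically", {
  scn <- generate_scenario("S1", seed = 6)
  paths <- as_path_list(scn$sites)
  n <- length(paths)
  init <- rep_len(1:3, n)
  perm <- withr::with_seed(1, sample(n))
  ctrl <- nlk_control(n_init = 1, fit = fast_fit(4))
  p1 <- nlk_cluster(paths, c(0, 10), 3, ctrl, seed = 99, init = init)
  p2 <- nlk_cluster(paths[perm], c(0, 10), 3, ctrl, seed = 99,
                    init = init[perm])
  expect_equal(unname(p2$assignments), unname(p1$assignments[perm]))
})

test_that("with normal likelihoods NLK reduces to Lloyd K-means on scalars", {
  # the likelihood criterion with unit-variance normal clusters is the
  # within-cluster sum of squares; verify on a 1-D toy set
  x <- c(0.1, 0.2, 0.3, 5.0, 5.1, 5.3, 9.6, 9.9)
  normal_obj <- function(assign, k) {
    -sum(sapply(seq_len(k), function(g) {
      xs <- x[assign == g]
      if (length(xs) == 0) 0 else sum((xs - mean(xs))^2)
    }))
  }
  parts <- expand.grid(rep(list(1:3), length(x)))
  scores <- apply(parts, 1, function(a) {
    if (length(unique(a)) < 3) -Inf else normal_obj(a, 3)
  })
  best_normal <- unlist(parts[which.max(scores), ])
  km <- withr::with_seed(2, kmeans(x, centers = 3, nstart = 20,
                                   algorithm = "Lloyd"))
  expect_equal(mcr(best_normal, km$cluster), 0)
})

test_that("k bounds and profile utility behave", {
  scn <- generate_scenario("S4", seed = 3)
  expect_error(nlk_cluster(scn$sites, scn$region, 11,
                           nlk_control(n_init = 1)), "k <= number of paths")
  prof <- nlk_profile(scn$sites, scn$region, 1:3,
                      nlk_control(n_init = 2, fit = fast_fit(4)), seed = 5)
  expect_equal(prof$k, 1:3)
  # richer partitions cannot decrease the achievable objective much;
  # the k = 3 optimum should beat k = 1
  expect_gt(prof$objective[3], prof$objective[1])
})
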