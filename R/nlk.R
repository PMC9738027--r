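#' Control parameters for NLK clustering
#'
#' @param n_init number of random initialisations; the best final
#'   objective wins. Default 10.
#' @param max_iter iteration cap per initialisation.
#' @param tol stop when the objective improves by less than this.
#' @param fit a [fit_control()] used for every cluster-intensity fit.
#'   Defaults to the cosine basis with a single random restart and a
#'   201-node quadrature grid — inside the iteration each refit is
#'   warm-started from the cluster's current intensity (and the
#'   moment-matched start is always tried), so extra restarts add
#'   little.
#' @return list of class `nlk_control`.
#' @export
nlk_control <- function(n_init = 10L, max_iter = 100L, tol = 1e-6,
                        fit = fit_control(n_restarts = 1L, grid_n = 201L)) {
  stopifnot(n_init >= 1, max_iter >= 1, tol > 0)
  structure(list(n_init = as.integer(n_init), max_iter = as.integer(max_iter),
                 tol = tol, fit = fit), class = "nlk_control")
}

# n_paths x k matrix of per-path log-likelihoods under each intensity.
# Shares the integral term across paths and evaluates all sites at once.
path_ll_matrix <- function(paths, intensities) {
  region <- intensities[[1]]$region
  sites <- unlist(paths, use.names = FALSE)
  idx <- rep(seq_along(paths), lengths(paths))
  n <- length(paths)
  ll <- vapply(intensities, function(intensity) {
    base <- -cumulative(intensity, region[1], region[2])
    ll <- rep(base, n)
    if (length(sites) > 0) {
      logs <- log(intensity_at(intensity, sites))
      add <- rowsum(logs, idx)
      ll[as.integer(rownames(add))] <- base + add[, 1]
    }
    ll
  }, numeric(n))
  matrix(ll, nrow = n)
}

#' Assign each sample path to its maximum-likelihood cluster
#'
#' Each path goes to the cluster whose intensity gives it the largest
#' NHPP log-likelihood; exact ties break toward the lowest cluster
#' index.
#'
#' @param paths sites tibble or path list.
#' @param intensities list of [nhpp_intensity()] cluster centroids.
#' @return integer vector of cluster indices, one per path.
#' @export
assign_step <- function(paths, intensities) {
  paths <- as_path_list(paths)
  ll <- path_ll_matrix(paths, intensities)
  max.col(ll, ties.method = "first")
}

#' NLK partition objective
#'
#' The likelihood K-means criterion: the sum over clusters of the joint
#' log-likelihood of the cluster's paths under the cluster's intensity.
#' Larger is better.
#'
#' @param paths sites tibble or path list.
#' @param partition an `nlk_partition`, or any list with integer
#'   `assignments` and a list `intensities`.
#' @return numeric objective value.
#' @export
nlk_objective <- function(paths, partition) {
  paths <- as_path_list(paths)
  a <- partition$assignments
  k <- length(partition$intensities)
  if (any(a < 1 | a > k)) stop("cluster index out of range", call. = FALSE)
  ll <- path_ll_matrix(paths, partition$intensities)
  sum(ll[cbind(seq_along(paths), a)])
}

random_assignment <- function(n, k) {
  for (try in 1:100) {
    a <- sample.int(k, n, replace = TRUE)
    if (length(unique(a)) == k) return(a)
  }
  sample(rep_len(seq_len(k), n))
}

# Move the globally worst-fitting path into each empty cluster.
repair_empty <- function(assignments, ll, k) {
  for (empty in setdiff(seq_len(k), unique(assignments))) {
    counts <- tabulate(assignments, k)
    movable <- which(counts[assignments] > 1)
    worst <- movable[which.min(ll[cbind(movable, assignments[movable])])]
    assignments[worst] <- empty
  }
  assignments
}

#' NHPP-likelihood K-means (NLK) clustering
#'
#' Partitional clustering of NHPP sample paths in which the cluster
#' centroid is a fitted intensity function and the distance from a path
#' to a centroid is the negative NHPP log-likelihood. Starting from a
#' random assignment into `k` clusters, the algorithm alternates
#' (re-)assigning every path to its maximum-likelihood cluster with
#' refitting each cluster's intensity by [fit_intensity_mle()], until the
#' assignment is stable, the objective gain falls below `control$tol`,
#' or `control$max_iter` is reached. `control$n_init` seeded random
#' initialisations are run and the partition with the best objective is
#' returned. Refits are warm-started from the cluster's current
#' intensity, which keeps the objective non-decreasing across
#' iterations. An emptied cluster is repaired by moving in the path
#' that fits its current cluster worst.
#'
#' @param sites sites tibble (`tf`, `position`) or named path list.
#' @param region study region `c(lo, hi)`.
#' @param k number of clusters, `1 <= k <=` number of paths.
#' @param control an [nlk_control()].
#' @param seed optional integer seed.
#' @param init optional explicit initial assignment (integer vector in
#'   `1..k`); when given it replaces the first random initialisation.
#' @return object of class `nlk_partition` with fields `assignments`
#'   (named integer vector), `intensities`, `objective`, `n_iter`,
#'   `objective_trace`, `k`, `region`. Use [tidy()] / [glance()] /
#'   [autoplot()] on it.
#' @export
nlk_cluster <- function(sites, region, k, control = nlk_control(),
                        seed = NULL, init = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, nlk_cluster(sites, region, k,
                                              control = control, init = init)))
  }
  region <- as_region(region)
  paths <- as_path_list(sites, region)
  n <- length(paths)
  if (k < 1 || k > n) stop("need 1 <= k <= number of paths", call. = FALSE)

  run_one <- function(assignments) {
    fits <- lapply(seq_len(k), function(ci) {
      fit_intensity_mle(paths[assignments == ci], region, control$fit)
    })
    obj <- sum(vapply(fits, `[[`, numeric(1), "log_lik"))
    trace <- obj
    converged <- FALSE
    iter <- 0L
    while (iter < control$max_iter) {
      iter <- iter + 1L
      intensities <- lapply(fits, `[[`, "intensity")
      ll <- path_ll_matrix(paths, intensities)
      new_assign <- max.col(ll, ties.method = "first")
      new_assign <- repair_empty(new_assign, ll, k)
      stable <- identical(new_assign, assignments)
      assignments <- new_assign
      fits <- lapply(seq_len(k), function(ci) {
        fit_intensity_mle(paths[assignments == ci], region, control$fit,
                          warm_start = fits[[ci]]$intensity)
      })
      new_obj <- sum(vapply(fits, `[[`, numeric(1), "log_lik"))
      trace <- c(trace, new_obj)
      gain <- new_obj - obj
      obj <- new_obj
      if (stable || gain < control$tol) { converged <- TRUE; break }
    }
    list(assignments = assignments,
         intensities = lapply(fits, `[[`, "intensity"),
         objective = obj, trace = trace, n_iter = iter, converged = converged)
  }

  best <- NULL
  for (run in seq_len(control$n_init)) {
    a0 <- if (run == 1L && !is.null(init)) {
      stopifnot(length(init) == n, all(init %in% seq_len(k)))
      as.integer(init)
    } else {
      random_assignment(n, k)
    }
    res <- run_one(a0)
    if (is.null(best) || res$objective > best$objective) best <- res
  }

  structure(list(assignments = stats::setNames(best$assignments, names(paths)),
                 intensities = best$intensities, objective = best$objective,
                 objective_trace = best$trace, n_iter = best$n_iter,
                 converged = best$converged, k = k, region = region,
                 control = control),
            class = "nlk_partition")
}

#' @export
print.nlk_partition <- function(x, ...) {
  cat(sprintf("<nlk_partition> k = %d, %d paths, objective %.4f (%d iterations)\n",
              x$k, length(x$assignments), x$objective, x$n_iter))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Objective-vs-k profile for choosing the number of clusters
#'
#' Runs [nlk_cluster()] for each `k` and reports the best objective — a
#' reporting utility for elbow-style inspection; no k is chosen
#' automatically.
#'
#' @inheritParams nlk_cluster
#' @param ks integer vector of cluster counts to profile.
#' @return tibble with columns `k` and `objective`.
#' @export
nlk_profile <- function(sites, region, ks, control = nlk_control(), seed = NULL) {
  purrr::map_dfr(ks, function(k) {
    p <- nlk_cluster(sites, region, k, control = control,
                     seed = if (is.null(seed)) NULL else seed + k)
    tibble::tibble(k = k, objective = p$objective)
  })
}
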