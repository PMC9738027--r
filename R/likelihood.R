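#' NHPP log-likelihood of a sample path
#'
#' For a path with sites \eqn{s_1, ..., s_n} on region \eqn{D} and rate
#' \eqn{\lambda}, the log-likelihood (up to an additive constant dropped
#' consistently everywhere in this package) is
#' \deqn{\ell = -\int_D \lambda(s)\,ds + \sum_j \log \lambda(s_j),}
#' with \eqn{\lambda} clamped at the intensity's floor inside both terms.
#' An empty path contributes just the negative integral.
#'
#' @param path numeric vector of site coordinates (one TF's sample path),
#'   or a sites tibble / path list for the joint version.
#' @param intensity an [nhpp_intensity()].
#' @return log-likelihood value (numeric scalar).
#' @export
path_log_lik <- function(path, intensity) {
  r <- intensity$region
  path <- as.numeric(path)
  if (length(path) > 0 && (min(path) < r[1] || max(path) > r[2])) {
    stop("sites outside region", call. = FALSE)
  }
  ll <- -cumulative(intensity, r[1], r[2])
  if (length(path) > 0) ll <- ll + sum(log(intensity_at(intensity, path)))
  ll
}

#' @rdname path_log_lik
#' @param paths sites tibble (`tf`, `position`) or named list of paths.
#' @details `joint_log_lik()` sums [path_log_lik()] over paths, so the
#'   integral term enters once per path. An empty path list returns 0.
#' @export
joint_log_lik <- function(paths, intensity) {
  paths <- as_path_list(paths)
  if (length(paths) == 0) return(0)
  sum(vapply(paths, path_log_lik, numeric(1), intensity = intensity))
}

#' Simulate one NHPP sample path by thinning
#'
#' Lewis–Shedler thinning: homogeneous candidates at rate
#' `lambda_max` (the grid maximum of the clamped intensity over a
#' 10001-point grid, times a 1.0001 safety factor) are kept independently
#' with probability `lambda(t)/lambda_max`. Exact for bounded
#' intensities; event locations are not discretised.
#'
#' @param intensity an [nhpp_intensity()].
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param lambda_max optional precomputed dominating rate (callers
#'   simulating many paths from one intensity can cache it).
#' @return sorted numeric vector of event coordinates (possibly empty).
#' @export
simulate_nhpp <- function(intensity, seed = NULL, lambda_max = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_nhpp(intensity, lambda_max = lambda_max)))
  }
  r <- intensity$region
  if (is.null(lambda_max)) lambda_max <- dominating_rate(intensity)
  if (lambda_max <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, lambda_max * region_length(r))
  if (n_cand == 0) return(numeric(0))
  t_cand <- stats::runif(n_cand, r[1], r[2])
  keep <- stats::runif(n_cand) <= intensity_at(intensity, t_cand) / lambda_max
  sort(t_cand[keep])
}

dominating_rate <- function(intensity, n_grid = 10001L) {
  gv <- intensity_grid_raw(intensity, n_grid)
  max(max(gv$raw), intensity$floor) * 1.0001
}
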