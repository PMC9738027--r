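#' True cluster intensity functions of the simulation scenarios
#'
#' The four synthetic study conditions on the region `[0, 10]`:
#' * **S1** ("easy"): three one-frequency cosine intensities,
#'   `lambda_i(t) = 3 cos(i*pi*t/10) + 3` for frequency indices
#'   `i = 2, 3, 4`.
#' * **S2** ("moderate"): three two-frequency cosine combinations
#'   (`2cos(2pi t/10) - cos(3pi t/10)`, `2cos(3pi t/10) + cos(4pi t/10)`,
#'   `cos(2pi t/10) - 2cos(4pi t/10)`), each affinely rescaled so its
#'   range over `[0, 10]` is exactly `[0, 6]`.
#' * **S3** ("hard"): `k = 10` random intensities on a degree-6
#'   B-spline basis with 10 uniform interior knots, coefficients i.i.d.
#'   uniform(0, 1), each rescaled to `[0, 6]`; requires `seed` (or an
#'   active RNG stream) since the intensities themselves are random.
#' * **S4** (hierarchy demonstration): `5cos(2pi t/10) + 5`,
#'   `(5/2)cos(2pi t/10) + (15/4)cos(4pi t/10) + 15/4`, and
#'   `-5cos(2pi t/10) + 5`.
#'
#' @param scenario one of `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @param seed optional seed (only S3 draws random intensities).
#' @return list of [nhpp_intensity()] objects, one per cluster.
#' @export
scenario_intensities <- function(scenario, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, scenario_intensities(scenario)))
  }
  region <- c(0, 10)
  a <- sqrt(2 / 10)  # cosine-harmonic normalisation on [0, 10]
  dc <- 1 / sqrt(10)
  cosine <- function(const, harm) {
    # const + sum_i harm[i] * cos(i*pi*t/10) expressed in basis coefficients
    nhpp_intensity(c(const / dc, harm / a), region, basis = "cosine")
  }
  switch(scenario,
    S1 = list(cosine(3, c(0, 3, 0, 0)),
              cosine(3, c(0, 0, 3, 0)),
              cosine(3, c(0, 0, 0, 3))),
    S2 = lapply(list(cosine(0, c(0, 2, -1, 0)),
                     cosine(0, c(0, 0, 2, 1)),
                     cosine(0, c(0, 1, 0, -2))),
                rescale_intensity, lo = 0, hi = 6),
    S4 = list(cosine(5, c(0, 5, 0, 0)),
              cosine(15 / 4, c(0, 5 / 2, 0, 15 / 4)),
              cosine(5, c(0, -5, 0, 0))),
    S3 = {
      knots <- seq(0, 10, length.out = 12)[2:11]
      lapply(seq_len(10), function(ci) {
        co <- stats::runif(length(knots) + 7L)  # degree 6 -> order 7
        rescale_intensity(
          nhpp_intensity(co, region, basis = "bspline", knots = knots,
                         degree = 6L),
          lo = 0, hi = 6)
      })
    },
    stop("unknown scenario: ", scenario, call. = FALSE)
  )
}

# Affine rescale of the raw expansion so its grid range maps onto
# [lo, hi]. Stays inside the same basis: cosine -> scale all
# coefficients and shift the DC term; B-spline -> scale and shift all
# coefficients (the basis sums to one).
rescale_intensity <- function(intensity, lo = 0, hi = 6, n_grid = 10001L) {
  grid <- seq(intensity$region[1], intensity$region[2], length.out = n_grid)
  raw <- intensity_raw(intensity, grid)
  a <- (hi - lo) / (max(raw) - min(raw))
  b <- lo - a * min(raw)
  co <- intensity$coef * a
  if (intensity$basis == "cosine") {
    co[1] <- co[1] + b * sqrt(region_length(intensity$region))
  } else if (intensity$basis %in% c("bspline", "constant")) {
    co <- co + b
  } else {
    stop("cannot rescale basis kind: ", intensity$basis, call. = FALSE)
  }
  nhpp_intensity(co, intensity$region, basis = intensity$basis,
                 floor = intensity$floor, knots = intensity$knots,
                 degree = intensity$degree)
}

scenario_sizes <- function(scenario) {
  switch(scenario,
    S1 = c(10, 9, 11),
    S2 = c(15, 10, 5),
    S4 = c(3, 3, 4),
    S3 = NULL,  # random composition, drawn at generation time
    stop("unknown scenario: ", scenario, call. = FALSE)
  )
}

# Random composition of `total` into `k` parts, each >= minimum.
random_composition <- function(total, k, minimum = 3L) {
  extra <- total - k * minimum
  stopifnot(extra >= 0)
  cuts <- sort(sample.int(extra + k - 1L, k - 1L))
  minimum + diff(c(0L, cuts, extra + k)) - 1L
}

#' Generate one synthetic multi-TF dataset from a scenario
#'
#' Draws each TF's sample path from its cluster's intensity with the
#' exact thinning simulator. Cluster sizes are (10, 9, 11) for S1,
#' (15, 10, 5) for S2, (3, 3, 4) for S4, and a random composition of
#' 100 into 10 parts (each at least 3) for S3.
#'
#' @param scenario `"S1"`, `"S2"`, `"S3"` or `"S4"`.
#' @param seed optional integer seed; a given seed reproduces the
#'   dataset exactly (S3 redraws its random intensities under the same
#'   stream).
#' @return list of class `tf_scenario`: `sites` tibble (`tf` factor,
#'   `position`), `truth` tibble (`tf`, `cluster`), `intensities`,
#'   `region`.
#' @export
generate_scenario <- function(scenario, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_scenario(scenario)))
  }
  region <- c(0, 10)
  intensities <- scenario_intensities(scenario)
  sizes <- scenario_sizes(scenario)
  if (is.null(sizes)) sizes <- random_composition(100L, 10L)
  labels <- rep(seq_along(sizes), sizes)
  tf <- sprintf("TF%02d", seq_along(labels))
  lam_max <- vapply(intensities, dominating_rate, numeric(1))
  paths <- lapply(labels, function(ci) {
    simulate_nhpp(intensities[[ci]], lambda_max = lam_max[ci])
  })
  names(paths) <- tf
  structure(list(sites = paths_to_sites(paths),
                 truth = tibble::tibble(tf = factor(tf, levels = tf),
                                        cluster = labels),
                 intensities = intensities, region = region,
                 scenario = scenario),
            class = "tf_scenario")
}

#' @export
print.tf_scenario <- function(x, ...) {
  cat(sprintf("<tf_scenario %s> %d TFs, %d clusters, %d sites on [%g, %g]\n",
              x$scenario, nlevels(x$sites$tf), length(x$intensities),
              nrow(x$sites), x$region[1], x$region[2]))
  invisible(x)
}
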