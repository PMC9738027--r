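#' Evaluate one orthonormal basis function
#'
#' The cosine (DCT-type) family on a region `[lo, hi]` of length `T` is
#' `psi_0(t) = 1/sqrt(T)` and `psi_i(t) = sqrt(2/T) cos(i*pi*(t-lo)/T)`
#' for `i >= 1`; it is orthonormal under the L2 inner product on the
#' region. The `constant` basis is `psi_0(t) = 1`, so a constant
#' intensity's single coefficient is its rate. The `bspline` basis is
#' evaluated through [splines::splineDesign()] and is indexed `0..K-1`
#' over the spline design columns (not orthonormal).
#'
#' @param basis one of `"cosine"`, `"constant"`, `"bspline"`.
#' @param i basis index, `i >= 0`.
#' @param t coordinate(s) inside `region`.
#' @param region study region `c(lo, hi)`.
#' @param knots,degree B-spline interior knots and degree (bspline only).
#' @return numeric vector of basis values at `t`.
#' @export
basis_eval <- function(basis, i, t, region, knots = NULL, degree = 6L) {
  region <- as_region(region)
  if (any(t < region[1] | t > region[2])) {
    stop("`t` outside region", call. = FALSE)
  }
  B <- basis_matrix(basis, t, region, n_basis = i + 1L, knots = knots, degree = degree)
  if (i + 1L > ncol(B)) stop("basis index out of range", call. = FALSE)
  B[, i + 1L]
}

# Design matrix with columns psi_0 .. psi_{n_basis-1} at coordinates t.
basis_matrix <- function(basis, t, region, n_basis, knots = NULL, degree = 6L) {
  T_len <- region_length(region)
  u <- t - region[1]
  switch(basis,
    cosine = {
      i <- seq_len(n_basis) - 1L
      B <- outer(u, i, function(uu, ii) cos(ii * pi * uu / T_len))
      B <- sweep(B, 2, c(1 / sqrt(T_len), rep(sqrt(2 / T_len), n_basis - 1L))[seq_len(n_basis)],
                 `*`)
      # column 0 is the constant 1/sqrt(T): cos(0)=1 already handled by sweep
      B
    },
    constant = matrix(1, nrow = length(u), ncol = 1L),
    bspline = {
      if (is.null(knots)) {
        stop("bspline basis requires `knots` (interior knots)", call. = FALSE)
      }
      ord <- degree + 1L
      full <- c(rep(region[1], ord), sort(knots), rep(region[2], ord))
      splines::splineDesign(full, x = t, ord = ord, outer.ok = FALSE)
    },
    stop("unknown basis kind: ", basis, call. = FALSE)
  )
}

#' Construct an intensity function object
#'
#' An NHPP intensity represented by basis coefficients:
#' `lambda(t) = max(sum_i c_i psi_i(t), floor)`. The small positive
#' `floor` keeps the rate strictly positive, which the point-process
#' log-likelihood requires at observed sites; the raw basis expansion is
#' free to dip below zero.
#'
#' @param coef numeric coefficient vector `c_0, c_1, ...`.
#' @param region study region `c(lo, hi)`.
#' @param basis basis kind (see [basis_eval()]).
#' @param floor clamp level, default `1e-8` events per unit length.
#' @param knots,degree B-spline parameters (bspline basis only).
#' @return object of class `nhpp_intensity`.
#' @export
nhpp_intensity <- function(coef, region, basis = "cosine", floor = 1e-8,
                           knots = NULL, degree = 6L) {
  region <- as_region(region)
  stopifnot(length(coef) >= 1, is.numeric(coef), floor > 0)
  structure(
    list(coef = as.numeric(coef), basis = basis, region = region,
         floor = floor, knots = knots, degree = as.integer(degree)),
    class = "nhpp_intensity"
  )
}

#' @export
print.nhpp_intensity <- function(x, ...) {
  cat(sprintf("<nhpp_intensity> %s basis, %d coefficient(s) on [%g, %g]\n",
              x$basis, length(x$coef), x$region[1], x$region[2]))
  cat("  coef:", paste(signif(x$coef, 4), collapse = " "), "\n")
  invisible(x)
}

# Raw (unclamped) basis expansion at t.
intensity_raw <- function(intensity, t) {
  B <- basis_matrix(intensity$basis, t, intensity$region,
                    n_basis = length(intensity$coef),
                    knots = intensity$knots, degree = intensity$degree)
  drop(B %*% intensity$coef)
}

#' Evaluate an intensity function
#'
#' Returns the clamped rate `max(sum_i c_i psi_i(t), floor)`; never zero
#' or negative.
#'
#' @param intensity an [nhpp_intensity()].
#' @param t coordinate(s); must lie inside the intensity's region.
#' @return numeric rate(s) at `t`.
#' @export
intensity_at <- function(intensity, t) {
  r <- intensity$region
  if (any(t < r[1] | t > r[2])) stop("`t` outside region", call. = FALSE)
  pmax(intensity_raw(intensity, t), intensity$floor)
}

# Cache of basis design matrices on canonical evaluation grids — the
# clustering loops evaluate the same (basis, region, K) design thousands
# of times on fixed grids.
.grid_cache <- new.env(parent = emptyenv())

grid_basis <- function(basis, region, n_basis, n_grid, knots = NULL,
                       degree = 6L) {
  key <- paste(basis, region[1], region[2], n_basis, n_grid,
               paste(knots, collapse = ","), degree, sep = "|")
  hit <- .grid_cache[[key]]
  if (!is.null(hit)) return(hit)
  grid <- seq(region[1], region[2], length.out = n_grid)
  out <- list(grid = grid,
              w = if (n_grid %% 2 == 1) simpson_weights(n_grid, grid[2] - grid[1]),
              B = basis_matrix(basis, grid, region, n_basis, knots, degree))
  .grid_cache[[key]] <- out
  out
}

intensity_grid_raw <- function(intensity, n_grid) {
  gb <- grid_basis(intensity$basis, intensity$region, length(intensity$coef),
                   n_grid, intensity$knots, intensity$degree)
  list(grid = gb$grid, w = gb$w, raw = as.vector(gb$B %*% intensity$coef))
}

# Simpson weights on an odd-length uniform grid.
simpson_weights <- function(n, h) {
  stopifnot(n >= 3, n %% 2 == 1)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  w * h / 3
}

# Integrate f given as values on a uniform odd grid.
simpson_grid <- function(a, b, n = 2001L) {
  seq(a, b, length.out = n)
}

#' Expected event count over an interval
#'
#' `cumulative(intensity, a, b)` is the integral of the clamped rate over
#' `[a, b]`, i.e. the Poisson mean of the event count there. Cosine and
#' constant bases use closed forms when the raw expansion stays above the
#' clamp level on a fine check grid; otherwise (and for B-splines) a
#' composite-Simpson rule on a 2001-point grid integrates the clamped
#' values.
#'
#' @inheritParams intensity_at
#' @param a,b interval endpoints, `region lo <= a <= b <= hi`.
#' @return nonnegative expected count; `a == b` gives 0.
#' @export
cumulative <- function(intensity, a, b) {
  r <- intensity$region
  if (a > b) stop("need a <= b", call. = FALSE)
  if (a < r[1] || b > r[2]) stop("interval outside region", call. = FALSE)
  if (a == b) return(0)
  if (a == r[1] && b == r[2]) {
    gv <- intensity_grid_raw(intensity, 2001L)
    raw <- gv$raw
  } else {
    gv <- list(grid = simpson_grid(a, b))
    gv$w <- simpson_weights(length(gv$grid), gv$grid[2] - gv$grid[1])
    raw <- intensity_raw(intensity, gv$grid)
  }
  if (intensity$basis %in% c("cosine", "constant") && all(raw >= intensity$floor)) {
    return(cumulative_closed(intensity, a, b))
  }
  raw[raw < intensity$floor] <- intensity$floor
  sum(gv$w * raw)
}

# Analytic integral of the raw cosine/constant expansion over [a, b].
cumulative_closed <- function(intensity, a, b) {
  if (intensity$basis == "constant") return(intensity$coef[1] * (b - a))
  T_len <- region_length(intensity$region)
  u_a <- a - intensity$region[1]; u_b <- b - intensity$region[1]
  co <- intensity$coef
  total <- co[1] / sqrt(T_len) * (b - a)
  if (length(co) > 1) {
    i <- seq_len(length(co) - 1L)
    ints <- sqrt(2 / T_len) * (T_len / (i * pi)) *
      (sin(i * pi * u_b / T_len) - sin(i * pi * u_a / T_len))
    total <- total + sum(co[-1] * ints)
  }
  total
}

#' L2 distance between two intensity functions
#'
#' `sqrt(integral over D of (lambda_a - lambda_b)^2)`, computed on the raw
#' basis representations. When both intensities share the orthonormal
#' cosine basis this is the Euclidean distance between (zero-padded)
#' coefficient vectors; otherwise composite Simpson quadrature is used.
#'
#' @param a,b [nhpp_intensity()] objects on the same region.
#' @return nonnegative distance.
#' @export
l2_distance <- function(a, b) {
  if (!isTRUE(all.equal(a$region, b$region))) {
    stop("intensities live on different regions", call. = FALSE)
  }
  if (a$basis == "cosine" && b$basis == "cosine") {
    k <- max(length(a$coef), length(b$coef))
    ca <- c(a$coef, rep(0, k - length(a$coef)))
    cb <- c(b$coef, rep(0, k - length(b$coef)))
    return(sqrt(sum((ca - cb)^2)))
  }
  grid <- simpson_grid(a$region[1], a$region[2])
  d2 <- (intensity_raw(a, grid) - intensity_raw(b, grid))^2
  sqrt(sum(simpson_weights(length(grid), grid[2] - grid[1]) * d2))
}
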