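#' Per-TF binding-site counts over equal-width windows
#'
#' Splits the region into `w` equal windows `[lo + (j-1)d, lo + j*d)`
#' (the last window closed on the right) and counts each TF's sites per
#' window. Row sums equal each path's site count.
#'
#' @param sites sites tibble or path list.
#' @param region study region `c(lo, hi)`.
#' @param w number of windows, `w >= 2`.
#' @return integer matrix, one row per TF, `w` columns.
#' @export
window_counts <- function(sites, region, w) {
  region <- as_region(region)
  if (w < 2) stop("need w >= 2", call. = FALSE)
  paths <- as_path_list(sites, region)
  breaks <- seq(region[1], region[2], length.out = w + 1L)
  counts <- t(vapply(paths, function(p) {
    idx <- pmin(findInterval(p, breaks, left.open = FALSE), w)
    tabulate(idx, nbins = w)
  }, integer(w)))
  rownames(counts) <- names(paths)
  counts
}

baseline_partition <- function(assignments, k, method, param) {
  structure(list(assignments = assignments, k = k, method = method,
                 param = param),
            class = c("baseline_partition"))
}

#' Window-count clustering baselines
#'
#' Traditional clustering on the vectors of per-window site counts:
#' `window_kmeans()` runs seeded multistart Lloyd K-means,
#' `window_hclust()` agglomerates with Ward linkage on Euclidean
#' distances and cuts at `k`. These are the conventional comparison
#' methods the likelihood approaches are measured against.
#'
#' @inheritParams window_counts
#' @param k number of clusters.
#' @param seed optional seed for the K-means starts.
#' @param n_start number of K-means starts.
#' @return `baseline_partition` with a named `assignments` vector.
#' @export
window_kmeans <- function(sites, region, k, w, seed = NULL, n_start = 10L) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, window_kmeans(sites, region, k, w,
                                                n_start = n_start)))
  }
  counts <- window_counts(sites, region, w)
  if (k > nrow(counts)) stop("k exceeds number of paths", call. = FALSE)
  km <- suppressWarnings(
    stats::kmeans(counts, centers = k, nstart = n_start,
                  algorithm = "Lloyd", iter.max = 100L))
  baseline_partition(stats::setNames(km$cluster, rownames(counts)),
                     k, "window_kmeans", w)
}

#' @rdname window_kmeans
#' @export
window_hclust <- function(sites, region, k, w) {
  counts <- window_counts(sites, region, w)
  if (k > nrow(counts)) stop("k exceeds number of paths", call. = FALSE)
  hc <- stats::hclust(stats::dist(counts), method = "ward.D2")
  baseline_partition(stats::cutree(hc, k = k), k, "window_hclust", w)
}

#' Pair-distance (K-function-style) clustering baseline
#'
#' Similarity between two TFs = number of cross pairs of binding sites
#' within `threshold` of each other, normalised by the product of site
#' counts; distances `1 - similarity` are min–max rescaled to `[0, 1]`
#' over the TF pairs and clustered by average-linkage agglomeration cut
#' at `k`.
#'
#' @inheritParams window_kmeans
#' @param threshold distance threshold in region units, `> 0`.
#' @return `baseline_partition`.
#' @export
kfunction_hclust <- function(sites, region, k, threshold) {
  if (threshold <= 0) stop("need threshold > 0", call. = FALSE)
  region <- as_region(region)
  paths <- as_path_list(sites, region)
  n <- length(paths)
  sim <- matrix(1, n, n, dimnames = list(names(paths), names(paths)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    na <- length(paths[[i]]); nb <- length(paths[[j]])
    sim[i, j] <- sim[j, i] <- if (na == 0 || nb == 0) 0 else {
      sum(abs(outer(paths[[i]], paths[[j]], `-`)) <= threshold) / (na * nb)
    }
  }
  d <- 1 - sim
  off <- d[upper.tri(d)]
  if (diff(range(off)) > 0) d <- (d - min(off)) / diff(range(off))
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  baseline_partition(stats::cutree(hc, k = k), k, "kfunction_hclust", threshold)
}

#' Co-localization-vector clustering baseline
#'
#' Bins the region at width `threshold`, builds each TF's
#' co-localization vector of per-bin site counts, uses
#' `1 - Pearson correlation` between vectors as the distance, and
#' agglomerates with average linkage cut at `k`. A TF with a constant
#' (zero-variance) vector gets correlation 0 to every other TF, with a
#' message.
#'
#' @inheritParams kfunction_hclust
#' @return `baseline_partition`.
#' @export
coloc_hclust <- function(sites, region, k, threshold) {
  if (threshold <= 0) stop("need threshold > 0", call. = FALSE)
  region <- as_region(region)
  w <- max(2L, as.integer(ceiling(region_length(region) / threshold)))
  counts <- window_counts(sites, region, w)
  const <- apply(counts, 1, stats::sd) == 0
  r <- suppressWarnings(stats::cor(t(counts)))
  r[const, ] <- 0; r[, const] <- 0
  if (any(const)) {
    message("constant co-localization vector for: ",
            paste(rownames(counts)[const], collapse = ", "))
  }
  d <- 1 - r
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  baseline_partition(stats::cutree(hc, k = k), k, "coloc_hclust", threshold)
}

#' Oracle grid search over a baseline's tuning parameter
#'
#' For each grid value, runs a replicated experiment
#' ([evaluate_replicates()] with shared seeds across grid values) and
#' returns the parameter minimising AMCR together with that AMCR/PPC
#' and the whole AMCR-vs-parameter curve. The search scores candidate
#' parameters against the *true* labels, so it is an evaluation device
#' that gives the baselines their most favourable setting — not a
#' usable clustering procedure (real data have no true labels).
#'
#' @param scenario scenario id for [generate_scenario()].
#' @param method_factory function `(param) -> method`, e.g.
#'   `function(w) method_window_kmeans(w)`.
#' @param grid non-empty vector of parameter values.
#' @param n_rep replicates per grid value.
#' @param base_seed seed of the first replicate (shared across grid
#'   values, so comparisons are paired).
#' @return list: `best_param`, `amcr`, `ppc`, and `curve` (tibble
#'   `param`, `amcr`, `ppc`).
#' @export
optimal_grid_search <- function(scenario, method_factory, grid, n_rep,
                                base_seed = 1L) {
  if (length(grid) == 0) stop("empty grid", call. = FALSE)
  scns <- lapply(seq_len(n_rep) - 1L, function(r) {
    generate_scenario(scenario, seed = base_seed + r)
  })
  curve <- purrr::map_dfr(grid, function(param) {
    method <- method_factory(param)
    rates <- vapply(seq_len(n_rep), function(r) {
      mcr(scns[[r]]$truth$cluster, method(scns[[r]], base_seed + r - 1L))
    }, numeric(1))
    tibble::tibble(param = param, amcr = mean(rates), ppc = mean(rates == 0))
  })
  best <- which.min(curve$amcr)
  list(best_param = curve$param[best], amcr = curve$amcr[best],
       ppc = curve$ppc[best], curve = curve)
}
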