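#' Co-membership adjacency matrix of a clustering
#'
#' Binary n-by-n matrix with entry (i, j) = 1 exactly when items i and j
#' carry the same cluster label; zero diagonal, symmetric, and invariant
#' to any relabelling of the clusters.
#'
#' @param labels vector of cluster labels (any type).
#' @return integer 0/1 matrix.
#' @export
adjacency <- function(labels) {
  A <- outer(labels, labels, `==`) * 1L
  diag(A) <- 0L
  unname(A)
}

#' Misclassification rate between two labelings
#'
#' Fraction of the `choose(n, 2)` upper-triangular co-membership
#' indicators on which the two labelings disagree. Label-invariant: a
#' prediction that is a relabelling of the truth scores 0.
#'
#' @param truth,predicted label vectors of equal length.
#' @return value in `[0, 1]`.
#' @export
mcr <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("labelings have different lengths", call. = FALSE)
  }
  ut <- upper.tri(diag(length(truth)))
  mean(adjacency(truth)[ut] != adjacency(predicted)[ut])
}

#' Replicated clustering evaluation (AMCR / PPC)
#'
#' Repeats: generate a scenario dataset, run a clustering method,
#' score it with [mcr()] against the true labels. Replicate `r` uses
#' seed `base_seed + r - 1` for both the data and the method, so the
#' whole experiment is reproducible. Reports the average
#' misclassification rate (AMCR) and the proportion of perfect
#' classification (PPC: fraction of replicates with mcr exactly 0).
#'
#' @param scenario scenario id passed to [generate_scenario()].
#' @param method function `(scn, seed) -> labels`, where `scn` is a
#'   `tf_scenario`; see [method_nlk()] and friends.
#' @param n_rep number of replicates `T >= 1`.
#' @param base_seed integer seed of the first replicate.
#' @return list of class `eval_summary`: `amcr`, `ppc`, `n_rep`, and the
#'   per-replicate `mcr` vector.
#' @export
evaluate_replicates <- function(scenario, method, n_rep, base_seed = 1L) {
  if (n_rep < 1) stop("need n_rep >= 1", call. = FALSE)
  rates <- vapply(seq_len(n_rep), function(r) {
    seed <- base_seed + r - 1L
    scn <- generate_scenario(scenario, seed = seed)
    mcr(scn$truth$cluster, method(scn, seed))
  }, numeric(1))
  structure(list(amcr = mean(rates), ppc = mean(rates == 0),
                 n_rep = n_rep, mcr = rates, scenario = scenario),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("<eval_summary %s> T = %d: AMCR %.4f, PPC %.1f%%\n",
              x$scenario, x$n_rep, x$amcr, 100 * x$ppc))
  invisible(x)
}

#' Clustering method adapters for replicated evaluation
#'
#' Each constructor returns a function `(scn, seed) -> labels` usable
#' with [evaluate_replicates()]. `method_nlk()` runs [nlk_cluster()] at
#' the scenario's true `k`; `method_window_kmeans()` /
#' `method_window_hclust()` run the window-count baselines at window
#' count `w`; `method_kfunction()` and `method_coloc()` run the
#' pair-distance and co-localization baselines at a distance
#' `threshold`; `method_oracle()` returns the true labels (a check of
#' the evaluation machinery itself).
#'
#' @param control method control object where applicable.
#' @param k number of clusters; default `NULL` uses the scenario truth.
#' @return a method function.
#' @export
method_nlk <- function(control = nlk_control(), k = NULL) {
  function(scn, seed) {
    kk <- if (is.null(k)) length(scn$intensities) else k
    nlk_cluster(scn$sites, scn$region, kk, control = control, seed = seed)$assignments
  }
}

#' @rdname method_nlk
#' @param w number of equal-width windows.
#' @export
method_window_kmeans <- function(w, k = NULL) {
  function(scn, seed) {
    kk <- if (is.null(k)) length(scn$intensities) else k
    window_kmeans(scn$sites, scn$region, kk, w, seed = seed)$assignments
  }
}

#' @rdname method_nlk
#' @export
method_window_hclust <- function(w, k = NULL) {
  function(scn, seed) {
    kk <- if (is.null(k)) length(scn$intensities) else k
    window_hclust(scn$sites, scn$region, kk, w)$assignments
  }
}

#' @rdname method_nlk
#' @param threshold distance threshold (region units).
#' @export
method_kfunction <- function(threshold, k = NULL) {
  function(scn, seed) {
    kk <- if (is.null(k)) length(scn$intensities) else k
    kfunction_hclust(scn$sites, scn$region, kk, threshold)$assignments
  }
}

#' @rdname method_nlk
#' @export
method_coloc <- function(threshold, k = NULL) {
  function(scn, seed) {
    kk <- if (is.null(k)) length(scn$intensities) else k
    coloc_hclust(scn$sites, scn$region, kk, threshold)$assignments
  }
}

#' @rdname method_nlk
#' @export
method_oracle <- function() {
  function(scn, seed) scn$truth$cluster
}
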