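#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for nhppclust result objects
#'
#' `tidy()` returns the per-element view of a result: fitted
#' coefficients for an intensity fit, per-TF cluster assignments for an
#' NLK partition or baseline partition, and the merge history for an
#' NLH dendrogram. `glance()` returns a one-row model summary.
#'
#' @param x a fitted object.
#' @param ... unused.
#' @return a tibble.
#' @name nhppclust-tidiers
NULL

#' @rdname nhppclust-tidiers
#' @export
tidy.nhpp_fit <- function(x, ...) {
  tibble::tibble(term = paste0("c", seq_along(x$intensity$coef) - 1L),
                 estimate = x$intensity$coef)
}

#' @rdname nhppclust-tidiers
#' @export
glance.nhpp_fit <- function(x, ...) {
  tibble::tibble(basis = x$intensity$basis,
                 n_coef = length(x$intensity$coef),
                 log_lik = x$log_lik, converged = x$converged,
                 n_paths = x$n_paths, n_sites = x$n_sites)
}

#' @rdname nhppclust-tidiers
#' @export
tidy.nlk_partition <- function(x, ...) {
  tibble::tibble(tf = names(x$assignments),
                 cluster = unname(x$assignments))
}

#' @rdname nhppclust-tidiers
#' @export
glance.nlk_partition <- function(x, ...) {
  tibble::tibble(k = x$k, objective = x$objective, n_iter = x$n_iter,
                 converged = x$converged, n_tfs = length(x$assignments))
}

#' @rdname nhppclust-tidiers
#' @export
tidy.baseline_partition <- function(x, ...) {
  tibble::tibble(tf = names(x$assignments),
                 cluster = unname(x$assignments))
}

#' @rdname nhppclust-tidiers
#' @export
tidy.nlh_dendrogram <- function(x, ...) {
  linkage_table(x)
}

#' @rdname nhppclust-tidiers
#' @export
glance.nlh_dendrogram <- function(x, ...) {
  tibble::tibble(n_leaves = length(x$labels), n_merges = nrow(x$merge),
                 min_height = min(x$height), max_height = max(x$height))
}

#' @rdname nhppclust-tidiers
#' @export
tidy.eval_summary <- function(x, ...) {
  tibble::tibble(replicate = seq_len(x$n_rep), mcr = x$mcr)
}

#' @rdname nhppclust-tidiers
#' @export
glance.eval_summary <- function(x, ...) {
  tibble::tibble(scenario = x$scenario, n_rep = x$n_rep,
                 amcr = x$amcr, ppc = x$ppc)
}
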