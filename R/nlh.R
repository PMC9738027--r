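#' NHPP-likelihood linkage between two clusters of sample paths
#'
#' Fits one intensity per cluster and returns the symmetrised negative
#' cross log-likelihood
#' \deqn{D(G_a, G_b) = -\Big[\sum_{s \in G_b} \log\pi(s\,|\,\hat\lambda_a)
#'   + \sum_{s \in G_a} \log\pi(s\,|\,\hat\lambda_b)\Big].}
#' Symmetric by construction; can be negative (paths that are very
#' likely under the other cluster's intensity give a positive cross
#' log-likelihood).
#'
#' @param cluster_a,cluster_b non-empty path lists (or sites tibbles).
#' @param region study region `c(lo, hi)`.
#' @param control [fit_control()] for the two intensity fits.
#' @return numeric linkage value.
#' @export
likelihood_linkage <- function(cluster_a, cluster_b, region,
                               control = fit_control()) {
  a <- as_path_list(cluster_a); b <- as_path_list(cluster_b)
  if (length(a) == 0 || length(b) == 0) stop("empty cluster", call. = FALSE)
  fa <- fit_intensity_mle(a, region, control)
  fb <- fit_intensity_mle(b, region, control)
  cross_linkage(a, b, fa$intensity, fb$intensity)
}

cross_linkage <- function(a, b, intensity_a, intensity_b) {
  -(joint_log_lik(b, intensity_a) + joint_log_lik(a, intensity_b))
}

#' NHPP-likelihood hierarchical (NLH) clustering
#'
#' Agglomerative clustering of sample paths under the likelihood
#' linkage: starting from singletons, the pair of current clusters with
#' the smallest [likelihood_linkage()] is merged; after each merge the
#' merged cluster's intensity is refitted and its linkage to every other
#' cluster recomputed (the linkage is defined on clusters, so no
#' Lance–Williams update applies). Ties break toward the lexicographically
#' smallest pair of cluster creation indices. Raw merge heights are not
#' necessarily monotone across merges and nothing here assumes they are.
#'
#' @param sites sites tibble (`tf`, `position`) or named path list
#'   (at least 2 paths).
#' @param region study region `c(lo, hi)`.
#' @param control [fit_control()] used for every cluster intensity.
#' @param seed optional seed (the fits' random restarts).
#' @return object of class `nlh_dendrogram`: `merge` (an
#'   `(n-1) x 2` matrix in [stats::hclust()] convention — negative
#'   entries are leaves, positive entries earlier merges), `height`
#'   (raw linkage per merge), `display_height` (the [1, 10] affine
#'   rescaling from [scale_branch_lengths()]), `labels`, `size`
#'   (cluster size after each merge).
#' @export
nlh_cluster <- function(sites, region, control = fit_control(), seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, nlh_cluster(sites, region, control = control)))
  }
  region <- as_region(region)
  paths <- as_path_list(sites, region)
  n <- length(paths)
  if (n < 2) stop("need at least 2 paths", call. = FALSE)

  # Active clusters: member path indices, fitted intensity, hclust node id
  # (negative leaf / positive merge), creation index for tie-breaking.
  members <- as.list(seq_len(n))
  intens <- lapply(seq_len(n), function(i) {
    fit_intensity_mle(paths[i], region, control)$intensity
  })
  node_id <- -seq_len(n)
  created <- seq_len(n)
  next_created <- n

  link <- matrix(NA_real_, n, n)
  pair_link <- function(i, j) {
    cross_linkage(paths[members[[i]]], paths[members[[j]]],
                  intens[[i]], intens[[j]])
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) link[i, j] <- pair_link(i, j)

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  size <- integer(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(members)
    # minimum linkage; ties -> lexicographically smallest creation pair
    best <- NULL
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      cand <- list(v = link[i, j],
                   key = sort(c(created[i], created[j])), i = i, j = j)
      if (is.null(best) || cand$v < best$v ||
          (cand$v == best$v && (cand$key[1] < best$key[1] ||
            (cand$key[1] == best$key[1] && cand$key[2] < best$key[2])))) {
        best <- cand
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(node_id[i], node_id[j]))
    height[step] <- best$v
    new_members <- c(members[[i]], members[[j]])
    size[step] <- length(new_members)

    keep <- setdiff(seq_len(m), c(i, j))
    members <- c(members[keep], list(new_members))
    intens <- c(intens[keep],
                list(fit_intensity_mle(paths[new_members], region, control)$intensity))
    node_id <- c(node_id[keep], step)
    next_created <- next_created + 1L
    created <- c(created[keep], next_created)

    old_link <- link
    m2 <- length(members)
    link <- matrix(NA_real_, m2, m2)
    if (m2 > 1L) {
      if (length(keep) > 1L) {
        link[seq_along(keep), seq_along(keep)] <-
          old_link[keep, keep, drop = FALSE]
      }
      for (q in seq_along(keep)) {
        link[q, m2] <- pair_link(q, m2)
      }
    }
  }

  dend <- structure(list(merge = merge, height = height,
                         display_height = NULL, size = size,
                         labels = names(paths), region = region,
                         control = control),
                    class = "nlh_dendrogram")
  scale_branch_lengths(dend)
}

#' Rescale raw merge heights to display heights in [1, 10]
#'
#' Affine map of the raw linkage heights onto `[1, 10]`, preserving
#' order. If all heights are equal (including a single merge) every
#' display height is 1.
#'
#' @param dendrogram an `nlh_dendrogram`.
#' @return the dendrogram with `display_height` filled in.
#' @export
scale_branch_lengths <- function(dendrogram) {
  h <- dendrogram$height
  rng <- range(h)
  dendrogram$display_height <- if (diff(rng) == 0) {
    rep(1, length(h))
  } else {
    1 + 9 * (h - rng[1]) / diff(rng)
  }
  dendrogram
}

#' @export
print.nlh_dendrogram <- function(x, ...) {
  cat(sprintf("<nlh_dendrogram> %d leaves, %d merges\n",
              length(x$labels), nrow(x$merge)))
  cat("  raw heights:", paste(signif(x$height, 4), collapse = " "), "\n")
  invisible(x)
}

# Members (path indices) of the cluster created at merge `step`.
merge_members <- function(merge, step) {
  out <- integer(0)
  for (id in merge[step, ]) {
    out <- c(out, if (id < 0) -id else merge_members(merge, id))
  }
  out
}

#' Cut an NLH dendrogram into flat clusters
#'
#' `k` clusters are obtained by undoing the last `k - 1` merges (the
#' merge sequence, not the heights, defines the nesting — raw likelihood
#' linkages need not be monotone). Alternatively `h` stops the merge
#' sequence before the first merge whose raw height exceeds `h`.
#'
#' @param dendrogram an `nlh_dendrogram`.
#' @param k desired number of clusters, or
#' @param h raw-height threshold (used only when `k` is missing).
#' @return named integer vector of cluster ids (1-based, in order of
#'   first appearance).
#' @export
cut_dendrogram <- function(dendrogram, k = NULL, h = NULL) {
  n <- length(dendrogram$labels)
  n_steps <- if (!is.null(k)) {
    stopifnot(k >= 1, k <= n)
    n - k
  } else if (!is.null(h)) {
    over <- which(dendrogram$height > h)
    if (length(over) == 0) n - 1L else min(over) - 1L
  } else {
    stop("supply k or h", call. = FALSE)
  }
  labels <- seq_len(n)
  if (n_steps > 0) {
    for (step in seq_len(n_steps)) {
      mem <- merge_members(dendrogram$merge, step)
      labels[mem] <- min(labels[mem])
    }
  }
  out <- match(labels, unique(labels))
  stats::setNames(out, dendrogram$labels)
}

#' Export an NLH dendrogram
#'
#' `write_newick()` writes a Newick string with leaf names set to TF
#' labels; each child edge of a merge carries that merge's display
#' height as its branch length. `linkage_table()` returns the merge
#' history as a tibble (`step`, `node_a`, `node_b`, `height`,
#' `display_height`, `size`), with the [stats::hclust()] node
#' convention.
#'
#' @param dendrogram an `nlh_dendrogram`.
#' @param file output path for the Newick text.
#' @return `write_newick()` the file path invisibly; `linkage_table()` a
#'   tibble.
#' @export
write_newick <- function(dendrogram, file) {
  lab <- gsub("[,();: ]", "_", dendrogram$labels)
  node_str <- function(id, len) {
    body <- if (id < 0) {
      lab[-id]
    } else {
      h <- dendrogram$display_height[id]
      sprintf("(%s,%s)", node_str(dendrogram$merge[id, 1], h),
              node_str(dendrogram$merge[id, 2], h))
    }
    if (is.na(len)) body else sprintf("%s:%g", body, len)
  }
  writeLines(paste0(node_str(nrow(dendrogram$merge), NA_real_), ";"), file)
  invisible(file)
}

#' @rdname write_newick
#' @export
linkage_table <- function(dendrogram) {
  tibble::tibble(step = seq_len(nrow(dendrogram$merge)),
                 node_a = dendrogram$merge[, 1], node_b = dendrogram$merge[, 2],
                 height = dendrogram$height,
                 display_height = dendrogram$display_height,
                 size = dendrogram$size)
}
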