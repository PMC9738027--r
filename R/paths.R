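#' Validate a genomic study region
#'
#' A region is a length-2 numeric `c(lo, hi)` with `lo < hi`, the interval
#' \eqn{D} on which binding sites live (after preprocessing, typically
#' `c(0, 10)`).
#'
#' @param region numeric length-2, `c(lo, hi)`.
#' @return the validated region (invisibly unchanged).
#' @export
as_region <- function(region) {
  if (!is.numeric(region) || length(region) != 2 || anyNA(region)) {
    stop("`region` must be a numeric vector c(lo, hi)", call. = FALSE)
  }
  if (region[1] >= region[2]) {
    stop("`region` must satisfy lo < hi", call. = FALSE)
  }
  unname(as.numeric(region))
}

region_length <- function(region) region[2] - region[1]

#' Convert a sites table to a list of sample paths
#'
#' User-facing functions accept binding sites as a tibble with columns
#' `tf` (factor or character) and `position` (numeric). Internally each
#' TF becomes one sample path: a sorted numeric vector of site
#' coordinates. A factor `tf` preserves levels, so TFs with zero sites
#' keep an (empty) path; a character `tf` uses order of appearance.
#'
#' @param sites tibble with columns `tf` and `position`, or an
#'   already-built named list of numeric vectors.
#' @param region optional region; when given, all sites are checked to
#'   lie inside it.
#' @return named list of sorted numeric vectors, one per TF.
#' @export
as_path_list <- function(sites, region = NULL) {
  if (is.list(sites) && !is.data.frame(sites)) {
    paths <- lapply(sites, function(p) sort(as.numeric(p)))
    if (is.null(names(paths))) {
      names(paths) <- sprintf("TF%02d", seq_along(paths))
    }
  } else {
    sites <- tibble::as_tibble(sites)
    if (!all(c("tf", "position") %in% names(sites))) {
      stop("`sites` must have columns `tf` and `position`", call. = FALSE)
    }
    tf <- sites$tf
    lev <- if (is.factor(tf)) levels(tf) else unique(as.character(tf))
    paths <- split(as.numeric(sites$position), factor(as.character(tf), levels = lev))
    paths <- lapply(paths, sort)
  }
  if (!is.null(region)) {
    region <- as_region(region)
    bad <- vapply(paths, function(p) {
      length(p) > 0 && (min(p) < region[1] || max(p) > region[2])
    }, logical(1))
    if (any(bad)) {
      stop("sites outside the region for: ", paste(names(paths)[bad], collapse = ", "),
           call. = FALSE)
    }
  }
  paths
}

#' Convert a list of sample paths to a sites tibble
#'
#' @param paths named list of numeric vectors (one sample path per TF).
#' @return tibble with columns `tf` (factor, levels in path order) and
#'   `position`, one row per binding site.
#' @export
paths_to_sites <- function(paths) {
  nm <- names(paths)
  tibble::tibble(
    tf = factor(rep(nm, lengths(paths)), levels = nm),
    position = as.numeric(unlist(paths, use.names = FALSE))
  )
}

#' Read / write sample paths as tab-separated text
#'
#' One row per binding site: `tf <TAB> position`. The writer/reader pair
#' round-trips row-for-row.
#'
#' @param file path to a TSV file.
#' @return `read_sites()` returns a sites tibble (`tf` as factor in
#'   first-appearance order, `position` numeric).
#' @export
read_sites <- function(file) {
  x <- readr::read_tsv(file, col_types = readr::cols(
    tf = readr::col_character(), position = readr::col_double()
  ))
  x$tf <- factor(x$tf, levels = unique(x$tf))
  tibble::as_tibble(x)
}

#' @rdname read_sites
#' @param sites sites tibble (columns `tf`, `position`).
#' @export
write_sites <- function(sites, file) {
  out <- tibble::tibble(tf = as.character(sites$tf), position = sites$position)
  readr::write_tsv(out, file)
  invisible(file)
}
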