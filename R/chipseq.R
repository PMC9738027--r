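#' Read TF binding sites from BED-dialect files
#'
#' Expects at least four tab-separated columns: chromosome, start, end
#' (0-based half-open interval), and TF name (no header). The point
#' location assigned to each peak is the interval midpoint
#' `(start + end) / 2` (configurable).
#'
#' @param files one or more BED file paths.
#' @param point `"midpoint"` (default) or `"start"`.
#' @return tibble with columns `tf`, `chrom`, `site` (numeric point
#'   coordinate on the 0-based scale).
#' @export
read_tf_bed <- function(files, point = c("midpoint", "start")) {
  point <- match.arg(point)
  purrr::map_dfr(files, function(f) {
    x <- utils::read.table(f, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(x) < 4) stop("BED file needs chrom/start/end/name columns: ", f,
                          call. = FALSE)
    tibble::tibble(
      tf = as.character(x[[4]]), chrom = as.character(x[[1]]),
      site = if (point == "midpoint") (x[[2]] + x[[3]]) / 2 else as.numeric(x[[2]])
    )
  })
}

#' Read a TSS annotation table
#'
#' Tab-separated with header columns `gene`, `chrom`, `tss` (1-based
#' coordinate), `strand` (`+`/`-`), one record per gene. Records with a
#' missing or invalid strand are rejected.
#'
#' @param file path to the annotation TSV.
#' @return tibble `gene`, `chrom`, `tss`, `strand`.
#' @export
read_tss <- function(file) {
  x <- readr::read_tsv(file, col_types = readr::cols(
    gene = readr::col_character(), chrom = readr::col_character(),
    tss = readr::col_double(), strand = readr::col_character()))
  bad <- !(x$strand %in% c("+", "-")) | is.na(x$tss) | x$tss < 1
  if (any(bad)) {
    message("rejecting ", sum(bad), " TSS record(s) with invalid strand/coordinate")
    x <- x[!bad, , drop = FALSE]
  }
  tibble::as_tibble(x)
}

#' Extract strand-oriented upstream-window site offsets
#'
#' For each gene, retains every binding site falling in the oriented
#' `[-8000, +2000]` window around the TSS: on the `+` strand the offset
#' is `site - tss`, on the `-` strand `tss - site` (so the window always
#' reads 5' to 3'). Sites whose chromosome matches no gene record are
#' skipped (count reported via message).
#'
#' @param tf_sites tibble from [read_tf_bed()] (`tf`, `chrom`, `site`).
#' @param tss tibble from [read_tss()].
#' @param window offset window, default `c(-8000, 2000)`.
#' @return tibble `tf`, `gene`, `offset` — one row per retained
#'   (site, gene) combination.
#' @export
extract_upstream <- function(tf_sites, tss, window = c(-8000, 2000)) {
  unmatched <- !(tf_sites$chrom %in% tss$chrom)
  if (any(unmatched)) {
    message("skipping ", sum(unmatched), " site(s) on chromosomes absent from the TSS table")
  }
  dplyr::inner_join(tf_sites, tss, by = "chrom", relationship = "many-to-many") |>
    dplyr::mutate(offset = ifelse(.data$strand == "+",
                                  .data$site - .data$tss,
                                  .data$tss - .data$site)) |>
    dplyr::filter(.data$offset >= window[1], .data$offset <= window[2]) |>
    dplyr::select("tf", "gene", "offset")
}

#' Select informative genes by TF coverage
#'
#' Keeps genes whose upstream window carries binding sites of at least
#' `min_tfs` distinct TFs (the mouse-ESC application keeps genes bound
#' by at least 8 of 14 TFs).
#'
#' @param regionized tibble from [extract_upstream()].
#' @param min_tfs minimum number of distinct TFs, default 8.
#' @return character vector of retained gene ids (sorted).
#' @export
filter_genes <- function(regionized, min_tfs = 8L) {
  counts <- regionized |>
    dplyr::distinct(.data$gene, .data$tf) |>
    dplyr::count(.data$gene)
  sort(counts$gene[counts$n >= min_tfs])
}

#' Build sample paths from upstream-window offsets
#'
#' Two strategies construct a single analysis region from the retained
#' genes' `[-8000, 2000]` windows:
#' * **pooling** — every gene's window is affinely mapped onto the whole
#'   target region and each TF's offsets from all genes are overlaid
#'   into one path (assumes a common binding intensity across genes);
#' * **concatenating** — the windows are laid end to end in
#'   lexicographic gene order, gene `g` of `G` occupying
#'   `[L(g-1)/G, Lg/G]` of a target region of length `L`.
#'
#' @param regionized tibble from [extract_upstream()].
#' @param genes genes to use, e.g. from [filter_genes()].
#' @param strategy `"pooling"` or `"concatenating"`.
#' @param target_region output region, default `c(0, 10)`.
#' @param window the offset window used upstream.
#' @return sites tibble (`tf` factor, `position` in the target region).
#' @export
build_paths <- function(regionized, genes,
                        strategy = c("pooling", "concatenating"),
                        target_region = c(0, 10), window = c(-8000, 2000)) {
  strategy <- match.arg(strategy)
  target_region <- as_region(target_region)
  genes <- sort(unique(genes))
  x <- dplyr::filter(regionized, .data$gene %in% genes)
  L <- region_length(target_region)
  W <- window[2] - window[1]
  unit <- (x$offset - window[1]) / W  # in [0, 1] within the gene window
  position <- if (strategy == "pooling") {
    target_region[1] + L * unit
  } else {
    g <- match(x$gene, genes)
    G <- length(genes)
    target_region[1] + L * (g - 1 + unit) / G
  }
  tf_levels <- sort(unique(regionized$tf))
  out <- tibble::tibble(tf = factor(x$tf, levels = tf_levels),
                        position = position)
  dplyr::arrange(out, .data$tf, .data$position)
}

#' Per-TF six-number summary of site locations
#'
#' For each TF: the site count and Min / 1st Qu. / Median / Mean /
#' 3rd Qu. / Max of its (scaled) site positions, with quartiles by
#' linear interpolation of order statistics (quantile type 7). TFs with
#' no sites report `NA` statistics.
#'
#' @param sites sites tibble or path list.
#' @return tibble with columns `tf`, `n_sites`, `min`, `q1`, `median`,
#'   `mean`, `q3`, `max`.
#' @export
summarize_paths <- function(sites) {
  paths <- as_path_list(sites)
  purrr::map_dfr(names(paths), function(nm) {
    p <- paths[[nm]]
    if (length(p) == 0) {
      return(tibble::tibble(tf = nm, n_sites = 0L, min = NA_real_,
                            q1 = NA_real_, median = NA_real_, mean = NA_real_,
                            q3 = NA_real_, max = NA_real_))
    }
    q <- stats::quantile(p, c(0, .25, .5, .75, 1), type = 7, names = FALSE)
    tibble::tibble(tf = nm, n_sites = length(p), min = q[1], q1 = q[2],
                   median = q[3], mean = mean(p), q3 = q[4], max = q[5])
  })
}
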