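#' Tile a chromosome into sequential windows and bin genes
#'
#' Windows are `[0,w), [w,2w), ...` half-open intervals covering the
#' chromosome (the last window is truncated at the chromosome end). A gene
#' belongs to the window containing its start coordinate, so every gene on
#' the chromosome falls in exactly one window per width.
#'
#' @param annotation gene annotation (`gene_id`, `chrom`, `start`, `end`).
#' @param chrom chromosome to tile.
#' @param width window width in bp (e.g. `10e6`).
#' @param chrom_length chromosome length; defaults to the largest gene end.
#' @return list with `windows` (`data.frame`: `chrom`, `start`, `end`) and
#'   `assignment`, an integer window index named by gene id for every gene
#'   on the chromosome.
#' @export
bin_genes <- function(annotation, chrom, width, chrom_length = NULL) {
  stopifnot(width > 0)
  on <- annotation$chrom == chrom
  if (!any(on)) stop("input error: unknown or empty chromosome ", chrom,
                     call. = FALSE)
  g <- annotation[on, , drop = FALSE]
  if (is.null(chrom_length)) chrom_length <- max(g$end)
  n_win <- ceiling(chrom_length / width)
  windows <- data.frame(chrom = chrom,
                        start = (seq_len(n_win) - 1) * width,
                        end = pmin(seq_len(n_win) * width, chrom_length))
  assignment <- stats::setNames(g$start %/% width + 1L, g$gene_id)
  list(windows = windows, assignment = assignment)
}

#' Per-window repression-score summary
#'
#' Joins a repression-score table onto the windows of one chromosome and
#' reports per-window gene counts and median RS.
#'
#' @param rs an [rs_table()]-style `data.frame` (needs `gene_id`, `chrom`,
#'   `start`, `rs`).
#' @param chrom chromosome to scan.
#' @param width window width in bp.
#' @param chrom_length optional chromosome length.
#' @return `data.frame`: `chrom`, `start`, `end`, `n_genes`, `median_rs`.
#' @export
window_scan <- function(rs, chrom, width, chrom_length = NULL) {
  b <- bin_genes(rs, chrom, width, chrom_length)
  w <- b$windows
  idx <- b$assignment
  vals <- rs$rs[match(names(idx), rs$gene_id)]
  w$n_genes <- as.integer(tabulate(idx, nbins = nrow(w)))
  w$median_rs <- vapply(seq_len(nrow(w)), function(i) {
    v <- vals[idx == i]
    if (length(v)) stats::median(v) else NA_real_
  }, numeric(1))
  w
}

#' Maximum-silencing region of a chromosome
#'
#' The window with the highest median repression score among windows
#' holding at least `min_genes` scored genes, computed at each requested
#' width (10/5/3 Mb by default — the coarse window is refined by narrower
#' scans). Ties break toward the window with more genes, then the leftmost.
#'
#' @inheritParams window_scan
#' @param widths window widths in bp.
#' @param min_genes minimum scored genes for a window to qualify
#'   (default 5).
#' @return `data.frame` with one row per width (`width`, `chrom`, `start`,
#'   `end`, `n_genes`, `median_rs`); a width with no qualifying window is
#'   dropped. Zero rows when nothing qualifies.
#' @export
max_silencing_region <- function(rs, chrom, widths = c(10e6, 5e6, 3e6),
                                 min_genes = 5, chrom_length = NULL) {
  stopifnot(min_genes >= 1)
  picks <- lapply(widths, function(w) {
    sc <- window_scan(rs, chrom, w, chrom_length)
    sc <- sc[sc$n_genes >= min_genes, , drop = FALSE]
    if (nrow(sc) == 0) return(NULL)
    o <- order(-sc$median_rs, -sc$n_genes, sc$start)
    cbind(width = w, sc[o[1], , drop = FALSE])
  })
  out <- do.call(rbind, picks)
  if (is.null(out)) {
    out <- data.frame(width = numeric(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_genes = integer(0), median_rs = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Fractions of genes per repression-score category
#'
#' Bins clipped scores into the configured categories (default
#' `[0,0.1), [0.1,0.4), [0.4,0.7), [0.7,1]`; the last bin is closed). Also
#' reports the fraction of genes with RS in `[0.1, 1]` as attribute
#' `frac_rs_0.1_1`.
#'
#' @param rs numeric repression scores in `[0, 1]`.
#' @param bins increasing break points partitioning `[0, 1]`.
#' @return named numeric vector of fractions summing to 1.
#' @export
categorize_rs <- function(rs, bins = c(0, 0.1, 0.4, 0.7, 1)) {
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0) stop("categorize_rs: empty gene set", call. = FALSE)
  if (bins[1] != 0 || bins[length(bins)] != 1 || is.unsorted(bins, strictly = TRUE)) {
    stop("configuration error: bins must be an increasing partition of [0,1]",
         call. = FALSE)
  }
  cut_idx <- findInterval(rs, bins, rightmost.closed = TRUE)
  k <- length(bins) - 1
  frac <- tabulate(cut_idx, nbins = k) / length(rs)
  names(frac) <- paste0("[", bins[-length(bins)], ",", bins[-1],
                        c(rep(")", k - 1), "]"))
  attr(frac, "frac_rs_0.1_1") <- mean(rs >= 0.1 & rs <= 1)
  frac
}

#' Percentage of silent genes
#'
#' `100 * n_silent / n_total`, rounded to the configured precision
#' (default: nearest integer, the convention used when quoting "~96%" style
#' figures); the unrounded value is kept in attribute `raw`.
#'
#' @param n_silent,n_total silent and total gene counts.
#' @param digits rounding digits for the reported value.
#' @return rounded percentage with attribute `raw`.
#' @export
#' @examples
#' percent_silent(630, 659)  # 96, raw 95.6
percent_silent <- function(n_silent, n_total, digits = 0) {
  if (n_total <= 0) stop("percent_silent: n_total must be positive", call. = FALSE)
  if (n_silent < 0 || n_silent > n_total) {
    stop("percent_silent: n_silent must lie in [0, n_total]", call. = FALSE)
  }
  raw <- 100 * n_silent / n_total
  structure(round(raw, digits), raw = raw)
}
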