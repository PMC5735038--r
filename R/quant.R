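#' Counts-per-million normalization
#'
#' Divides each gene's total read-pair count by the sample's library size
#' (sum of totals over genes) and scales to one million. Each sample is
#' normalized independently; no cross-sample shrinkage.
#'
#' @param counts an [allelic_counts()] object, or a gene x sample matrix of
#'   total counts.
#' @return gene x sample matrix of CPM values.
#' @export
normalize_cpm <- function(counts) {
  total <- if (inherits(counts, "allelic_counts")) counts$total else as.matrix(counts)
  lib <- colSums(total)
  if (any(lib <= 0)) {
    stop("input error: zero library size in sample(s) ",
         paste(which(lib <= 0), collapse = ", "), call. = FALSE)
  }
  sweep(total, 2, lib, "/") * 1e6
}

#' Split CPM expression by allele
#'
#' Allocates a gene's CPM to the two alleles proportionally to the
#' allele-assignable counts: `expr_a1 = cpm * a1/(a1+a2)` and
#' `expr_a2 = cpm * a2/(a1+a2)`. Where no read is allele-assignable
#' (`a1 + a2 = 0`) both outputs are `NA` (missing, not zero): the allelic
#' ratio is unobserved there.
#'
#' @param cpm CPM matrix/vector from [normalize_cpm()].
#' @param a1,a2 allele-assignable counts, same shape as `cpm`.
#' @return list with `expr_a1` and `expr_a2`.
#' @export
split_allelic <- function(cpm, a1, a2) {
  stopifnot(all(a1 >= 0, na.rm = TRUE), all(a2 >= 0, na.rm = TRUE))
  assign <- a1 + a2
  frac <- ifelse(assign > 0, a1 / assign, NA_real_)
  list(expr_a1 = cpm * frac, expr_a2 = cpm * (1 - frac))
}

#' Build the allelic expression matrix for a count set
#'
#' Runs [normalize_cpm()] and [split_allelic()] and attaches the gene
#' filter mask from [filter_genes()].
#'
#' @inheritParams normalize_cpm
#' @param filter_policy,threshold forwarded to [filter_genes()].
#' @return An object of class `allelic_expression`: `cpm`, `expr_a1`,
#'   `expr_a2` matrices, the `genes` annotation, `samples` sheet, and
#'   logical `filter_mask` over genes.
#' @export
allelic_expression <- function(counts, filter_policy = "mean_gt1",
                               threshold = 8) {
  stopifnot(inherits(counts, "allelic_counts"))
  cpm <- normalize_cpm(counts)
  spl <- split_allelic(cpm, counts$a1, counts$a2)
  out <- structure(list(cpm = cpm, expr_a1 = spl$expr_a1,
                        expr_a2 = spl$expr_a2,
                        genes = counts$genes, samples = counts$samples,
                        filter_mask = rep(TRUE, nrow(counts$genes))),
                   class = "allelic_expression")
  out$filter_mask <- filter_genes(out, policy = filter_policy,
                                  threshold = threshold)
  out
}

#' @export
print.allelic_expression <- function(x, ...) {
  cat("allelic_expression:", nrow(x$cpm), "genes x", ncol(x$cpm),
      "samples;", sum(x$filter_mask), "genes pass the expression filter\n")
  invisible(x)
}

#' Expression filters
#'
#' `mean_gt1` keeps genes whose CPM averaged across all samples is strictly
#' above 1 (the default interpretation of "on average above one").
#' `allelic_sum_gt` keeps genes whose allelic expression summed over both
#' alleles and every sample is strictly above `threshold` (used at 8 for
#' time-course designs and 6 for truncated-construct designs). Comparisons
#' are strict, so a gene summing to exactly the threshold is removed.
#'
#' @param expr an `allelic_expression` object.
#' @param policy `"mean_gt1"` or `"allelic_sum_gt"`.
#' @param threshold cutoff for `allelic_sum_gt`.
#' @return logical vector over genes (TRUE = keep).
#' @export
filter_genes <- function(expr, policy = c("mean_gt1", "allelic_sum_gt"),
                         threshold = 8) {
  if (!is.character(policy) || !policy[1] %in% c("mean_gt1", "allelic_sum_gt")) {
    stop("configuration error: unknown filter policy", call. = FALSE)
  }
  policy <- match.arg(policy)
  if (policy == "mean_gt1") {
    rowMeans(expr$cpm) > 1
  } else {
    s <- rowSums(expr$expr_a1, na.rm = TRUE) + rowSums(expr$expr_a2, na.rm = TRUE)
    s > threshold
  }
}
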