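#' Full allelic-silencing analysis of one count set
#'
#' Runs the complete scoring pipeline: expression filtering, orientation
#' and transgene-chromosome inference (unless fixed by the caller),
#' repression scores, chromosome-wide permutation p-values on the candidate
#' chromosome, Fisher combination across replicates, BH adjustment, cRS
#' calibration and silent-gene calls.
#'
#' @param counts an [allelic_counts()] object.
#' @param orientation `"auto"` (infer with [detect_transgene()]), `"a1"`,
#'   or `"a2"`.
#' @param candidate_chrom transgene chromosome; `NULL` to infer.
#' @param control_rs optional [rs_table()] of a matched control line for
#'   per-gene rRS calibration (otherwise the scalar non-candidate median
#'   is used).
#' @param n_perm permutations per gene on the candidate chromosome.
#' @param detect_n_perm permutations per gene during the genome-wide
#'   detection screen.
#' @param q_max,crs_min silent-call thresholds.
#' @param filter_policy,threshold expression filter (see [filter_genes()]).
#' @param seed integer seed for all permutation streams.
#' @return object of class `silencing_analysis`: `rs` (score table for the
#'   candidate chromosome with `p_rep*`, `p_combined`, `q`, `rrs`, `crs`,
#'   `silent` columns), `rs_genome` (all scored genes), `transgene`
#'   (a `transgene_call` or the fixed assignment), `n_silent`, and the
#'   parameters used.
#' @export
silencing_analysis <- function(counts, orientation = "auto",
                               candidate_chrom = NULL, control_rs = NULL,
                               n_perm = 10000, detect_n_perm = 1000,
                               q_max = 0.05, crs_min = 0.1,
                               filter_policy = "mean_gt1", threshold = 8,
                               seed = 1L) {
  stopifnot(inherits(counts, "allelic_counts"))
  params <- list(orientation = orientation, n_perm = n_perm,
                 detect_n_perm = detect_n_perm, q_max = q_max,
                 crs_min = crs_min, filter_policy = filter_policy,
                 threshold = threshold, seed = seed)
  tg <- NULL
  if (orientation == "auto" || is.null(candidate_chrom)) {
    tg <- detect_transgene(counts, n_perm = detect_n_perm, q_max = q_max,
                           crs_min = crs_min, filter_policy = filter_policy,
                           threshold = threshold, seed = seed)
    if (tg$status == "none") {
      out <- list(rs = NULL, rs_genome = NULL, transgene = tg,
                  n_silent = 0L, params = params)
      class(out) <- "silencing_analysis"
      return(out)
    }
    if (orientation == "auto") orientation <- tg$silenced_allele
    if (is.null(candidate_chrom)) candidate_chrom <- tg$chrom
  }
  rst <- rs_table(counts, orientation, filter_policy = filter_policy,
                  threshold = threshold)
  on <- rst$chrom == candidate_chrom
  cand <- rst[on, , drop = FALSE]
  perm <- permutation_test(counts, orientation, gene_ids = cand$gene_id,
                           n_perm = n_perm, seed = seed)
  m <- match(cand$gene_id, perm$gene_id)
  for (col in grep("^p_rep", names(perm), value = TRUE)) {
    cand[[col]] <- perm[[col]][m]
  }
  cand$p_combined <- perm$p_combined[m]
  cand$q <- bh_adjust(cand$p_combined)
  cand$rrs <- if (is.null(control_rs)) {
    random_rs(rst, candidate_chrom = candidate_chrom)[1]
  } else {
    random_rs(cand, control = control_rs)
  }
  cand$crs <- calibrated_rs(cand$rs, cand$rrs)
  cand$silent <- call_silent(cand$crs, cand$q, crs_min = crs_min,
                             q_max = q_max)
  attr(cand, "orientation") <- orientation
  attr(cand, "candidate_chrom") <- candidate_chrom
  out <- list(rs = cand, rs_genome = rst,
              transgene = if (is.null(tg))
                list(chrom = candidate_chrom, silenced_allele = orientation,
                     status = "fixed") else tg,
              n_silent = sum(cand$silent, na.rm = TRUE), params = params)
  class(out) <- "silencing_analysis"
  out
}

#' @export
print.silencing_analysis <- function(x, ...) {
  if (is.null(x$rs)) {
    cat("silencing_analysis: no transgene-bearing chromosome identified\n")
    return(invisible(x))
  }
  chrom <- attr(x$rs, "candidate_chrom")
  pct <- percent_silent(x$n_silent, nrow(x$rs))
  cat("silencing_analysis:", chrom, "/ silenced allele",
      attr(x$rs, "orientation"), "\n")
  cat(sprintf("  %d of %d genes silent (%s%%, q < %.2f & cRS > %.2f)\n",
              x$n_silent, nrow(x$rs), format(pct), x$params$q_max,
              x$params$crs_min))
  invisible(x)
}
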