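#' Per-gene repression score
#'
#' The repression score contrasts the relative expression change of the
#' putatively active allele against that of the putatively silenced allele
#' between an untreated baseline (subscript 0) and a treated condition
#' (subscript i):
#' \deqn{RS_{raw} = \frac{A_i - A_0}{A_0} - \frac{S_i - S_0}{S_0}}
#' and `rs = min(1, max(0, rs_raw))`. Complete silencing of the silenced
#' allele with an unchanged active allele gives 1; a proportional change of
#' both alleles gives 0. Which measured allele plays the active/silenced
#' role is the *orientation* and is iterated genome-wide by
#' [detect_transgene()].
#'
#' RS is undefined (returned as `NA`) when either baseline value is missing
#' or non-positive; such genes are dropped from downstream tables rather
#' than imputed.
#'
#' @param active_0,active_i active-allele expression at baseline / treated.
#' @param silenced_0,silenced_i silenced-allele expression at baseline /
#'   treated.
#' @param clip clip the raw score into `[0, 1]` (default). Set `FALSE` for
#'   the raw score.
#' @return numeric vector of repression scores.
#' @export
#' @examples
#' repression_score(100, 100, 100, 0)   # complete silencing -> 1
#' repression_score(100, 50, 100, 50)   # proportional change -> 0
repression_score <- function(active_0, active_i, silenced_0, silenced_i,
                             clip = TRUE) {
  bad0 <- !is.finite(active_0) | !is.finite(silenced_0) |
    active_0 <= 0 | silenced_0 <= 0
  raw <- (active_i - active_0) / active_0 - (silenced_i - silenced_0) / silenced_0
  raw[bad0] <- NA_real_
  if (clip) pmin(1, pmax(0, raw)) else raw
}

# per-sample cpm, allelic fractions and a pooled baseline pseudo-sample
.expr_components <- function(counts, baseline_condition, treated_condition,
                             pooling) {
  smp <- counts$samples
  b <- which(smp$condition == baseline_condition)
  t <- which(smp$condition == treated_condition)
  if (length(b) == 0 || length(t) == 0) {
    stop("input error: conditions '", baseline_condition, "' and '",
         treated_condition, "' must both be present", call. = FALSE)
  }
  cpm <- normalize_cpm(counts)
  assign <- counts$a1 + counts$a2
  f1 <- ifelse(assign > 0, counts$a1 / assign, NA_real_)
  if (pooling == "pooled") {
    tot0 <- rowSums(counts$total[, b, drop = FALSE])
    n0 <- rowSums(assign[, b, drop = FALSE])
    a1_0 <- rowSums(counts$a1[, b, drop = FALSE])
    cpm0 <- tot0 / sum(tot0) * 1e6
    f0 <- ifelse(n0 > 0, a1_0 / n0, NA_real_)
    base <- list(cpm0 = matrix(cpm0, ncol = 1), f0 = matrix(f0, ncol = 1),
                 n0 = matrix(n0, ncol = 1), a1_0 = matrix(a1_0, ncol = 1),
                 pair = rep(1L, length(t)))
  } else {
    if (length(b) < length(t)) {
      stop("input error: matched pooling needs a baseline replicate per ",
           "treated replicate", call. = FALSE)
    }
    pair <- match(smp$replicate[t], smp$replicate[b])
    if (anyNA(pair)) {
      stop("input error: no replicate-matched baseline for every treated sample",
           call. = FALSE)
    }
    base <- list(cpm0 = cpm[, b, drop = FALSE], f0 = f1[, b, drop = FALSE],
                 n0 = assign[, b, drop = FALSE],
                 a1_0 = counts$a1[, b, drop = FALSE], pair = pair)
  }
  list(cpm = cpm, f1 = f1, assign = assign, baseline_idx = b, treated_idx = t,
       base = base)
}

#' Repression-score table for one orientation
#'
#' Computes the repression score for every gene passing the expression
#' filter, one score per treated replicate against the pooled (default) or
#' replicate-matched baseline, and reports their mean as the gene's RS.
#' Genes with an undefined score in any replicate (zero allele-assignable
#' baseline reads, or a zero baseline on either allele) are excluded.
#'
#' @param counts an [allelic_counts()] object.
#' @param orientation which allele is putatively silenced: `"a1"` or `"a2"`.
#' @param baseline_condition,treated_condition condition labels (defaults
#'   `"NoDox"` / `"Dox"`).
#' @param pooling `"pooled"` (baseline replicates summed into one
#'   pseudo-sample, default) or `"matched"` (replicate-paired baseline).
#' @param filter_policy,threshold forwarded to [filter_genes()].
#' @return `data.frame` with gene coordinates, per-replicate scores
#'   (`rs_rep*`), the mean raw score `rs_raw` and the mean clipped score
#'   `rs`. Orientation and conditions are recorded as attributes.
#' @export
rs_table <- function(counts, orientation = c("a1", "a2"),
                     baseline_condition = "NoDox", treated_condition = "Dox",
                     pooling = c("pooled", "matched"),
                     filter_policy = "mean_gt1", threshold = 8) {
  orientation <- match.arg(orientation)
  pooling <- match.arg(pooling)
  stopifnot(inherits(counts, "allelic_counts"))
  comp <- .expr_components(counts, baseline_condition, treated_condition, pooling)
  expr <- allelic_expression(counts, filter_policy = filter_policy,
                             threshold = threshold)
  mask <- expr$filter_mask

  tr <- comp$treated_idx
  nrep <- length(tr)
  rs_rep <- rs_raw_rep <- matrix(NA_real_, nrow(counts$genes), nrep)
  for (k in seq_len(nrep)) {
    s <- tr[k]; bk <- comp$base$pair[k]
    f0 <- comp$base$f0[, bk]; cpm0 <- comp$base$cpm0[, bk]
    fi <- comp$f1[, s]; cpmi <- comp$cpm[, s]
    if (orientation == "a1") {
      S0 <- cpm0 * f0;        Si <- cpmi * fi
      A0 <- cpm0 * (1 - f0);  Ai <- cpmi * (1 - fi)
    } else {
      S0 <- cpm0 * (1 - f0);  Si <- cpmi * (1 - fi)
      A0 <- cpm0 * f0;        Ai <- cpmi * fi
    }
    rs_raw_rep[, k] <- repression_score(A0, Ai, S0, Si, clip = FALSE)
    rs_rep[, k] <- pmin(1, pmax(0, rs_raw_rep[, k]))
  }
  keep <- mask & rowSums(is.na(rs_rep)) == 0
  out <- data.frame(gene_id = counts$genes$gene_id,
                    chrom = counts$genes$chrom,
                    start = counts$genes$start,
                    end = counts$genes$end,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  for (k in seq_len(nrep)) out[[paste0("rs_rep", k)]] <- rs_rep[keep, k]
  out$rs_raw <- rowMeans(rs_raw_rep[keep, , drop = FALSE])
  out$rs <- rowMeans(rs_rep[keep, , drop = FALSE])
  rownames(out) <- out$gene_id
  attr(out, "orientation") <- orientation
  attr(out, "baseline_condition") <- baseline_condition
  attr(out, "treated_condition") <- treated_condition
  attr(out, "pooling") <- pooling
  out
}

#' Random repression score (rRS) background
#'
#' The background against which RS is calibrated. With a matched control
#' table (an independent control cell line scored under the same
#' orientation), the rRS is that line's per-gene RS. Without one, the rRS
#' is a scalar: the median RS over all genes on non-candidate chromosomes
#' of the analysed line, broadcast to every gene.
#'
#' @param rs an [rs_table()] result for the analysed line.
#' @param control optional [rs_table()] result for a control line.
#' @param candidate_chrom candidate transgene chromosome, required when no
#'   control table is given.
#' @return numeric rRS vector aligned with the rows of `rs`.
#' @export
random_rs <- function(rs, control = NULL, candidate_chrom = NULL) {
  if (!is.null(control)) {
    rrs <- control$rs[match(rs$gene_id, control$gene_id)]
    return(rrs)
  }
  if (is.null(candidate_chrom)) {
    stop("configuration error: random_rs needs a control table or a ",
         "candidate chromosome", call. = FALSE)
  }
  other <- rs$rs[rs$chrom != candidate_chrom]
  if (length(other) == 0) {
    stop("configuration error: no non-candidate genes to estimate rRS from",
         call. = FALSE)
  }
  rep(stats::median(other), nrow(rs))
}

#' Calibrated repression score
#'
#' `crs = rs - rrs`. Not re-clipped: negative values flag genes whose
#' apparent repression is below the background.
#'
#' @param rs,rrs repression score and random-RS background (recycled).
#' @return numeric cRS vector.
#' @export
calibrated_rs <- function(rs, rrs) rs - rrs

#' Infer the transgene-bearing chromosome and silenced allele
#'
#' Iterates both orientations over every chromosome: genes on the candidate
#' chromosome are permutation-tested ([permutation_test()]), p-values are
#' Fisher-combined across replicates, BH-adjusted within the chromosome,
#' and genes are called silent ([call_silent()]) using the cRS calibrated
#' against the non-candidate median ([random_rs()]). The
#' chromosome/orientation with the largest number of silent genes wins;
#' ties break toward the higher median RS on the candidate chromosome,
#' then lexicographic chromosome name.
#'
#' @param counts an [allelic_counts()] object (>= 2 chromosomes).
#' @param n_perm permutations per gene (default 1000 for a genome-wide
#'   screen; rerun the winning chromosome at 10000 for reporting).
#' @param q_max,crs_min silent-call thresholds (see [call_silent()]).
#' @param filter_policy,threshold forwarded to [filter_genes()].
#' @param seed integer seed for the permutation streams.
#' @inheritParams rs_table
#' @return object of class `transgene_call`: `chrom`, `silenced_allele`
#'   (both `NA` with `status = "none"` when no chromosome has any silent
#'   gene), and the full orientation x chromosome `scores` matrix of
#'   silent-gene counts.
#' @export
detect_transgene <- function(counts, n_perm = 1000, q_max = 0.05,
                             crs_min = 0.1,
                             baseline_condition = "NoDox",
                             treated_condition = "Dox",
                             filter_policy = "mean_gt1", threshold = 8,
                             seed = 1L) {
  stopifnot(inherits(counts, "allelic_counts"))
  chroms <- unique(counts$genes$chrom)
  if (length(chroms) < 2) {
    stop("input error: detect_transgene needs at least 2 chromosomes",
         call. = FALSE)
  }
  orientations <- c("a1", "a2")
  scores <- matrix(0L, 2, length(chroms),
                   dimnames = list(orientations, chroms))
  med_rs <- matrix(NA_real_, 2, length(chroms),
                   dimnames = list(orientations, chroms))
  for (ori in orientations) {
    rst <- rs_table(counts, ori, baseline_condition, treated_condition,
                    filter_policy = filter_policy, threshold = threshold)
    perm <- permutation_test(counts, ori, gene_ids = rst$gene_id,
                             baseline_condition = baseline_condition,
                             treated_condition = treated_condition,
                             n_perm = n_perm, seed = seed)
    p_comb <- perm$p_combined[match(rst$gene_id, perm$gene_id)]
    for (chr in chroms) {
      on <- rst$chrom == chr
      if (!any(on)) next
      med_rs[ori, chr] <- stats::median(rst$rs[on])
      q <- bh_adjust(p_comb[on])
      # background from the full table, excluding the candidate chromosome
      rrs <- random_rs(rst, candidate_chrom = chr)[seq_len(sum(on))]
      crs <- calibrated_rs(rst$rs[on], rrs)
      scores[ori, chr] <- sum(call_silent(crs, q, crs_min = crs_min,
                                          q_max = q_max), na.rm = TRUE)
    }
  }
  best <- max(scores)
  if (best == 0) {
    warning("no significantly repressed genes on any chromosome; ",
            "transgene chromosome not identifiable")
    res <- list(chrom = NA_character_, silenced_allele = NA_character_,
                scores = scores, status = "none")
  } else {
    cand <- which(scores == best, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      meds <- med_rs[cand]
      cand <- cand[order(-meds, chroms[cand[, 2]], orientations[cand[, 1]]),
                   , drop = FALSE]
    }
    res <- list(chrom = chroms[cand[1, 2]],
                silenced_allele = orientations[cand[1, 1]],
                scores = scores, status = "ok")
  }
  class(res) <- "transgene_call"
  res
}

#' @export
print.transgene_call <- function(x, ...) {
  if (x$status == "none") {
    cat("transgene_call: no transgene-bearing chromosome identified\n")
  } else {
    cat("transgene_call:", x$chrom, "with silenced allele",
        x$silenced_allele, "\n")
  }
  cat("silent-gene counts (orientation x chromosome):\n")
  print(x$scores)
  invisible(x)
}
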