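#' Permutation p-values for the repression score
#'
#' For each gene, the allele-assignable reads of every involved sample
#' (pooled baseline and each treated replicate) are repeatedly re-assigned
#' to the two alleles by a binomial draw, totals (and hence CPM) held
#' fixed, and the repression score is recomputed through the identical
#' path, including clipping. The per-replicate p-value is the fraction of
#' null scores at least as large as the observed score,
#' `p = #{RS_null >= RS_obs} / n_perm`; replicate p-values are combined
#' with [fisher_combine()]. Applied chromosome-wide, every gene on a
#' candidate chromosome is tested the same way.
#'
#' The binomial success probability defaults to the gene's pooled allelic
#' fraction across baseline samples (`allelic_p = "nodox"`), preserving
#' constitutive allelic skew while destroying any condition-specific skew;
#' `"half"` uses 0.5. Each gene draws from its own counted seed stream, so
#' p-values do not depend on which other genes are in the tested set.
#'
#' @param counts an [allelic_counts()] object.
#' @param orientation putatively silenced allele, `"a1"` or `"a2"`.
#' @param gene_ids genes to test (default: all genes with a defined score).
#' @param n_perm number of permutations (default 10000).
#' @param allelic_p `"nodox"` (default) or `"half"`.
#' @param seed integer seed for the per-gene permutation streams.
#' @inheritParams rs_table
#' @return `data.frame`: `gene_id`, per-replicate observed scores
#'   (`rs_obs_rep*`) and p-values (`p_rep*`), and the Fisher-combined
#'   `p_combined`. Genes whose score is undefined are omitted.
#' @export
permutation_test <- function(counts, orientation = c("a1", "a2"),
                             gene_ids = NULL,
                             baseline_condition = "NoDox",
                             treated_condition = "Dox",
                             n_perm = 10000, allelic_p = c("nodox", "half"),
                             seed = 1L) {
  orientation <- match.arg(orientation)
  allelic_p <- match.arg(allelic_p)
  if (n_perm < 1) stop("configuration error: n_perm must be >= 1", call. = FALSE)
  stopifnot(inherits(counts, "allelic_counts"))
  comp <- .expr_components(counts, baseline_condition, treated_condition,
                           pooling = "pooled")
  all_ids <- counts$genes$gene_id
  idx <- if (is.null(gene_ids)) seq_along(all_ids) else match(gene_ids, all_ids)
  if (anyNA(idx)) stop("input error: unknown gene ids", call. = FALSE)

  tr <- comp$treated_idx
  nrep <- length(tr)
  n0 <- comp$base$n0[, 1]
  a1_0 <- comp$base$a1_0[, 1]
  cpm0 <- comp$base$cpm0[, 1]
  f0 <- comp$base$f0[, 1]
  phat <- if (allelic_p == "half") rep(0.5, length(n0)) else
    ifelse(n0 > 0, a1_0 / n0, NA_real_)

  rs_from_f <- function(fb, fi, c0, ci) {
    if (orientation == "a1") {
      repression_score(c0 * (1 - fb), ci * (1 - fi), c0 * fb, ci * fi)
    } else {
      repression_score(c0 * fb, ci * fi, c0 * (1 - fb), ci * (1 - fi))
    }
  }

  rows <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    g <- idx[j]
    ni <- comp$assign[g, tr]
    fi <- comp$f1[g, tr]
    cpmi <- comp$cpm[g, tr]
    rs_obs <- rs_from_f(rep(f0[g], nrep), fi, rep(cpm0[g], nrep), cpmi)
    if (anyNA(rs_obs) || !is.finite(phat[g])) next
    set.seed(as.integer((as.double(seed) * 2654435761 + g * 97) %% 2147483629))
    f0_null <- stats::rbinom(n_perm, n0[g], phat[g]) / n0[g]
    p_rep <- rs_null_keep <- numeric(nrep)
    for (k in seq_len(nrep)) {
      fi_null <- if (ni[k] > 0)
        stats::rbinom(n_perm, ni[k], phat[g]) / ni[k] else rep(NA_real_, n_perm)
      rs_null <- rs_from_f(f0_null, fi_null, cpm0[g], cpmi[k])
      p_rep[k] <- sum(rs_null >= rs_obs[k], na.rm = TRUE) / n_perm
    }
    rows[[j]] <- c(rs_obs, p_rep)
  }
  got <- !vapply(rows, is.null, logical(1))
  m <- do.call(rbind, rows[got])
  out <- data.frame(gene_id = all_ids[idx][got], stringsAsFactors = FALSE)
  for (k in seq_len(nrep)) out[[paste0("rs_obs_rep", k)]] <- m[, k]
  for (k in seq_len(nrep)) out[[paste0("p_rep", k)]] <- m[, nrep + k]
  out$p_combined <- apply(m[, nrep + seq_len(nrep), drop = FALSE], 1,
                          fisher_combine, n_perm = n_perm)
  attr(out, "n_perm") <- n_perm
  attr(out, "orientation") <- orientation
  out
}

#' Combine p-values across replicates with Fisher's method
#'
#' `-2 * sum(log(p))` referred to a chi-square distribution on `2k` degrees
#' of freedom. Permutation p-values of exactly 0 are floored at
#' `1/(n_perm + 1)` before taking logs (reported p-values keep the raw 0).
#' A single p-value is returned unchanged (the k = 1 identity).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param n_perm permutation count used to floor zero p-values.
#' @return combined p-value.
#' @export
fisher_combine <- function(p, n_perm = 10000) {
  if (length(p) == 0) stop("fisher_combine: empty input", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("fisher_combine: p-values must lie in [0, 1]", call. = FALSE)
  }
  p <- pmax(p, 1 / (n_perm + 1))
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false-discovery-rate adjustment
#' (`stats::p.adjust(method = "BH")`): monotone in the p-value ranks and
#' capped at 1.
#'
#' @param p vector of finite p-values.
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p))) stop("bh_adjust: p-values must be finite", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Silent-gene call
#'
#' A gene is silent when both the calibrated repression score and the
#' q-value pass: `q < q_max` and `crs > crs_min`. Defaults: `q_max = 0.05`
#' (stated), `crs_min = 0.1` (the lower edge of the reported RS range of
#' interest; configurable).
#'
#' @param crs calibrated repression scores.
#' @param q BH q-values.
#' @param crs_min,q_max thresholds.
#' @return logical vector.
#' @export
call_silent <- function(crs, q, crs_min = 0.1, q_max = 0.05) {
  q < q_max & crs > crs_min
}
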