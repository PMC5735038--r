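#' Library-size normalization for ATAC coverage
#'
#' Scales raw fragment counts to 10 million mapped reads:
#' `count * 1e7 / mapped_total`.
#'
#' @param counts raw counts (vector or matrix).
#' @param mapped_total mapped reads in the sample (scalar, or one per
#'   column of `counts`).
#' @param scale target library size (default `1e7`).
#' @return normalized coverage, same shape as `counts`.
#' @export
normalize_atac <- function(counts, mapped_total, scale = 1e7) {
  if (any(mapped_total <= 0)) {
    stop("input error: mapped_total must be positive", call. = FALSE)
  }
  if (is.matrix(counts) && length(mapped_total) == ncol(counts)) {
    sweep(counts, 2, mapped_total, "/") * scale
  } else {
    counts * scale / mapped_total
  }
}

#' Allelic accessibility differential (ddscore)
#'
#' The induced change in the normalized allelic accessibility difference:
#' \deqn{ddscore = [G1(Dox) - G2(Dox)] - [G1(NoDox) - G2(NoDox)]}
#' where G1/G2 are library-size-normalized allele-1/allele-2 coverages.
#' On a chromosome whose allele 1 loses accessibility upon induction the
#' ddscore is negative.
#'
#' @param g1_dox,g2_dox,g1_nodox,g2_nodox normalized allelic coverages
#'   (vectors recycle).
#' @return numeric ddscore.
#' @export
#' @examples
#' ddscore(2, 8, 6, 6)  # (2-8) - (6-6) = -6
ddscore <- function(g1_dox, g2_dox, g1_nodox, g2_nodox) {
  (g1_dox - g2_dox) - (g1_nodox - g2_nodox)
}

#' Per-element ddscore track
#'
#' Normalizes each sample of an ATAC track to 10 million mapped reads,
#' computes the ddscore per element for each replicate pair
#' (Dox rep k vs NoDox rep k), and reports the per-replicate columns plus
#' their mean.
#'
#' @param track an `atac_track` (see [simulate_atac_counts()]).
#' @return `data.frame`: element coordinates and state, `ddscore_rep*`
#'   per replicate, and the mean `ddscore`.
#' @export
ddscore_track <- function(track) {
  stopifnot(inherits(track, "atac_track"))
  smp <- track$samples
  n1 <- normalize_atac(track$a1, track$mapped_total)
  n2 <- normalize_atac(track$a2, track$mapped_total)
  reps <- sort(unique(smp$replicate))
  out <- track$elements
  dd <- matrix(NA_real_, nrow(out), length(reps))
  for (k in seq_along(reps)) {
    dox <- which(smp$condition == "Dox" & smp$replicate == reps[k])
    nod <- which(smp$condition == "NoDox" & smp$replicate == reps[k])
    if (length(dox) != 1 || length(nod) != 1) {
      stop("input error: need one Dox and one NoDox sample per replicate",
           call. = FALSE)
    }
    dd[, k] <- ddscore(n1[, dox], n2[, dox], n1[, nod], n2[, nod])
    out[[paste0("ddscore_rep", reps[k])]] <- dd[, k]
  }
  out$ddscore <- rowMeans(dd)
  out
}

#' Mean ddscore per chromatin state per chromosome
#'
#' @param dd a [ddscore_track()] result (needs `chrom`, `state`,
#'   `ddscore`).
#' @return `data.frame`: `chrom`, `state`, `n_elements`, `mean_ddscore`.
#'   States with no elements on a chromosome are omitted (with a warning
#'   if a requested state is empty everywhere).
#' @export
aggregate_by_state <- function(dd) {
  if (!all(c("chrom", "state", "ddscore") %in% names(dd))) {
    stop("input error: need chrom/state/ddscore columns", call. = FALSE)
  }
  if (nrow(dd) == 0) {
    warning("empty element set; nothing to aggregate")
    return(data.frame(chrom = character(0), state = character(0),
                      n_elements = integer(0), mean_ddscore = numeric(0)))
  }
  agg <- stats::aggregate(ddscore ~ chrom + state, data = dd,
                          FUN = function(v) c(n = length(v), m = mean(v)))
  out <- data.frame(chrom = agg$chrom, state = agg$state,
                    n_elements = as.integer(agg$ddscore[, "n"]),
                    mean_ddscore = agg$ddscore[, "m"],
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$state), , drop = FALSE]
}

# exact two-sided Mann-Whitney p by enumeration of all assignments
.rank_sum_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  u_all <- apply(combos, 2, function(ix) sum(r[ix])) - nx * (nx + 1) / 2
  # tolerance-free comparison: ranks are multiples of 0.5
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# normal approximation with tie correction and continuity correction
.rank_sum_normal <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- table(c(x, y))
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = u_obs, p = 1))
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
  list(U = u_obs, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Mann-Whitney rank-sum comparison
#'
#' Two-sided comparison of element-level values (e.g. ddscores on a target
#' chromosome vs a control chromosome). Uses exact enumeration of all
#' `choose(n1+n2, n1)` group assignments when both samples have at most 8
#' observations (or when forced), otherwise the normal approximation with
#' tie and continuity corrections.
#'
#' @param target,control numeric samples (non-empty).
#' @param method `"auto"` (default), `"exact"`, or `"normal"`.
#' @return list: `U` (statistic for `target`), `p` (two-sided), `method`.
#' @export
rank_sum_compare <- function(target, control,
                             method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  target <- target[!is.na(target)]; control <- control[!is.na(control)]
  if (length(target) == 0 || length(control) == 0) {
    stop("rank_sum_compare: both samples must be non-empty", call. = FALSE)
  }
  if (method == "auto") {
    method <- if (length(target) <= 8 && length(control) <= 8) "exact" else "normal"
  }
  res <- if (method == "exact") .rank_sum_exact(target, control)
         else .rank_sum_normal(target, control)
  c(res, list(method = method))
}
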