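#' Simulate a gene annotation for a scenario
#'
#' Places `genes_per_chromosome` non-degenerate genes uniformly on each
#' chromosome. Coordinates are 0-based half-open (BED convention), sorted by
#' start within chromosome. Deterministic given the scenario seed.
#'
#' @param scenario a [silencing_scenario()].
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
simulate_genome <- function(scenario) {
  stopifnot(inherits(scenario, "silencing_scenario"))
  set.seed(.sample_seed(scenario$seed, "NoDox", 0L, stream = 1L))
  rows <- lapply(names(scenario$chrom_lengths), function(chr) {
    len <- scenario$chrom_lengths[[chr]]
    n <- scenario$genes_per_chromosome
    glen <- pmax(200, round(stats::rlnorm(n, meanlog = log(2e4), sdlog = 0.6)))
    glen <- pmin(glen, floor(len * 0.9))
    start <- floor(stats::runif(n, 0, len - glen))
    o <- order(start, start + glen)
    data.frame(
      gene_id = sprintf("%s_g%04d", chr, seq_len(n)),
      chrom = chr,
      start = start[o],
      end = start[o] + glen[o],
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  ann <- do.call(rbind, rows)
  rownames(ann) <- ann$gene_id
  ann
}

#' Container for allele-split gene counts
#'
#' Bundles a gene annotation, a sample sheet, and three gene x sample
#' integer matrices: `total` read pairs, and allele-assignable pairs `a1`
#' (Cast/G1 by convention) and `a2` (129S1/G2). Enforces
#' `a1 + a2 <= total` and positive library sizes.
#'
#' @param genes annotation `data.frame` (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param samples sample sheet `data.frame` (`sample_id`, `condition`,
#'   `replicate`).
#' @param total,a1,a2 gene x sample count matrices.
#' @return An object of class `allelic_counts`.
#' @export
allelic_counts <- function(genes, samples, total, a1, a2) {
  stopifnot(is.data.frame(genes), is.data.frame(samples))
  total <- as.matrix(total); a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!all(dim(total) == dim(a1)) || !all(dim(total) == dim(a2))) {
    stop("count matrices must share dimensions", call. = FALSE)
  }
  if (nrow(total) != nrow(genes) || ncol(total) != nrow(samples)) {
    stop("count matrices must be genes x samples", call. = FALSE)
  }
  if (any(total < 0) || any(a1 < 0) || any(a2 < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(a1 + a2 > total)) {
    stop("allelic counts exceed totals (a1 + a2 must be <= total)", call. = FALSE)
  }
  if (any(colSums(total) <= 0)) {
    stop("input error: every sample needs a positive library size", call. = FALSE)
  }
  dimnames(total) <- dimnames(a1) <- dimnames(a2) <-
    list(genes$gene_id, samples$sample_id)
  structure(list(genes = genes, samples = samples,
                 total = total, a1 = a1, a2 = a2),
            class = "allelic_counts")
}

#' @export
print.allelic_counts <- function(x, ...) {
  cat("allelic_counts:", nrow(x$genes), "genes x", nrow(x$samples),
      "samples (", paste(x$samples$sample_id, collapse = ", "), ")\n")
  invisible(x)
}

.sample_sheet <- function(scenario) {
  grid <- expand.grid(replicate = seq_len(scenario$n_replicates),
                      condition = scenario$conditions,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$condition, scenario$conditions), grid$replicate), ]
  data.frame(sample_id = sprintf("%s_rep%d", grid$condition, grid$replicate),
             condition = grid$condition, replicate = grid$replicate,
             stringsAsFactors = FALSE, row.names = NULL)
}

# per-gene latent parameters: relative expression, allele-1 share, true RS
.gene_params <- function(annotation, scenario) {
  set.seed(.sample_seed(scenario$seed, "NoDox", 0L, stream = 2L))
  n <- nrow(annotation)
  kappa <- scenario$allelic_balance_concentration
  rel <- stats::rlnorm(n, meanlog = 0, sdlog = 0.5)
  share_a1 <- stats::rbeta(n, kappa / 2, kappa / 2)
  true_rs <- numeric(n)
  if (!is.null(scenario$transgene_chrom) &&
      scenario$repression_strength > 0 && scenario$repressed_fraction > 0) {
    on_tg <- which(annotation$chrom == scenario$transgene_chrom)
    n_aff <- round(length(on_tg) * scenario$repressed_fraction)
    affected <- sort(sample(on_tg, n_aff))
    rs <- rep(scenario$repression_strength, n_aff)
    if (!is.null(scenario$distance_decay_halflife)) {
      mid <- (annotation$start[affected] + annotation$end[affected]) / 2
      d <- abs(mid - scenario$integration_site)
      rs <- rs * exp(-d * log(2) / scenario$distance_decay_halflife)
    }
    true_rs[affected] <- rs
  }
  mu <- scenario$library_size * rel / sum(rel)
  list(mu = mu, share_a1 = share_a1, true_rs = true_rs)
}

#' Simulate allele-split gene counts and the matching ground truth
#'
#' Draws, per sample, total counts (negative binomial), allele-assignable
#' counts (binomial at `informative_fraction`), and the allele-1 fraction of
#' assignable counts (binomial at the gene's allelic share). For Dox samples
#' on the transgene chromosome, affected genes lose silenced-allele signal:
#' with share \eqn{\pi} of the silenced allele and true repression
#' \eqn{\rho}, the total mean scales by \eqn{1-\pi\rho} and the silenced
#' share becomes \eqn{\pi(1-\rho)/(1-\pi\rho)} — the active allele's
#' absolute expected signal is unchanged.
#'
#' Random streams are split per sample (seeded from condition and replicate
#' id), so increasing `n_replicates` reproduces all existing samples
#' bit-identically.
#'
#' @param annotation gene annotation from [simulate_genome()].
#' @param scenario the [silencing_scenario()] used for the annotation.
#' @return A list with `counts` (an [allelic_counts()] object) and `truth`
#'   (`data.frame` of `gene_id`, `chrom`, `true_rs`, with the transgene
#'   chromosome and silenced allele as attributes).
#' @export
simulate_allelic_counts <- function(annotation, scenario) {
  stopifnot(inherits(scenario, "silencing_scenario"))
  if (!all(annotation$chrom %in% names(scenario$chrom_lengths))) {
    stop("annotation inconsistent with scenario chromosomes", call. = FALSE)
  }
  par <- .gene_params(annotation, scenario)
  samples <- .sample_sheet(scenario)
  n <- nrow(annotation)
  size <- 1 / scenario$dispersion

  # silenced-allele share per gene (a1-share is the stored parameter)
  sil_share <- if (scenario$silenced_allele == "a1") par$share_a1 else 1 - par$share_a1

  total <- a1 <- a2 <- matrix(0L, n, nrow(samples))
  for (s in seq_len(nrow(samples))) {
    cond <- samples$condition[s]
    set.seed(.sample_seed(scenario$seed, cond, samples$replicate[s], stream = 3L))
    if (cond == "Dox") {
      scale <- 1 - sil_share * par$true_rs
      sil_share_s <- sil_share * (1 - par$true_rs) / scale
    } else {
      scale <- rep(1, n)
      sil_share_s <- sil_share
    }
    share_a1_s <- if (scenario$silenced_allele == "a1") sil_share_s else 1 - sil_share_s
    tot <- stats::rnbinom(n, mu = par$mu * scale, size = size)
    assign <- stats::rbinom(n, tot, scenario$informative_fraction)
    a1s <- stats::rbinom(n, assign, share_a1_s)
    total[, s] <- tot
    a1[, s] <- a1s
    a2[, s] <- assign - a1s
  }

  truth <- data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
                      true_rs = par$true_rs, stringsAsFactors = FALSE)
  attr(truth, "transgene_chrom") <- scenario$transgene_chrom
  attr(truth, "silenced_allele") <-
    if (is.null(scenario$transgene_chrom)) NULL else scenario$silenced_allele
  list(counts = allelic_counts(annotation, samples, total, a1, a2),
       truth = truth)
}

#' Simulate labelled regulatory elements for ATAC simulation
#'
#' Lays disjoint fixed-grid elements with chromatin-state labels
#' (promoter/enhancer/CTCF by default) on every scenario chromosome.
#'
#' @param scenario a [silencing_scenario()].
#' @param n_per_chromosome elements per chromosome.
#' @param states state labels cycled across elements.
#' @return BED-like `data.frame`: `chrom`, `start`, `end`, `state`.
#' @export
simulate_elements <- function(scenario, n_per_chromosome = 60,
                              states = c("promoter", "enhancer", "CTCF")) {
  stopifnot(inherits(scenario, "silencing_scenario"))
  set.seed(.sample_seed(scenario$seed, "NoDox", 0L, stream = 4L))
  rows <- lapply(names(scenario$chrom_lengths), function(chr) {
    len <- scenario$chrom_lengths[[chr]]
    step <- floor(len / (n_per_chromosome + 1))
    width <- min(2000, max(200, floor(step / 4)))
    start <- step * seq_len(n_per_chromosome) +
      floor(stats::runif(n_per_chromosome, 0, step - width))
    data.frame(chrom = chr, start = start, end = start + width,
               state = rep_len(sample(states), n_per_chromosome),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.validate_elements <- function(elements) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(elements))) {
    stop("input error: elements need chrom/start/end columns", call. = FALSE)
  }
  if (any(elements$end <= elements$start)) {
    stop("input error: malformed element intervals (end <= start)", call. = FALSE)
  }
  for (chr in unique(elements$chrom)) {
    e <- elements[elements$chrom == chr, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      stop("input error: overlapping elements on ", chr, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Simulate allelic ATAC fragment counts over elements
#'
#' Per element, allele and sample, fragment counts are negative binomial
#' around an element-specific accessibility mean split between alleles. On
#' the transgene chromosome under Dox, the silenced allele's mean is
#' multiplied by `atac_dox_factor` (1 = no change) for every element —
#' accessibility loss is chromosome-wide, not restricted to repressed
#' genes.
#'
#' @param elements labelled BED-like `data.frame` (`chrom`, `start`, `end`,
#'   `state`), e.g. from [simulate_elements()].
#' @param scenario a [silencing_scenario()].
#' @return An object of class `atac_track`: elements, sample sheet, `a1`
#'   and `a2` count matrices (element x sample) and per-sample
#'   `mapped_total`.
#' @export
simulate_atac_counts <- function(elements, scenario) {
  stopifnot(inherits(scenario, "silencing_scenario"))
  .validate_elements(elements)
  elements <- elements[order(elements$chrom, elements$start), , drop = FALSE]
  rownames(elements) <- NULL
  samples <- .sample_sheet(scenario)
  n <- nrow(elements)
  set.seed(.sample_seed(scenario$seed, "NoDox", 0L, stream = 5L))
  base_mu <- stats::rgamma(n, shape = 4, rate = 4 / scenario$atac_mean)
  kappa <- scenario$allelic_balance_concentration
  share_a1 <- stats::rbeta(n, kappa / 2, kappa / 2)
  size <- 1 / scenario$dispersion

  on_tg <- if (is.null(scenario$transgene_chrom)) rep(FALSE, n) else
    elements$chrom == scenario$transgene_chrom

  a1 <- a2 <- matrix(0L, n, nrow(samples))
  for (s in seq_len(nrow(samples))) {
    cond <- samples$condition[s]
    set.seed(.sample_seed(scenario$seed, cond, samples$replicate[s], stream = 6L))
    f1 <- rep(1, n); f2 <- rep(1, n)
    if (cond == "Dox") {
      if (scenario$silenced_allele == "a1") {
        f1[on_tg] <- scenario$atac_dox_factor
      } else {
        f2[on_tg] <- scenario$atac_dox_factor
      }
    }
    a1[, s] <- stats::rnbinom(n, mu = base_mu * share_a1 * f1, size = size)
    a2[, s] <- stats::rnbinom(n, mu = base_mu * (1 - share_a1) * f2, size = size)
  }
  mapped_total <- colSums(a1) + colSums(a2)
  dimnames(a1) <- dimnames(a2) <- list(NULL, samples$sample_id)
  names(mapped_total) <- samples$sample_id
  structure(list(elements = elements, samples = samples, a1 = a1, a2 = a2,
                 mapped_total = mapped_total),
            class = "atac_track")
}

#' @export
print.atac_track <- function(x, ...) {
  cat("atac_track:", nrow(x$elements), "elements x", nrow(x$samples),
      "samples\n")
  invisible(x)
}
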