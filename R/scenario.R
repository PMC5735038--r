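#' Define a simulation scenario for allelic silencing data
#'
#' A scenario fixes the generative world for [simulate_genome()],
#' [simulate_allelic_counts()] and [simulate_atac_counts()]: a hybrid cell
#' line with two distinguishable alleles per gene, two conditions (`NoDox`
#' untreated baseline, `Dox` transgene induction), and at most one
#' transgene-bearing chromosome on which one allele loses a stated fraction
#' of its signal in cis upon induction.
#'
#' Total gene counts are negative binomial; per-gene allelic ratios are
#' Beta-distributed around 0.5; only a fraction of reads is
#' allele-assignable (intronic/SNP-overlapping reads in real nascent-RNA
#' libraries). Silencing removes silenced-allele signal, so for an affected
#' gene with silenced-allele share \eqn{\pi} and true repression \eqn{\rho}
#' the Dox total-count mean scales by \eqn{1-\pi\rho} and the silenced
#' share becomes \eqn{\pi(1-\rho)/(1-\pi\rho)}.
#'
#' @param n_chromosomes number of autosomes to simulate.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   default 100 Mb each, named `chr1..chrN`.
#' @param genes_per_chromosome genes placed per chromosome.
#' @param baseline_mean expected total read pairs per gene per sample.
#' @param dispersion negative-binomial overdispersion; variance is
#'   `mu + dispersion * mu^2` (NB size = `1/dispersion`).
#' @param allelic_balance_concentration total concentration of the
#'   symmetric Beta prior on the per-gene allele-1 share; larger is tighter
#'   around 0.5.
#' @param transgene_chrom chromosome carrying the inducible transgene, or
#'   `NULL` for a global null (no gene repressed).
#' @param silenced_allele which allele is silenced in cis: `"a1"` (Cast) or
#'   `"a2"` (129S1).
#' @param repressed_fraction fraction of transgene-chromosome genes subject
#'   to repression.
#' @param repression_strength expected fractional loss of silenced-allele
#'   signal for affected genes, i.e. the true repression score in `[0,1]`.
#' @param integration_site bp position of the transgene; defaults to the
#'   middle of `transgene_chrom`. Only used when distance decay is on.
#' @param distance_decay_halflife exponential half-life (bp) of repression
#'   strength with distance from the integration site, or `NULL` (default)
#'   for uniform strength along the chromosome.
#' @param n_replicates biological replicates per condition (>= 1).
#' @param library_size expected read pairs per sample; default
#'   `total genes * baseline_mean`.
#' @param informative_fraction fraction of a gene's reads that are
#'   allele-assignable; default 0.4 (roughly the intronic read fraction of
#'   nascent-RNA libraries).
#' @param atac_mean expected ATAC fragments per element per allele.
#' @param atac_dox_factor multiplier retained by the silenced allele's
#'   accessibility mean under Dox on the transgene chromosome; 1 means no
#'   change, 0.5 means half the accessibility is lost.
#' @param seed integer master seed; all randomness in the generators is a
#'   pure function of the scenario (including this seed).
#'
#' @return An object of class `silencing_scenario` (a validated list).
#' @export
#' @examples
#' sc <- silencing_scenario(n_chromosomes = 3, transgene_chrom = "chr2")
#' ann <- simulate_genome(sc)
#' sim <- simulate_allelic_counts(ann, sc)
silencing_scenario <- function(n_chromosomes = 3,
                               chrom_lengths = NULL,
                               genes_per_chromosome = 100,
                               baseline_mean = 500,
                               dispersion = 0.15,
                               allelic_balance_concentration = 40,
                               transgene_chrom = NULL,
                               silenced_allele = c("a1", "a2"),
                               repressed_fraction = 0.6,
                               repression_strength = 0.5,
                               integration_site = NULL,
                               distance_decay_halflife = NULL,
                               n_replicates = 2,
                               library_size = NULL,
                               informative_fraction = 0.4,
                               atac_mean = 200,
                               atac_dox_factor = 0.5,
                               seed = 1L) {
  silenced_allele <- match.arg(silenced_allele)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- stats::setNames(rep(100e6, n_chromosomes),
                                     paste0("chr", seq_len(n_chromosomes)))
  }
  if (length(chrom_lengths) != n_chromosomes) {
    stop("configuration error: chrom_lengths must have one entry per chromosome",
         call. = FALSE)
  }
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths))) {
    stop("configuration error: chrom_lengths must be uniquely named", call. = FALSE)
  }
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("configuration error: chromosome lengths must be positive", call. = FALSE)
  }
  stopifnot(genes_per_chromosome >= 1, n_replicates >= 1,
            baseline_mean > 0, dispersion > 0,
            allelic_balance_concentration > 0, atac_mean > 0)
  for (nm in c("repressed_fraction", "repression_strength")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("configuration error: ", nm, " must lie in [0,1]", call. = FALSE)
    }
  }
  if (informative_fraction <= 0 || informative_fraction > 1) {
    stop("configuration error: informative_fraction must lie in (0,1]", call. = FALSE)
  }
  if (atac_dox_factor < 0 || atac_dox_factor > 1) {
    stop("configuration error: atac_dox_factor must lie in [0,1]", call. = FALSE)
  }
  if (!is.null(transgene_chrom) && !transgene_chrom %in% names(chrom_lengths)) {
    stop("configuration error: transgene_chrom not among chromosome names",
         call. = FALSE)
  }
  if (!is.null(transgene_chrom) && is.null(integration_site)) {
    integration_site <- floor(chrom_lengths[[transgene_chrom]] / 2)
  }
  if (is.null(library_size)) {
    library_size <- n_chromosomes * genes_per_chromosome * baseline_mean
  }
  out <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_lengths = chrom_lengths,
    genes_per_chromosome = as.integer(genes_per_chromosome),
    baseline_mean = baseline_mean,
    dispersion = dispersion,
    allelic_balance_concentration = allelic_balance_concentration,
    transgene_chrom = transgene_chrom,
    silenced_allele = silenced_allele,
    repressed_fraction = repressed_fraction,
    repression_strength = repression_strength,
    integration_site = integration_site,
    distance_decay_halflife = distance_decay_halflife,
    n_replicates = as.integer(n_replicates),
    conditions = c("NoDox", "Dox"),
    library_size = library_size,
    informative_fraction = informative_fraction,
    atac_mean = atac_mean,
    atac_dox_factor = atac_dox_factor,
    seed = as.integer(seed)
  )
  class(out) <- "silencing_scenario"
  out
}

#' @export
print.silencing_scenario <- function(x, ...) {
  cat("silencing_scenario:", x$n_chromosomes, "chromosomes x",
      x$genes_per_chromosome, "genes,", x$n_replicates,
      "replicates per condition\n")
  if (is.null(x$transgene_chrom)) {
    cat("  global null (no transgene)\n")
  } else {
    cat("  transgene on", x$transgene_chrom, "silencing allele",
        x$silenced_allele, sprintf("(strength %.2f, fraction %.2f)\n",
                                   x$repression_strength, x$repressed_fraction))
  }
  invisible(x)
}

# deterministic per-sample seed so adding replicates never perturbs
# existing samples' draws; kept below 2^31
.sample_seed <- function(seed, condition, replicate, stream = 0L) {
  cond_code <- match(condition, c("NoDox", "Dox"))
  base <- (as.double(seed) * 48271 + cond_code * 1664525 +
             replicate * 22695477 + stream * 69069) %% 2147483629
  as.integer(base)
}
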