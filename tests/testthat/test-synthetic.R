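test_that("simulate_genome respects bounds, counts and determinism", {
  sc <- silencing_scenario(n_chromosomes = 1,
                           chrom_lengths = c(chr1 = 100e6),
                           genes_per_chromosome = 100, seed = 4)
  ann <- simulate_genome(sc)
  expect_equal(nrow(ann), 100)
  expect_true(all(ann$start >= 0 & ann$start < ann$end & ann$end <= 100e6))
  expect_identical(ann, simulate_genome(sc))

  sc3 <- silencing_scenario(n_chromosomes = 3, genes_per_chromosome = 50,
                            seed = 4)
  ann3 <- simulate_genome(sc3)
  expect_equal(nrow(ann3), 150)
  expect_equal(as.vector(table(ann3$chrom)), rep(50L, 3))
  expect_false(is.unsorted(ann3$start[ann3$chrom == "chr2"]))
})

test_that("invalid scenario configuration errors", {
  expect_error(silencing_scenario(chrom_lengths = c(chr1 = -5), n_chromosomes = 1),
               "positive")
  expect_error(silencing_scenario(repression_strength = 1.4), "\\[0,1\\]")
  expect_error(silencing_scenario(informative_fraction = 0), "informative_fraction")
  expect_error(silencing_scenario(transgene_chrom = "chrX"), "transgene_chrom")
})

test_that("allelic counts conserve mass and are deterministic", {
  sim <- tiny_simulation()
  cnt <- sim$counts
  expect_true(all(cnt$a1 + cnt$a2 <= cnt$total))
  expect_true(all(colSums(cnt$total) > 0))
  sim2 <- tiny_simulation()
  expect_identical(cnt$total, sim2$counts$total)
  expect_identical(cnt$a1, sim2$counts$a1)
  expect_identical(sim$truth, sim2$truth)
})

test_that("adding replicates does not perturb existing samples", {
  a <- tiny_simulation(n_replicates = 2)
  b <- tiny_simulation(n_replicates = 3)
  shared <- a$counts$samples$sample_id
  expect_identical(a$counts$total, b$counts$total[, shared])
  expect_identical(a$counts$a1, b$counts$a1[, shared])
})

test_that("null scenario carries no true repression", {
  sim <- tiny_simulation(transgene_chrom = NULL)
  expect_true(all(sim$truth$true_rs == 0))
  sim0 <- tiny_simulation(repression_strength = 0)
  expect_true(all(sim0$truth$true_rs == 0))
})

test_that("full-strength silencing empties the silenced allele under Dox", {
  sim <- tiny_simulation(repression_strength = 1, informative_fraction = 1,
                         baseline_mean = 2000, repressed_fraction = 1)
  cnt <- sim$counts
  aff <- sim$truth$true_rs == 1
  dox <- cnt$samples$condition == "Dox"
  sil_share_dox <- sum(cnt$a1[aff, dox]) / sum(cnt$a1[aff, dox] + cnt$a2[aff, dox])
  expect_lt(sil_share_dox, 0.005)
  # NoDox never repressed: silenced allele keeps its balanced share
  nod <- cnt$samples$condition == "NoDox"
  sil_share_nod <- sum(cnt$a1[aff, nod]) / sum(cnt$a1[aff, nod] + cnt$a2[aff, nod])
  expect_gt(sil_share_nod, 0.4)
})

test_that("Dox/NoDox silenced-share ratio matches the generative expectation", {
  # closed form under the generator: share ratio = (1-rho)/(1-pi*rho) with
  # pi ~ Beta(kappa/2, kappa/2); oracle = numerical integral over the prior
  rho <- 0.5; kappa <- 40
  oracle <- stats::integrate(function(p) {
    (1 - rho) / (1 - p * rho) * stats::dbeta(p, kappa / 2, kappa / 2)
  }, 0, 1)$value
  ratios <- vapply(1:3, function(s) {
    sc <- silencing_scenario(n_chromosomes = 20, genes_per_chromosome = 500,
                             transgene_chrom = "chr5", silenced_allele = "a1",
                             repressed_fraction = 0.6, repression_strength = rho,
                             allelic_balance_concentration = kappa,
                             baseline_mean = 500, seed = s)
    sim <- simulate_allelic_counts(simulate_genome(sc), sc)
    cnt <- sim$counts
    aff <- sim$truth$true_rs > 0
    dox <- cnt$samples$condition == "Dox"
    nod <- cnt$samples$condition == "NoDox"
    sh <- function(idx) rowSums(cnt$a1[aff, idx]) /
      rowSums(cnt$a1[aff, idx] + cnt$a2[aff, idx])
    mean(sh(dox) / sh(nod))
  }, numeric(1))
  expect_true(all(abs(ratios - oracle) < 0.05))
})

test_that("distance decay attenuates repression away from the integration site", {
  sim <- tiny_simulation(distance_decay_halflife = 10e6,
                         integration_site = 50e6, repressed_fraction = 1)
  tr <- merge(sim$truth, sim$counts$genes[, c("gene_id", "start", "end")])
  on <- tr$chrom == "chr2"
  d <- abs((tr$start[on] + tr$end[on]) / 2 - 50e6)
  expect_equal(tr$true_rs[on], 0.5 * exp(-d * log(2) / 10e6), tolerance = 1e-12)
  expect_true(all(tr$true_rs[!on] == 0))
})

test_that("element validation rejects malformed and overlapping intervals", {
  bad <- data.frame(chrom = "chr1", start = c(10, 5), end = c(5, 50),
                    state = "promoter")
  expect_error(simulate_atac_counts(bad, tiny_scenario()), "malformed")
  over <- data.frame(chrom = "chr1", start = c(10, 40), end = c(50, 80),
                     state = "promoter")
  expect_error(simulate_atac_counts(over, tiny_scenario()), "overlapping")
})

test_that("atac generator: null factor gives zero-mean ddscore, zero counts give zero", {
  sc <- tiny_scenario(atac_dox_factor = 1, atac_mean = 2000, dispersion = 0.02)
  el <- simulate_elements(sc, n_per_chromosome = 80)
  track <- simulate_atac_counts(el, sc)
  dd <- ddscore_track(track)
  cov_scale <- mean(normalize_atac(track$a1 + track$a2, track$mapped_total))
  expect_lt(abs(mean(dd$ddscore)), 0.02 * cov_scale)
  track$a1[] <- 0L; track$a2[] <- 0L; track$mapped_total[] <- 1
  expect_true(all(ddscore_track(track)$ddscore == 0))
})
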