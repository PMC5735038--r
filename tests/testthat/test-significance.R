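test_that("permutation p is 1 at rs_obs = 0 and 0 is attainable under deep silencing", {
  # gene 1: silenced allele goes UP under Dox -> raw rs < 0 -> rs_obs = 0
  # gene 2: near-complete silencing at depth -> p can reach 0
  cnt <- manual_counts(
    total = cbind(c(4000, 4000), c(4000, 4000)),
    a1 = cbind(c(500, 1000), c(1500, 2)),
    a2 = cbind(c(1500, 1000), c(500, 1998)),
    conditions = c("NoDox", "Dox"), replicates = c(1, 1))
  perm <- permutation_test(cnt, "a1", n_perm = 400, seed = 1)
  expect_equal(perm$p_rep1[perm$gene_id == "g001"], 1)
  expect_equal(perm$p_rep1[perm$gene_id == "g002"], 0)
  expect_true(all(perm$p_combined >= 0 & perm$p_combined <= 1))
})

test_that("permutation p is stable across seeds within binomial error", {
  sim <- tiny_simulation(genes_per_chromosome = 15)
  ids <- rs_table(sim$counts, "a1")$gene_id
  ids <- ids[startsWith(ids, "chr2")]
  n_perm <- 2000
  p1 <- permutation_test(sim$counts, "a1", gene_ids = ids, n_perm = n_perm,
                         seed = 1)
  p2 <- permutation_test(sim$counts, "a1", gene_ids = ids, n_perm = n_perm,
                         seed = 99)
  for (k in c("p_rep1", "p_rep2")) {
    se <- sqrt(pmax(p1[[k]], 1 / n_perm) * (1 - pmin(p1[[k]], 1 - 1 / n_perm)) / n_perm)
    within3 <- abs(p1[[k]] - p2[[k]]) <= 3 * se + 2 / n_perm
    # a 3*SE band is an ~99.7% per-gene event, not a uniform bound
    expect_gte(mean(within3), 0.9)
    expect_true(all(abs(p1[[k]] - p2[[k]]) <= 5 * se + 2 / n_perm))
  }
  # counted per-gene streams: p does not depend on the tested set
  sub <- permutation_test(sim$counts, "a1", gene_ids = ids[3], n_perm = n_perm,
                          seed = 1)
  expect_equal(sub$p_rep1, p1$p_rep1[3])
})

test_that("fisher_combine matches the chi-square closed form", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  # analytic chi-square(4) survival: exp(-x/2) * (1 + x/2)
  x <- -2 * 2 * log(0.05)
  expect_equal(fisher_combine(c(0.05, 0.05)), exp(-x / 2) * (1 + x / 2))
  expect_equal(fisher_combine(0.32), 0.32)  # k = 1 identity
  # zero p floored at 1/(n_perm+1), finite result
  expect_true(is.finite(fisher_combine(c(0, 0.01), n_perm = 100)))
  expect_error(fisher_combine(numeric(0)), "empty")
  expect_error(fisher_combine(c(0.5, 2)), "\\[0, 1\\]")
})

test_that("bh_adjust equals a hand step-up oracle", {
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # oracle: literal step-up on random vectors
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
  }
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("call_silent needs both the q and cRS condition", {
  expect_true(call_silent(0.5, 0.01))
  expect_false(call_silent(0.9, 0.20))
  expect_false(call_silent(0.05, 0.01, crs_min = 0.1))
  expect_equal(call_silent(c(0.5, 0.05), c(0.01, 0.01)), c(TRUE, FALSE))
})

test_that("silent-call power at generator defaults exceeds the documented target", {
  # regression target (documented, not literature-derived): >= 80% of
  # affected genes called silent at default depth, strength 0.5
  sim <- tiny_simulation(n_chromosomes = 4, genes_per_chromosome = 100, seed = 3)
  res <- silencing_analysis(sim$counts, n_perm = 2000, detect_n_perm = 300,
                            seed = 5)
  aff <- sim$truth$gene_id[sim$truth$true_rs > 0]
  expect_identical(attr(res$rs, "candidate_chrom"), "chr2")
  expect_gte(mean(res$rs$silent[res$rs$gene_id %in% aff]), 0.8)
})

test_that("null pipeline controls the silent-call rate", {
  # exchangeability under the null, scaled down: 20 datasets, small genomes
  n_sil <- 0L; n_tot <- 0L
  for (s in 1:20) {
    sim <- tiny_simulation(n_chromosomes = 3, genes_per_chromosome = 40,
                           transgene_chrom = NULL, seed = 100 + s)
    rst <- rs_table(sim$counts, "a1")
    for (chr in unique(rst$chrom)) {
      on <- rst$chrom == chr
      perm <- permutation_test(sim$counts, "a1", gene_ids = rst$gene_id[on],
                               n_perm = 250, seed = s)
      q <- bh_adjust(perm$p_combined)
      rrs <- random_rs(rst, candidate_chrom = chr)[1]
      crs <- calibrated_rs(rst$rs[on][match(perm$gene_id, rst$gene_id[on])], rrs)
      n_sil <- n_sil + sum(call_silent(crs, q), na.rm = TRUE)
      n_tot <- n_tot + nrow(perm)
    }
  }
  se <- sqrt(0.05 * 0.95 / n_tot)
  expect_lte(n_sil / n_tot, 0.05 + 3 * se)
})
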