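test_that("repression_score evaluates and clips the role-based formula", {
  expect_equal(repression_score(100, 100, 100, 0), 1)    # complete silencing
  expect_equal(repression_score(100, 50, 100, 50), 0)    # proportional change
  expect_equal(repression_score(50, 60, 50, 20), 0.8)
  expect_equal(repression_score(100, 300, 100, 100), 1)  # clipped from 2
  expect_equal(repression_score(100, 300, 100, 100, clip = FALSE), 2)
  expect_equal(repression_score(100, 100, 100, 150), 0)  # clipped from -0.5
  expect_true(is.na(repression_score(0, 10, 5, 5)))      # zero baseline
  expect_true(is.na(repression_score(10, 10, 0, 5)))
})

test_that("rs_table is null on identical conditions and scale-invariant", {
  base <- cbind(c(100, 200, 50), c(100, 200, 50))
  a1 <- cbind(c(30, 80, 10), c(30, 80, 10))
  a2 <- cbind(c(40, 70, 20), c(40, 70, 20))
  cnt <- manual_counts(total = base * 100, a1 = a1, a2 = a2,
                       conditions = c("NoDox", "Dox"), replicates = c(1, 1))
  rst <- rs_table(cnt)
  expect_true(all(rst$rs == 0))

  # scaling one sample's counts uniformly cancels through CPM
  sim <- tiny_simulation()
  cnt1 <- sim$counts
  cnt2 <- cnt1
  cnt2$total[, "Dox_rep1"] <- cnt1$total[, "Dox_rep1"] * 3L
  cnt2$a1[, "Dox_rep1"] <- cnt1$a1[, "Dox_rep1"] * 3L
  cnt2$a2[, "Dox_rep1"] <- cnt1$a2[, "Dox_rep1"] * 3L
  expect_equal(rs_table(cnt2)$rs, rs_table(cnt1)$rs, tolerance = 1e-12)
})

test_that("rs_table recovers known repression and collapses when flipped", {
  # per-gene RS keeps the NB overdispersion of the total-count ratio, so
  # the median needs many affected genes (not just depth) to settle
  sim <- tiny_simulation(n_chromosomes = 3, genes_per_chromosome = 300,
                         baseline_mean = 2000)
  rst <- rs_table(sim$counts, "a1")
  aff <- sim$truth$gene_id[sim$truth$true_rs > 0]
  expect_lt(abs(median(rst$rs[rst$gene_id %in% aff]) - 0.5), 0.05)
  flipped <- rs_table(sim$counts, "a2")
  expect_lt(median(flipped$rs[flipped$gene_id %in% aff]), 0.05)
  expect_true(all(rst$rs >= 0 & rst$rs <= 1))
})

test_that("random_rs and calibrated_rs behave per contract", {
  sim <- tiny_simulation()
  rst <- rs_table(sim$counts, "a1")
  # self-calibration: control identical to the analysed line
  crs <- calibrated_rs(rst$rs, random_rs(rst, control = rst))
  expect_true(all(crs == 0))
  rrs <- random_rs(rst, candidate_chrom = "chr2")
  expect_equal(length(rrs), nrow(rst))
  expect_true(all(rrs == rrs[1]) && rrs[1] >= 0)
  expect_identical(rrs, random_rs(rst, candidate_chrom = "chr2"))
  expect_equal(rrs[1], median(rst$rs[rst$chrom != "chr2"]))
  expect_error(random_rs(rst), "configuration error")
  expect_equal(calibrated_rs(0.8, 0.1), 0.7)
  expect_equal(calibrated_rs(0.3, 0.3), 0)
  expect_equal(calibrated_rs(0, 0.2), -0.2)  # not re-clipped
})

test_that("detect_transgene recovers the planted chromosome and allele", {
  for (ori in c("a1", "a2")) {
    sim <- tiny_simulation(silenced_allele = ori, seed = 7)
    tg <- detect_transgene(sim$counts, n_perm = 300, seed = 2)
    expect_identical(tg$chrom, "chr2")
    expect_identical(tg$silenced_allele, ori)
    expect_identical(tg$status, "ok")
    expect_equal(max(tg$scores), tg$scores[ori, "chr2"])
  }
})

test_that("detect_transgene returns none under the global null", {
  sim <- tiny_simulation(transgene_chrom = NULL, seed = 5)
  expect_warning(tg <- detect_transgene(sim$counts, n_perm = 200, seed = 3),
                 "not identifiable")
  expect_identical(tg$status, "none")
  expect_true(is.na(tg$chrom))
  one <- tiny_simulation(n_chromosomes = 1, chrom_lengths = c(chr2 = 1e8))
  expect_error(detect_transgene(one$counts), "at least 2 chromosomes")
})
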