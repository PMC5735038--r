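# shared fixtures: everything is generated in code, no files

tiny_scenario <- function(...) {
  args <- list(n_chromosomes = 4, genes_per_chromosome = 60,
               transgene_chrom = "chr2", silenced_allele = "a1", seed = 11L)
  args[names(list(...))] <- list(...)
  do.call(silencing_scenario, args)
}

tiny_simulation <- function(...) {
  sc <- tiny_scenario(...)
  sim <- simulate_allelic_counts(simulate_genome(sc), sc)
  sim$scenario <- sc
  sim
}

# hand-built count container: one gene vector per argument, samples
# NoDox_rep1..k then Dox_rep1..k
manual_counts <- function(total, a1, a2, conditions, replicates,
                          chrom = "chr1", starts = NULL) {
  n <- nrow(as.matrix(total))
  starts <- starts %||% (seq_len(n) * 1e6)
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
                      start = starts, end = starts + 1000, strand = "+",
                      stringsAsFactors = FALSE)
  rownames(genes) <- genes$gene_id
  samples <- data.frame(sample_id = sprintf("%s_rep%d", conditions, replicates),
                        condition = conditions, replicate = replicates,
                        stringsAsFactors = FALSE)
  allelic_counts(genes, samples, as.matrix(total), as.matrix(a1), as.matrix(a2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent oracle for the window scan: exhaustive enumeration with the
# stated tie rules (higher median, then more genes, then leftmost)
brute_max_window <- function(rs, chrom, width, min_genes, chrom_length) {
  n_win <- ceiling(chrom_length / width)
  best <- NULL
  for (i in seq_len(n_win)) {
    lo <- (i - 1) * width; hi <- min(i * width, chrom_length)
    v <- rs$rs[rs$chrom == chrom & rs$start >= lo & rs$start < hi]
    if (length(v) < min_genes) next
    cand <- list(start = lo, end = hi, n = length(v), med = median(v))
    if (is.null(best) || cand$med > best$med ||
        (cand$med == best$med && cand$n > best$n)) {
      best <- cand
    }
  }
  best
}
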