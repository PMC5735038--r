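n_chromosomes: 4
genes_per_chromosome: 100
baseline_mean: 500
transgene_chrom: chr2
silenced_allele: a1
repressed_fraction: 0.6
repression_strength: 0.5
n_replicates: 2
seed: 7
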