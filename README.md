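# repscore

Allelic repression-score analysis of chromosome-wide silencing.

## What this is for

In hybrid cell lines (e.g. Cast × 129S1 mouse ES cells) every autosomal gene
carries strain SNPs that let allele-split RNA-seq counts be assigned to the
two parental chromosomes. When an inducible silencing transgene (an
Xist-type long non-coding RNA) integrates on one chromosome, induction
represses genes *in cis* on that chromosome — on one allele only. `repscore`
quantifies that allele-specific silencing from gene-level allelic count
tables: it scores every gene, finds the chromosome and allele carrying the
transgene, assesses significance by permutation, locates the most strongly
silenced region, and summarizes the matching loss of allelic chromatin
accessibility from ATAC fragment counts. A synthetic-data generator with
known ground truth makes the whole pipeline testable without any external
download.

## The statistic

For a gene with active-allele expression `A` and putatively silenced-allele
expression `S` (CPM split by the allelic read ratio), comparing untreated
(`0`) and induced (`i`) conditions, the repression score is

    RS_raw = (A_i - A_0)/A_0  -  (S_i - S_0)/S_0,      RS = clip(RS_raw, 0, 1)

so complete silencing of one allele with the other unchanged gives 1 and a
proportional change of both alleles gives 0. Which measured allele plays the
silenced role (the *orientation*) is iterated together with all chromosomes;
the chromosome with the most significantly repressed genes wins. Per-gene
significance comes from a permutation null — allele-assignable reads
re-split binomially at the gene's baseline allelic fraction, totals held
fixed, RS recomputed `N = 10000` times; `p = #{RS_null >= RS_obs}/N` — with
replicate p-values combined by Fisher's method and BH-adjusted. A calibrated
score `cRS = RS - rRS` subtracts a random-RS background (a matched control
line, or the median RS of all non-candidate chromosomes), and a gene is
called *silent* when `q < 0.05` and `cRS > 0.1`. For accessibility, the
allelic ATAC differential per element is

    ddscore = [G1(Dox) - G2(Dox)] - [G1(NoDox) - G2(NoDox)]

on coverages normalized to 10 million mapped reads, averaged per ChromHMM
state per chromosome and compared between chromosomes by Mann-Whitney.

## Worked example

```r
library(repscore)
cfg <- system.file("extdata", "example_scenario.dcf", package = "repscore")
sc  <- read_scenario_config(cfg)       # 4 chromosomes, transgene on chr2 (allele a1)
sim <- simulate_allelic_counts(simulate_genome(sc), sc)
res <- silencing_analysis(sim$counts, n_perm = 10000, detect_n_perm = 1000, seed = 1)
res
#> silencing_analysis: chr2 / silenced allele a1
#>   59 of 100 genes silent (59%, q < 0.05 & cRS > 0.10)
max_silencing_region(res$rs, "chr2")
#>   width chrom   start     end n_genes median_rs
#> 1 1e+07  chr2 8.0e+07 9.0e+07      11 0.5416868
#> 2 5e+06  chr2 8.0e+07 8.5e+07       6 0.5694671
#> 3 3e+06  chr2 8.4e+07 8.7e+07       5 0.4689378
round(categorize_rs(res$rs$rs), 3)
#>   [0,0.1) [0.1,0.4) [0.4,0.7)   [0.7,1]
#>      0.26      0.28      0.34      0.12
```

The pipeline recovered the planted transgene chromosome (`chr2`) and allele
(`a1`); 59 of the 100 scored chr2 genes pass the silent-gene definition
(the scenario plants repression of strength 0.5 on 60% of them). The
maximum-silencing windows at 10/5/3 Mb have median RS near the planted 0.5,
and 74% of chr2 genes fall in the RS 0.1–1 range (the `frac_rs_0.1_1`
attribute of `categorize_rs`).

## Command line

Every step is also a subcommand of the installed `exec/repscore` script (or
`repscore::rs_cli()` in-process):

```sh
repscore simulate --config scenario.dcf --out sim/
repscore score    --in sim/ --out scored/ --n-perm 10000 --seed 1
repscore scan     --rs scored/rs_table.tsv --chrom chr2 --windows 10,5,3 --out scan/
repscore atac     --in sim/atac_counts.tsv --out atac/ \
                  --target-chrom chr2 --control-chrom chr3
repscore report   --rs scored/rs_table.tsv
```

All outputs are plain tab-separated/BED/bedGraph text with a DCF
run-metadata sidecar recording seed and parameters; reruns with the same
config and seed are byte-identical.

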