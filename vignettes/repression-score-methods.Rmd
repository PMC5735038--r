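---
title: "Methods: the allelic repression score, its null, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the allelic repression score, its null, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(repscore)
```

## The model and its assumptions

`repscore` analyses gene-level counts from a hybrid cell line whose two
parental chromosomes are distinguishable by SNPs. Each sample provides, per
gene, a total read-pair count and the subset of pairs assignable to allele 1
(Cast/G1) or allele 2 (129S1/G2). Totals are normalized per sample to
counts per million (CPM) and split by the allelic ratio:
`expr_a1 = CPM * a1/(a1+a2)`. Genes with no allele-assignable read in a
sample have an *unobserved* ratio there and are treated as missing, never
as zero.

The repression score of a gene contrasts the relative change of the two
alleles between the untreated baseline (0) and the induced condition (i):

$$RS_{raw} = \frac{A_i - A_0}{A_0} - \frac{S_i - S_0}{S_0}, \qquad
  RS = \min(1, \max(0, RS_{raw}))$$

with $A$ the active and $S$ the putatively silenced allele. The underlying
assumption is that ordinary transcriptional variation (induction side
effects, culture drift) affects both alleles proportionally and cancels in
the difference, while cis-limited silencing moves only $S$. Writing the
score by *role* rather than by fixed allele letters matters: a formula
pinned to one strain yields $-1$ instead of $+1$ under full silencing of
the other strain's allele. The package therefore treats "which allele is
silenced" as an explicit orientation and iterates both orientations during
transgene detection, keeping the score in $[0,1]$ in the orientation that
fits.

Because the total-count ratio between conditions multiplies the whole
allelic term, per-gene RS inherits the negative-binomial overdispersion of
expression (CV roughly $\sqrt{\phi}$ even at infinite depth). Single-gene
scores are therefore noisy at any coverage; medians over windows or
chromosomes, and the permutation test below, are the units of inference.

## Significance: permutation, Fisher, BH

For each gene the allele-assignable reads of every involved sample are
re-assigned to alleles by a binomial draw and RS is recomputed through the
identical code path (clipping included), `n_perm = 10000` times;
`p = #{RS_null >= RS_obs}/n_perm`. Two choices are deliberate:

* **Totals are held fixed** and only the allelic split is permuted, so CPM
  (and hence the library normalization) is invariant across permutations;
  the null destroys condition-specific allelic skew only.
* **The binomial probability defaults to the gene's pooled baseline
  allelic fraction** (`allelic_p = "nodox"`). This preserves constitutive
  allelic skew (eQTL-like imbalance that exists in both conditions) so it
  is not mistaken for induced silencing; `"half"` is available for a
  strict 50:50 null.

Replicate p-values are combined with Fisher's method
($-2\sum\ln p \sim \chi^2_{2k}$) and BH-adjusted per chromosome (the
permutation scheme is applied chromosome-wide). A permutation p of exactly
0 is reported as 0 but floored at $1/(n_{perm}+1)$ inside the logarithm.
The calibrated score $cRS = RS - rRS$ subtracts either a matched control
line's per-gene RS or, absent one, the scalar median RS of all
non-candidate chromosomes; $cRS$ is *not* re-clipped, so negative values
flag genes below background (any log-transform of cRS must floor at
$1/n_{perm}$). A gene is silent when $q < 0.05$ **and** $cRS > 0.1$; the
cRS cutoff is not quantified in the source analysis and 0.1 (the lower
edge of the conventional RS range of interest) is the documented,
configurable default.

**p-values are conservative, not uniform.** Clipping puts an atom of the
null RS distribution at 0, and the contract fixes `p = 1` whenever
`RS_obs = 0`. Under a global null roughly $P(RS_{raw} \le 0) \approx 0.3$
of genes therefore sit at `p = 1`, and the two-sided KS distance between
the null p distribution and U(0,1) equals that atom mass — it can never be
small. What *does* hold, and what the property tests assert, is validity:
the anti-conservative deviation $\sup_t(\hat F_p(t) - t)$ is near zero and
the silent-call rate under the null stays below the nominal 5%. The
acceptance test that demands two-sided KS < 0.05 is left failing by
design.

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `n_perm` | 10000 | permutations per gene (detection screen uses 1000) |
| `q_max` | 0.05 | BH q cutoff of the silent-gene call |
| `crs_min` | 0.1 | cRS cutoff of the silent-gene call |
| filter | `mean_gt1` | keep genes with mean CPM > 1 across samples; `allelic_sum_gt` with threshold 8 (time course) or 6 (truncated constructs) sums allelic expression over all samples, strictly `>` |
| windows | 10, 5, 3 Mb | sequential half-open tiles from position 0; genes bin by start coordinate |
| `min_genes` | 5 | genes a window needs before its median is trusted |
| RS bins | [0,0.1), [0.1,0.4), [0.4,0.7), [0.7,1] | reporting categories; the four-way split is an assumption, the source shows it only as a colour ramp |
| pooling | `pooled` | baseline replicates summed into one pseudo-sample; `matched` pairs replicates |

The "mean CPM above one" filter is read as mean-across-samples > 1 (the
alternative per-sample reading is a stricter subset and can be emulated
with `allelic_sum_gt`). Replicates are normalized independently with no
cross-replicate shrinkage; the reported RS is the mean of per-replicate
scores, and p-values are per replicate then combined, never computed on
averaged counts.

## The synthetic world

`silencing_scenario()` states the generative world once; all generators are
pure functions of it (per-sample seed streams derived from condition and
replicate id, so adding replicates reproduces existing samples
bit-identically).

* Totals: negative binomial, default mean 500 read pairs per gene per
  sample (a realistic figure for ~40M read-pair nascent-RNA libraries over
  ~20k expressed genes), dispersion 0.15.
* Allele-assignable reads: binomial at `informative_fraction = 0.4`,
  mirroring the ~40% intronic read fraction of 4sU-type libraries.
* Per-gene allelic ratio: Beta with total concentration 40 around 0.5
  (constitutive skew, SD ≈ 0.08).
* Silencing: on the transgene chromosome a fraction (default 0.6) of genes
  loses a fraction $\rho$ (default 0.5) of silenced-allele signal under
  induction. Because silencing *removes* signal, the total-count mean
  scales by $1-\pi\rho$ and the silenced share becomes
  $\pi(1-\rho)/(1-\pi\rho)$; the active allele's absolute expectation is
  untouched. This is the parameterization under which the RS estimator
  recovers $\rho$; the naive alternative (multiply the share by $1-\rho$,
  totals unchanged) silently inflates RS by $\approx 1/(1-\pi)$ and was
  rejected.
* Optional exponential distance decay of $\rho$ from the integration site
  (off by default — spread along the chromosome is reported without a
  stated kernel).
* ATAC: element-level fragment counts per allele, NB around an
  element-specific mean; under induction every element on the transgene
  chromosome keeps `atac_dox_factor` (default 0.5) of its silenced-allele
  mean, giving the closed-form expectation
  $E[ddscore] = -(1-f)\,\bar G_{sil}^{NoDox}$ used as the generator
  oracle in tests.

What the generator does **not** emulate: intron/exon structure and read
placement, mapping or SNP-ascertainment bias between alleles, rRNA
contamination, replicate-level batch effects, correlated neighbouring
genes, and the empirical dispersion of any particular deposited dataset
(defaults are not calibrated to one). A green recovery test therefore
establishes correctness of the inference machinery under the stated world,
not robustness to alignment artifacts upstream of the count tables.

## Numerical and design choices

* RS is undefined (gene dropped) when either baseline allele expression is
  0 — no imputation, avoiding division by zero in the denominators.
* Strict inequalities throughout the filters and calls, as specified
  (`> 8` removes a gene summing to exactly 8; `q < 0.05`).
* Window tie-breaks: higher median RS, then more genes, then leftmost.
  Transgene detection ties: higher median RS on the candidate chromosome,
  then lexicographic chromosome name, then orientation a1.
* Gene-to-window assignment uses the BED 0-based half-open start
  coordinate (midpoint/TSS are not stated in the source).
* Mann–Whitney: exact enumeration of all assignments when both samples
  have ≤ 8 observations, otherwise the normal approximation with tie and
  continuity corrections. Normal-approximation agreement with enumeration
  is asserted at moderate effect sizes; in extreme tails the relative
  error of the approximation grows, which is inherent, not a defect.
* Fisher combination with k = 1 returns the p-value unchanged (the
  $\chi^2_2$ identity), so single-replicate designs degrade gracefully.
* BH adjustment delegates to `stats::p.adjust(method = "BH")`; the tests
  verify it against a literal step-up implementation.
* Config files use base-R DCF (`key: value`) because no YAML parser is a
  guaranteed dependency; the schema is the argument list of
  `silencing_scenario()`.
* All outputs are UTF-8, Unix-newline, plain text (TSV/BED/bedGraph) and
  byte-stable under a fixed seed and config.

## Known limitations

Time-course designs are handled by treating each timepoint as a separate
treated condition; no trend model is fit across timepoints. The detection
screen assumes at most one transgene-bearing chromosome. The scalar rRS
background ignores gene-specific variability that a matched control line
would capture — when a control line exists, pass its `rs_table()` as
`control_rs`. Element-level (not per-base) ddscores are computed; per-base
bedGraph output would require fragment positions the count tables do not
carry.
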