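---
title: "From weighted BayesB GWAS to a TF-anchored co-association network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From weighted BayesB GWAS to a TF-anchored co-association network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfawm)
```

## The problem

Selection programmes in livestock record many correlated quantitative
traits — growth rate, backfat thickness, lean percent, litter size — and
genotype elite animals on dense SNP chips. A single-trait GWAS answers
"which windows of the genome move this trait", but breeders and
geneticists also want the *gene-by-gene structure shared across traits*:
which genes co-associate with the whole trait complex, and which
transcription factors (TFs) plausibly sit upstream of them. `bfawm`
implements that chain of analyses as one reproducible pipeline:

1. **Response preparation** — deregressed estimated breeding values
   (DEBV) with per-animal reliabilities are filtered and weighted.
2. **Weighted BayesB** — a Gibbs sampler fits all markers jointly with a
   point-mass mixture prior; each marker gets a posterior mean effect and
   a *model frequency* (how often it was in the model).
3. **Significance** — model frequencies become Bayes factors (BF);
   marker effects are aggregated into 1-Mb window shares of genomic
   variance; windows pass at >1% variance or a member SNP at BF > 20.
4. **Association weight matrix (AWM)** — one representative SNP per
   gene, z-normalised additive effects, genes × traits.
5. **PCIT** — partial-correlation filtering of the gene-gene
   co-association matrix yields the network.
6. **TF validation** — network genes that are TFs are scanned against
   the promoters of the other network genes with position weight
   matrices (PWMs); the three TFs jointly covering the most targets are
   reported.

Because farm genotype/phenotype panels are proprietary, the package
ships a simulator (`simulate_all()`) that generates every input with the
statistical structure the analysis assumes, so the pipeline is fully
testable offline.

## Response weighting

DEBV records differ wildly in information content. The per-record weight

$$w_i \;=\; \frac{1-h^2}{\bigl[c + (1-r_i^2)/r_i^2\bigr]\,h^2}$$

(with $r_i^2$ the DEBV reliability, $h^2$ the trait heritability, and
$c$ the fraction of genetic variance not captured by markers, default
0.40) enters the sampler as a heteroscedastic residual variance
$\sigma_e^2 / w_i$. Reliable records get larger weights, hence smaller
residual variances. `compute_weight()` also exposes a `"literal"`
product form $w_i=(1-h^2)\{c+(1-r_i^2)/r_i^2\}h^2$ for comparison; it is
*decreasing* in reliability and therefore cannot serve the stated
purpose of accounting for heterogeneous DEBV variance — the ratio form
is the default and the one used throughout. Records with reliability
below 0.10 are removed (the boundary is kept).

## The weighted BayesB sampler

The model is
$$y_i = \mu + \sum_{j=1}^{k} Z_{ij}\,u_j\,\delta_j + e_i,\qquad
  e_i \sim N(0, \sigma_e^2 / w_i),$$
with $Z$ the column-centered allele dosages, $\delta_j \in \{0,1\}$ an
inclusion indicator with prior $P(\delta_j=0)=\pi$ (default 0.99), and
$u_j \sim N(0, \sigma_{u_j}^2)$ a locus-specific effect. Key numerical
choices:

* **Joint $(\delta_j, u_j)$ update.** The effect is integrated out
  analytically when sampling $\delta_j$, avoiding the reducibility of a
  naive two-block Gibbs step on $(\delta, u)$; when $\delta_j = 1$ the
  effect is drawn from its conjugate normal full conditional.
* **Locus-variance prior.** Scaled inverse chi-square with
  $\nu = 4.2$ degrees of freedom; the scale is set so that the prior
  expectation of the total genetic variance,
  $(1-\pi)\sum_j \mathrm{var}(z_j)\,E[\sigma_u^2]$, matches the supplied
  initial genetic variance. This is the standard construction for
  mixture-prior whole-genome regression; the hyperparameters of the
  original software implementations are not published, so this choice is
  documented rather than matched.
* **Chain length.** The production defaults are 110,000 iterations,
  10,000 burn-in, thinning 5 (20,000 saved samples). Tests and the demo
  use 2,000–5,000 iterations, which parameter-recovery checks show to be
  ample at desk-scale problem sizes (the demo is m = 1,500 markers,
  n = 300 animals; the recovery benchmark m = 2,000, n = 400).
* **Model frequency** is counted over saved (post-burn-in, thinned)
  samples only. Whether burn-in iterations should count is ambiguous in
  the field's usage; excluding them is the statistically defensible
  choice and the one implemented.
* Zero-variance dosage columns are never updated (model frequency 0);
  missing dosages are mean-imputed with a warning.

The ridge limit ($\pi = 0$, fixed variances) has a closed form — the
weighted ridge solution of the normal equations — and the test suite
holds the sampler to it within Monte-Carlo error, which pins down the
likelihood, the weighting and the updates in one check.

## Bayes factors and 1-Mb windows

With $\hat p$ the model frequency,
$$\mathrm{BF} = \frac{\hat p/(1-\hat p)}{(1-\pi)/\pi},$$
i.e. posterior odds over prior odds; $\hat p = 1-\pi$ gives BF = 1
exactly. Evidence classes use strict thresholds: suggestive > 3.2,
strong > 20, decisive > 100. $\hat p = 1$ maps to `Inf` and is
serialised as `"inf"` in the TSV reports.

Because LD spreads one QTL's signal over neighbouring markers, per-SNP
statistics underestimate regional signal. The window summary therefore
computes, *per saved MCMC sample*, the variance across animals of each
1-Mb window's genomic values $Z_w u_w$ as a share of the variance of the
total $Z u$, then averages the shares ("sample" basis). Using
posterior-mean effects instead (`basis = "postmean"`) is cheaper but
underestimates the shares of uncertain windows. Shares sum to exactly
100% per sample when windows are orthogonal; under LD the sum can
exceed 100% slightly — this is a property of variance partitioning, not
an error. Windows are half-open megabase bins labelled
`chrom_floor(bp/1e6)`, and a window is *informative* when its share
exceeds 1.0% **or** it holds a SNP with BF above 20 (the OR combination
is deliberate: either criterion alone identifies a region worth
reporting).

## AWM construction

Per-trait GWAS tables are combined into a genes × traits matrix:

1. keep SNPs significant (BF ≥ 3.2) for the key trait or for at least
   two traits;
2. apply the gene-distance filter. Two conventions exist in the AWM
   literature, and they are *opposites*: `mode = "literal"` (default)
   **eliminates** SNPs closer than 2,500 bp or farther than 1.5 Mb from
   the nearest gene; `mode = "proximal"` keeps SNPs within 2,500 bp.
   The default follows the stated rule of the method this package
   implements; users who prefer the proximity convention switch modes.
   This choice materially changes which SNPs represent genes and is
   flagged here for that reason;
3. keep one SNP per gene, ranked by the number of significant traits,
   then the key-trait BF, then (a deterministic tie-break the method
   sources leave unspecified) the lowest genomic coordinate.

Surviving SNPs with no gene on their chromosome are retained as their
own rows, mirroring matrices that mix annotated genes with bare SNPs.
Columns are standardised to mean 0, sample SD 1; a constant column
(possible at very small scale when a trait's selected markers were never
included in its model) is a hard error naming the trait, since a z-score
is undefined there.

Nearest-gene distances are plain base-pair gaps (0 inside the gene),
with ties broken toward the smaller gene start. Gene intervals are
1-based inclusive in memory and converted from 0-based half-open BED on
I/O.

## PCIT

For every trio $(x, y, z)$ of AWM rows the three first-order partial
correlations are computed, e.g.
$$r_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
  {\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}},$$
and the trio's tolerance $\varepsilon$ is the mean of the
$|r_{\cdot\cdot\cdot}/r_{\cdot\cdot}|$ ratios (pairs with $|r| <
10^{-12}$ are skipped; degenerate trios with a unit correlation are
skipped entirely). The edge $x$–$y$ is flagged when
$|r_{xy}| \le |\varepsilon\, r_{xz}|$ **and**
$|r_{xy}| \le |\varepsilon\, r_{yz}|$; an edge survives iff no trio
flags it. Surviving edges with $|r| < 10^{-12}$ are dropped as numerical
noise. The $O(n^3)$ loop is compiled; the test suite holds it to an
independent brute-force R implementation on random correlation
matrices.

Two behavioural notes. The rule compares *direct* correlations against
the tolerance-scaled alternatives, so it is conservative where all
correlations are strong: in a chain $r_{xy}=r_{yz}=0.9$,
$r_{xz}=0.81$ the indirect edge survives ($\varepsilon \approx 0.50$,
$0.81 > 0.45$), while at $r_{xy}=r_{yz}=0.3$ the indirect edge
$r_{xz}=0.09$ is removed. And with only seven trait columns, row
correlations are high-variance, so edge counts are sensitive to the
number of traits — a property of the design, not a defect.

## TF validation

Network nodes are matched case-insensitively against a TF symbol list;
TFs without motifs are dropped with a warning (real motif databases
cover only a fraction of TFs). PWMs get a 0.01 pseudocount, are
renormalised per position, and scored as $\log_2$ odds against a
background (uniform by default). Promoters — 2,000 bp upstream flanks —
are scanned on the forward strand only, since the flanks are already
oriented; windows containing `N` are skipped. The p-value of a score is
exact: a dynamic program over integer-discretised scores (granularity
$10^{-3}$) gives $P(\text{score} \ge t)$ for a random background
sequence, and the suite verifies it against exhaustive $4^L$ enumeration
for short motifs. A gene is a target at $p \le 0.001$; the published
cluster-scoring refinement of hit sets is simplified to this per-hit
threshold. The top trio is found by exhaustive search over all
3-subsets (TF counts here are small), maximising the union of target
sets, with a lexicographic tie-break for determinism.

## What the simulator emulates — and what it does not

`sim_config()` defaults describe the desk-scale study conditions used
throughout: 5 chromosomes × 20 Mb, 1,500 markers, 300 animals, 7 traits
with heritabilities 0.36, 0.42, 0.35, 0.42, 0.11, 0.10, 0.08 (growth,
production and reproduction-trait magnitudes), $\pi_{true} = 0.99$,
reliabilities uniform on (0.1, 0.99], 150 genes, 8 TFs with planted
promoter sites.

* **LD** is block-wise: markers within an `ld_block_bp` window (default
  500 kb) share a per-gamete latent indicator that raises or lowers the
  allele frequency symmetrically, so marginal frequencies stay in
  `maf_range` while adjacent markers correlate. This gives *tunable*
  LD, not a coalescent: no LD decay with distance within a block, no
  inter-block LD, no mutation/recombination history.
* **Traits** draw `round((1 - pi_true) * n_markers)` QTL with normal
  effects, scaled so the true breeding values have variance exactly
  $h^2$ of a unit phenotype. DEBVs are TBV plus noise of variance
  $\mathrm{var(TBV)}(1-r^2)/r^2$, bypassing explicit pedigree
  deregression — the weight formula is still exercised on these
  records, but pedigree structure, selection, and multi-trait genetic
  correlations are *not* simulated. Passing tests therefore demonstrate
  the machinery, not robustness to correlated-trait architectures.
* **Promoters** are i.i.d. uniform ACGT with exact consensus sites
  planted; real promoters have composition bias and degenerate sites,
  so real-data sensitivity at $p \le 0.001$ will be lower than the
  near-perfect recovery seen here.

Every generator stage derives its randomness from `seed` plus a fixed
stage offset, so a config reproduces its bundle bit-for-bit and
downstream stages do not perturb each other's streams.

## Degenerate inputs and numerical conventions

* `reliability = 0` is an error everywhere (the weight and deregression
  formulas divide by it); `reliability = min_r2` is kept by the filter.
* `pi = 1` is rejected at configuration; `pi = 0` turns the sampler
  into its ridge limit.
* A saved MCMC sample with zero total genomic variance is skipped (with
  a warning) in window shares.
* PWM p-value thresholds are discretised to the same $10^{-3}$ grid as
  the scores, so scan hits and reported p-values are mutually
  consistent; `p_max = 0` yields no hits because every achievable score
  has positive tail probability.
* All file formats are plain text; infinite BFs round-trip as `"inf"`.

## Known limitations

* Variance components and EBV/reliability estimation (REML/BLUP) are
  out of scope: DEBVs and reliabilities are inputs, simulated or
  user-supplied.
* Traits are analysed by independent chains; no multi-trait sampler.
* The network stage offers a degree/density summary, not clique-density
  clustering, and no layout/visualisation export beyond SIF-style
  edges.
* Promoter scanning is forward-strand; motif databases and annotation
  retrieval are the user's responsibility (files in MEME minimal,
  FASTA, BED).

## A worked run

```{r demo, eval = FALSE}
bundle <- simulate_all(sim_config(seed = 1))
run <- run_pipeline(bundle,
                    pipeline_config(n_iter = 3000, burn_in = 1000, seed = 1),
                    outdir = "demo_out")
print(run)
run$trio   # NULL when fewer than 3 network genes are TFs (common at
           # demo scale; the TF module can also be run directly, see
           # assign_targets())
```
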