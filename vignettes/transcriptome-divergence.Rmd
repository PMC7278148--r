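---
title: "Methods: population-level transcriptome divergence in rice"
author: "oryzadiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-level transcriptome divergence in rice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`oryzadiv` implements a population-level analysis of transcriptome
divergence between the two subspecies of cultivated rice (*Oryza sativa*
ssp. *indica* and ssp. *japonica*), for panels of inbred accessions with
replicated RNA-seq and genome-wide SNP genotypes.  The stages are:

1. expression filtering, size-factor normalization, and rank-based inverse
   normal transformation;
2. genotype PCA and a two-cluster subspecies classification;
3. per-gene mixed-model tests of differential expression (DE) and of
   presence–absence expression variation (PAV) between subspecies;
4. expression diversity (CV) and nucleotide diversity (site-wise and
   windowed pi) within each subspecies;
5. broad- and narrow-sense heritability of expression, across and within
   subspecies, with a permutation test for heritability differences;
6. joint cis-eQTL mapping across subspecies by Bayesian model averaging
   over activity configurations; and
7. a diversity-based selection scan around the classified eQTL.

A seeded synthetic-data generator reproduces the statistical structure the
analysis assumes, so every stage is exercised end-to-end without any
external download.

# The models

## Replicate-level mixed models (DE, broad-sense heritability)

For gene $g$, accession $i$, replicate $j$, transformed expression is
modeled as
$$ y_{ij} = \mu + \beta S_i + u_i + e_{ij}, \qquad
   u_i \sim N(0, \sigma^2_a),\; e_{ij} \sim N(0, \sigma^2_e), $$
where $S_i$ is the subspecies covariate (coded $\pm 1/2$, Japonica
positive).  The DE test compares the maximum-likelihood fit against the
reduced model without $\beta$ by a likelihood-ratio test on 1 df; ML (not
REML) is used because REML likelihoods are not comparable across
fixed-effect structures.  Broad-sense heritability is
$H^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)$ from the REML fit of the
intercept-only model, with a *restricted* LRT against $\sigma^2_a = 0$
referred to a simulated null (see *Numerical choices*).

Because the one-way likelihood depends on the data only through
per-accession means, within-accession sums of squares and group sizes, all
per-gene fits reduce to closed forms (balanced designs) or 1-D profile
optimizations (unbalanced), which is what makes transcriptome-wide scans
and permutation nulls affordable.  `lme4` reproduces these fits and serves
as the independent cross-check in the test suite, not as the engine.

## Presence–absence expression variation

Expression is binarized (expressed $\iff$ read count $> 10$) and genes
with expressed-sample fraction in $[0.2, 0.8]$ are candidates.  The test is
a random-intercept logistic regression with subspecies as the fixed effect;
the accession intercept is integrated out by adaptive Gauss–Hermite
quadrature (9 nodes by default, mode and curvature found by Newton per
accession).  Both full and reduced fits carry a weak ridge penalty on the
fixed effects (Gaussian, variance 25, i.e. prior sd 5 on the log-odds
scale) so that completely separated genes — genes never expressed in one
subspecies are expected and are exactly the interesting ones — have finite
estimates; applying the identical penalty in both fits keeps the 1-df LRT
valid.  The symmetric $\pm 1/2$ coding makes the penalized fit invariant to
which subspecies is the reference.

## Heritability, GRM, and the difference test

The genomic relationship matrix follows VanRaden:
$G = Z_{cs} Z_{cs}'/m$ with marker columns centered and scaled to unit
population variance (denominator $n$), which forces
$\mathrm{mean}(\mathrm{diag}(G)) = 1$.  Narrow-sense heritability per gene
is from the restricted likelihood of
$y \sim N(\mu 1, \sigma^2_g G + \sigma^2_e I)$, profiled over
$\lambda = \sigma^2_g/\sigma^2_e$ after one spectral decomposition of $G$;
each gene then costs a single 1-D Brent optimization on the rotated data
($h^2 = \lambda/(1+\lambda)$).  A dense GLS evaluation of the same
likelihood is the oracle in the tests.

Within-subspecies heritability subsamples the larger subspecies to the
smaller's size (seeded), re-applies the expression filter within each
subspecies, and refits.  The difference test for $\Delta H^2 = H^2_J -
H^2_I$ (and the $h^2$ analog) draws $B = 100$ random partitions of all
accessions, ignoring subspecies labels, into two disjoint groups of the
common size; the same partitions are evaluated for every gene, matching the
resampling scheme of the study design this package follows, and the
two-sided empirical p uses the add-one convention ($p \ge 1/(B+1) \approx
0.0099$, consistent with calling significance at $p < 0.01$).

## Joint cis-eQTL mapping

Expression enters as inverse-normal-transformed accession BLUPs; the first
four genotype PCs are covariates.  For each gene, candidate SNPs lie within
100 kb of the TSS (closed interval, unsigned distance) at pooled MAF
$\ge 0.1$.  Within each subspecies, OLS gives an effect $\hat\beta$ and
sampling variance $V$; the Wakefield approximate Bayes factor
$$ \mathrm{BF}(W) = \sqrt{\tfrac{V}{V+W}}
   \exp\!\Big(\tfrac{z^2 W}{2(V+W)}\Big) $$
is averaged (unweighted) over the prior-variance grid
$W \in \{0.01, 0.04, 0.16, 0.64\}$ — a geometric grid spanning small to
large standardized effects on the INT scale.

Three activity configurations are scored per SNP: Indica-specific
(BF$_I$), Japonica-specific (BF$_J$), and shared.  The shared
configuration uses the *exchangeable-effect* (fixed-effect meta-analytic)
Bayes factor on the inverse-variance-combined estimate, averaged over the
same grid.  This choice is deliberate and load-bearing: with an
independent-effects product BF$_I \cdot$BF$_J$, the shared configuration
likelihood-dominates the specific ones (the BF in the inactive subspecies
hovers near 1 under its null), the EM weight collapses onto "shared", and
every specific eQTL is misclassified.  Under exchangeability, a flat signal
in one subspecies dilutes the combined estimate, so "shared" and
"specific" are genuinely distinguishable.  A configuration that includes a
subspecies in which the SNP does not segregate is excluded for that SNP
(an eQTL cannot be active at an invariant locus); if the SNP is invariant
in both groups every configuration keeps BF $= 1$.

The hierarchical model treats each gene as: no eQTL with probability
$\pi_0$, else one cis SNP (uniform prior) active in configuration $c$ with
weight $w_c$,
$$ L_g = \pi_0 + (1-\pi_0)\, S_g^{-1} \sum_s \sum_c w_c\, \mathrm{BF}_{gsc}. $$
The EM over the latent (null / SNP / configuration) indicator estimates
$(\pi_0, w)$ with a provably non-decreasing log-likelihood.  The EM's
$\pi_0$, however, is only weakly identified once signal genes exist
(SNP-averaged null BFs concentrate at their expectation 1), so the
*reported* gene-level posteriors use a Storey-type $\pi_0$ estimated from
the gene-level permutation p-values at $\lambda = 0.5$ — the same
permutation-based route the original BMA software takes.  Gene-level
significance itself comes from permutations: residualized expression is
shuffled across accessions *within each subspecies independently*, the
averaged alternative likelihood is recomputed with fixed weights, p =
(1 + #{perm $\ge$ obs})/(B+1), and BH across genes.  A gene is called at
$q \le 0.05$ when its top configuration posterior exceeds 0.5.  Each
gene's permutation stream derives from (seed, gene index), so results are
reproducible regardless of evaluation order.

## Selection scan

For each classified eQTL, per-subspecies site-pi
($\pi = n_{\mathrm{ref}} n_{\mathrm{alt}}/\binom{n}{2}$, missing alleles
excluded site-wise) is averaged over SNPs within 100 kb of the top SNP.
The genome-wide background tiles the genome into 100 kb windows after
excluding SNPs within 100 kb of any called eQTL and sites of low diversity
in both groups (within-group MAF $< 0.1$ in $\ge 2$ of the 2 groups; the
rule is parameterized so a 12-subpopulation panel can use MAF $< 0.01$ in
$\ge 10$ of 12).  Per (eQTL class, subspecies), a Welch two-sided t-test
compares eQTL-window means against background means — Welch rather than
pooled-variance since the two sets have very different sizes and spreads —
and each eQTL window is flagged low-diversity when its mean pi falls at or
below the group's empirical 5% background quantile.  The eQTL window is
$\pm 100$ kb around the SNP while background tiles are 100 kb wide; both
radii are arguments.

# The synthetic generator

`sim_config()` defaults define the emulated study conditions: 35 + 56
accessions (Indica-like "I", Japonica-like "J"), 2 replicates each, 1,000
genes, 20,000 SNPs on 12 chromosomes of 30 Mb.  Genotypes follow a
two-population Balding–Nichols model: ancestral frequency $p \sim
U(0.05, 0.95)$, population frequency $\sim \mathrm{Beta}(p(1-F_k)/F_k,
(1-p)(1-F_k)/F_k)$, inbred haploid dosages $\sim \mathrm{Bernoulli}$.
Asymmetric drift ($F_I = 0.30$, $F_J = 0.55$) yields a Hudson Fst near 0.4
— the two subspecies are strongly divergent — and a Japonica/Indica
within-group diversity ratio near 0.65, the qualitative asymmetry seen in
rice panels.

Gene architectures mix seven classes (null, DE, PAV, polygenic-heritable,
and cis-eQTL active in I, J, or both).  The accession-level log-mean is
$b_0 + g_i + \delta S_i + \epsilon_i$ with baseline $b_0 \sim U(\log 20,
\log 2000)$ and total accession-level variance 0.25 (natural-log scale, sd
0.5 — strong but realistic biological variation between accessions).  For
heritable/eQTL classes the genetic part is rescaled — and the non-genetic
accession effect orthogonalized and rescaled — so the realized genetic
variance fraction equals `target_h2` essentially exactly.  cis SNPs are
required to segregate (MAF $\ge 0.1$) in every subspecies where the effect
is active, so truth labels always describe a realizable architecture.
Counts are negative binomial with mean $s_j \exp(\eta_{gi})$ and
dispersion $\phi = 10$ (Var $= \mu + \mu^2/\phi$; $\phi$ is a free
parameter since replicate-level noise magnitude is not dictated by the
design; $\phi = \infty$ gives Poisson).  PAV genes first draw an
accession-level on/off state from a logistic model; "off" accessions emit
Poisson(0.1) background counts.  `inject_sweep()` emulates selection by
forcing near-fixation (minor-allele count $\le 1$) in a target
subpopulation inside given regions.

What the generator does *not* emulate — and what passing tests therefore
do not certify on real data: linkage disequilibrium (SNPs are drawn
independently, so cis windows have no LD structure and fine-mapping
behavior is optimistic), admixed accessions, batch or library-preparation
artifacts beyond a scalar size factor, gene–gene correlation, and
count overdispersion that varies across genes.

# Numerical choices

* **Normalization**: median-of-ratios size factors (reference = per-gene
  geometric mean over zero-free genes; total-count fallback when no such
  gene exists) followed by $\log_2(x/s_j + 1)$.  This is a monotone,
  practically variance-stabilizing stand-in for spline-based VSTs; the
  analysis stages consume ranks (INT) downstream, so only monotonicity and
  scale stability matter.
* **INT ties**: broken randomly under a dedicated seed per gene, derived
  from the stage seed, independent of all other streams.
* **Boundary truncation**: all variance components are truncated at 0, so
  heritabilities always lie in $[0, 1]$.
* **Null distributions**: the broad-sense restricted LRT uses a simulated
  null per design (balanced designs reduce to closed-form functions of two
  chi-square draws; roughly half the null mass sits at 0).  The
  narrow-sense LRT also defaults to a simulated null per GRM: the common
  $0.5\chi^2_0 + 0.5\chi^2_1$ mixture is available but measurably
  conservative at $n \approx 70$, where more than half the null mass is on
  the boundary.
* **Degenerate fits**: residual sums of squares are floored at `1e-300`
  before logs, so perfectly separated or noiseless genes yield huge finite
  LRTs rather than NaNs; SNPs without variation within a subspecies carry
  BF = 1 (no information) and are flagged.
* **Profile bounds**: variance-ratio profiles run over $\log\rho \in
  [-30, 15]$ (one-way) and $\log\lambda \in [-10, 10]$ (GRM), with the
  boundary $\rho = 0$ / $\lambda = 0$ always compared explicitly.
* **Seeds**: every stochastic step takes a seed derived as a fixed affine
  function of the base seed and a stage index, and restores the caller's
  RNG state, which is what makes the full pipeline bit-reproducible.

# Design decisions taken where the design was open

* Subspecies classification is PCA + 2-means on PC1 with labeled anchors;
  model-based admixture inference is out of scope and PC1 separates the
  subspecies cleanly at the divergence levels involved.
* "Expressed" is count $\ge 10$ for the expression filter but count $> 10$
  for PAV coding; both thresholds are arguments.  The PAV candidate-band
  denominator is all samples.
* The eQTL scan consumes INT-transformed BLUPs (a flag-level change would
  swap in accession means); the heritability stage runs the same input for
  the narrow-sense fits.
* The permutation partitions for $\Delta H^2/\Delta h^2$ are drawn from
  the union of all accessions (not within subspecies), once per call,
  shared across genes.
* The eQTL permutation count defaults to $B = 1000$ per gene
  (configurable; the reference analysis used 10,000) — with BH across
  genes the p-value floor $1/(B+1)$ is far below any q-threshold in use.

# Problem sizes

The test suite and the acceptance script run, by design, at these scales:
null calibrations on 200–800 genes with 35 accessions per subspecies and 2
replicates; narrow-sense recovery on $n = 200$, $m = 2000$ panels at
moderate structure ($F = 0.15$ — at $F \approx 0.4$ a single
population-contrast eigenvector dominates per-gene genetic variance and
the mean estimate measures draw volatility rather than estimator bias);
configuration recovery on 200 genes (50 null / 50 I / 50 J / 50 shared,
cis effect 40% of accession variance, $n = 35 + 56$); and the full
pipeline on the default 91-accession, 1,000-gene, 20,000-SNP panel.

# Known limitations

* GRM-based narrow-sense heritability has little power against
  single-locus architectures: one cis SNP contributes weight $1/m$ to $G$,
  so a mono-locus gene shows high broad-sense but near-null narrow-sense
  heritability within a single subpopulation.  This is a property of
  GRM REML, not a defect of the implementation.
* The Storey $\pi_0$ inherits upward bias from weak-signal genes whose
  permutation p exceeds 0.5.
* Configuration classification for SNPs invariant in one subspecies rests
  on the exclusion rule described above; with LD (absent in the
  generator) a tag SNP invariant in one group can shadow a causal variant
  that does segregate there.
* The Welch t-test across windows ignores spatial autocorrelation of
  diversity; on real genomes neighboring windows are correlated and the
  test is anti-conservative to a degree the synthetic genome (independent
  SNPs) does not show.
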