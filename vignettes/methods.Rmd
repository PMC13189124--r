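---
title: "Methods: cis-MR of plasma pQTLs with correlated instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-MR of plasma pQTLs with correlated instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqtlmr)
```

## Scope and model

`pqtlmr` estimates putative causal effects of circulating proteins on
diseases and biomarkers from GWAS summary statistics, using cis-acting
variants near the protein-coding gene as instruments. Because cis variants
at one locus are correlated through linkage disequilibrium (LD), both
estimators — inverse-variance weighted (IVW) and MR-Egger — are solved by
generalized least squares with residual covariance
$\Sigma = D_{\sigma_Y}\,\rho\,D_{\sigma_Y}$, where $\rho$ is the LD
correlation estimated from a reference dosage panel and $D_{\sigma_Y}$ holds
the outcome standard errors. The IVW design is the exposure-effect vector
alone; MR-Egger adds an intercept that absorbs constant directional
pleiotropy. With a single instrument the GLS solution reduces exactly to the
Wald ratio $\beta_Y/\beta_X$ with standard error $\sigma_Y/|\beta_X|$, and
with $\rho = I$ it reduces to the classical inverse-variance weighting; both
identities are enforced in the test suite against independent closed-form
oracles.

Key assumptions: instruments are associated with the protein (enforced by
the F filter), effects are linear on the analysis scale (SD units for
quantitative traits, log-odds for diseases), and any pleiotropy is either
constant across variants (absorbed by the Egger intercept) or removed by the
diagnostic filters. Sample overlap between exposure and outcome cohorts is
assumed absent; the simulator enforces a strict two-sample design so this
assumption holds by construction in all calibration studies.

## Pipeline order and parameters

Stages run in a fixed order: cis selection → harmonization → reference LD →
clumping → Steiger filter → initial fits → leverage/outlier iteration →
Rücker selection. The defaults, all exposed in `mr_config()`:

| parameter | default | meaning |
|---|---|---|
| `window_bp` | 200000 | closed flanks around the gene body |
| `maf_min` | 0.01 | minimum minor allele frequency |
| `f_min` | 15 | minimum single-variant F, computed as $(\beta/\mathrm{se})^2$ |
| `palindrome_maf` | 0.42 | MAF at or above which A/T and G/C variants are ambiguous |
| `r2_max` | 0.40 | clumping ceiling on pairwise $r^2$ |
| `min_variants` | 5 | below this, no estimate is reported |
| `leverage_mult` | 3 | leverage cut at 3× the mean leverage |
| `outlier_chisq` | 11 | cut on the squared decorrelated residual |
| `rucker_alpha` | 0.05 | χ²₁ level for the Q difference |

Design choices the literature leaves open, and how they were resolved:

- **Window anchoring.** The cis window flanks the gene body (start and end),
  not the transcription start site, with closed interval arithmetic; a
  variant exactly at `start − window_bp` is retained.
- **Palindrome band.** "Near 0.5" is operationalized as MAF ≥ 0.42,
  configurable; palindromic variants below the band are kept because their
  allele frequencies resolve the strand.
- **Dispersion model.** Standard errors use the multiplicative
  random-effects factor $\phi = \max(1, Q/(p-k))$. This floors dispersion at
  the fixed-effect level and is mildly conservative: integrating the
  rejection rule over the $\chi^2$ distribution of $Q$ gives a true type-I
  error of ≈ 0.038–0.041 (not 0.05) at 5–25 instruments, which the
  calibration suite reproduces. Normal (not t) reference distributions are
  used throughout, as is standard for summary-statistic asymptotics.
- **Filter order and one-at-a-time removal.** Steiger runs before model
  fitting; leverage/outlier exclusion then removes the single worst violator
  (largest relative exceedance of its cut), refits, and repeats, which
  avoids masking. Diagnostics come from the currently Rücker-selected model.
  When removal would push the instrument count below five, the violation is
  logged and nothing is removed.
- **Egger orientation.** Variants are flipped to non-negative exposure
  effects jointly in $x$, $y$ and the rows/columns of $\rho$ before the
  intercept model; the slope-only model is orientation-invariant and fitted
  as supplied. When oriented instrument strengths are all equal the
  intercept is unidentifiable and the implementation falls back to IVW.
- **Regularization.** $\Sigma$ receives a $10^{-8}$ diagonal jitter before
  factorization; singularity beyond that raises an error rather than a
  silent fallback.
- **Multiplicity.** The Bonferroni threshold is computed from the
  protein × trait grid (for 151 × 64 this is $0.05/9664 = 5.17\times10^{-6}$);
  a config override accepts an externally fixed constant instead.

## Colocalization

Each protein-trait region uses variants in a closed 500-kbp flank of the
gene body with **no MAF or p-value filtering** — any variant in the region
could be causal, and pre-filtering biases the posterior. Per-variant
evidence is the Wakefield log approximate Bayes factor
$\mathrm{lABF} = \tfrac12[\log(1-r) + r z^2]$ with $r = W/(W+V)$,
$W$ the squared effect-size prior SD (0.15 for quantitative traits, 0.2 on
the log-odds scale for binary ones) and $V$ the squared standard error
(SE-based, rather than allele-frequency-based, variance approximations are
used throughout). Priors are the conventional $p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$. All five hypothesis weights are accumulated in log space
(log-sum-exp), so the posterior vector sums to one within $10^{-9}$ even
with extreme Bayes factors. A single causal variant per trait is assumed; no
conditioning or masking is attempted. A region is called colocalized when
PP.H4 ≥ 0.8, inclusive.

## The simulator: what it emulates, and what it does not

The generator is the package's study design, not a tuning knob. A locus is
`n_variants` biallelic variants whose two haplotypes per individual come
from a latent Gaussian AR(1) process with correlation `ld_decay^|i−j|`,
thresholded at the MAF quantile — LD is controllable, dosages are valid
0/1/2, and the implied haplotype correlation is validated against an
independent Monte-Carlo oracle. Phenotypes follow

$$X = G\beta + \kappa\,G b_{rev} + e_x,\qquad
  Y = \alpha\,(G\beta + e_x) + G b_{rev} + G b_{pleio} + e_y,$$

so reverse-causal variants load on the outcome fully and on the exposure
only through the attenuated feedback $\kappa$ (default 0.5) — the exact
pattern Steiger filtering targets. Exposure, outcome and reference cohorts
are disjoint draws from one population (two-sample MR with an external LD
panel). Binary outcomes use a liability threshold with per-variant logistic
fits reported as log-odds. All randomness flows from one master seed through
labelled hash-derived substreams, so each stage is independently
reproducible and fixed seeds give byte-identical artifacts.

Default architecture: three causal cis variants spread across the locus
(effects 0.3–0.4 SD per allele), MAFs uniform on [0.05, 0.5], AR(1) 0.5,
reference panel of 5000 — mirroring a setting where a handful of partially
correlated signals drive a protein and reference LD comes from a biobank
subsample. The pipeline demonstration uses four causal variants over 24 so
that a typical locus retains at least five clumped instruments. The
calibration studies use exposure/outcome cohorts of 3000 (10000 for the
exposure in the Egger study, where near-exact instrument effects are needed
for the intercept to be estimated without dilution) and 500/200/100
replicates depending on the statistic; these sizes were chosen once as
realistic and are stated in `analysis/03`–`06`.

What the simulator does **not** emulate: real human LD maps (block
structure, recombination hotspots), population stratification, relatedness,
imputation error, assay differences between pQTL platforms, sample overlap,
or multi-allelic variation. Passing calibration here shows the estimators
and filters behave as designed under their own assumptions — it does not
certify behaviour under the violations listed above.

## Knowledge graph and annotation layers

Proteins, traits and tissues are typed nodes; edges are multiplicity-
significant MR associations (strictly below the threshold), trial records
(drug target → indicated trait, including trials of a protein's interactors),
protein overexpression (expression above the protein's cross-tissue mean by
more than 1.645 SD, one-sided 0.05 — a documented stand-in for an external
tissue-specificity test), and tissue-trait links whose literature
co-occurrence score exceeds 8 (strict). The co-occurrence score is
operationalized as $-\log_{10}$ of the one-sided hypergeometric tail of the
observed co-mention count, floored at zero when the observed count does not
exceed expectation; precomputed scores can be supplied instead. Louvain
community detection (resolution 1, unweighted, on the simplified graph over
all node types together) is delegated to `igraph::cluster_louvain` under a
fixed seed; modularity is recomputed from first principles when reporting,
and the test suite checks Louvain output against brute-force enumeration of
all partitions on small fixtures. Pathway enrichment compares the in- versus
out-of-community membership proportions with a two-proportion Wald
statistic; when both proportions are degenerate, 0.5 is added to all four
cells. A pathway is eligible at p < 0.05 with at least two community
proteins, ranked by proportion difference; the top pathway is reported
unless flagged broad (configurable denylist or more than 300 members), in
which case the runner-up is taken.

## Prioritization conventions

Diseases always classify a risk-increasing protein effect as harmful;
biomarkers compose the effect sign with a per-trait beneficial-direction
label. The 75% concordance rule is inclusive (3 of 4 qualifies) and applies
only to proteins with at least four significant associations — below four a
75% cutoff cannot be meaningfully assessed, so such proteins are labelled
`insufficient`. Replication requires sign concordance plus p < 0.05
(nominal) or p < 0.05/`n_proteins_available` (conservative). Positive
controls restrict to phase ≥ 3 trials of the protein or an interactor for
the same trait; risk-increasing effects are concordant with inhibitors,
protective effects with agonists, and a pair trialed under both mechanisms
takes the majority label (ties resolved as inhibitor). Printed percentages
are nearest-integer; quartiles use linear interpolation between order
statistics (type 7).

## Numerical notes and limitations

- GLS solves go through a Cholesky whitening of $\Sigma$; the test oracles
  use explicit matrix inverses, so agreement to $10^{-10}$ exercises two
  distinct numerical paths.
- Clumping ties on p-value break by position then variant id, making the
  retained set invariant to input row order.
- Degenerate inputs are first-class: monomorphic variants raise
  `zero_variance`, irreconcilable alleles are audited as `allele_mismatch`,
  starved loci report `insufficient_variants` rather than erroring, and
  every dropped variant appears exactly once in the audit trail with a
  machine-readable reason.
- The estimator inherits the known mild conservatism of floor-type
  dispersion corrections (true type-I ≈ 0.04 at nominal 0.05); confidence
  coverage of a planted effect of 0.3 sits between 0.90 and 0.99 across the
  calibration replicates.
- Weak-instrument dilution biases the Egger intercept when instrument
  effects carry large estimation error; the Egger calibration therefore uses
  a strong-instrument regime, and results on weak instruments should be
  interpreted with that caveat.
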