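---
title: "Gene-based tests of methylation-moderated SNP effects: models and design"
author: "methgene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based tests of methylation-moderated SNP effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methgene)
```

## The problem

Methylation at a CpG site can modulate how strongly a nearby SNP affects a
quantitative trait. Testing each SNP-CpG pair on its own wastes power and
multiplies the testing burden, so this package aggregates per-pair evidence
into one statistic per gene (or per arbitrary variant set) and assesses its
significance by permutation. The trait of interest is the change in
log-transformed triglyceride level between a baseline and a follow-up
visit, measured in a cohort of related individuals (nuclear families), but
nothing in the machinery is specific to lipids.

## The two-stage model

**Stage 1.** The change score for individual $i$ is
$y_i = \overline{\ln TG}^{fu}_i - \overline{\ln TG}^{base}_i$, where each
visit's (up to two) measurements are log-transformed *before* averaging.
It is residualized on the covariates (age, center, smoking status, MSDX
score, fasting time, baseline ln-HDL, baseline ln-TG) and on the family
structure via the additive polygenic model

$$ y = X\beta + g + e, \qquad g \sim N(0,\, 2\Phi\sigma^2_g), \quad
   e \sim N(0,\, \sigma^2_e I), $$

where $\Phi$ is the expected kinship matrix from the pedigree. The REML
fit is exact: one eigendecomposition $2\Phi = UDU'$ rotates the model so
the covariance is diagonal in $\lambda = \sigma^2_g/\sigma^2_e$, and a 1-D
profile optimization over $\log\lambda$ (with the boundary $\lambda = 0$
checked explicitly) finds the REML solution; the suite verifies it against
a dense 200-point grid-search oracle. Residuals follow the
$r_i = \hat y_i - y_i$ convention, and $\hat y$ includes the BLUP of $g$
("conditional" residuals) by default; all downstream F-tests are invariant
to the residual sign, and a marginal option ($\hat y = X\hat\beta$) is kept
alongside.

A point worth knowing: conditional residuals do **not** have zero familial
correlation. Their covariance is $\sigma_e^2\,V^{-1}$
(with $V = 2\Phi\sigma^2_g + \sigma^2_e I$), whose within-family entries
are mildly negative — with sib-pair families and $\sigma^2_g = 0.3$ the sib
correlation is about $-0.14$, while marginal residuals retain
$+2\phi\sigma^2_g \approx +0.15$. Neither choice makes residuals exactly
exchangeable; the permutation test's null calibration is therefore checked
directly (below) rather than assumed.

**Stage 2.** For each SNP $j$ paired with CpG $j$,

$$ r = \beta_{S_j} SNP_j + \beta_{C_j} CPG_j + \beta_{SC_j}\, SNP_j\,CPG_j
   \;(+\; \mu), $$

with $SNP_j \in \{0,1,2\}$ minor-allele counts and $CPG_j \in [0,1]$, and
$p_j$ is the overall-model F-test p-value (jointly
$\beta_S = \beta_C = \beta_{SC} = 0$) on $(3, n-4)$ df. The equation is
sometimes written without an intercept; we include one by default because
permuted residuals are not constrained to mean zero within the fitting
subset, and the F-test then targets the three slope terms — the literal
no-intercept form is available via `include_intercept = FALSE`. Aliased
designs are handled as `lm()` handles them: dropped columns, F on the
remaining slopes, so a constant CpG column cleanly reduces the model to a
single-SNP regression. P-values are clamped to $[10^{-300}, 1]$ so their
logarithms stay finite.

## Gene statistics

Six combiners map a gene's $p_1,\dots,p_m$ to a statistic $G$, all
oriented so smaller $G$ means stronger evidence (the orientation is a
package convention; it fixes which permutation tail is counted):

| method | $G$ | character |
|---|---|---|
| `sum_ln_p` | $\sum_j \ln p_j$ | Fisher-type averaging / burden-like |
| `sum_neg_sq_ln_p` | $\sum_j -(\ln p_j)^2$ | variance-components-like |
| `min_p` | $\min_j p_j$ | robust to many null pairs |
| `pt_T`, $T \in \{0.01, 0.05, 0.10\}$ | $\sum_{j: p_j \le T} -(\ln(p_j/T))^2$ | truncated: null pairs contribute 0 |

The threshold statistics are continuous at $p_j = T$ (both branches give
0) and reduce exactly to `sum_neg_sq_ln_p` at $T = 1$. The comparator is a
single-marker rule declaring a gene significant iff $\min_j p_j <
\alpha/m$.

## Permutation significance

Stage-1 residuals are shuffled $B = 1000$ times; *the same shuffles are
reused for every pair and every gene*, preserving the correlation
structure among pairs. For each shuffle all pair p-values and all gene
statistics are recomputed, and the empirical p-value is the add-one rank
$(1 + \#\{b: G^{(b)} \le G_{obs}\})/(B+1)$, ties counted as extreme. The
add-one estimator is a deliberate deviation from a raw proportion: a raw
proportion can be zero, which is not a valid p-value; the cost is a floor
of $1/(B+1)$. Because only the response changes across shuffles, each
pair's design is QR-factorized once and the whole sweep is one
$(\text{rank} \times n)(n \times B)$ matrix product per pair; the suite
checks this batched path against naive refitting to ten significant
digits.

## The synthetic cohort generator

The generator emulates the structure of the family study the method was
designed around: about 670 related individuals in nuclear families
(sibships of 2-4), seven covariates, a ln-TG change phenotype with up to
two measurements per visit, and causal SNP-CpG pairs with per-pair
heritabilities $\{0.125, 0.10, 0.075, 0.05, 0.025\}$ (and $0.001$ for
"minor" genes) at minor allele frequencies $\{0.11, 0.19, 0.10, 0.41,
0.14\}$. Choices the source material leaves open were fixed once:

* **Moderation form.** The causal term is $\beta_j\,SNP_j\,(1 - CPG_j)$ —
  methylation attenuates the SNP effect; a "direct" ($w = CPG$) option
  exists. $\beta_j$ is calibrated analytically from the first two moments
  of $SNP \sim Bin(2, maf)$ and $CPG$ so that the term's variance equals
  the target heritability in a phenotype whose covariate-adjusted variance
  is normalized to 1 ($h^2$ shares + polygenic $\sigma^2_g$ + residual
  $= 1$).
* **Methylation distribution** defaults to $Beta(2,2)$ (symmetric,
  moderately dispersed, strictly inside $[0,1]$); a point-mass option
  exercises the unmoderated limit.
* **Polygenic share** defaults to $\sigma^2_g = 0.2$ — a moderate familial
  resemblance for a change score; it is a config field, not an estimate.
* **Covariate effects on the change score** default to zero (the
  covariates are simulated and always adjusted for in stage 1, so they
  carry no signal by default); measurement noise on each duplicate visit
  measurement is ln-scale Gaussian with sd 0.05, and the second
  measurement is present with probability 0.8.
* **No linkage disequilibrium**: noise SNPs are independent, and
  transmission is independent across SNPs. This is the main respect in
  which passing tests do *not* speak to real data: with real LD, noise
  pairs are correlated with causal ones and with each other, which changes
  gene-level power (though not null calibration, which the shared shuffles
  preserve by construction).

Genotypes are gene-dropped through the pedigree (founder alleles at the
stated MAF, Mendelian transmission), and the kinship matrix comes from the
recursive tabular method, verified against a gene-dropping Monte Carlo
oracle.

## What the experiments show — and what they cannot

`run_experiment()` replays the whole pipeline over replicate cohorts
(family structure held fixed, genotypes/methylation/phenotypes
regenerated) and tabulates rejection proportions by gene category. Three
behaviors are reproducible study-level claims and are asserted by the
acceptance tests:

* **Null calibration**: pooled rejection of noncausal genes at
  $\alpha = 0.05$ stays at or below the nominal rate (within binomial
  error) for every method.
* **Positive control**: a 5-pair all-causal set (total $h^2 = 0.375$,
  $n = 670$) is detected essentially always by every method.
* **Power rises with heritability** for a single causal pair, other
  things equal.

One claim from the source study does *not* transfer to this generator:
in a large spiked set (many null pairs, few causal), `min_p` and the
threshold statistics should beat `sum_ln_p` by a wide margin. That
ordering lives in a regime where the causal pairs' p-values are moderate
(roughly $10^{-3}$-$10^{-5}$), so the log-p sum drowns in noise while the
minimum survives. Under this generator's calibration, a pair with
$h^2 = 0.125$ at $n = 670$ yields p-values near $10^{-20}$: every
combiner saturates at power 1.0 and no ordering is observable. The
original data's effective signal was evidently much weaker than its
nominal per-SNP heritabilities (its generative model — treatment response,
visit structure, LD — is not public). The noise-robustness *mechanism* is
still demonstrable in the interior-power regime (see the
power-vs-heritability test, and try small $h^2$ with a large noise pool);
the saturated ordering test is retained at the stated study conditions and
fails honestly there.

## Numerical and procedural details

* QC keeps a SNP iff HWE $p > 10^{-6}$, folded MAF $> 1\%$ and missing
  rate $< 5\%$ (strict inequalities); HWE is a 1-df chi-square without
  continuity correction by default, with a Levene-Haldane exact option.
* Nearest-CpG pairing is point-to-point distance on the same chromosome;
  exact ties go to the lower-coordinate CpG (determinism). An override
  table can force designated pairs (warning past 12.5 kb).
* Gene membership is 1-based inclusive `[start, stop]`; a designated
  major-effect SNP outside every gene is appended to the nearest gene
  within 50 kb, else a synthetic gene spanning $\pm$50 kb of the SNP is
  created. BED I/O converts to/from 0-based half-open coordinates.
* Replicate seeds derive deterministically from the master seed; the same
  seed gives bit-identical cohorts, permutation plans and reports.
* Problem sizes used by the shipped experiments: the type-I run uses 60
  replicates of 39 noncausal genes (5-30 pairs each, 660 pairs total) at
  $B = 1000$; the positive control 50 replicates; the spiked-set run 100
  replicates of a 96-pair set at $B = 500$. These are the package's
  desk-scale defaults for a single CPU.

## Limitations

No LD, no sex chromosomes, no dominance/epistasis beyond the single
interaction form, no treatment modeling, no strand-aware CpG handling,
and permutation only (no asymptotic null for the combiners). Empirical
p-values are floored at $1/(B+1)$, so genome-wide significance levels
would require far larger $B$ than the default 1000.
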