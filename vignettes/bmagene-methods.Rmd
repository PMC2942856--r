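---
title: "Multilocus association mapping by Bayesian model averaging: models, search and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilocus association mapping by Bayesian model averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case-control genome scans are usually analysed one SNP at a time, which
loses power exactly where the genetics is most interesting: when two loci
influence disease risk jointly but neither shows a marginal effect.
`bmagene` addresses dichotomous phenotypes with a Bayesian model-averaging
(BMA) scheme whose model space explicitly contains gene-gene interactions,
and whose per-model scores are available in closed form, so that model
search is cheap enough to consider interactions at realistic scales.

## The model family

Let $y_i \in \{0,1\}$ be the phenotype and $Z_{ij} \in \{0,1,2\}$ the
minor-allele count of individual $i$ at locus $j$. Five *elementary*
penetrance models assign each individual a disease-probability class from
one or two loci:

| model | classes | interpretation |
|---|---|---|
| M1(j) | 3 | full single-locus model (one probability per genotype) |
| M2(j) | 2 | dominant single-locus model ($Z_j = 0$ vs $Z_j > 0$) |
| M3(j,k) | 9 | full two-locus model |
| M4(j,k) | 4 | dominant two-locus model with main effects |
| M5(j,k) | 2 | dominant two-locus model *without* main effects (both carriers vs rest) |

A *combined* model is any set of elementary models with pairwise-disjoint
loci; its partition of individuals is the product (all intersections) of
the component partitions, so class counts multiply: three M3 components
span $9^3 = 729$ classes, three M5 components $2^3 = 8$. The disjointness
rule exists because overlapping components (say M1(j) with M5(j,k)) make
contradictory statements about the main effect at $j$.

Given a partition $S = \{s_1,\dots,s_d\}$, class probabilities
$p_c \sim \mathrm{beta}(\alpha,\alpha)$ integrate out analytically:

$$P(\mathrm{Data} \mid M) \;=\; \prod_{c=1}^{d}
  \frac{\Gamma(2\alpha)}{\Gamma(2\alpha + |s_c|)}
  \prod_{b=0}^{1} \frac{\Gamma(\alpha + n_{cb})}{\Gamma(\alpha)},$$

the product over classes of beta-binomial predictive probabilities
($n_{cb}$ = individuals in class $c$ with status $b$). The structure prior
is geometric in the number of SNPs, $P(M) \propto \xi^{L_M}$, so adding a
SNP always costs a factor $\xi$ and models with equally many SNPs are
a-priori exchangeable.

All scores are kept in natural-log space throughout: the likelihood
product underflows double precision around $N \approx 1700$, which is
below the package's default sample sizes. Posterior normalisations and
mixtures go through `logsumexp`.

### Canonical model identity

M3(j,k) induces exactly the partition of {M1(j), M1(k)}, and M4(j,k) that
of {M2(j), M2(k)}. Both spellings are therefore the *same* statistical
model, and the package expands M3/M4 into their single-locus equivalents
when it forms a model's canonical key. Without this, the visited-model
estimator below would count one model twice and bias the inclusion
posteriors. M3 and M4 remain in the proposal pool as one-move shortcuts to
plausible two-locus states. Whether the original formulation deduplicated
these spellings is not documented; canonicalisation is this package's
choice, made so that the estimator sums over *distinct* models.

Empty structural classes are retained in partitions: an empty class
contributes a factor of exactly 1 to the marginal likelihood, so this is
score-neutral and keeps the bookkeeping (mixed-radix class labels in
canonical component order) reproducible.

## Learning procedure

1. Score all $2L + 3\binom{L}{2}$ elementary models in closed form (one
   vectorised pass; all pairwise genotype contingency tables come from
   indicator-matrix crossproducts).
2. Keep the $K$ highest-posterior elementary models and union in all $2L$
   single-locus models (pool $\mathcal{M}_{e1}$). Ties break by canonical
   model order so the pool is deterministic.
3. Search the space of conflict-free combinations with a non-reversible
   Metropolis-Hastings sampler started at the empty model M0. Operators
   and probabilities: ADD 0.5, REMOVE 0.45, SWITCH 0.05. ADD inserts a
   uniformly drawn pool model after deleting all conflicting components;
   REMOVE deletes a uniform component (on M0 it proposes M0 itself, a
   self-loop, so operator probabilities stay unconditional); SWITCH is
   REMOVE then ADD. A proposal is accepted with probability
   $\min\{1, P(D\mid M^{*})P(M^{*}) / P(D\mid M)P(M)\}$ — deliberately
   *without* the proposal-ratio correction.
4. Let $\mathcal{M}^{*}$ be the distinct models visited. Because every
   model's unnormalised posterior is exact, posteriors are estimated by
   self-normalisation over $\mathcal{M}^{*}$; the per-SNP inclusion
   probability is the mass of models containing the SNP and the BMA score
   is its log posterior odds.

The sampler is not reversible, so $\mathcal{M}^{*}$ is a *search trace*,
not a stationary sample — the renormalisation step is what makes the
estimator consistent, and it only requires the search to reach the models
carrying non-negligible mass. For this reason the package records every
state whose score it computes, proposals included, in
$\mathcal{M}^{*}$: scoring a proposal constitutes a visit, and a larger
covered set can only improve the estimator. (The alternative reading —
accepted states only — is not documented anywhere we could check; the
recorded-proposals choice strictly dominates it.)

Loci that appear in no visited model are reported with inclusion
probability 0 and score $-\infty$ (serialised as `"-inf"`); ranking treats
them as strictly smallest, with ties broken by locus index.

Defaults follow the two operating scales: $K = 5000$, 200,000 iterations,
$\xi = 1/460$ for 460-SNP replicate scans; $K = 50{,}000$, 3.5M
iterations, $\xi = 1/1000$ for chromosome-length scans. $\alpha = 3$
throughout: with equal numbers of cases and controls, class probabilities
near 0.5 are a-priori plausible, and values of $\alpha$ above 1 encode
odds ratios of realistic magnitude. The sensitivity sweep
(`sensitivity_sweep`) reruns a scan over $\alpha \in \{1,3,10\}$ and
$\xi \in \{1/46, 1/460, 1/4600\}$: $\alpha$ barely moves the scores while
$\xi$ changes their spread, which is why $\xi$ should scale like $1/L$.

Convergence is monitored the pragmatic way: `run_search` returns the full
log-posterior trace, and the CLI writes it at a 1,000-iteration cadence
for trace-plot inspection. No automatic convergence test is imposed.

## Comparator scores

* **Marginal LRT**: the three-parameter logistic model (one intercept per
  genotype class) against the intercept-only null, $\chi^2_2$ reference,
  score $-\log_{10} p$.
* **Pairwise GxG LRT**: the four-parameter dominant-coded interaction
  model per pair, $\chi^2_3$ reference, maximised over partners.
* **Pairwise GxG Bayes factor**: per pair, the equally weighted mixture of
  the M3/M4/M5 marginal likelihoods against the null, maximised over
  partners. Averaging is the default; a max-over-kinds variant is behind a
  flag (the two agree in practice).

Both LRT models are *saturated* on their class partitions, so the
maximised likelihoods have closed forms (fitted class probability = class
case fraction) and no IRLS is needed; the test suite verifies agreement
with `glm` fits to 8+ digits. Two deliberate reproductions of standard
practice: degrees of freedom stay at the nominal 2 and 3 even when empty
cells reduce the effective dimension, and zero cells follow the
$0 \log 0 = 0$ convention, which is the limit an iterative fitter
approaches under separation.

## Simulation design

The package's simulation engine emulates a cohort-based protocol in which
hidden causal SNPs must be detected through linkage disequilibrium (LD)
with observed flanking markers.

**Pool.** Real cohort genotypes are not redistributable, so
`synthesize_pool` builds a synthetic stand-in: haplotypes follow a
first-order Markov allele-copying process with block structure (geometric
block lengths, mean 15 SNPs; adjacent-pair allele correlation drawn
uniformly from [0.2, 0.95] within blocks, clipped to the range feasible
for the two MAFs, and 0 across block boundaries), and genotypes are sums
of two independent haplotypes. Per-SNP MAFs mix a broad uniform(0.02, 0.5)
component with narrow windows around 0.05, 0.1 and 0.2 (so causal
candidates at the canonical targets always exist), drift slowly on the log
scale within blocks (sd 0.25) and are redrawn afresh with probability 0.15
per SNP (so a low-MAF causal SNP can still have common flankers). These
choices were fixed once, as a plausible dense-array LD profile; the LD
strength is a config knob precisely so users can stress weaker or stronger
linkage than any one real panel. What the synthetic pool does *not*
reproduce: long-range LD, recombination hotspot geometry, population
structure, genotyping error. Power results on it therefore validate the
*method machinery*, not power on any particular real cohort.

**Replicates.** Each replicate selects four causal SNPs with pool MAF
within ±1% of target from disjoint, separated regions (the stand-in for
"different chromosomes"), takes the 20 closest flanking SNPs with
MAF > 0.1 per side, deletes the causal column (its position falls in the
gap between retained SNPs 20 and 21), and interleaves three 100-SNP null
intervals: area, null, area, null, area, null, area — 460 SNPs, with the
four 40-SNP disease areas covering 160/460 ≈ 0.35 of the sequence. At
chromosome scale, five ~1700-SNP null intervals surround the four areas
instead.

**Phenotypes.** Disease probabilities come from one of three generative
models over the four causal genotypes — multiplicative
($\beta_0\,\mathrm{GRR}^{\#\text{carrier loci}}$), threshold (two carrier
pairs, one GRR factor each), triplet
($\beta_0\,\mathrm{GRR}^{I(Z_1>0,\,Z_2=0)\,Z_3}\,\mathrm{GRR}^{I(Z_4>0)/2}$)
— with $\beta_0$ calibrated by bisection so the pool-mean probability hits
the target prevalence of 0.40 over the 2131-individual pool, giving ~850
cases per replicate. Probabilities are capped at $\min(1,\cdot)$: under
the strongest multiplicative setting $\beta_0\,\mathrm{GRR}^4$ can exceed
1, and the calibration is cap-aware (the uncapped closed form
$\beta_0 = \text{prevalence}/\bar f$ is used whenever no individual caps).
All cases are kept and an equal number of controls is drawn uniformly
without replacement from the non-cases; a replicate with fewer non-cases
than cases is rejected and redrawn under a derived seed.

**Grids.** The replicate experiment crosses generative model ×
GRR ∈ {1.3, 1.6, 2.0} × MAF ∈ {0.05, 0.1, 0.2}, 100 replicates per cell
(2,700 data sets) in the full design; `run_experiment` derives every seed
from the master seed with a counter-based split, so enlarging a grid never
perturbs existing replicates, and finished replicates are skipped by
checksum on resume.

## Evaluation

Scores are judged by *area detection*: walking down the ranked SNP list,
how many false positives (SNPs outside every disease area) accumulate
before $k$ distinct areas are hit. Curves are summarised by the mean and
2.5th/97.5th percentile false-positive counts across replicates, and by an
AUC on unit-normalised axes, integrated as a left-continuous step function
(the curve is a ranked-list walk, so step integration — not trapezoidal —
matches the walk exactly and makes cross-implementation comparison
bitwise). Note the y-axis counts *areas*, not true-positive SNPs, so a
random ranking's expected AUC is not exactly 0.5.

*Location accuracy* is the marker distance from the top-ranked SNP to the
nearest hidden causal position: within an area the gap sits after retained
position 20, so distances run 1 (positions 20/21) to 20 (area edges), and
20 is also the sentinel outside every area. Under the triplet model the
fourth causal SNP is the only one with a main effect and dominates the
ranking, so triplet evaluation excludes its area from the arg-max. Exact
score ties always break by ascending locus index, keeping every report
deterministic.

Paired methods are compared per grid cell by win/loss counts (ties
dropped) with a two-sided binomial test at level 0.05; cells with
$|a-b| < 5$ count as no practical difference.

## Numerical and design choices, in brief

* All scores in natural logs; `logsumexp` everywhere; the structure
  prior's normalising constant is never computed (it cancels).
* Missing genotypes are imputed at the *allele* level: two independent
  draws from the locus's empirical allele frequency (Hardy-Weinberg
  pairing), not a genotype-level draw. Frequencies are computed on the
  table being imputed. Sentinels `NA` and `-1` are read; `NA` is written.
* Loci are 0-based nowhere a user sees: all reports are 1-based.
* The top-K pool, the search, the imputation and the whole experiment
  driver are deterministic given their seeds; seeds derive from one master
  seed by counter splitting.
* Validation-scale choices used by the test suite: quadrature cross-checks
  at 1,000 count configurations; exhaustive-enumeration equivalence at
  L = 3, N = 200, 200,000 iterations (total variation < 0.01); LRT-vs-IRLS
  agreement on 200 random tables; power spot-check at threshold/GRR 2.0/
  MAF 0.2 with 20 replicates and 50,000-iteration searches; null
  calibration with 200 GRR = 1 replicates against the 160/460 baseline.
  Replicates in these suites share one synthesized pool, mirroring the
  reuse of one cohort's genotypes across replicates.

## Known limitations

* Recessive-effect elementary models are not included (the M1/M3 full
  models can absorb recessive patterns at the cost of parameters).
* The likelihood is prospective; no retrospective/matched correction is
  applied. $\alpha > 1$ partially encodes the balanced design instead.
* Continuous covariates cannot enter without destroying the closed-form
  integration; categorical covariates could in principle be treated as
  pseudo-loci but are not implemented.
* Non-reversibility means posterior estimates are conditional on the
  visited set: a SNP whose models were never visited gets $-\infty$, and
  rare downward spikes in sweep overlays reflect coverage differences, not
  prior sensitivity. Longer searches shrink both effects.
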