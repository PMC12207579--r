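---
title: "Models and methods for tetrasomic diallel analysis"
author: "tetrablup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for tetrasomic diallel analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrablup)
```

This vignette documents the statistical models implemented in `tetrablup`,
the assumptions behind them, the numerical choices made where the design
was genuinely open, and what the bundled simulator does and does not
emulate.

## The diallel mixed model

The core model for a single trait measured on plot records of clones from
an incomplete diallel is

$$y = Xb + Z_a a + Z_l l + Z_f f + e,$$

with fixed effects $b$ (block-by-year, correcting soil heterogeneity and
year effects, and the maternally inherited cytoplasm type), additive
genetic effects $a \sim N(0, M\sigma^2_a)$ over a relationship matrix $M$,
iid line effects $l \sim N(0, I\sigma^2_l)$ capturing repeatable but
non-transmissible clone deviations (including seed-lot and storage effects
and within-clone non-additive variance), iid family effects
$f \sim N(0, I\sigma^2_f)$ keyed by the unordered sire–dam pair (the
specific combining ability), and iid residuals. Graded traits (1–9 or
recoded 1–6 scales) are treated as Gaussian responses, justified by the
large number of observations; counts are handled through the normal
approximation to a high-mean Poisson.

Conventions: the line effect is included only for replicated traits and can
be nested within year (used for multi-year traits such as dry matter
content); the family effect requires both parents known; the reference
levels are the first block-by-year cell and the W/γ cytoplasm type, so
cytoplasm contrasts are reported against W/γ. A parent's estimated breeding
value equals twice its general combining ability, and the SCA/GCA variance
ratio is $\sigma^2_f / (\tfrac14\sigma^2_a)$, since the GCA variance is a
quarter of the additive variance.

Heritabilities: the plot heritability
$h^2 = \sigma^2_a / (\sigma^2_a+\sigma^2_f+\sigma^2_l+\sigma^2_e)$ refers
to a single plot record; the design heritability replaces $\sigma^2_e$ by
$\sigma^2_e/n_{rep}$ and is the heritability of a clone's
replicate-averaged corrected phenotype, which is what cross-validated
prediction correlations are measured against.

## Relationship matrices

**Pedigree (A).** Autotetraploid kinship is propagated through a
topologically sorted pedigree with the recursions
$\phi_{ij} = (\phi_{sj}+\phi_{dj})/2$,
$F_i = \gamma_s/6 + \gamma_d/6 + 2\phi_{sd}/3$ and
$\gamma_p = w + (1-w)F_p$, where $\phi$ is the coancestry, $F$ the
probability that two distinct alleles of a clone are identical by descent,
$\gamma_p$ the probability that the two alleles of a gamete from $p$ are
IBD, and $w$ the double-reduction rate. Then $A_{ij} = 4\phi_{ij}$ with
diagonal $1+3F_i$; unknown parents are unrelated non-inbred founders. The
recursion is validated in the test suite against a labelled-allele
gene-dropping oracle (Monte-Carlo IBD probabilities) for $w \in \{0,
0.1\}$, rather than against published matrices. `w = 0` is the default,
and `profile_double_reduction()` refits the model over a grid of $w$ to
let the likelihood choose; in simulations the profile only separates
reliably from a few hundred clones upward.

**Genomic (G).** From 0–4 allele dosages (non-integer allowed), missing
entries are imputed to the observed marker mean, allele frequencies are
computed from the non-missing entries, and
$G = ZZ'/(4\sum_j p_j(1-p_j))$ with $Z$ the column-centred dosages — the
ploidy-4 scaling of the VanRaden denominator (at Hardy–Weinberg a marker's
dosage variance is $4pq$). Markers below 1% minor allele frequency are
dropped. An optional `allele_freq` argument accepts base-population
frequencies; only then does $E[G]$ equal the pedigree matrix, since sample
frequencies re-centre G on the genotyped panel (the package's genomic
inbreeding estimates are therefore panel-referenced).

**Single-step (H).** G is first rescaled so its mean diagonal matches the
pedigree matrix of the genotyped clones,
$G_{adj} = G \cdot \overline{\mathrm{diag}}(A_{22}) /
\overline{\mathrm{diag}}(G)$ (an idempotent adjustment), then blended. At
the default $\tau=\omega=1$ the direct block identity is used, with
$\Delta = G_{adj}-A_{22}$; general $\tau,\omega$ go through the blended
inverse $H^{-1} = A^{-1} + \mathrm{blockdiag}(0, \tau G_{adj}^{-1} -
\omega A_{22}^{-1})$. Only $\tau=\omega=1$ is exercised by the shipped
tests; other values are pass-through parameters. Near-singular blocks are
ridge-regularised with a logged jitter of $10^{-8}$; relationship matrices
that fail a Cholesky inside the fitter are ridged by $10^{-6}$ times their
mean diagonal with a message, and `psd_clip()` offers explicit eigenvalue
clipping at $-10^{-8}$.

## REML estimation

Variance components are estimated by average-information REML on the
mixed-model-equations form: all likelihood pieces come from the coefficient
matrix $C = W'R^{-1}W + G^{-1}$ via
$\log|V| + \log|X'V^{-1}X| = \log|C| + \log|G| + \log|R|$, traces of
$P\,dV$ from the corresponding blocks of $C^{-1}$, and the AI matrix from
quadratic forms in $(dV/d\theta_k) Py$, each requiring one extra solve
against the Cholesky factor of $C$. Fixed-effect columns made aliased by
the design are dropped by QR pivoting before fitting.

Numerical policy, in order of preference at each iteration:

1. an AI (quasi-Newton) step, projected onto the parameter space
   (variances floored at $10^{-6}$ times the phenotypic variance, 2×2
   covariance blocks clamped to a correlation of at most 0.999) and
   step-halved until the deviance does not increase;
2. a *pinned* AI step that freezes parameters sitting on their constraint
   with the score pushing outward and updates the rest;
3. an EM-REML step, with step-length extrapolation (the EM direction
   amplified up to 16× when that still decreases the deviance), since
   plain EM creeps near boundaries.

Convergence is declared when the relative change of $-2\log L$ falls below
$10^{-8}$ (at most 100 iterations), or when accepted steps stop moving the
parameters (relative change $<10^{-5}$ three times in a row — a boundary
stall). Parameters glued to a constraint for four consecutive iterations
are frozen there with a warning, as variance-component solvers
conventionally do. Standard errors come from the inverse AI matrix.
Components sitting at the floor are flagged as boundary estimates, not
errors: under a true zero component the REML estimator puts roughly half
its mass exactly at zero, so boundary estimates in null settings are
expected behaviour.

Breeding values at the estimates come from Henderson's equations; the
prediction error variance of a clone is the corresponding diagonal of the
additive block of $C^{-1}$, and 95% intervals are
$\hat a \pm 1.96\sqrt{\mathrm{PEV}}$. These intervals are exact under the
model when the components are known; when the components are REML
estimates from designs where $\sigma^2_a$ is weakly separated from the
line variance (few parents, two replicates), the plug-in intervals
under-cover, which the calibration tests make explicit by checking
coverage in the known-component case.

## Bivariate models and correlations

Trait pairs are fitted with unstructured 2×2 covariance matrices for the
additive term ($N(0, A \otimes C)$), the line and family terms, and the
residual. The residual covariance applies only to records of the two
traits from the same plot context (clone–year–replicate); when no such
pairs exist (traits recorded in disjoint years) it is structurally not
estimable, is fixed at zero and flagged, and the phenotypic correlation is
reported as undefined. The genetic correlation is
$r_g = C_{12}/\sqrt{C_{11}C_{22}}$ with a delta-method CI from the inverse
AI matrix. The phenotypic correlation is the plug-in composition: the sum
of the additive, line, family and residual covariances over the geometric
mean of the two total phenotypic variances — the line covariance entering
only when both traits carry a line term (a trait without replicates drops
to a single-trait line variance that still contributes to its own total).
This composition is a commitment of this package; reasonable alternatives
(e.g. excluding the line covariance throughout) differ only in which
non-transmissible covariance is counted as "phenotypic".

## Cross-validation

`cross_validate()` estimates components once on the full data (or accepts
them as priors), then for each fold of each repeat re-solves the BLUP
equations with the validation clones' phenotype records removed while
keeping their pedigree/genomic links — the single-step use case of
predicting unphenotyped clones. Fold plans partition the validated clones
(by default only the F1 generation, i.e. clones with both parents known)
into k folds differing in size by at most one; repeat $r$ uses the
sub-seed $(seed + 7919\,r) \bmod (2^{31}-1)$ so any repeat can be
regenerated independently. Reported metrics: the per-repeat Pearson
correlation between validation EBVs and mean corrected phenotypes
$\bar y^c_i = \mathrm{mean}(y - x'\hat b)$ (fixed effects from the
full-data fit of the same model), its mean and SD, the prediction accuracy
$r/\sqrt{h^2_{design}}$, and the dispersion slope $\beta$ from regressing
$\bar y^c$ on the EBVs — oriented so that $\beta > 1$ literally means
extreme EBVs are deflated. In simulations the prediction accuracy tracks
the true $\mathrm{corr}(a, \hat a)$ and $\beta$ averages close to 1.

## The simulator

`sim_diallel()` generates the study design the package is meant for: a
set of parents with cytoplasm types drawn at frequencies 0.56/0.25/0.19
(T/β, D, W/γ), all W/γ parents male-sterile plus additional steriles up to
roughly 5/18 of the panel; an incomplete diallel of unordered parent pairs
with a fertile sire, a configurable fraction of crosses dropped as
infertile, and no reciprocals (the motivating design contains almost
none); maternal transmission of cytoplasm; and tetrasomic gamete formation
in which each marker independently receives two distinct homologs, or one
duplicated homolog with probability $w$ (double reduction). Founder allele
frequencies are Beta(2, 2) draws truncated to [0.02, 0.98] — a
deliberately non-extreme spectrum so that a few hundred markers give
stable genomic matrices; marker effects are iid normal, rescaled so the
expected founder breeding-value variance $\sum_j \alpha_j^2 4p_jq_j$
equals the configured $\sigma^2_a$.

Breeding values are *genotypic* — sums of marker effects over the dropped
alleles — rather than draws from $N(0, A\sigma^2_a)$. This makes the
pedigree, genomic and single-step matrices mutually consistent by
construction and gives the right Mendelian-sampling behaviour (the
within-family breeding-value variance is $\sigma^2_a/2$ at $w = 0$). Line,
family and residual effects are exchangeable Gaussian draws at the
configured variances (the non-additive mechanism is not modelled
mechanistically — the generator emulates the model's own assumption), and
block-by-year effects are Gaussian with configurable SD. Phenotypes for
two traits correlate through marker effects ($r_g$), line, family and
residual draws.

The default configuration is desk-scale: 12 parents, ~40 families of 25
offspring (~1000 clones), 500 markers, 17% missing genotype calls on a
panel of the parents plus 15% of offspring, one year with two replicates
in blocks of 28, dry-matter-like components (additive 2.42, line 4.61,
family 0.38, residual 0.70 in squared trait units, mean 20.26) and
cytoplasm shifts of −2.24 (T/β) and −1.45 (D) against W/γ. These values
mirror the magnitudes reported for elite tetraploid potato material, so
the recovery tests exercise a realistic signal-to-noise regime; a full
run of simulation, A-matrix, REML fit and a short cross-validation takes
well under a minute on one CPU.

What the simulator does **not** emulate: linkage (markers segregate
independently, so realized relationships concentrate faster around their
pedigree expectations than with real chromosomes), genotyping error and
allele-frequency dosage noise, selection during population construction
(the real population lost degenerate clones before phenotyping),
genotype-by-environment interaction, and mechanistic dominance/epistasis.
Passing recovery tests therefore show that the estimators are correct
*under the model*, not that the model captures every feature of real
field data.

## Trait preparation details

Dry matter content uses the under-water-weighing calibration
$DM\% = 214(w_{air}/(w_{air}-w_{water}) - 0.988)$; extreme values are
retained (an optional flag lists values above a user threshold without
removing them). Grade scales 1–9 with unused low categories are pooled:
values ≤ 4 become 1 and the rest shift down so 9 maps to 6; already
recoded 1–6 data are left unchanged with `pool_threshold = 1`. Outliers in
tuber length/diameter batches are removed iteratively by Dixon's Q test
(gap to nearest neighbour over range), two-tailed, with tabulated critical
values for batches of 3–30 and an $a + b/\sqrt{n}$ regression fitted to
the tail of the table for batches of 31–200 (the published analysis states
a regression extension without coefficients; ours is fitted to the
n = 10–30 tabulated values at each confidence level, default 95%).
Zero-range batches and batches below three values are returned unchanged.

## Known limitations

Dense matrix algebra limits pedigrees to a few thousand clones; no sparse
inverse (Henderson rules / APY) path is provided. Only pairwise bivariate
models are available, matching the analysis this package reproduces. Fits
on weakly identified small designs can legitimately end at parameter
boundaries; the reported SEs are then asymptotic approximations of limited
value, and the boundary flags in the fitted object should be consulted.
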