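---
title: "Bidirectional Mendelian randomization with twin data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional Mendelian randomization with twin data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdoc2)
```

## The model

`mrdoc2` implements a structural equation model for two phenotypes measured
on monozygotic (MZ) and dizygotic (DZ) twin pairs, with a polygenic score
for each phenotype serving as a genetic instrument. For individual $j$ of
pair $i$ the structural equations are

$$
\begin{aligned}
Ph1_{ij} &= a_1 A_{1ij} + c_1 C_{1ij} + e_1 E_{1ij} + g_2\, Ph2_{ij} + b_1\, PS1_{ij},\\
Ph2_{ij} &= a_2 A_{2ij} + c_2 C_{2ij} + e_2 E_{2ij} + g_1\, Ph1_{ij} + b_3\, PS2_{ij}.
\end{aligned}
$$

Each phenotype has its own additive-genetic (A), shared-environment (C) and
unique-environment (E) factors with unit variances; the two traits'
factors correlate within a person ($r_a$, $r_c$, $r_e$), and the two scores
correlate ($r_f$, e.g. through linkage disequilibrium or genetic overlap).
The parameters of interest are the reciprocal causal paths $g_1$
(Ph1 $\to$ Ph2) and $g_2$ (Ph2 $\to$ Ph1). Direct (horizontally
pleiotropic) paths from each score to the *other* phenotype — `b2`
(PS1 $\to$ Ph2) and `b4` (PS2 $\to$ Ph1) — exist in the model but are fixed
to zero by default: that restriction is what makes the model locally
identified, and relaxing it is exactly the violation studied by
`pleiotropy_violation_study()`. Note that even with $b_2 = b_4 = 0$ each
score is still correlated with the other phenotype, through $r_f$ and
through the causal loop; only the *direct* effect is excluded.

Solving the simultaneous equations gives the reduced form with mixing
matrix $(I-B)^{-1} = \frac{1}{1-g_1 g_2}\begin{pmatrix}1 & g_2\\ g_1 & 1
\end{pmatrix}$, which exists whenever $|g_1 g_2| < 1$
(`reduced_form()`). From it, `implied_moments()` assembles the $8\times 8$
covariance matrix of the pair vector
(Ph1, Ph2, PS1, PS2 for each twin). Cross-twin covariances follow the
standard biometrical rules: A-factor covariances are scaled by the genetic
share (1 for MZ, 0.5 for DZ), C factors are shared fully, E factors are
uncorrelated across twins. Polygenic scores are additive genotype
aggregates, so their cross-twin covariances follow the same rule as A:
$\mathrm{cov}(PS_{t1}, PS_{t2}) = \sigma^2$ for MZ and $0.5\sigma^2$ for
DZ, and the cross-twin cross-score covariance is $r_f \sigma_x \sigma_y$
(MZ) and $0.5\, r_f \sigma_x \sigma_y$ (DZ). The DZ factor of 0.5 on the
$r_f$ term is a modelling choice (the alternative, an unattenuated $r_f$,
is not compatible with the published power values we reproduce, see below).
Scores and latent A factors are uncorrelated in the model: $r_a$ and $r_f$
are distinct parameters, which is what makes the sensitivity constraint
$r_a = m\, r_f$ (below) meaningful. All means are structurally zero;
everything is covariance-structure-only.

## The MZ likelihood and the singular score block

MZ co-twins carry identical genotypes, hence identical polygenic scores:
the model-implied MZ pair covariance has a cross-twin score correlation of
exactly 1 and is singular. The likelihood therefore lives on the six
non-degenerate coordinates — both twins' phenotypes plus one twin's two
scores — and `mrdoc_fit()` computes the MZ group's discrepancy from the
corresponding $6\times 6$ submatrix (the DZ group uses the full
$8\times 8$). This is the full-information likelihood on the support of the
distribution, equivalent to entering each MZ pair's scores once.
`simulate_twins()` makes the degeneracy literal: MZ co-twins receive
identical score values. The $8\times 8$ matrix is still what
`implied_moments()` returns, because it is the natural population object.

## Estimation

Fitting minimises the two-group normal-theory discrepancy

$$
F(\theta) = \sum_{g \in \{MZ, DZ\}} n_g\left[\ln|\Sigma_g(\theta)| +
\mathrm{tr}\left(S_g \Sigma_g(\theta)^{-1}\right) - \ln|S_g| - p_g\right],
$$

which is zero iff the model reproduces the observed moments. Numerical
choices that matter:

* **Optimizer.** Bounded quasi-Newton (L-BFGS-B) on the *per-pair*
  discrepancy $F/(n_{MZ}+n_{DZ})$ — the rescaling keeps gradients $O(1)$
  and the line search stable. The gradient is computed by central finite
  differences inside compiled code (step $10^{-7}\max(1,|x|)$). A stalled
  line search (detected by a nonzero return code or a large projected
  gradient at the reported optimum) falls back to the PORT algorithm
  (`nlminb`). A final L-BFGS-B pass at near-zero tolerance (`factr = 1`)
  polishes the solution; bulk factorial runs skip the polish
  (`polish = FALSE`), trading roughly the last $10^{-4}$ of parameter
  precision for half the run time.
* **Bounds instead of transforms.** Correlations are constrained to
  $(-0.999, 0.999)$ and loadings $a, c, e$ to $[0, 3]$ by box bounds
  directly, rather than via tanh/log reparameterisations: the bounded
  quasi-Newton methods handle boxes natively, and the nonnegativity of the
  loadings removes the latent factors' sign indeterminacy with no loss
  (variance components are squares).
* **Inadmissible regions.** Parameter points with an indefinite implied
  covariance return a penalty that grows with the eigenvalue violation
  (not a flat cap), so line searches that overshoot are steered back.
* **Multi-start.** After the first minimisation, jittered restarts
  (uniform $\pm 0.15$ on each free parameter) run until the best
  discrepancy is reproduced twice within $10^{-6}$ or the restart budget is
  exhausted; a failure to reproduce is flagged in the result, never
  silent.
* **Degrees of freedom** of a likelihood-ratio comparison are counted as
  the difference in free-parameter counts.

On exact population moments the estimates equal the generating values (the
test suite verifies recovery to $10^{-5}$ over 50 random admissible
configurations), and the discrepancy of a constrained fit is the exact
noncentrality parameter (NCP) of the corresponding LR test at the given
group sizes — no Monte-Carlo noise. `power_from_ncp()` converts an NCP to
power via the noncentral $\chi^2$ upper-tail probability beyond the central
$\chi^2$ critical value.

## Identification

`check_identification()` establishes local identification numerically: it
stacks the unique elements of the MZ and DZ implied covariances, takes
central-difference derivatives (step $10^{-6}$) with respect to the free
parameters at several generic random points (correlations drawn from
$(-0.6, 0.6)$, paths from $(0.1, 0.7)$, seeded), and compares the rank of
the Jacobian (singular values above $10^{-8}$ of the largest) with the
free-parameter count. Means carry no information and are excluded. A
verdict that differs across points is reported as unstable rather than
resolved by majority. The package reproduces the published configurations:
the model is identified with $b_2 = b_4 = 0$; freeing both breaks
identification; fixing $r_e = 0$ buys back exactly one of the two direct
paths; and the equality constraint $r_a = m\, r_f$ (fixed $m$, the device
for treating the score as a noisy measure of the additive-genetic
liability) likewise identifies one of $b_2$/$b_4$ but not both. One caveat
found while testing: at parameter points where $c_1 = c_2 = 0$ the
derivative with respect to $r_c$ vanishes, so the full ACE pattern is rank
deficient *at AE points*; the AE pattern with the structural zeros fixed is
the identified one there.

## The factorial power designs

`factorial_design()` encodes three grids (levels on the path-coefficient
scale, i.e. signed square roots of the variance-scale levels; $e$ always
derived as $\sqrt{1-a^2-c^2}$; both score standard deviations 1; 1000 MZ +
1000 DZ pairs; $\alpha = 0.05$):

* **design1** — full ACE confounding, 12 two-level factors, $2^{12} = 4096$
  cells;
* **design2** — AE ($r_c = c_1 = c_2 = 0$), two or three levels per factor,
  $3^7 2^2 = 8748$ cells;
* **design3** — AE with signed instrument and causal paths, $4^4 = 256$
  cells ($r_a = r_e = r_f = 0.3$, $a_1^2 = 0.5$, $a_2^2 = 0.3$).

`run_design()` evaluates, per cell, the exact NCP and power of the three
tests $g_1 = 0$, $g_2 = 0$ (1 df each) and $g_1 = g_2 = 0$ (2 df). The
fitted model is the design's own generating family — the AE designs fix
the structural zeros — and the constrained fits start from the generating
values (exact data make the full-model discrepancy identically zero, so
only the constrained fit is needed). `regress_ncp()` then standardises the
NCP and the varying parameters across cells and reports squared
standardised OLS coefficients — on these orthogonal grids, exactly each
factor's ANOVA share of the NCP variance — plus the total $R^2$;
`order = 2` adds centred squares of the three-level factors and reports the
$R^2$ gain. Linear terms leave roughly 7–9% of the NCP variance to
curvature and interactions, which is the gap $1 - R^2$ visible in the
decompositions.

`required_n_curve()` traces the sample size needed for 80% power to reject
$g_1 = 0$ as a function of the instrument's explained variance
$R^2(Ph1 \sim PS1)$: it solves for the $b_1$ matching each target $R^2$,
evaluates the per-pair NCP once, and exploits the exact proportionality of
the NCP in the total pair count (equal MZ/DZ split) to jump to the
crossing, verifying it directly.

## Violation studies

Two parameterised experiments mirror the model's two known failure modes:

* **Direct pleiotropy** (`pleiotropy_violation_study()`): generate exact
  moments with $b_2, b_4 > 0$, fit with both fixed to zero. The causal
  paths absorb the unmodelled direct effects ($\hat g_1, \hat g_2$ biased
  upward) and the background correlations compensate downward
  ($\hat r_a, \hat r_c, \hat r_e$ underestimated); with no true causation
  the inflated $\hat g$ shows up as a false-positive rate above $\alpha$,
  reported through the NCP of the misspecified test. Exact moments are
  used because the claims concern estimates, not sampling noise. The
  default violation grid puts 0.5–2% of phenotypic variance on each direct
  path.
* **Unmodeled measurement error** (`measurement_error_study()`): simulate,
  degrade the phenotypes to reliability `rel`, refit. Error injection is
  *additive* — noise with variance $\mathrm{var}(x)(1-rel)/rel$, so that
  `rel` is the proportion of observed variance that is true score. Additive
  noise leaves every covariance intact, which is why it is absorbed
  entirely by the unique-environment side: $\hat e_1, \hat e_2$ inflate,
  $\hat r_e$ attenuates, while $\hat g_1, \hat g_2, \hat b_1, \hat b_3$
  stay unbiased and only the *power* to reject $g_1 = 0$ drops. (A
  rescaling injection of the form $\sqrt{rel}\,x + \sqrt{1-rel}\,\epsilon$
  would shrink the score–phenotype covariances and push bias into
  $\hat b_1, \hat b_3$ — a different, less standard notion of reliability;
  we use the additive one.) This study needs raw data, so it is the one
  Monte-Carlo component: defaults are 100 replicates of 1000 + 1000 pairs,
  reliabilities 0.8, with per-parameter Monte-Carlo standard errors
  reported alongside the biases.

## What the generator does and does not emulate

`simulate_twins()` draws from the exact multivariate normal implied by the
model: linear effects, normal homoscedastic phenotypes, no assortative
mating, no dominance, no sex limitation, no selection or ascertainment, no
genotype-level structure beneath the scores, zero means. Passing tests
therefore demonstrate correctness of the moment algebra, the estimation
machinery and the power calculus *under the model's own assumptions*; they
do not speak to robustness against non-normality, ordinal measurement, or
score misspecification beyond the two violation studies above.

## Problem sizes and defaults

The study conditions follow the published design throughout: 1000 MZ +
1000 DZ pairs, $\alpha = 0.05$, $\sigma_x = \sigma_y = 1$, derived $e$.
The Monte-Carlo moment oracle in the tests uses 200,000 pairs per
zygosity; the measurement-error study defaults to 100 replicates (40 in
the acceptance suite's combined property block); the full factorial runs
(4096- and 8748-cell) are executed in `scripts/acceptance.R`, while the
test suite exercises a 128-cell smoke subsample of the ACE design. Bulk
runs use the unpolished fast fits, whose NCPs agree with polished ones to
about $10^{-6}$.

## Known limitations

* Ordinal or threshold phenotypes, five-group sex-limitation designs,
  dominance (ADE) and longitudinal/multivariate extensions are out of
  scope.
* Fitting consumes complete-data moments; there is no FIML for missing
  entries, and no sandwich or profile-likelihood standard errors.
* The identification check is local (Jacobian rank at generic points), not
  a global or symbolic proof.
* Real MZ pairs whose recorded scores differ (e.g. from genotyping error)
  violate the degeneracy the MZ likelihood relies on; such data would need
  a measurement model for the scores.
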