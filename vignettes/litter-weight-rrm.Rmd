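---
title: "A random regression animal model for total litter weight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A random regression animal model for total litter weight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrmlw)
```

## The measurement problem

In mice, pigs and other multiparous species, the birth weight of a whole
litter is often recorded as a single weighing of all live pups. Total
litter weight (LW) is then the sum of individual birth weights that were
never observed separately, and it confounds two very different biological
channels: how many pups there are (litter size, LS) and how heavy each pup
is. Treating LW as an ordinary maternal trait of the dam mixes these
channels and, in particular, hides the genetic contribution of the sire,
which enters only through the pups' own genes.

`rrmlw` implements a random regression resolution of this confounding.
Writing the individual birth weight of each pup as the sum of the dam's
maternal effect $m_d$, half the dam's and half the sire's direct breeding
values ($\tfrac12 b_d$, $\tfrac12 b_s$) and a residual, the litter total
for $n_i$ pups becomes

$$ y_i = n_i\,(m_d + \tfrac12 b_d + \tfrac12 b_s) + e_i, $$

where the single residual $e_i$ absorbs measurement error, non-genetic
variation and the pup-level direct Mendelian sampling terms. Each parent
therefore acts on LW through a *random linear slope* on litter size: the
dam through $a_d = m + \tfrac12 b$ and the sire through $a_s = \tfrac12 b$,
where $m$ and $b$ are that animal's maternal and direct breeding values.
In matrix form $(a_d, a_s)' = K' (m, b)'$ with
$K' = \begin{pmatrix} 1 & \tfrac12 \\ 0 & \tfrac12 \end{pmatrix}$, an
invertible map, so the slope and maternal--direct parameterizations carry
identical information (`slope_from_maternal_direct()`,
`maternal_direct_from_slope()`, and the effect-level analogues).

## The fitted model

The univariate model fitted by `rrm_fit()` is

$$ y_{ij} = \alpha_j + \sum_{k=1}^{2} \phi_{tk}\beta_k + x_i \beta_0 +
   x_i u_m + x_i u_s + e_{ij}, $$

with generation fixed effects $\alpha_j$, a fixed mating-age curve of
linear and quadratic Legendre polynomials $\phi_{tk}$ (age rescaled to
$[-1, 1]$; the constant term is absorbed by the intercept), a fixed
regression $\beta_0$ on the standardized litter size $x_i = n_i/n_{max}
\in (0, 1]$, and random parental slopes $u_m, u_s$ with
$\mathrm{var}(u) = G \otimes A$ and $\mathrm{var}(e) = I\sigma_e^2$. $A$ is
the pedigree numerator relationship matrix. There are deliberately no
random intercepts and no random quadratic terms: the regression exists
solely to multiply each parent's average genetic effect by the number of
pups.

Because of the $x$-scaling, the elements of
$G = \begin{pmatrix} \sigma_t^2 & \sigma_{ts} \\ \sigma_{ts} &
\sigma_s^2 \end{pmatrix}$ are expressed at the maximum litter size
($x = 1$). At litter size $n$ the genetic variance is $x^2$ times the
$x=1$ value, which gives the litter-size-dependent heritabilities

$$ h^2_{dam}(n) = \frac{x^2\sigma_t^2}{x^2(\sigma_t^2 + \sigma_s^2) +
   \sigma_e^2}, \qquad
   h^2_{sire}(n) = \frac{x^2\sigma_s^2}{x^2(\sigma_t^2 + \sigma_s^2) +
   \sigma_e^2}, $$

and their sum $h^2_{tot}(n)$ (`heritability_at_ls()`,
`average_heritability()`, `heritability()`). A larger litter is a more
informative observation on its parents, so all three increase with $n$.
Conversely, the genetic correlation between litters of *any* two sizes is
identically 1 (`litter_genetic_correlation()` computes the
covariance/variance ratio and the cancellation is exact): LW at different
litter sizes is genetically one trait, unlike random regression models
over age or lactation where the correlation decays along the trajectory.

Two definitional choices deserve a note because the algebra admits
variants:

* **Total genetic variance.** The default total at litter size $n$ is
  $x^2(\sigma_t^2 + \sigma_s^2)$, the form used in the heritability
  denominators; the variance of one mating's combined parental
  contribution would add $2x^2\sigma_{ts}$ and is available via
  `genetic_variance_at_ls(..., include_covariance = TRUE)`.
* **Standard-error scaling.** Reported SEs of the genetic (co)variances
  apply at $x = 1$. `scale_se_to_ls()` defaults to multiplying by $x$
  (the linear rescaling of a slope SE); since the *variance* at litter
  size $n$ is $x^2$ times the $x=1$ value, an `x_squared` mode is also
  provided. Both conventions appear in practice; the default follows the
  field's reporting habit.

## Baselines and the model battery

For comparison with traditional analyses, `rrm_fit()` also fits LW with a
plain dam (and optionally sire) intercept effect and no LS adjustment
(`TLW`), the same with a fixed linear regression on the raw pup count
(`LWA`; the covariate is $n_i$, not $x_i$, matching how such adjustments
are usually specified), and average birth weight $y_i/n_i$ modelled
conventionally (`ABW`). `fit_bivariate_lw_ls()` fits LW jointly with LS,
where LS carries a dam intercept genetic effect and the two records of a
litter share an estimated $2\times2$ residual covariance — the same pups
generate both numbers, so this covariance is a free parameter, not zero.
The headline output is the genetic correlation between the dam effect on
LW and the breeding value for LS. Litter size is fitted with
generation effects only by default (`ls_fixed_age = TRUE` adds the age
curve); the choice is configurable because the right fixed structure for
LS is not dictated by the LW model.

The significance of the sire channel is assessed by a restricted
likelihood ratio test (`rlrt_sire()`): twice the difference between the
restricted log-likelihoods of the full and the dam-only fit, referred to
$\chi^2_2$ for the joint removal of $\sigma_s^2$ and $\sigma_{ts}$. The
null value $\sigma_s^2 = 0$ lies on the boundary of the parameter space,
so the 2-df reference is conservative; the package keeps it as the default
test and offers the $\tfrac12\chi^2_1 + \tfrac12\chi^2_2$ mixture behind
`boundary_mixture = TRUE`. The calibration test in the suite confirms the
conservative direction empirically.

## Pedigree machinery

Pedigrees are topologically sorted at construction; unknown parents are
unrelated base-population founders and no genetic-group structure is
modelled (the intended data are complete within-line pedigrees).
Inbreeding is computed by the Meuwissen--Luo recursive algorithm, with an
exact generation-matrix fast path for strictly layered pedigrees (the kind
the simulator produces; 40+ closed generations make $F$ material, so the
$A^{-1}$ assembly by the Henderson/Quaas rules always uses inbreeding
rather than the non-inbred shortcut). The dense tabular $A$ is available
for small pedigrees (`a_matrix()`, capped at 2000 animals by default) and
serves as the oracle against which the sparse `a_inverse()` is verified in
the tests.

## REML: estimation, standard errors, numerics

Variance components are estimated by restricted maximum likelihood
through Henderson's mixed-model equations. With $\Gamma = G/\sigma_e^2$
and $C = W'W + \Gamma^{-1} \otimes A^{-1}$,

$$ -2\ell_R = (n-p)\log\sigma_e^2 + m\log|\Gamma| + b\log|A| + \log|C| +
   \frac{y'y - \hat s'W'y}{\sigma_e^2} + (n-p)\log 2\pi , $$

and $\sigma_e^2$ profiles out analytically
($\hat\sigma_e^2 = (y'y - \hat s'W'y)/(n-p)$), leaving a three-parameter
(one-parameter for dam-only) search over the Cholesky factor of $\Gamma$,
log-scaled on the diagonal so positive definiteness is structural rather
than enforced by penalties. The search is derivative-free
(Nelder--Mead; golden-section for one parameter), warm-started from a
cheap dam-only profile fit. Each evaluation is a numeric fill of the
precomputed sparse pattern of $C$ followed by a fresh supernodal sparse
Cholesky factorization (CHOLMOD via the Matrix package), which on
pedigree-structured systems is substantially faster than updating a
cached simplicial factorization. $\log|A|$ costs nothing: it is
$\sum_i \log d_i$ over the Mendelian sampling variances already produced
by the inbreeding pass.

Standard errors come from the inverse of the average-information matrix
assembled at the optimum,
$\mathrm{AI}_{ij} = \tfrac12 (V_i P y)' P (V_j P y)$, which requires only
MME solves because $V$ is linear in every parameter; the SE of the
dam--sire correlation $r_{ts}$ follows by the delta method. Exact
score-based AI or EM *updates* were deliberately not used for the point
estimation: their trace terms need selected elements of the sparse MME
inverse (a Takahashi-style partial inverse), which no available sparse
backend exposes, and dense inverses do not scale to the
$\sim 2 \times 10^4$-equation systems of the validation studies. Instead a
full EM-REML with dense inverses (`reml_fit_em()`) is kept as an
independent algorithm for small systems, and the test suite checks that it
climbs monotonically to the same optimum as the profiled search. A second,
fully independent oracle — the dense $V = Z(G\otimes A)Z' + I\sigma_e^2$
likelihood (`reml_loglik_direct()`) — is matched by the sparse path to
$10^{-6}$ on randomized small instances.

Numerical guard rails, all visible in the code rather than hidden:
likelihood evaluations return a large finite penalty when $\Gamma$ is
numerically singular (condition number below $10^{-14}$) or the
factorization fails, which steers the simplex away from degenerate
parameter sets; Cholesky diagonals are clamped to $e^{\pm 23}$ on the log
scale; a sire variance below $10^{-6}$ of the phenotypic variance flags
the fit as a boundary case. Convergence uses a relative tolerance of
$10^{-9}$ on $-2\ell_R$ by default ($10^{-8}$ in the replicated
simulation studies, where the difference is far below Monte Carlo noise).

BLUPs of $a_d$ and $a_s$ come from the final MME solve; prediction error
variances are read off the exact inverse of the coefficient matrix
(computed when the system has at most `pev_cap = 5000` equations) and
reliabilities are $1 - \mathrm{PEV}/\sigma^2$ against the $x = 1$ prior
variance. `mme_blup()` exposes the same computation at user-fixed
components, which is the cleanest way to study the information content of
litters: under the RRM, reliability rises with litter size; under the ABW
baseline it cannot.

The bivariate model generalizes the same machinery to a blocked residual
covariance; its nine parameters are maximized by a coarse simplex followed
by a BFGS polish, with observed-information standard errors from a
scaled-step numerical Hessian (SEs are withheld rather than fabricated
when the curvature at the returned point is not positive definite).

## The simulator

`simulate_dataset()` generates data with exactly the statistical structure
the model assumes, so that estimation and testing can be validated by
parameter recovery. Its defaults describe a control-line-like population:
40 discrete generations of 125 breeding pairs with a 1:1 mating ratio, a
single litter per pair (a fraction of sires can be mated twice, as happens
in growth-selected lines), litter sizes from a discretized normal
truncated to $[1, n_{max}]$ with mean 11.61 and SD 2.98 at
$n_{max} = 22$, and slope (co)variances of a few g² against a residual of
about 2 g². Mating-age is drawn around 90 ± 25 days and enters through the
same Legendre curve the fitter uses; generation means are drawn once from
$N(0, 1)$ so the fixed/random separation is testable; the fixed LS
regression $\beta_0 = 39$ g at $x=1$ reproduces a realistic mean LW near
21 g. Presets mirroring a growth-selected and a high-fecundity line ship
as YAML (`sim_preset()`). All randomness flows from the single seed in
the configuration.

Breeding values descend the pedigree as parent averages plus Mendelian
sampling with covariance $d_i G$, $d_i = \tfrac12 - \tfrac14(F_s + F_d)$,
so drift and inbreeding in closed lines shrink within-family variance
exactly as in the model. Three generative modes exist:

* `rrm_exact` — one $N(0, \sigma_e^2)$ residual per litter: the model is
  true, and the litter residual variance is flat in litter size;
* `pup_level` — every pup contributes its own direct Mendelian deviation
  and measurement noise, so the residual variance grows with litter size.
  This is the data-generating mechanism the single-weighing practice
  actually implies, and fitting the homoscedastic model to it quantifies
  the cost of the homoscedasticity assumption;
* `bivariate` — litter size itself carries a genetic dam effect correlated
  with the weight effects, for validating the bivariate fit.

Features of real data the simulator does **not** emulate: directional
selection across generations (lines are simulated under drift only),
stillbirth or cannibalism processes (only surviving-pup counts are
modelled, as in the data the model is meant for), litter-size-dependent
residual variance in the default mode, seasonal or cage environmental
structure, and next-generation breeders are drawn uniformly over litters
rather than proportionally to litter size. Passing recovery tests
therefore demonstrates correctness of the estimation machinery under the
model's assumptions, not robustness to every violation real data can
offer. Simulated litter weights are floored at 0.1 g, which only ever
binds for single-pup litters in the far tail.

## Validation scale

The shipped tests validate at sizes chosen to exercise the same code
paths as a full analysis while staying desk-scale: oracle equivalence on
randomized pedigrees of 60–140 animals; parameter recovery on 20
replicates of 5,000 litters / 10,000 animals (the scale of a real
control-line dataset); test-size calibration on 200 replicates of 210
litters; bivariate recovery on 600 litters. The recovery study checks
that every component lands within two reported (average-information)
standard errors of the truth in at least 90% of replicates, which
simultaneously validates point estimation and the SEs themselves.

## Limitations

Residual variance is homoscedastic across litter size by assumption (the
pup-level mode exists precisely to probe this); there is no
permanent-environment effect, appropriate for designs with a single
litter per dam but too restrictive for repeated-litter species (repeated
sires are handled through $A$ alone); no genomic relationships; and
heritability is reported on the litter-mean scale defined above, with the
dam--sire covariance excluded from the genetic variance by the default
definition. Models with more than two traits, random regression of order
above one, and selection-response prediction are out of scope.
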