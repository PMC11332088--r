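---
title: "Multiplex social relations models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex social relations models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multisrm)
```

## The problem

Roster-based field designs — network-structured economic games and dyadic
peer ratings — produce several binary directed networks over one shared set
of people: who gave to whom, who took from whom, who punished whom, who
rates whom as generous or selfish. The scientific questions concern
*reciprocity*: does a flow from $j$ to $k$ in one layer predict the reverse
flow, or a flow in another layer, between the same two people (dyadic
reciprocity)? And do people who send a lot in one layer also receive a lot,
in the same or another layer, at the level of stable individual propensities
(generalized reciprocity)?

`multisrm` estimates these quantities with a Bayesian multiplex
generalization of the Social Relations Model (SRM) for binary directed
outcomes, and ships a generative simulator so that the whole pipeline can be
validated by simulate-then-fit parameter recovery.

## The model

For sender $j$, receiver $k$ and layer $m \in \{1,\dots,M\}$ the tie
indicator is

$$G_{[j,k,m]} \sim \mathrm{Bernoulli}\big(\mathrm{logistic}(\theta_{[j,k,m]})\big),
\qquad
\theta_{[j,k,m]} = \eta_{[m]} + \alpha_{[j,m]} + \beta_{[k,m]} + \delta_{[j,k,m]} + \dots$$

with per-layer intercept $\eta_{[m]}$, sender effect $\alpha_{[j,m]}$,
receiver effect $\beta_{[k,m]}$ and dyad-direction effect
$\delta_{[j,k,m]}$. The ellipsis is an optional covariate hook: layer-specific
coefficients on sender, receiver and dyadic predictors (e.g.
$\lambda_{[1,m]}W_{[j]} + \lambda_{[2,m]}W_{[k]} + \lambda_{[3,m]}R_{[j,k]}$
for a wealth covariate $W$ and a relatedness matrix $R$).

**Generalized block.** Each person's $2M$-vector
$(\alpha_{[j,1..M]}, \beta_{[j,1..M]})$ is multivariate normal with zero
mean and covariance $\mathrm{diag}(\sigma)\,L L^\top \mathrm{diag}(\sigma)$.
It is implemented in non-centered form: unit-normal raws are mapped through
$\sigma \circ (L z_j)$, where $L$ is the Cholesky factor of the $2M \times
2M$ generalized correlation matrix. Off-diagonal entries of $LL^\top$ are the
generalized reciprocity parameters, within and across layers.

**Dyadic block.** Each unordered dyad $\{j,k\}$ carries a $2M$-vector
$(\delta_{[j,k,1..M]}, \delta_{[k,j,1..M]})$, again non-centered:
$\varsigma_{\mathrm{full}} \circ (\Gamma u_{jk})$. Two constraints follow
from the exchangeability of the two directions of a dyad:

1. *Tied scales.* $\varsigma_{[m]} = \varsigma_{[m+M]}$ — only $M$ free
   dyadic standard deviations exist, so the two directions of a layer have
   identical marginal scale *exactly, by construction*.
2. *Block symmetry.* The dyadic correlation matrix
   $\rho = \Gamma\Gamma^\top$ should have the form
   $\rho = \begin{pmatrix} C & B \\ B & C \end{pmatrix}$ with $B = B^\top$;
   $\mathrm{diag}(B)$ holds the within-layer dyadic reciprocities. No known
   Cholesky-style parameterization produces exactly this form while
   guaranteeing positive definiteness, so the constraint is imposed
   *softly*: for every layer pair $m<n$ the discrepancies
   $\lvert\rho_{[m+M,n+M]} - \rho_{[m,n]}\rvert$ and
   $\lvert\rho_{[m,n+M]} - \rho_{[n,m+M]}\rvert$ receive
   $\mathrm{Normal}(0,\epsilon)$ log-density penalties. As
   $\epsilon \to 0$ the posterior concentrates on the block structure; the
   default is $\epsilon = 0.1$, and the recovery experiment checks that
   fitted posterior means respect the symmetries to well within 0.1.

**Priors.** Raw effects are standard normal (the non-centered
parameterization); standard deviations have Exponential(2.5) priors (prior
mean 0.4 on the log-odds scale); both correlation Cholesky factors have
LKJ(2.5) priors, mildly favouring the identity. Intercepts and covariate
coefficients get Normal(0, 5): with a binary outcome and a full set of
random effects the model is identified through its priors, so a flat
intercept prior is deliberately avoided. All of these are adjustable via
`hyper_priors()`.

## Data model

A `multiplex_network` holds a roster (ids plus an `is_ego` flag), named
layers, and a $J \times J \times M$ array of 0/1/NA cells. Three design
decisions matter:

* **Self-ties are structurally excluded.** The diagonal is never observed
  and never modelled; sender effects concern flows to *others*.
* **Rectangular observation.** Roster members who are not egos (no recorded
  outgoing choices) stay in the roster: they have receiver effects and
  latent dyadic slots, and only their *outgoing* cells are masked from the
  likelihood. This uses the full printed design of ego/alter rosters rather
  than dropping alters.
* **Absent edges are observed zeros.** Edge-list files record placed
  coins/tokens only; an unlisted ego-to-alter pair is a 0, not missing
  data. This matches how roster-based games are coded.

Exactly `(#egos) * (J-1) * M` cells enter the likelihood.

## Inference

No general-purpose gradient-based MCMC engine is available to this package
as a dependency, so it carries its own: the joint log-density and its
analytic gradient are written in C++ (including reverse-mode differentiation
through the canonical-partial-correlation construction of the Cholesky
factors and through $\rho = \Gamma\Gamma^\top$ for the symmetry penalty),
and sampling uses the No-U-Turn criterion over leapfrog trajectories with

* dual-averaging step-size adaptation (target acceptance 0.8 by default,
  `adapt_delta`),
* a diagonal mass matrix estimated from a single warmup window (iterations
  25%–70% of warmup, shrunk towards a small constant), after which step-size
  adaptation restarts,
* a maximum tree depth of 10 and the standard divergence threshold (an
  energy error of 1000).

Unconstrained parameterization: log scales (with exponential-prior plus
Jacobian terms) and tanh-transformed canonical partial correlations for the
correlation factors (with LKJ plus transform-Jacobian terms). The C++
density is tested against an independent pure-R implementation of the same
joint density (they agree to machine precision) and the analytic gradient
against central finite differences.

Initialization follows the non-centered geometry: raw effects at zero,
scales at their prior means, correlation factors at the identity, intercepts
at zero, plus a small jitter (sd 0.01) to break symmetry between chains. All
randomness flows through R's RNG, so fits are exactly reproducible given
`seed`, chain count and iteration counts on a fixed platform.

Summaries use posterior means and **equal-tailed** credible intervals (89%
by default, i.e. the 5.5% and 94.5% quantiles). Equal-tailed intervals were
chosen over HPD intervals for quantile stability and reproducibility.
Convergence is monitored with split-$\hat R$ and an autocorrelation-based
effective sample size (Geyer initial positive-pair truncation); both are
hand-implemented and checked against white-noise and divergent-chain
oracles. In `correlation_report()` an off-diagonal entry is flagged
*reliable* when its credible interval excludes zero — a display convention,
not a hypothesis test.

## The simulator and the recovery experiment

`simulate_multiplex()` runs the generative model exactly as written: raws
from unit normals, the two non-centered transforms, Bernoulli cells for all
ordered non-self pairs, then the ego mask. Ground truth is specified on the
interpretable scale (SDs and correlation matrices; `assemble_block_rho()`
builds and PD-checks the block-structured dyadic target) and intercepts can
be solved from target marginal densities by integrating the logistic over
the random-effect distribution (`eta_for_density()`).

The default fixture (`simulation_config()`) is a 30-person community with
three layers (give/exploit/rate) at marginal densities 0.10, 0.40, 0.05 —
mimicking the range seen in published roster-based game data, where
exploitation layers are dense (~0.4–0.6) and punishment/rating layers are
sparse (~0.01–0.13).

The recovery condition (`recovery_config()`) is J = 50 (all egos), M = 3,
unit scales, within-layer dyadic reciprocities (0.6, 0.2, 0.6), one
within-person cross-layer dyadic correlation of −0.5, one generalized
correlation of 0.5, at marginal densities (0.30, 0.50, 0.20). Two deliberate
choices:

* *Positive definiteness constrains joint truths.* With within-layer
  reciprocities of 0.6 on two layers, a within-person cross-layer
  correlation $c$ between them must satisfy $c^2 < (1-b_1)(1-b_2)$; at
  $b_1 = b_2 = 0.6$ that bounds $|c| < 0.4$, so the −0.5 entry is paired
  with reciprocities (0.6, 0.2) on the layers it couples.
* *Density determines identification.* The number of reciprocated dyads —
  the information that identifies within-layer reciprocity — scales with
  density squared. At $J \le 50$ a layer of density 0.05 is expected to
  contain only a handful of reciprocated pairs, so no method can recover the
  sign of its reciprocity; the recovery layers are therefore kept at
  moderate densities, while sparse layers are exercised by the default
  fixture and the descriptive statistics.

What passing recovery shows — and what it does not: the experiment confirms
that the estimator finds the right signs for strong correlations and that
the credible intervals have roughly nominal coverage *under the model's own
generative process* at desk scale. It does not show that real field data
satisfy the model's assumptions (no covariate confounding, exchangeable
dyads, logistic link), and posterior means of correlation parameters are
noticeably shrunk towards zero at these sizes — sign and coverage, not
point-estimate magnitude, are the scorable quantities. Published
community-scale estimates (hundreds of people, tens of thousands of
observed cells) require the original field data and community-scale MCMC
and are not reproduced by this package's tests.

## Descriptive statistics

`summary()` on a network reports, per layer: directed edge count, density
$E / (V(V-1))$, edge reciprocity (the probability that a tie is
reciprocated), transitivity, and mean shortest-path distance, alongside the
reputation score (in-degree as generous minus in-degree as selfish).
Published tables rarely state the exact conventions, so ours are explicit:

* transitivity is the *global clustering coefficient of the symmetrized
  (undirected) graph* — the common software default; a directed-triplet
  convention would give different values;
* mean distance is over *directed* geodesics, averaging only ordered pairs
  with a finite path (so sparse layers still get finite values);
* all statistics are computed over the full roster, isolates included.

These statistics are verified against exhaustive brute-force enumeration on
all random digraphs with up to 6 nodes across 200 seeds.

## Numerical choices and degenerate inputs

* Bernoulli log-masses use the stable log-sigmoid form; naive
  `log(plogis(theta))` is never evaluated.
* The Cholesky construction floors the remaining squared row norm at
  1e-14 to keep gradients finite at extreme partial correlations.
* `assemble_block_rho()` rejects non-PD targets and reports the minimum
  eigenvalue; correlation matrices from Cholesky factors are valid by
  construction (unit diagonal, eigenvalues ≥ −1e−8 numerically).
* An edgeless layer has density, reciprocity and transitivity 0 and an
  undefined mean distance (`NA` in `summary()`, an error when requested
  directly).
* A single-layer model (M = 1) has an empty symmetry penalty: the block
  constraint is vacuous.
* Constant posterior draws yield `NA` diagnostics rather than spurious
  values.

## Problem sizes used by the test suite

The package's own checks run at reduced scale, chosen to exercise every
code path while staying desk-sized: the recovery experiment uses J = 50,
M = 3, 2 chains of 800 warmup + 800 sampling iterations (about three
minutes on one core); the grid-integration check uses a 4-person
intercept-only model; Monte-Carlo transform checks use 1e5 draws.
Full-scale fits (hundreds of people, M = 5) are supported by the same code
path but are not part of the test suite.

## Known limitations

* Outcomes are binary only; count-valued allocations are out of scope.
* Posterior correlation magnitudes are prior-shrunk at small J; treat desk-
  scale point estimates as conservative.
* The sampler is single-threaded; chains run sequentially.
* `diagnose()` implements classic split-$\hat R$ (no rank normalization).
* The "reliable" flag is a display convention on one interval level and
  should not be read as a test with controlled error rates.
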