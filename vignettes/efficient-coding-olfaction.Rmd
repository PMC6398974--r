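---
title: "Efficient coding of olfactory receptor abundances: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Efficient coding of olfactory receptor abundances: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfadapt)
```

## The model

The olfactory epithelium contains many olfactory sensory neurons (OSNs),
each expressing a single receptor type out of a genetically fixed
repertoire of $M$ types. All OSNs of a type pool onto glomeruli in the
olfactory bulb, so the information the brain receives is carried by $M$
pooled channels. `olfadapt` asks: given a fixed total budget of
$K_{tot}$ neurons, how many neurons $K_a$ should express each receptor
type $a$ so that glomerular responses carry as much information as
possible about the odor environment?

Three ingredients define the problem.

**Environment.** Olfactory scenes are summarized as a concentration
vector $c \in \mathbb{R}^N$ over a panel of $N$ odorants, modeled as
Gaussian, $c \sim \mathcal{N}(c_0, \Gamma)$. This is a maximum-entropy
approximation constrained by means and covariances; it deliberately
ignores the sparse, episodic structure of real olfactory scenes (see
*Limitations*).

**Response.** A single neuron of type $a$ responds linearly with gain
$S_{ai}$ per unit concentration of odorant $i$, plus Gaussian noise of
variance $\sigma_a^2$. A glomerulus pooling $K_a$ such neurons responds

$$ r_a = K_a \sum_i S_{ai} c_i + \sqrt{K_a}\,\eta_a, \qquad
   \eta_a \sim \mathcal{N}(0, \sigma_a^2), $$

the $\sqrt{K_a}$ arising because independent per-neuron noise adds in
variance. With this scaling the signal-to-noise matrix of the pooled
channels is exactly $K \Sigma^{-1} Q$ below, which is what makes the
information formula close; the noise scaling and the response model are
two faces of the same assumption.

**Objective.** Because everything is Gaussian, the mutual information
between responses and concentrations is

$$ I(r, c) = \tfrac{1}{2} \operatorname{Tr} \log\!\left( \mathbf{1} +
   K \Sigma^{-1} Q \right), \qquad Q = S \Gamma S^{\mathsf T}, $$

with $K = \mathrm{diag}(K_1,\dots,K_M)$ and
$\Sigma = \mathrm{diag}(\sigma_1^2,\dots,\sigma_M^2)$. The *overlap
matrix* $Q$ is the covariance of the noiseless glomerular signals; its
diagonal over the noise variances is the per-receptor squared SNR. The
environment mean $c_0$ never appears: ever-present odors carry no
scene-to-scene information, so chronic exposure leaves the optimum
unchanged (the package asserts this bitwise in its tests).

The optimal repertoire solves

$$ \max_{K_a \ge 0,\ \sum_a K_a = K_{tot}} I(r, c). $$

### Why the optimization is benign

Writing $v_a = \Gamma^{1/2} S_a^{\mathsf T}$ for the whitened affinity
profile of receptor $a$, the determinant identity
$\det(\mathbf{1}_M + K\Sigma^{-1}Q) = \det(\mathbf{1}_N + \sum_a
(K_a/\sigma_a^2) v_a v_a^{\mathsf T})$ shows the objective is a logdet
of an *affine* function of $K$ — hence concave. The feasible set is a
simplex, so there are no spurious local optima and the maximal
information value is unique. This is the same structure as classic
water-filling over parallel Gaussian channels, generalized to
correlated channels. `optimal_distribution()` therefore uses a single
deterministic start (uniform) rather than random restarts; restarts
remain available via `n_restarts` as a safeguard for nearly degenerate
inputs (e.g. duplicated receptors, where the optimal *allocation* is
non-unique even though the optimal *information* is — in that case the
symmetric solution is returned and comparisons should be made on $I$,
not on $K$). Determinism has a practical payoff: re-solving an
identical problem returns bitwise identical abundances, so
no-op perturbations (e.g. subsampling with nothing removed) give
Pearson correlation exactly 1.

The solver runs projected gradient ascent with Barzilai–Borwein steps
and Euclidean projection onto the simplex, then polishes with an
active-set Newton step using the analytic Hessian
$H_{ab} = -\tfrac12 G_{ab} G_{ba}$, where
$G = \Sigma^{-1} Q (\mathbf{1} + K\Sigma^{-1}Q)^{-1}$ is also the
gradient's source ($\partial I/\partial K_a = \tfrac12 G_{aa}$). All
resolvents are evaluated through the symmetric similarity
$\mathbf{1} + K^{1/2}\Sigma^{-1/2} Q \Sigma^{-1/2} K^{1/2}$, which is
well conditioned for every feasible $K$ including the boundary.
Convergence is declared when the relative Karush–Kuhn–Tucker (KKT)
residual — the spread of the gradient over expressed types plus any
gradient excess on unexpressed ones, normalized by the multiplier —
falls below `tol` (default $10^{-6}$).

### Analytic limits

Two closed forms serve as independent checks. At high SNR
($K_{tot} \to \infty$),

$$ K_a \approx \frac{K_{tot}}{M} -
   \left( \sigma_a^2 A_{aa} - \overline{\sigma^2 A} \right),
   \qquad A = Q^{-1}, $$

a near-uniform allocation corrected by the noise-scaled diagonal of the
inverse overlap matrix (`highsnr_distribution()`; negative entries of
the raw asymptotic formula are returned as-is unless `project = TRUE`).
At very low $K_{tot}$ the whole budget concentrates on
$\arg\max_a Q_{aa}/\sigma_a^2$ (`lowsnr_support()`; ties broken toward
the lowest index). Between the limits, receptor diversity grows with
the budget in step transitions (`receptor_count_curve()`, with a type
counted as expressed when $K_a > 10^{-3} \cdot K_{tot}/M$; the
threshold separates the zero cluster from the first plateau).

## Birth/death dynamics

In mammals OSNs turn over continuously, so the optimal repertoire must
be reached dynamically. The package integrates

$$ \frac{dK_a}{dt} = \alpha \left\{ K_a - \lambda K_a^2 -
   \sigma_a^2 (R^{-1})_{aa} K_a^2 \right\}, $$

where $R = \mathrm{diag}(K)\, Q\, \mathrm{diag}(K) +
\mathrm{diag}(K \sigma^2)$ is the response covariance at the current
abundances (`response_covariance()`). Birth is experience-independent;
the death rate contains a density term $\lambda K_a$ and an
experience term read off the inverse response covariance. Without the
experience term the dynamics are pure logistic growth saturating at
$K_a = 1/\lambda$, so $M/\lambda$ sets the asymptotic total population.

At any interior fixed point, substituting the identity
$\sigma_a^2 (R^{-1})_{aa} K_a^2 = K_a \big[(\mathbf{1} +
\Sigma^{-1} Q\, \mathrm{diag}(K))^{-1}\big]_{aa}$ and
$\big[(\mathbf{1} + \Sigma^{-1} Q \mathrm{diag}(K))^{-1}\big]_{aa} =
1 - 2 K_a\, \partial I/\partial K_a$ turns the stationarity condition
into $\partial I / \partial K_a = \lambda/2$ for every surviving type:
exactly the KKT condition of the constrained maximization with
multiplier $\mu = \lambda/2$. The death coefficient thus picks the
emergent budget implicitly ($\mu(K_{tot}) = \lambda/2$), and the
dynamics relax to the information optimum at that budget — verified in
the tests by integrating random instances and checking the endpoint's
KKT residual and its distance to the independently computed optimum.

**Numerics.** The integrator is explicit Euler with `dt` chosen so
$\alpha\,dt \le 10^{-2}$, halving the step when an abundance would
overshoot below zero, and clipping at zero (zero is an absorbing state
of the exact flow; the growth rate vanishes as $K_a \to 0$, which is
also why rare types converge slowly). The experience term is always
evaluated through the algebraic form above rather than by inverting
$R$: the two agree to machine precision on the interior (unit-tested),
but the stable form remains finite when abundances hit zero, where $R$
is singular and a literal inverse would need pseudo-inverse fallbacks.
Trajectories are recorded on a log-spaced time grid, matching the
logarithmic time axis on which convergence spreading is visible.

## Synthetic ensembles

`random_environment()` draws covariances
$\Gamma = D^{1/2} C D^{1/2}$: a random correlation matrix $C$ obtained
by normalizing $G G^{\mathsf T}$ to unit diagonal ($G$ an
$N \times \lceil \beta N \rceil$ standard-normal matrix), scaled by
lognormal variances. $\beta$ tunes correlation strength — more columns
mean weaker off-diagonal correlations (at $\beta = 8$, the default,
typical inter-odorant correlations are a few percent); the lognormal
defaults are $\mu = 0$, $\sigma_{\ln} = 1$. Perturbation generators
cover single-odorant variance increases (rank-one PSD updates), sets of
boosted odorants (default: 10 odorants boosted by 100 times the median
base variance), odor-content-disjoint environment pairs (each odorant
retains appreciable variance in at most one environment; the silenced
half sits at a floor of $10^{-4}$ times the median variance), and
square-root jitter $(\Gamma^{1/2} + \epsilon Z)(\Gamma^{1/2} +
\epsilon Z)^{\mathsf T}$, which perturbs without ever leaving the PSD
cone. `random_sensing_matrix()` controls tuning width: each receptor
senses `round(width * N)` odorants strongly (lognormal$(0, 0.5)$
magnitudes) and the rest at 2% of that scale. All generators are pure
functions of (parameters, seed) and restore the session RNG stream.

**What the ensembles do not emulate.** Real affinity panels have
strongly correlated receptor profiles (phylogenetically related
receptors share ligands), response magnitudes spanning orders of
magnitude, and sign structure (inhibitory responses). The synthetic
rows are independent given the width, so synthetic overlap matrices are
much better conditioned than real ones. Consequently the *absolute*
scale of abundance changes between environments is smaller than with
measured affinities, and passing tests demonstrate the model's
mechanics and trends — not quantitative agreement with any measured
repertoire. Supplying a measured sensing matrix via
`read_sensing_matrix()` is the intended path to quantitative
predictions.

## Choice of noise scale

Only the combination $K \Sigma^{-1} Q$ enters the objective, so the
regime — noise-dominated, intermediate, or effectively noiseless — is
set by $\sigma^2$ relative to the signal scale and the budget. Rather
than fixing an arbitrary variance, the experiment drivers use
`calibrate_noise(Q, Ktot, snr2)`, which sets a flat $\sigma^2$ so that
the per-glomerulus squared SNR at the uniform allocation,
$(K_{tot}/M)\,\overline{Q_{aa}}/\sigma^2$, equals `snr2`. The packaged
experiments use `snr2 = 10`, placing the reference budget in the
intermediate regime where abundances are non-uniform and adapt visibly
— the biologically relevant setting, since selection would not maintain
neurons beyond the point of diminishing information returns. With the
calibration anchored at $K_{tot} = 25\,000$ for the fly-shaped panel,
smaller budgets recover the expected regimes: at $K_{tot} = 100$ most
types are silent (low SNR), at $2\,000$ the repertoire is strongly
non-uniform, at $25\,000$ it is near-uniform with small adaptive
corrections.

## Problem sizes and tolerances

The shipped experiments and tests run at deliberately modest sizes
chosen to exercise every code path at desk scale: fly-shaped panels of
24 receptors by 110 odorants (59 x 63 for the mammalian-shaped
exposure experiment), 50 environment pairs for change statistics, 10
subsampling trials, and 24 exposure replicates. Optimizer tolerance is
a relative KKT residual of $10^{-6}$ (iteration cap $10^4$); dynamics
runs use horizons long enough that the endpoint residual falls below
$10^{-3}$. Grid-search cross-checks use a simplex resolution of
$K_{tot}/2000$ with closed-form small-matrix determinants, keeping the
oracle independent of the package's eigendecomposition path. Input
validation symmetrizes covariances up to a relative asymmetry of
$10^{-8}$ and clips eigenvalues down to $-10^{-10}$ of the largest;
anything worse is rejected rather than silently repaired.

## Limitations

- The linear-Gaussian response model ignores saturation and competitive
  binding; it is a linearization around an operating point, and odor
  concentrations in nature routinely leave that range.
- Gaussian scene statistics ignore the sparseness of olfactory scenes
  (odors come as discrete objects); a mixture model would be the
  natural extension.
- Abundances are treated as real numbers; predictions for types with
  very few neurons should be read as rates, not counts.
- Spike timing carries odor information that a firing-rate model cannot
  represent.
- The dynamics model demographic effects only through the deterministic
  ODE; demographic (birth/death) noise matters precisely for the rare
  types that converge slowest.
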