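---
title: "Weighted stochastic block models in wsbm: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted stochastic block models in wsbm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsbm)
```

## The model

`wsbm` models a directed graph on `n` vertices with no self-loops through
three coupled layers. Latent block labels are drawn independently,
$Z_i \sim \mathcal{M}(1; \theta_1, \dots, \theta_Q)$. Conditional on the
labels, edge indicators are independent Bernoulli draws,
$X_{ij} \mid Z_i = q, Z_j = l \sim \mathcal{B}(\pi_{ql})$ for $i \neq j$,
and each existing edge carries a positive weight
$Y_{ij} \mid X_{ij} = 1 \sim \mathrm{Ga}(\alpha_{ql}, \beta_{ql})$, while
$Y_{ij} = 0$ whenever $X_{ij} = 0$. The weight distribution is gamma in
the **shape/rate** parameterisation — we state this prominently because
shape/scale is an equally common convention and silently mixing the two
inverts every rate estimate. The gamma family is flexible per block
pair: shapes below one give sharply decaying, exponential-like weights,
large shapes give concentrated, nearly Gaussian ones.

The complete-data log-likelihood sums over ordered pairs
$$
\mathcal{L}_1 = \sum_{i \neq j} X_{ij}\{\log \pi_{z_i z_j} +
  \log f(Y_{ij}; \alpha_{z_i z_j}, \beta_{z_i z_j})\}
  + (1 - X_{ij}) \log(1 - \pi_{z_i z_j}),
$$
and the observed-data log-likelihood marginalises $\mathcal{L}_1$ over
all $Q^n$ label allocations. `exact_loglik()` evaluates that sum by
direct lexicographic enumeration with a max-shifted log-sum-exp; it
refuses problems with more than $10^6$ allocations because it exists as
a brute-force oracle for tests, not as an estimator.

### Regularity assumptions and the compact box

The model is identified only under separability conditions: no two
blocks may share identical connectivity probabilities to and from every
block (and analogously for the gamma pairs), edge probabilities must be
bounded away from 0 and 1, and block proportions bounded away from 0.
`check_assumptions()` audits a parameter set for all of these.

One constraint deserves emphasis because it is numerical, not merely
theoretical. Writing the gamma density at its mean with
$y = a/b$ fixed, Stirling's approximation gives
$f(y; a, b) \approx \sqrt{a} / (\sqrt{2\pi}\, y)$, which grows without
bound as $a \to \infty$. A fitted shape can therefore run away to
infinity on a near-constant weight cell and the likelihood degenerates.
All estimation in `wsbm` is consequently carried out over a compact box
(`parameter_box()`), by default $\alpha, \beta \in [10^{-3}, 10^3]$ and
$\pi \in [\zeta, 1 - \zeta]$ with $\zeta = 10^{-6}$. The box was chosen
once, wide enough to contain both built-in benchmark settings with two
orders of magnitude to spare; estimates that hit its boundary are
flagged. Note that heavy-tailed recovery-error summaries (means of
Frobenius errors for $\alpha$, $\beta$ at small $n$) depend on this
choice: a tighter box truncates outlying shape estimates and shrinks
those means, so reported values are only comparable across
implementations at the same box.

## Variational estimation

The posterior over labels is approximated by a product of per-vertex
multinomials with membership matrix $\tau$ ($n \times Q$, rows on the
simplex), chosen to maximise the evidence lower bound $J$ (see
`elbo()`). The fit alternates:

1. **Memberships.** The stationarity condition for row $i$ of $\tau$
   collects every pairwise term involving vertex $i$ — for a *directed*
   graph that means both the outgoing pairs $(i, j)$ with parameters
   $\pi_{ql}, \alpha_{ql}, \beta_{ql}$ and the incoming pairs $(j, i)$
   with $\pi_{lq}, \alpha_{lq}, \beta_{lq}$. `update_tau()` implements
   the two-sided update; dropping the incoming half would not maximise
   $J$ over $\tau_i$ and breaks the ascent property below. Rows are
   updated **sequentially** (Gauss–Seidel) in compiled code, each row
   set to its exact conditional maximiser via a max-shifted softmax.
   Because every row update is an exact coordinate maximisation, the
   sweep can only increase $J$ — no damping is needed (a `damping`
   argument exists for experimentation; a damped *parallel* scheme is
   the common alternative but oscillates on near-symmetric graphs and
   offers no ascent guarantee). Entries are floored at $10^{-12}$ and
   renormalised so that entropies stay finite. The default of at most
   10 sweeps per outer iteration simply splits work between the two
   loops; the outer loop supplies the remaining iterations.
2. **Proportions and edge probabilities.** Closed forms:
   $\tilde\theta_q = \frac1n \sum_i \tau_{iq}$ and
   $\tilde\pi_{ql} = \sum_{i \neq j} \tau_{iq}\tau_{jl} X_{ij} /
   \sum_{i \neq j} \tau_{iq}\tau_{jl}$, clipped into
   $[\zeta, 1-\zeta]$. These are the exact maximisers of $J$.
3. **Gamma parameters.** The gamma likelihood has no closed-form joint
   maximiser, but the closed-form moment estimators of Ye–Chen type,
   built from the per-cell statistics $W = \sum \tau\tau'$,
   $U = \sum \tau\tau' Y$, $V = \sum \tau\tau' \log Y$,
   $S = \sum \tau\tau' Y \log Y$ over existing edges:
   $$\tilde\alpha = \frac{WU}{WS - VU}, \qquad
     \tilde\beta = \frac{W^2}{WS - VU},$$
   are strongly consistent and essentially as accurate as the MLE at
   realistic edge counts. `ye_chen_update()` clips them into the box
   and handles two degeneracies explicitly: a cell with `W < 1e-6`
   (effectively no edges) falls back to the pooled global estimate, and
   a cell with $WS - VU \le 0$ (zero weighted variance of $\log Y$,
   e.g. all weights identical) takes the zero-variance limit — shape at
   the upper box bound with the rate matched to the cell mean — and is
   flagged.

### Keeping the bound monotone

Steps 1 and 2 are exact coordinate ascents of $J$; step 3 is not — the
moment estimator maximises nothing. In practice this matters: iterating
the three steps verbatim can enter a **period-2 limit cycle** in which
the gamma update and the membership update repeatedly undo each other
and the ELBO oscillates forever. `wsbm` therefore applies a
generalized-EM guard: per block pair, the moment proposal is accepted
only if it does not lower that cell's gamma contribution
$W(\alpha\log\beta - \log\Gamma(\alpha)) + V(\alpha - 1) - U\beta$ at
the current $\tau$. Wherever the fit converges regularly the proposal
is accepted and the final estimates are exactly the closed-form ones;
the guard binds only in pathological cells. With it, the recorded ELBO
trace is non-decreasing (tests assert increments $\ge -10^{-8}$, which
absorbs floating-point cancellation in sums of order $n^2$ terms).

### Initialisation, restarts, seeds, convergence

Published block-model studies rarely state their initialisation, so we
fixed a default once: the first restart clusters the rows of
$[X \,\|\, X \circ \log(1+Y) \,\|\, X^\top \,\|\, (X \circ \log(1+Y))^\top]$
with k-means into $Q$ groups and softens the labels to membership 0.9
(rest spread uniformly); the remaining `restarts - 1` (default 10 in
total) start from softened uniform random labels. The restart with the
highest final ELBO wins. A restart whose smallest fitted proportion
falls below $10^{-4}$ is marked degenerate, abandoned immediately (such
a block cannot refill) and excluded unless every restart degenerated,
in which case the fit fails with advice to lower `Q` — `wsbm_select()`
records such `Q` as missing rather than aborting its sweep. All
randomness flows from one master seed through a documented splitting
scheme (`restart r` gets child seed `r`; experiment replicate `r` at
size `n` derives its seed from the master seed, setting name, `n` and
`r`, so any grid subset reproduces in isolation). The outer loop stops
when the relative ELBO change drops below $10^{-8}$ (default cap 500
iterations); the inner sweep stops when the largest membership change
in a sweep is below $10^{-6}$.

Hard assignments take the row-wise argmax with ties broken toward the
lowest block index. Indices on disk (edge lists, reports) are 1-based.

## Choosing the number of blocks

`icl()` evaluates the approximate integrated completed likelihood: the
completed-data log-likelihood at the hard assignment with the fitted
parameters, plus $\sum_i \log \tilde\theta_{\tilde z_i}$, minus the
penalty $\tfrac{3}{2} Q(Q+1)\log\{n(n-1)\} + \tfrac{Q-1}{2}\log n$. Two
deliberate choices: (i) the completed term uses the parameters the
variational fit produced, not a re-optimisation at the hard labels —
the standard fit-then-evaluate protocol; (ii) the penalty is used in
exactly this form even though a directed model has $3Q^2$ block-pair
parameters, which would suggest $\tfrac{3}{2}Q^2$ instead of
$\tfrac{3}{2}Q(Q+1)$ — the conventional form is kept as the default and
the directed count is available via `icl_penalty(form = "directed")`.
Ties in the argmax go to the smaller `Q` (parsimony).

## The simulation harness and what it does (not) show

`builtin_setting()` returns the two benchmark parameter sets used
throughout: a well-separated two-block model
($\theta = (0.7, 0.3)$, within-block edge probabilities 0.8/0.9 versus
0.2/0.3 between, gamma means ranging from 0.3 to 15) and a harder
three-block model whose gamma shapes span $0.02$ to $6$.
`recovery_experiment()` samples replicate graphs, fits at the true `Q`,
aligns labels by exhaustive permutation search (misclassification
count, ties broken by the Frobenius distance of the permuted
edge-probability matrix; feasible for $Q \le 10$) and aggregates
accuracy and the aligned errors $\lVert\tilde\theta-\theta^*\rVert_2$,
$\lVert\tilde\pi-\pi^*\rVert_F$, $\lVert\tilde\alpha-\alpha^*\rVert_F$,
$\lVert\tilde\beta-\beta^*\rVert_F$ with Monte-Carlo standard errors.
`icl_frequency_experiment()` tabulates the block count selected per
replicate.

The generator emulates exactly the model's own assumptions —
independent multinomial labels, independent Bernoulli edges,
independent gamma weights. Real networks violate most of these
(degree heterogeneity, reciprocity, transitivity, non-gamma weights),
so passing recovery tests certifies the *inference machinery*, not the
model's adequacy for any particular data set. Two further caveats on
comparing recovery tables across implementations. First, with perfect
label recovery the estimators are closed-form empirical quantities, so
their error distributions are dictated by the generative model itself:
the L2 error of $\tilde\theta$ cannot fall below the multinomial
sampling noise of the block counts (about $0.10$ at $n = 25$ for the
two-block setting, by direct binomial computation), and the Frobenius
error of $\tilde\pi$ cannot fall below the binomial noise of the
empirical edge frequencies. Published tables that quote smaller values
than these floors cannot be matched by any correct implementation, and
this package's acceptance tests document exactly which cells reproduce
and which sit below the floor. Second, the mean $\alpha$/$\beta$ errors
at small $n$ are heavy-tailed (a handful of replicates dominate the
mean through near-degenerate cells), so those means are sensitive to
the compact box and to Monte-Carlo luck; medians would be stabler but
means are reported for comparability.

Problem sizes used by the shipped study runs (`scripts/acceptance.R`):
25 replicates at $n \in \{25, 100\}$ (two-block) and
$n \in \{25, 50\}$ (three-block), 10 replicates at $n = 500$, and 8
ICL-selection replicates at $n \in \{250, 1000\}$ with candidate
$Q \in 1{:}4$ and 2 restarts; the test suite uses 50 replicates at the
small sizes. These sizes keep a full run in the minutes range on one
core while leaving standard errors small relative to the effects being
checked.

## Known limitations

* Boundary edge probabilities $\pi_{ql} \in \{0, 1\}$ are excluded by
  assumption; saturated cells are clipped to $1 - \zeta$.
* The mean-field bound is known to be loose for small, weakly separated
  graphs; the enumeration oracle shows the gap directly for $n \le 7$.
* Exhaustive label alignment is factorial in `Q` (capped at 10).
* The sampler, not the fitter, is the scalability limit's complement:
  fitting is $O(n^2 Q^2)$ per sweep, so graphs beyond a few thousand
  vertices become expensive on one core.
* Covariate-dependent edge probabilities or weight means are out of
  scope, as are undirected-model likelihoods — undirected *input* is
  supported by explicit symmetrisation at the I/O layer, after which
  the directed model is fitted (a documented caveat, never silent).

## A minimal run

```{r example, eval = FALSE}
params <- builtin_setting("two_class")
s <- sample_wsbm(params, n = 100, seed = 42)
fit <- wsbm(s$graph, Q = 2, restarts = 5, seed = 1)
align_labels(fit, s$z, true_params = params)
wsbm_select(s$graph, 1:3, restarts = 3, seed = 7)$Q
```
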