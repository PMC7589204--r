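---
title: "Mixture-model beta diversity and medoid clustering: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-model beta diversity and medoid clustering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

microclust clusters microbiome samples from sparse OTU count tables by
modelling, one OTU at a time, the population distribution of latent
abundance rates, conditioning that model on each subject's observed count,
and measuring pairwise L2 distances between the resulting subject-specific
distributions. This vignette is the package's own account of the method:
the model and its assumptions, the tunable parameters, the synthetic-data
generator, the numerical choices, and the limits of what the simulations
show.

## The per-OTU mixture model

### Observation model and assumptions

For OTU counts $n_1, \dots, n_I$ over $I$ subjects we assume
$n_i \mid r_i \sim \mathrm{Poisson}(r_i\, t_i)$, where $r_i$ is the
subject's latent abundance rate for this OTU and
$t_i = N_i / \bar N$ is the subject's *relative resolution* — total reads
over the cohort mean, so $\mathrm{mean}(t) = 1$. Deeper-sequenced samples
see proportionally larger counts; `compute_relative_resolution()` computes
$t$ from the full (unfiltered) table, and an externally supplied $t$ is
accepted. Samples with zero total reads have no defined resolution; the
default is an error, and the pipeline uses an epsilon guard (half the
smallest positive total) because fully empty samples arise legitimately in
very sparse tables.

The population law of $r$ is approximated by a finite mixture over a
*fixed* component grid; only the weights are estimated:

* a **structural-zero point mass** ($r = 0$; the subject never carries the
  taxon),
* three **low-rate Gamma components** with shape $0.5$ and means
  $0.1, 0.3, 0.6$ — a left-skewed set for rates near zero whose counts are
  mostly sampling zeros,
* **small-count components** $\Gamma(n+1, 1)$ for $n = 0..c_{mid}$, the
  posterior of a Poisson rate given count $n$ under a flat prior,
* **high-range components** $\Gamma(k_j+1, 1)$ with $k_j$ the rounded
  exponentials of an even grid on $[\log c_{mid}, \log C]$ — log-spacing
  matches the thinning tail density of real counts,
* a **high point mass** absorbing all counts above the cutoff $C$.

A $\Gamma(\alpha,\beta)$ rate observed through Poisson thinning gives
negative-binomial counts $\mathrm{NB}(\alpha, \beta/(t_i+\beta))$; the
package evaluates these by the stable multiplicative recurrence rather than
repeated density calls.

Defaults, and why: $C$ is the 99th percentile of the OTU's counts (rounded
up, floored at 10) — large enough that the tail bin is genuinely sparse,
small enough to keep the category space tight; $c_{mid} = \min(10, C-1)$
gives every small count its own component where small counts dominate;
5 high-range knots. All are arguments of `build_component_grid()`.

### Weight estimation

With aggregated counts $y_k = \#\{i : n_i = k\}$ for $k = 0..C$ plus a tail
bin, the weights solve

$$\hat w = \arg\min_w \sum_k \Big(y_k - I \sum_m w_m \bar p_{km}\Big)^2
\quad \text{s.t. } \textstyle\sum_m w_m = 1,\; w_m \ge 0,$$

where $\bar p_{km}$ is the component's bin probability averaged over the
subjects' resolutions. This is an equality-constrained non-negative
quadratic program, solved exactly by an active-set QP (`method = "qp"`); a
Lawson–Hanson NNLS with a heavily weighted sum-to-one row and final
renormalisation (`method = "nnls"`) is the second route, and the two agree
to ~1e-4 on well-conditioned grids. Adjacent grid components are
deliberately redundant (that is what makes the grid flexible), so the
*weights* of near-duplicate components are only identified up to their sum;
the *fitted distribution* — and everything downstream — is stable. A tiny
ridge (1e-10 of the Gram trace) keeps the QP positive definite.

One visible consequence: the structural-zero weight and the low-rate
components (whose count distributions put ~0.9 of their mass on zero) are
nearly collinear, so "structural mass" is best read as the zero weight
*plus* the sub-unit-mean component weights. Parameter-recovery checks that
target the zero weight alone therefore use candidate grids without the
low-rate block.

### Bootstrap model selection

`fit_otu_mixture()` resamples subjects with replacement $B$ times; every
candidate grid (default: $c_{mid} \in \{5, 10\}$ crossed with
$\{3, 5\}$ high knots, sharing one cutoff so objectives are comparable) is
fit to each resample; the grid with the smallest mean bootstrap objective
wins, ties toward fewer components; final weights are the renormalised mean
of the winning grid's bootstrap weight vectors. $B$ defaults to 50 for
single-OTU fits; the replicated studies below use $B = 10$ and the same
candidate family — at study scale the selection is very stable and the
extra replicates change third decimals.

### Subject-specific mixtures

Posterior component weights follow Bayes' rule,
$w_{i,m} \propto w_m\, p_m(n_i \mid t_i)$, with the structural zero
compatible only with $n_i = 0$ and the high mass only with $n_i > C$. Each
subject's *category distribution* over $(z, 0, 1, \dots, C, h)$ is
$P_i = w_i^\top P$ with $P$ the shared component-by-category matrix built
from subject-averaged pmfs — so $P_i(z)$ is exactly the subject's posterior
probability of being a structural zero, a coordinate *distinct* from an
observed zero count. The category order places $z$ before count 0; the CDF
metrics below inherit it.

## Distances

Three L2 norms between subject mixtures, per OTU:

* **discrete PDF**: $\lVert P_i - P_j \rVert_2$ over the categories;
  equivalently the quadratic form $(w_i-w_j)^\top P P^\top (w_i-w_j)$ —
  the two routes agree to 1e-10 because $P$ is shared across subjects;
* **discrete CDF**: the same on running sums in category order;
* **continuous CDF**: $\sqrt{\int_0^C [F_i(k)-F_j(k)]^2\,dk}$. Component
  CDFs are step functions constant on unit intervals, so the Gram matrix
  $G_{q_1 q_2} = \int_0^C F_{q_1}F_{q_2}\,dk$ equals
  $\sum_{k=0}^{C-1} F_{q_1}(k)F_{q_2}(k)$ *exactly*; no quadrature error
  enters. Eigenvalues in $[-10^{-8}, 0)$ from round-off are clamped; more
  negative values raise an error.

Per-OTU matrices are combined across OTUs by the root-sum-of-squares rule
by default (per-OTU distances as orthogonal coordinates); `"sum"` and
`"mean"` are available since the aggregation is a genuinely open choice.

Baselines: Manhattan, Euclidean, Bray-Curtis, weighted and generalized
($\alpha = 0.5$) UniFrac, all on relative abundances, optionally after
`log(x + 1e-8)`. The ratio metrics add $10^{-8}$ to their denominators so
fully empty pairs give 0 rather than NaN; generalized-UniFrac branch terms
with zero combined abundance contribute 0 (the limit of the summand). The
log pseudo-count mirrors the denominator guard; no canonical value exists,
so it is prominent in the interface.

## Clustering and validation

PAM minimises the summed distance to the nearest medoid: greedy BUILD
initialisation, then steepest-descent swaps (all medoid/non-medoid
exchanges evaluated; the single best strictly improving swap applied per
iteration; all ties toward the lowest index). A single-start hill climber
can stall: even the canonical reference implementation misses the
exhaustive optimum on a few percent of tiny random instances. `pam_cluster()`
therefore adds seeded random restarts (default 5) and keeps the best local
optimum, which empirically attains the exhaustive optimum on all tested
instances with $n \le 8$. The replicated studies run BUILD only
(`restarts = 0`): fully deterministic, and on hundreds of samples restarts
change costs marginally while tripling runtime.

Internal indices: Dunn (single-linkage separation over maximum diameter),
Silhouette (singletons contribute 0), Xie-Beni and Wemmert-Gancarski in
their standard medoid forms — the latter three have no formulas in the
source literature for this method, so the standard definitions are used and
tested against brute-force oracles. `select_k()` takes the extremum in the
index's direction, ties toward smaller K.

External validation: **matched accuracy** maximises correct samples over
injective mappings between predicted clusters and true classes (unmatched
clusters count as errors; the provable lower bound on balanced truth is
$1/\max(c, k)$, not $1/k$); **matched-set Jaccard** averages
$|C \cap K|/|C \cup K|$ over matched pairs, which on balanced two-class
designs with symmetric errors equals $a/(2-a)$ for accuracy $a$ — the
relation that pins this reading of the Jaccard index (as opposed to
pairwise-comembership Jaccard).

## The synthetic-data generator

`simulate_dataset()` emulates sub-class-structured sparse count tables:
balanced subclasses (default 200 subjects each), 25 OTUs, resolutions
$t_i \sim U(2/3, 4/3)$. Per OTU: a mixture size $M \sim U\{5..15\}$; $M-1$
Gamma components with means log-uniform on $[2, 20]$ and integer shapes
1..5, with Dirichlet(1) relative weights, shared across subclasses; each
subclass draws its structural-zero weight $z_c$ from its own Beta
distribution; subjects are allocated multinomially, draw a rate from their
component ($r = 0$ for the zero component), and a count from
$\mathrm{Poisson}(r\,t_i)$.

Sparsity **is** the class signal: within a zero-proportion tier (realized
ZP low 13–27%, medium 39–61%, high 84–93%) the subclasses' Beta means
target evenly spaced realized-ZP levels across the tier interval, including
the endpoints — the reading under which the printed tiers, controlled by
per-subclass Beta parameters, constitute the between-class difference. The
structural-zero targets discount the average sampling-zero probability of
the positive mixture part (0.081, measured once by Monte Carlo at design
time); Beta standard deviations are an eighth of the interval width; and
every OTU is rejection-resampled (cap 100) until its realized ZP lies in
the tier interval. The component-mean range $[2, 20]$ matches the scale of
real genus-level OTU summaries (means of a few units, medians 0–3) and is
the smallest range feasible for the low tier, where sampling zeros alone
approach the 13% floor. `subclass_mode = "independent"` instead redraws the
whole mixture per subclass.

What the generator does **not** emulate: compositional (sum-constrained)
abundances, phylogenetic signal (trees for the UniFrac baselines are random
with exponential branch lengths), covariate effects, and longitudinal
structure. Passing simulations therefore show that the pipeline recovers
sparsity-driven structure under its own observation model — not that it
will stratify any particular real cohort.

## Study configuration and a known limitation

The replicated studies (`run_simulation_study()`, and
`scripts/acceptance.R`, which recomputes them from scratch) use 20
replicates per scenario, $B = 10$, the 2×2 candidate-grid family, PAM over
$K = 2..10$ with BUILD initialisation, and Dunn selection of $K$.

The dominant driver of external accuracy in these studies is the selected
$K$: matched accuracy degrades almost mechanically as $K$ grows past the
true number of subclasses, because samples in unmatched clusters count as
errors. On weakly separated data the Dunn index has no pronounced optimum —
its numerator is bounded below by the minimum cross-boundary distance and
its denominator shrinks as outlying groups are peeled off — so over a wide
candidate range the argmax often lands at large $K$ for the smoother
distance geometries. Restricting the sweep (e.g. $K \in 2..5$) or using an
index with a stronger small-$K$ preference changes the picture materially;
both are exposed as arguments (`k_range`, `index`). Users clustering real
data should treat the choice of index and sweep range as first-class
analysis decisions and run the sensitivity across all four indices, as the
real-data workflow in the source literature for this class of methods does.

```{r, eval = FALSE}
library(microclust)
st <- run_simulation_study(n_subclasses = 2, tier = "high",
                           metrics = c("l2_d_pdf", "l2_d_cdf", "euclidean"),
                           n_replicates = 20, base_seed = 1)
glance(st)
autoplot(st)
```

## Numerical choices, collected

* NB pmfs by multiplicative recurrence in linear time; log-space start.
* Exact piecewise-constant integration for the CDF Gram matrix; PSD clamp
  at $-10^{-8}$ relative.
* QP ridge $10^{-10}\cdot\mathrm{tr}$; NNLS penalty row $10^3 \max(y/I)$.
* Tie-breaks: lowest index (PAM assignment and swaps), smaller K
  (`select_k`), fewer components (bootstrap model selection).
* Seeds: every stochastic step (simulation, bootstrap, random PAM starts)
  takes an explicit seed; replicate $r$ of a study uses `base_seed + r`, and
  per-OTU fits derive seeds from the study seed plus the OTU index.
* Degenerate inputs: all-zero OTUs are skipped with a warning when fitting;
  all-zero samples get guarded resolutions and all-zero abundance rows (with
  a warning); empty filter results, missing tree leaves, incompatible
  subject counts all raise early, named errors.
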