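---
title: "Wavelength selection with EIAO: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelength selection with EIAO: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eiaoselect)
```

## 1. The model

Wavelength (band) selection is cast as minimization of the wrapper
objective over nonempty bit masks $m \in \{0,1\}^D$:

$$\mathrm{fitness}(m) \;=\; \alpha\,\rho(m) \;+\; (1-\alpha)\,\frac{|m|}{D},$$

where $\rho(m)$ is the misclassification rate of a $k$-nearest-neighbour
classifier ($k=3$, Euclidean distance) restricted to the selected bands,
and $|m|$ is the selected-band count. Both terms lie in $[0,1]$, so the
fitness does too; with $\alpha = 1$ it reduces to pure error minimization.
Lower is better throughout, and the objective is strictly increasing in
both the error and the subset size — a property the test suite checks by
sampling.

**Assumptions.** The KNN error is a serviceable proxy for downstream
classifier quality (the classic wrapper assumption); the internal split
used inside the fitness is fixed per run so that every candidate subset is
scored on identical data and fitness values are comparable; and features
are z-scored with training-partition statistics so that no band dominates
the metric by scale alone.

## 2. The optimizer

EIAO searches a continuous box ($[-4,4]^D$ by default) and maps positions
to masks through the sigmoid transfer $T(x) = 1/(1+e^{-x})$ with
threshold $C$. Each iteration, each agent runs three stages — differential
*collection* moves, *filtering* moves relative to a random reference agent
modulated by the subjective error $\Delta = \cos(\frac{\pi}{2}|\Gamma|)^\Xi$,
and *organization* moves around the global best scaled by
$\cos(\frac{\pi}{2}\Lambda^{1/3})$ with $\Lambda = 2(|\Gamma|-2)$ — with
greedy acceptance, followed by one Laplace crossover per iteration. The
stochastic factors ($\Xi$: subjective influence; $\Phi$: information
quality, decaying to 0 at the final iteration; $\Gamma$: reliability) are
redrawn per agent per iteration.

The enhancements over plain IAO are individually switchable
(`optimizer_config()` flags): chaotic-logistic initialization with elite
opposition-based learning, the second difference pair in stage 1, the
sine/cosine stage-2 form, the Lévy step in stage 3, and the Laplace
crossover. `iao_config()` turns them all off, and the test suite verifies
the ablation is trajectory-identical (bit-exact) to the flags-off run.

### Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `n_pop` | 20 | agents | common swarm size at this budget |
| `max_iter` | 50 | iterations | the reference iteration budget |
| `lb`, `ub` | −4, 4 | position units | sigmoid spans ≈ (0.018, 0.982), so both bit values stay reachable under $C=0.5$; a $[0,1]$ box would force all-ones masks |
| `elite_fraction` | 0.10 | fraction of N | elite group size for opposition learning |
| `mu` | 4 | logistic rate | the fully chaotic regime of the logistic map |
| `levy_exponent` | 1.5 | (1, 2] | standard Mantegna stability exponent |
| `levy_scale` | 0.01 | fraction of box width | cuckoo-search convention for step scale |
| `laplace_p`, `laplace_q` | 0, 0.5 | location, scale | small symmetric crossover spread; unstated upstream, chosen once |
| `alpha` | 0.99 | [0, 1] | dominant wrapper-selection convention; makes one band worth 0.01/D fitness |
| `knn_k` | 3 | neighbours | the stated wrapper classifier |

## 3. Numerical choices and ambiguity resolutions

Several printed formulas in the source material are ambiguous or
ill-typed; the package resolves them as follows (all configurable where it
matters, none revisited after testing began):

* **$\Xi$ (subjective influence).** The printed argument $\arccos(\gamma
  \times 10^4)$ is outside the domain of $\arccos$ for $\gamma > 10^{-4}$;
  implemented as $\Xi = 2\,\mathrm{mod}(3.648\,\nu(1-\beta_r)
  \arccos(\gamma_r)\cdot 10^4,\,1)$, so the mod-1 wrap makes the factor an
  effectively uniform chaotic multiplier in $[0,2)$.
* **$\Gamma$ (reliability).** The trailing term is read as
  $\log_{10}(\mathrm{iter}/\mathrm{max\_iter})/8$, keeping $|\Gamma|$
  moderate so $\cos(\frac{\pi}{2}|\Gamma|)$ stays meaningful; `iter = 0`
  is rejected (log of 0).
* **Signed powers.** $\Delta = \cos(\frac{\pi}{2}|\Gamma|)^{\Xi}$ with
  non-integer $\Xi$ and a possibly negative base uses the sign-preserving
  power $\mathrm{sgn}(c)|c|^{\Xi}$; $\Lambda^{1/3}$ is the real signed
  cube root, so negative $\Lambda$ is legal.
* **Laplace sampling.** The printed one-uniform recipe reuses the same
  draw for branch and magnitude, leaving an empty support band
  $[p,\,p+q\ln 2)$ (the tests verify the gap by enumeration). The default
  is the genuine two-uniform Laplace; the printed variant is available as
  `variant = "as_printed"`.
* **Binarization threshold.** $C$ is unspecified upstream; default is the
  fixed $C = 0.5$, with a per-dimension uniform-random mode provided since
  stochastic thresholds are standard for S-shaped transfers. An all-zero
  mask is repaired by setting one uniformly random bit, because fitness on
  the empty subset is undefined.
* **Greedy acceptance.** The binarized fitness landscape is piecewise
  constant in the continuous positions: most small moves flip no bit. With
  strictly-improving acceptance such moves are always rejected and the
  continuous dynamics freeze, which we observed as premature convergence.
  The package therefore accepts *ties* in stages 1–2 (whose candidates are
  relative to the agent itself, so tie acceptance lets the search drift
  across plateaus) but requires *strict* improvement in stage 3 and the
  crossover (whose candidates derive from the global best — accepting ties
  there collapses population diversity onto the incumbent). This is the
  one deliberate refinement of the stage contract, and it is what the
  ablation (IAO) uses too, so the ablation identity is preserved.
* **IAO ablation boundary.** Chaotic initialization and elite opposition
  are treated as one enhancement unit under the `elite_opposition` flag;
  with it off, initialization is uniform random — matching the stated
  plain-IAO behaviour.
* **Stage flow.** Per iteration each agent executes the three stages
  sequentially; the Laplace crossover runs once per iteration between the
  global best and one uniformly random agent, with the better offspring
  accepted if it beats that agent. The per-iteration trace records the
  archived global best, which is therefore non-increasing by construction.

## 4. Preprocessing

* **SNV** is exact row-wise z-scoring; constant rows are an error (not
  silently zeroed), and the transform is idempotent.
* **MSC** fits each spectrum on a reference by OLS and inverts the affine
  fit; rows whose slope is below `b_tol` (default 1e−12) are an error. The
  reference defaults to the mean spectrum *of the data given*, but the
  evaluation harness always computes it on the training partition and
  reuses it on the test partition (`msc_reference()`), preventing
  test-information leakage.
* **Savitzky–Golay** builds the full linear smoothing operator: central
  least-squares coefficients in the interior, fit-and-evaluate on the
  terminal windows (no shrinkage). Window 11 / order 3 is the default — a
  common chemometrics choice at ~1.7 nm sampling; both are configurable
  and validated. Linearity and exact reproduction of degree-≤order
  polynomials are tested, as is the classic (−3, 12, 17, 12, −3)/35
  five-point quadratic kernel.

The harness applies preprocessing before selection and before any split
statistics are computed, and selectors only ever see the training
partition.

## 5. The synthetic world — and what a green test does not establish

`generate_seed_spectra()` emulates the *shape* of seed reflectance data: a
smooth base curve rising over 500–700 nm and flat-high in the NIR with a
small water-related dip near 760 nm; three balanced classes (an untreated
control and two aging analogues); per-class reflectance offsets planted at
a known set of informative bands with alternating sign; per-sample affine
scatter ($b \sim U(0.8, 1.2)$, $a \sim U(-0.05, 0.05)$) — exactly the
distortion family MSC/SNV remove; and i.i.d. Gaussian band noise (default
$\sigma = 0.01$ reflectance units) — what SG smooths. Defaults: 100
samples per class, $D = 360$ over 395.24–1008.20 nm (the canonical axis),
8 informative bands with effect 0.05.

What it does **not** emulate: band-to-band correlated noise, instrument
drift, water-band nonlinearities, spatial (image) structure, class overlap
from biological variability, or unbalanced designs. A green planted-band
test therefore establishes that the machinery recovers signal it was
promised under the stated noise model — not that it would select
biochemically meaningful bands on a real instrument.

One subtlety the acceptance analysis surfaced: when planted effects are
large (5σ), a few bands already give perfect KNN accuracy, and the size
penalty then *correctly* prunes the remaining informative bands — recall
of all planted bands anti-correlates with optimization quality. Recall is
only a meaningful recovery measure near the 2σ recoverability bound, where
every planted band carries marginal information; the acceptance test for
band recovery therefore runs at effect = 2σ.

`generate_fs_benchmark()` provides the generic tabular analogue
(class-shifted Gaussian informative columns, noisy redundant copies, pure
noise for the rest), and `exhaustive_oracle()` enumerates all $2^d - 1$
subsets for $d \le 12$ with the *same* fitness the optimizers use — the
independent standard against which oracle-equivalence and
sparsity-monotonicity are asserted.

## 6. Classifier harness

ELM is the bespoke implementation the method calls for: random $U(-1,1)$
input weights and biases, sigmoid hidden layer, Moore–Penrose pseudoinverse
output weights against one-hot labels; with hidden units ≥ training
samples on distinct inputs it interpolates (training accuracy 1), which is
an acceptance check. Because no tree or SVM package is available in the
target environment, the random forest is an in-package bagging ensemble of
Gini-grown CART trees (`mtry = floor(sqrt(d))`, majority vote), and the
SVM solves the soft-margin RBF dual directly with `quadprog` (one-vs-rest,
z-scored features, escalating ridge on the kernel for numerical safety).
Grids follow the reference protocol — hidden units 30..100 step 10, 300
trees with depth 1..20, the classic logarithmic $(C, \gamma)$ grid — all
selected by stratified 5-fold CV accuracy on the training partition and
all overridable through `eval_protocol()`, which the tests use to keep
runtimes sensible. Macro (equal-weight) averaging is used for
precision/recall/F1, with 0/0 defined as 0.

## 7. Known limitations

* Pure-R optimizer and classifiers: fine at the reference scales
  ($D \le 360$, $n \le 1000$, 50 iterations), not tuned for much larger
  problems.
* The wrapper fitness shares one internal split across a run (by design,
  for comparability); subset quality estimates are therefore optimistic
  relative to nested resampling.
* The oracle-equivalence rate is seed-dependent: on the frozen acceptance
  seeds EIAO attains the exhaustive optimum in 17/20 runs; across wider
  seed sets the rate is nearer 70–85%, with misses typically one
  redundant band away from the optimum (fitness gap 0.001 at $D = 10$,
  $\alpha = 0.99$).
* The `as_printed` Laplace variant is distribution-defective by
  construction (support gap) and retained only for fidelity; all defaults
  use the genuine Laplace.
* CSA and SO comparators are intentionally absent; any object honouring
  the `selection_result` contract can be benchmarked alongside.
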