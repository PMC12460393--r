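---
title: "Cell-fate dynamics as random dynamical systems: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-fate dynamics as random dynamical systems: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatedyn)
```

## Why this package exists

Cell types are commonly pictured as attractors of gene-expression dynamics:
a cell's molecular state moves through a high-dimensional state space and
settles into one of several stable modes, the "valleys" of a landscape.
That picture quietly assumes autonomous, deterministic dynamics. Real
cells are thermodynamically open and noisy: the appropriate formal object
is a *random dynamical system* — a cocycle on the state space driven by a
measure-preserving noise model — and the appropriate notions of stability
are time-dependent (forward and pullback attractors, random attractors) or
only temporary (long transients, quasistability).

`fatedyn` turns that formal apparatus into executable, tested code. The
defining axioms of each formalism are not assumed — they are *checked*,
numerically, on seeded samples, and the package is organised around those
checks:

1. **Deterministic formalisms** (`autonomous_system`, `process_system`,
   `skew_product_flow`): identity, semigroup, initial-value, causality and
   cocycle axioms as `check_axioms()` reports, plus the classical
   conversions between the formalisms.
2. **Driving systems** (`bernoulli_scheme`, `symbol_sequence`): shift
   spaces with cylinder-set product measure, the canonical discrete noise
   model.
3. **Random systems** (`random_map_system`, `random_dynamical_system`):
   perfect cocycles by map composition, with the degenerate reduction to
   deterministic dynamics.
4. **Attractors** (`estimate_global_attractor`, `pullback_convergence`,
   `random_pullback_estimate`, `transient_length`): numerical attraction
   diagnostics built on the directed Hausdorff distance.
5. **Boolean networks** (`generate_random_network`, `enumerate_cycles`,
   `perturbation_analysis`): the discrete-state model of gene regulation,
   with exhaustive cycle/basin analysis.
6. **The landscape chain** (`reaction_network` → `simulate_sde` →
   `estimate_density` → `quasipotential` → `find_valleys` →
   `detect_transitions`): from mass-action kinetics through stochastic
   simulation to an empirical quasi-potential and fate-transition events.

## Time, durations, and the three deterministic formalisms

A time set is either a continuous interval $[t_0, \infty)$ or an integer
range; from it derive the duration set $\mathbb{D} = \{(s,t) : s \le t\}$
and the duration-length monoid $\mathbb{L} = \{t-s\}$. We deliberately
restrict to these two concrete cases: the abstract theory allows arbitrary
totally ordered semigroups, but every worked example lives in
$\mathbb{R}$ or $\mathbb{Z}$, and an abstract-semigroup representation
would add machinery nothing here exercises.

An autonomous system evolves by duration length alone,
$\theta(l+m,x) = \theta(m,\theta(l,x))$; a process may depend on the
actual time points, $\phi((s,t),x) = \phi((u,t),\phi((s,u),x))$ for
$s \le u \le t$; a skew-product flow is a cocycle
$\phi(t+s,p,x) = \phi(t,\theta(s,p),\phi(s,p,x))$ over a driving system
on a parameter space. The package ships the standard conversions:
`duration_length_form()` (valid only for translation-invariant processes,
and *refused* with a witness otherwise, because the construction
$\theta(l,x) := \phi((s,s+l),x)$ is ill-defined without invariance),
`process_to_skew()` (time itself as the base), and `skew_to_autonomous()`
(the associated flow on $P \times X$).

### How the axiom checks work

Evolution maps are opaque callables, so the axioms are checked by
sampling, not symbolically. `check_axioms()` draws `n_samples` tuples
reproducibly from a seed (time points and duration lengths from the
system's declared sampling window, states uniformly from the declared
bounds, or from a custom sampler for structured states such as symbol
sequences) and records the worst relative residual
$|{\rm lhs} - {\rm rhs}| / (1 + |{\rm lhs}|)$, the tolerance, the verdict
and the worst witness tuple. The relative form keeps one tolerance
meaningful across state magnitudes. Default tolerance for analytic maps
is `1e-9`; discrete symbol dynamics are compared exactly. A passing
verdict certifies the axiom *on the sampled tuples*; it is evidence, not
proof. Errors raised by the map are themselves recorded as failing
witnesses rather than aborting the check. A zero-width sampling window is
refused outright — it would make every check vacuous.

Backward time is only admitted when a system declares `invertible`;
otherwise $\mathbb{L}$ is its nonnegative cone, matching the fact that
cocycles are often defined in forward time only.

## Driving noise: Bernoulli schemes

The canonical discrete noise model is the Bernoulli scheme: i.i.d.
symbols with positive probabilities $(p_1,\dots,p_n)$ under the left
shift, with the product measure
$\rho(C_z[(a_i)]) = \prod_i p_{a_i}$ on cylinder sets. Infinite sequences
are represented by a finite materialized window plus a *counter-based*
lazy extension: the symbol at index $j$ is a pure function of the scheme
seed and $j$, so reading outside the window in any order always yields
the same symbols. This consistency is what makes shifted and un-shifted
views of the same noise path agree exactly — the property the
perfect-cocycle check relies on.

Measure preservation of the shift is verified two ways in
`check_measure_preservation()`: analytically, via the preimage identity
$\theta_t^{-1}(C_z[\cdot]) = C_{z+t}[\cdot]$ evaluated with the product
formula on both sides; and empirically, comparing Monte-Carlo cylinder
frequencies against the analytic value with a z-score. Statistical
verdicts in the package use a fixed z-threshold of 4 and report the
z-score itself rather than a p-value: at the simulation sizes used
(10^4–10^5 draws) this gives reproducible verdicts with a false-alarm
probability around $6 \times 10^{-5}$ per check. Joint measurability of
the shift is a property of the idealized object; it is documented here
and not (cannot be) certified numerically.

## Random dynamical systems

`random_map_system` implements the standard construction of a
discrete-time random dynamical system: a finite family of self-maps
$(f_1,\dots,f_n)$ on an interval, composed in the order dictated by the
noise path, $\phi(z,\omega,x) = f_{\omega(z-1)} \circ \cdots \circ
f_{\omega(0)}(x)$, with $\phi(0,\omega,x)=x$. Because composition is
associative and symbol reads are exact, the cocycle property holds with
residual exactly zero — `check_perfect_cocycle()` asserts this at
tolerance 0, and the test suite includes a deliberately broken cocycle
(one that keeps reading $\omega(0)$ after a shift) to show the check has
teeth. Crude cocycles (almost-sure exceptional sets) are out of scope:
a.s. statements are not decidable from finitely many seeded realizations,
and we say so rather than approximate silently.

`degenerate_to_deterministic()` implements the reduction of a
noise-independent cocycle to an ordinary deterministic system. Noise
independence is decided by sampling pairs of independent paths at probe
tuples — caller-visible probe count and tolerance — and refused with a
concrete witness $(\omega_1,\omega_2,t,x)$ on any detected dependence.

## Attractors as point-cloud diagnostics

All attraction notions quantify over bounded sets; the package's
desk-scale surrogate is a finite point cloud, with attraction measured by
the exact cloud-to-cloud directed Hausdorff distance
$d_H(V,W) = \sup_{v \in V}\inf_{w \in W} d(v,w)$. Compactness becomes
finiteness; the sampling error of the surrogate shows up in the reported
distances and is never hidden. Verdicts are three-valued: `pass` when the
tracked distance reaches tolerance, `inconclusive` when it still
decreases at the deepest horizon (limits are asymptotic — attractors are
technically never reached), `fail` when it grows.

- **Global** (`estimate_global_attractor`): iterate the cloud forward,
  deduplicate the final cloud (default merge tolerance `1e-6`), report
  distances along the way plus a one-step invariance residual, and
  declare "no bounded attractor found" on divergence.
- **Forward vs pullback**: forward attraction chases a moving target
  $A_t$ as $t \to \infty$; pullback attraction fixes the target time and
  recedes the start, the construction `random_pullback_estimate` mirrors
  through the past symbols $\omega(-k),\dots,\omega(-1)$ of a two-sided
  noise path. The two coincide for autonomous systems, a property the
  tests verify numerically.
- **Random** attractors are defined almost surely over the noise; the
  estimator evaluates single seeded realizations (and small ensembles via
  `pushforward_ensemble`) and therefore estimates the fibre $A(\omega)$
  of those paths only — an explicit limitation, not an approximation.
  The family of attracted random sets is fixed to constant-in-$\omega$
  bounded clouds; tempered families are not implemented.
- **Long transients** (`transient_length`): residence bookkeeping of a
  trajectory relative to reference sets within a radius, from which
  quasistability (long but finite residences) is read off. Overlapping
  reference sets at the chosen radius are an error, not a silent
  ambiguity.

## Boolean networks

The discrete model of gene regulation: $N$ binary genes, each reading $K$
inputs through a truth table drawn from the $2^{2^K}$ Boolean maps,
updated synchronously (all genes at once), which makes the dynamics a
deterministic function on $\{0,1\}^N$ — a random construction with
deterministic behaviour. Design choices, each deliberate: input indices
are distinct per gene (the construction samples without replacement;
repetition is representable by an equivalent table but never generated);
self-inputs are allowed; updates are synchronous only, as asynchronous
schedules define a different (nondeterministic) model; cycles are stored
rotated so the lexicographically smallest state leads, making cycle
identity a plain equality; exhaustive enumeration refuses beyond
$N = 20$ (~10^6 states) instead of silently sampling. Perturbations are
applied to cycle states (single-bit flips), matching the question "does
the network return to its cycle after a perturbation"; perturbing
arbitrary transient states would be a different experiment and is left as
an extension.

## The landscape chain

The continuous model starts from mass-action kinetics: each reaction
contributes its rate constant times the product of reactant abundances
raised to stoichiometric powers, times the net stoichiometric change
(`species_formation_rate`, with $0^0 = 1$). Deterministic dynamics are
integrated with `deSolve`; fixed points are located by a BFGS descent on
$|f|^2$ with Newton polishing and classified by the real parts of the
Jacobian eigenvalues — "negative eigenvalues" is read as the real-part
convention so that complex spectra are covered, with a `nonhyperbolic`
band of half-width `1e-6` around zero.

Stochasticity enters as the Langevin model
$dx = f(x)\,dt + g(x)\,dW_t$ with increment covariance
$E[dW_t\,dW_s] = \epsilon\,\delta(t-s)$. Two conventions had to be fixed
where the formalism leaves slack, and both are declared rather than
assumed: the noise strength $\epsilon$ is a variance scale multiplying
$\Delta t$ inside the increment ($g$ carries any state dependence), so
the Euler–Maruyama step is
$x_{k+1} = x_k + f(x_k)\Delta t + g(x_k)\sqrt{\epsilon \Delta t}\,\xi_k$;
and the Itô interpretation is fixed (Stratonovich is not offered).
Nonnegativity of molecular abundances is enforced by reflection at zero
by default, switchable to `"none"` for landscape models posed on all of
$\mathbb{R}^d$ (the shipped OU and double-well fixtures use `"none"`).
With $g = 0$ every path reproduces the deterministic Euler solution
exactly — a useful degeneracy check. Paths that overflow are flagged and
reported, never dropped silently.

The population profile $\rho$ is estimated by histogram binning on a
user grid (not kernel smoothing: the grid is explicit, the estimator is
unbiased per bin, and attractor states may be near-singular so smoothing
bandwidths would be another silent convention). The quasi-potential is
$U_q = -\ln \max(\rho, \text{floor})$, with the proportionality constant
fixed to 1 and the minimum shifted to zero — only differences of $U_q$
are meaningful. The floor defaults to one tenth of the density a single
observation would contribute ($0.1/(n \cdot \text{bin volume})$); it
keeps $U_q$ finite on empty bins and its value is recorded in the
returned object.

Valleys are strict local minima of $U_q$ over axis neighbours, merged
within a separation radius (keeping the deeper valley). One further rule
matters in practice: a candidate valley must have *local density
support* — its own bin and its neighbours must lie above the floor.
Without this rule a single stray observation in an otherwise empty
region of state space (both neighbours at the floor) registers as a
strict minimum of $U_q$ and hence as a spurious "fate". Since valleys
are, scientifically, local maxima of a probability density, requiring
local support is part of the definition, not a tuning knob. The
degenerate case this excludes — a perfectly concentrated deterministic
ensemble occupying a single bin — is flagged by the constant-landscape
warning path instead.

One sign convention deserves note: the discrete valley criterion
implements "local minima of $U_q$ with the neighbourhood growing upward"
(positive-definite curvature); a literal Laplacian inequality
$\nabla\!\cdot\!\nabla U_q(x^*) < 0$ would be negative at a convex
minimum, so the implementation follows the stated intent (valleys =
minima) and flags the inequality's sign as an ambiguity of the source
formalism.

Fate transitions are emitted per path whenever consecutive valley
memberships (within a radius, non-overlapping by construction) differ,
with exit and entry times — the event $x \in V_i \to x \in V_j$.
Finally, `gradient_check()` tests the time-reversibility condition:
forward and backward transition paths can only coincide when the drift
is a gradient field and the diffusion constant; the numerical version
checks constancy of $g$ across probes and symmetry of the
finite-difference Jacobian of $f$ (equality of mixed partials), with
every smooth 1-D drift trivially a gradient.

## What the synthetic conditions emulate — and what they do not

The shipped fixtures *are* the study conditions exercised by the tests
and the acceptance script:

- **OU fixture** ($f = -x$, $g = 1$, $\epsilon = 2$): 2000 paths on
  $[0, 10]$ at $\Delta t = 0.01$, pooled after a 50% burn-in on an
  81-edge grid over $[-4, 4]$. The stationary law is Gaussian with
  variance $\epsilon/2 = 1$, so the fitted quadratic coefficient of
  $U_q$ has the known value $1/(2\sigma^2) = 0.5$ — a genuine
  parameter-recovery check on synthetic data.
- **Double-well fixture** ($f = x - x^3$, $\epsilon = 0.5$): 100 paths
  on $[0, 200]$ at $\Delta t = 0.01$. The well bottoms sit at $\pm 1$;
  $\epsilon = 0.5$ is large enough that a path hops between wells many
  times over the horizon (order 10^3 events in the ensemble), so the
  detailed-balance symmetry of the symmetric landscape is testable as
  $|n_{12} - n_{21}| \lesssim 4\sqrt{n_{12}+n_{21}}$.
- **Affine random contraction** ($f_b(x) = x/2 + b/2$): its pullback
  fibre is the explicit random series $\sum_{k \ge 1} 2^{-k}
  b_{\omega(-k)}$, giving a machine-precision oracle for the random
  pullback estimator.

These fixtures are one-dimensional, with constant diffusion and white
Gaussian noise. Passing tests therefore demonstrate correctness of the
machinery on analytically solvable models; they do not demonstrate that
real gene-expression data are one-dimensional, gradient, constant-noise
or Markovian — the package's own reversibility check exists precisely to
interrogate such assumptions, and the source framework emphasises that
biological noise may be non-Gaussian, coloured, and functional rather
than a disturbance.

Problem sizes throughout (sample counts of 10^2–10^3 for axiom checks,
10^5 symbol draws, 2000 SDE paths, exhaustive Boolean enumeration to
$N = 10$ in tests) were chosen as the smallest sizes at which the
statistical assertions have comfortable power; all are parameters, not
constants.

## Numerical choices, in one place

| Quantity | Default | Why |
|---|---|---|
| axiom tolerance | `1e-9` relative | analytic maps agree to round-off; leaves margin over `1e-16` noise |
| cocycle tolerance (symbol-driven) | `0` | composition is exact |
| z-score threshold | `4` | reproducible verdicts, ~6e-5 false-alarm rate |
| dedup / attractor tolerance | `1e-6` | above round-off accumulation, below any fixture's feature scale |
| density floor | `0.1/(n·vol)` | a tenth of one observation's density |
| nonhyperbolic band | `1e-6` on Re(λ) | finite-difference Jacobian accuracy |
| exhaustive Boolean limit | `N = 20` | ~10^6 states; beyond this, refuse rather than sample silently |

Degenerate inputs are errors, not silent passes: zero-width sampling
windows, empty point clouds, overlapping reference sets or valley
neighbourhoods, stale cycle sets, cylinder words outside the alphabet,
negative shifts of one-sided sequences, and non-invertible pullback
requests all refuse with a message naming the problem.

## Known limitations

- Axiom verdicts are sample-based evidence at a tolerance, not proofs;
  measurability conditions are documented, not certified.
- Random attractor estimates are per-realization; almost-sure statements
  are out of reach by construction.
- Density estimation (and hence the quasi-potential chain) is
  implemented for 1-D and 2-D state spaces; higher dimensions need a
  different estimator class.
- Exact jump-process simulation (Gillespie), least-action paths and
  fluctuation–dissipation computations are outside the package's scope.
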