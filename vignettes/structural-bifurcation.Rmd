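---
title: "Structural bifurcation analysis: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural bifurcation analysis: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sban)
```

## The model and its assumptions

A reaction network of $M$ chemicals and $N$ reactions evolves as
$\dot{x} = \nu\, r(x; k)$ with integer stoichiometric matrix $\nu$ and
unknown, smooth, positive rate functions $r$. The analysis needs only the
*signs* of the rate derivatives $\partial r_n / \partial x_m$, which follow
from topology: positive for a reactant, the annotated sign for a regulator,
zero otherwise. Three structural assumptions matter:

* **Algebraic independence.** The symbols $r_{n,m}$ are treated as
  independent quantities even when several derive from the same rate
  function. Sign structure is modeled; accidental cancellations for a
  specific kinetics are not. Consequently a block classified
  `indeterminate` *can* change sign for some kinetics — the package never
  claims it must.
* **Genericity.** Results describe generic parameter values: a perfect
  matching on the nonzero pattern of the structural matrix $A$ exists
  (otherwise $\det A \equiv 0$ and the network is reported as structurally
  degenerate), and nonzero entries are treated as generically nonzero.
* **Equilibrium bifurcations only.** The determinant detects zero
  eigenvalues of the reduced Jacobian. Bifurcations driven by complex
  eigenvalue pairs (Hopf) are out of scope by design.

The central identity, verified numerically in the test suite on every
bundled network at randomly drawn states, is
$\det A = \frac{\det(D^\top D)\,\det(C^\top C)}{\det\Lambda}\,\det J_g$,
where $C$ spans $\ker\nu$ (reaction loops), $D$ spans $\ker\nu^\top$
(conserved moieties), $\Lambda = [[\nu, D], [C^\top, 0]]$, and
$J_g = V^\dagger J_f V$ is the Jacobian restricted to the stoichiometric
subspace $\mathrm{im}\,\nu$. Because conserved quantities force
$D^\top J_f = 0$, $\det J_f$ vanishes identically whenever $Q > 0$ and is
useless as an indicator; $\det J_g$ — and hence $\det A$ — is not. The
companion instability criterion,
$\mathrm{sign}(\det\Lambda \cdot \det A|_x) \ne (-1)^{M-L} \Rightarrow x$
unstable, is one-sided: agreement never certifies stability, and the package
words its verdicts accordingly (`not_stable` / `possibly_stable`).

## Counting conventions for the index

A buffering structure is an output-complete subnetwork $\gamma$ with zero
index. We implement the index as

$$0 = \#\text{chemicals}(\gamma) - \#\text{reactions}(\gamma)
      + \#\text{loops}(\gamma) - \#\text{conserved}(\gamma),$$

with two deliberate conventions that the block-triangular structure forces:

* **Sign of the conserved term.** The diagonal block of $\gamma$ has
  columns = chemicals + loop columns and rows = reactions + conserved rows.
  Squareness of that block dictates the minus sign on the conserved count
  (conserved rows sit on the *reaction* side). With a plus sign the bundled
  conserved example — three chemicals, three reactions, one loop, one
  conserved quantity — would have index 2 and could not be the buffering
  structure it demonstrably is.
* **Touching vs. contained for conserved quantities.** Loops are counted by
  the dimension of $\ker\nu$ restricted to $\gamma$'s reactions: a flux mode
  belongs to $\gamma$ only if it can run entirely inside it. Conserved
  quantities are counted by $Q - \dim(\mathrm{coker}\,\nu$ restricted to the
  *complement* chemicals$)$: a moiety belongs to $\gamma$ as soon as its
  support touches $\gamma$'s chemicals, because its constraint row must then
  be carried inside any influence-closed set containing them. The
  subset-support alternative misclassifies, e.g., one half of an
  interconverting pair upstream of a chain as "buffering" although
  perturbations inside it demonstrably propagate out through the shared
  total.

With these conventions the two independent routes — descendant-closed unions
of determinant structures on the influence graph, and brute-force enumeration
of all output-complete index-zero subsets — agree on every bundled network
and on every well-formed random network in the property tests.

## Basis choices and localization

Automatic bases are computed by exact fraction-free integer elimination,
scaled to primitive integer columns (entry gcd 1, first nonzero entry
positive), so Gram determinants and $\det\Lambda$ are reproducible integers.
Any valid basis gives the same analysis — the identity's prefactor absorbs
the choice, and $\det J_g$ is invariant under a change of image basis
(property-tested) — but the *block assignment* of loop columns is cleanest
when basis vectors have minimal support. A greedy integer column-reduction
pass therefore shrinks supports before decomposition. User-supplied bases
(such as the hand-picked loop vectors of the worked examples, which pin the
printed constants 8, 2, 16) are validated and used as given.

Determinant structures are reported in a deterministic order: topological
order of the influence DAG with ties broken by the smallest original column
index. Permutation parities of the rearrangement are reported
(`perm_sign`), never applied silently; block determinants are therefore
pinned only up to that overall sign, and the sign classes
`always_positive`/`always_negative` should be read as "never zero, fixed
sign".

## Rate laws and their parameters

The kinetic layer supports seven law kinds (see `?kinetic_model`); all
parameters are in concentration/time units consistent with the state:

* `constant` (`k`): reservoir inflows.
* `mass_action` (`k`): deactivations and degradations.
* `hill_inhibited` (`k`, inhibitor strengths `a`, Hill exponents `h`):
  activation under saturating inhibition,
  $k\,x_s / (1 + \sum_i a_i x_i^{h_i})$. Exponent 2 is the package default
  in the polarization presets — the smallest exponent giving robust
  bistability for a two-sided toggle.
* `hill_activated` (`k0`, `k1`, `theta`, `h`): basal plus saturating
  activation; the saddle-node preset.
* `sigmoid_activated` (`k`, `theta`, `tau`, `eps`): logistic activation;
  the pitchfork preset (steepness `tau` is its sweep parameter).
* `mass_action_mod`, `ma_poly`: bilinear activation and polynomial removal;
  the transcritical preset.

Every law's dependency set must equal the network's annotated dependencies,
and the analytic derivative signs are property-tested against the
annotations at random states — so the symbolic layer and the numeric layer
can never drift apart.

## What the bundled models emulate — and what they do not

The exact rate functions and parameters behind the original polarization
study are in supplementary material that is not machine-readable here, so
the shipped presets are *qualitative stand-ins*, chosen once:

* Example network presets are fixed to exhibit pitchfork, transcritical and
  saddle-node diagrams respectively; in all three, only chemical B varies
  across branches, which is the structural prediction being exercised.
* The macrophage preset uses unit activation/deactivation rate constants,
  Hill exponent 2, and inhibition strengths (STAT6⁺⊣STAT1 activation 1.5,
  STAT1⁺⊣STAT6 activation 2, STAT1⁺⊣STAT3 activation 1, weak couplings
  0.05–0.3 elsewhere) calibrated once so that the wild type is bistable over
  the upper part of $\eta_1 \in [6, 8.5]$ (totals of the other three pairs
  fixed at 8) with the M1-like branch (high STAT1⁺/NFκB⁺) lost at low
  $\eta_1$, and the mutants keep a fold inside the range. The acceptance
  suite asserts the *existence and location class* of these folds, not the
  original study's printed threshold values, which would require the
  original parameter set (it can be supplied through the kinetics JSON
  config, at which point the same sweeps apply unchanged).

A green sweep test therefore establishes that the numeric bifurcation
diagrams of these stand-in models localize exactly as the topology predicts
— it does not establish quantitative agreement with any measured macrophage
system.

The random-network generator draws well-formed, signaling-style networks:
conserved moieties only from dedicated interconversion pairs, every
flow-through species both produced and consumed, no duplicated
stoichiometric columns. The exclusions are deliberate: duplicated columns
make the buffering family degenerate (interchangeable loop splits), and
dead-end chains force boundary equilibria — both violate the genericity the
theory assumes, and neither occurs in the curated models the package
targets.

## Numerical choices

* Exact integer arithmetic (fraction-free elimination, Bareiss determinants)
  for everything structural; floating point only in the kinetic layer.
* Equilibria: damped Newton on $(V^\dagger \nu r(x),\, D^\top x - \eta)$
  with analytic Jacobians, multistart from conservation-respecting random
  points biased toward simplex corners; residual tolerance
  $\|H\|_\infty < 10^{-10}$; duplicates merged at $10^{-6}$ relative.
  Nonnegative boundary equilibria are kept (the transcritical branch lives
  at $B = 0$).
* Continuation is grid-plus-multistart with warm starts from the previous
  grid point — robust for fold-type diagrams and fully deterministic under
  a seed — not pseudo-arclength. Branch identity uses nearest neighbors
  with a jump tolerance of half the median inter-branch distance; branch
  birth/death is bracketed by bisection to $10^{-3}$ in the parameter.
* Perturbation stability integrates a Cash–Karp adaptive Runge–Kutta scheme
  from displacements drawn inside $\mathrm{im}\,\nu$ (conserved totals
  untouched), calling a point stable when every trial returns to within a
  quarter of the displacement.
* Structural degeneracy (no perfect matching), non-equilibrium inputs, and
  schema violations are errors with distinct messages and CLI exit codes;
  they are never silently repaired.

## Limitations

* No Hopf/limit-cycle detection; no bifurcation-type classification from
  structure (type is a property of the kinetics, as the three example
  presets on one network demonstrate).
* `classify_sign` is a sufficient condition; `indeterminate` blocks may
  still be sign-definite for particular rate families.
* Buffering-structure enumeration caps at 512 closed sets by default
  (flagged `truncated`); the minimal structure per block — all that the
  bifurcation report needs — is always exact.
* Exact arithmetic assumes intermediate integer values below $2^{53}$,
  ample for networks up to a few hundred nodes but not for arbitrary
  stoichiometries.
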