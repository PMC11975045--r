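---
title: "Structured random binding: model, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured random binding: model, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srb)
```

## The model

Structured random binding (SRB) is a minimal statistical-physics model of
protein–protein interactions.  A protein is a bag of `nP` surface peptide
epitopes, each a sequence of `l` letters from a primary alphabet of size
`‖A‖`.  Every sliding window of `ξ` consecutive residues is assigned a
structural motif by a bijective map `f`, so an epitope carries a secondary
structure of `l′ = l − ξ + 1` motifs drawn from a motif alphabet of size
`‖M‖ = ‖A‖^ξ`.  All energetics live in a quenched symmetric random coupling
table `J(m, m′)` with mean zero and variance `σ_J²`: the binding energy of
an aligned epitope pair is the sum of its `l′` paired motif couplings, in
parallel orientation

&nbsp;&nbsp;&nbsp;&nbsp;`u↑↑(p, b) = Σᵢ J[f(p)ᵢ, f(b)ᵢ]`,

and with one motif sequence reversed in antiparallel orientation.  The
binding energy of a binary complex is the minimum over all epitope pairs
and both orientations.  `ξ` is the *structural correlation length*: how far
a single residue substitution propagates into the secondary structure.

Units: `k_B = 1`; `σ_J` (default 1) is the energy unit, and temperatures
are expressed in the same unit.

```{r params}
params <- srb_params(alphabet_size = 4, peptide_length = 10, xi = 3)
params
```

## What follows from the model without simulation

Because we take Gaussian couplings (see *Design choices*), a single
epitope-pair energy is exactly Gaussian with variance `l′σ_J²` at every
`l′`.  A complex of two random proteins is then an `n = 2·nP·nB`-level
system with iid level energies, and its ground state — the nonspecific
binding energy — follows, for large `n`, a min-type Gumbel law whose
location `μ` is the lower `1/n` quantile of the level law and whose scale
`β` is the distance to the `1/(n·e)` quantile:

```{r gumbel}
gp <- gumbel_params(n = 800, l_prime = 8)
gp
```

The customary scale parameter `ϕ` of this law is negative; we store the
positive `β = −ϕ`, so the mean is `μ − γβ` with `γ` the Euler–Mascheroni
constant.  Both parameters are *asymptotic* (`n → ∞`): at `n = 800` the
exact mean of the minimum of `n` Gaussian levels (obtainable by numerical
integration of the order-statistic density) sits about `0.04 σ_J` above
`μ − γβ`, and the exact Kolmogorov–Smirnov distance between the true
minimum law and the Gumbel is ≈ 0.015.  Tests that compare simulation to
these formulas therefore resolve the asymptotic error once the Monte-Carlo
error drops below a few hundredths of `σ_J`; the package documents the
formulas as limits rather than finite-`n` truths.

The same level-count `n` sets the condensation temperature
`T_c = σ_J √(l′ / (2 log n))` below which the Boltzmann measure of the
complex freezes onto a few configurations.  The participation ratio
`Y(T)` diagnoses this: its disorder average approaches the broken line
`max(0, 1 − T/T_c)` as `n → ∞`.  Convergence is logarithmic: even at
`n = 80000` the mean curve near `T_c` sits ≈ 0.1 above the limit (this is
a property of the random-energy reference model itself, reproducible with
iid Gaussian levels, not an artifact of this implementation).

## Alphabet size: when the small alphabet is not the generic model

The model's generic setting is the amino-acid alphabet, `‖A‖ = 20`.  The
4-letter alphabet is a device for making mutation–selection numerics
tractable (the motif alphabet, `4^ξ`, stays enumerable for `ξ` up to 7),
and we keep it for all evolution runs.  But at `‖A‖ = 4` two small-alphabet
artifacts appear that matter for quantitative comparisons:

* *Window collisions.*  With only `64` motifs at `ξ = 3`, two windows of
  the same peptide repeat a motif with appreciable probability, so a
  parallel isologous self-energy `Σᵢ J[mᵢ, mᵢ]` can count the same diagonal
  coupling twice.  This inflates its variance from `l′σ_J²` to ≈ `1.11·l′σ_J²`
  at `l′ = 8`, pulling the antiparallel/parallel variance ratio down from 2
  to ≈ 1.83 and visibly raising the share of random homodimers whose
  ground state is parallel isologous.
* *Shared couplings across levels.*  A 20-epitope protein uses 160 motif
  draws from a 64-motif alphabet, so distinct complex levels share
  couplings and are weakly correlated, visibly distorting extreme-value
  statistics at the `Δ ≈ 0.01` KS level.

At `‖A‖ = 20` both effects are negligible (collision probabilities scale
like `‖A‖^(−ξ)`).  The package therefore runs interface censuses, the
variance-doubling estimate and the Gumbel comparisons at `‖A‖ = 20`, and
evolution at `‖A‖ = 4`; this split reproduces the model's reference
values (33 / 3.3 / 63.7 % random-census fractions), which the 4-letter
alphabet does not.

## Homodimer state space

For a homodimer we count each unordered pair of distinct epitopes once per
orientation (the coupling symmetry makes the two orderings identical in
energy) plus two isologous states per epitope: `nP(nP−1) + 2nP` levels,
i.e. 420 at `nP = 20`, of which 20 are antiparallel isologous.  An
antiparallel isologous state pairs motif `i` with motif `l′−i+1`, so for
even `l′` its energy is twice a sum of `l′/2` couplings — twice the
variance of any other category — which is why roughly a third of *random*
homodimers, and nearly all *evolved* tightly-bound homodimers, have an
antiparallel isologous ground state.  For odd `l′` the middle motif pairs
with itself once and the antiparallel variance is `(2l′−1)σ_J²`; the even
case is the one the reference census uses.

```{r census, eval = FALSE}
p20 <- srb_params(alphabet_size = 20, peptide_length = 10, xi = 3)
random_homodimer_census(p20, n_epitopes = 20, n_realizations = 10000, seed = 1)
```

## Mutation–selection dynamics

`evolve_population()` starts from `N` identical copies of one random
complex and, per generation: mutates every residue independently with
probability `ε` (a substitution draws uniformly from the other `‖A‖−1`
letters); recomputes each member's binding energy; sets the selection
threshold `U₀` to the *post-mutation, pre-selection* ensemble mean;
draws survival with the Fermi probability `1/(e^{(U−U₀)/σ_J} + 1)`; and
resamples survivors uniformly with replacement back to size `N`.

The survival rule is prescribed by the model; the repopulation scheme is
not, and several choices were genuinely open:

* *Resampling.*  We resample survivors with replacement to a fixed `N`
  (Wright–Fisher style).  This keeps the ensemble size constant, which the
  fixed-`N` ensemble phrasing of the model implies, and makes the
  threshold's feedback well defined.
* *Threshold timing.*  `U₀` tracks the current (post-mutation) ensemble,
  read from "coevolves to maintain selection pressure"; the trajectory
  records it alongside the means so the bookkeeping is testable.
* *Extinction.*  If no member survives (probability vanishing at
  `N = 10³`), the pre-selection ensemble is retained for that generation.
* *Census readout.*  The evolved-homodimer census classifies the
  lowest-energy final member of each realization — one label per
  realization, matching per-complex category reporting.

Evolution is most effective at short `ξ`: with `ξ → 1` the motif sequence
can be optimised almost term by term, while at large `ξ` only an
exponentially small and sparse fraction `‖A‖^{l − l′ξ}` of motif sequences
is realisable by any primary sequence (`invertible_fraction()`), so the
accessible search space fragments and affinity gains stall.  Long-time
trajectories show the slow `log(t)` improvement characteristic of glassy
dynamics.

## What the generator emulates, and what it does not

All inputs are generated internally: random proteins with iid uniform
letters, and couplings produced by a counter-based deterministic hash of
`(coupling_seed, min(m,m′), max(m,m′))` mapped through the Gaussian
quantile function.  The hash makes any entry reproducible without storing
the table — necessary because `‖M‖ = 16384` at `ξ = 7` — and the
"materialized" mode simply tabulates the same function, so both modes
agree entry for entry by construction.  Every stochastic routine draws its
seed from a named stream derived from a master seed; identical
configurations give identical outputs.

The synthetic universe deliberately omits: 3-D geometry and force fields,
conformational flexibility and its entropy, chemistry-specific amino-acid
couplings, interfaces formed by sequentially distal residues, and partial
or shifted epitope alignments.  Passing tests therefore validate the
statistical mechanism — extreme-value binding, condensation, selection on
a random energy landscape — not any structure-level prediction about a
particular protein.

## Numerical choices

* Boltzmann sums shift energies by the spectrum minimum (log-sum-exp),
  since `u/T ≈ −40` at low temperature would overflow naive sums.
* Melting temperatures come from the discrete argmax of central-difference
  `−dY/dT` on the user's grid; no interpolation.  Flat curves report `NA`.
* Exact energy ties (measure zero under continuous couplings) are broken
  lexicographically on `(epitope_i, epitope_j, orientation)` for
  reproducibility.
* The default motif map is the identity permutation; because couplings are
  exchangeable random variables, any bijection is statistically
  equivalent, and a seeded random permutation is available to check that.
* The evolution kernel materializes the coupling table when `‖M‖ ≤ 4096`
  and otherwise evaluates the hash per lookup, bounding memory at large
  `ξ`.
* Mutation inside the kernel draws the per-member substitution count from
  `Binomial(n_residues, ε)` and places it on uniformly chosen distinct
  positions — exactly the per-residue iid Bernoulli process, at a fraction
  of the random-number cost.

## Problem sizes used by the tests

The test suite and the acceptance script run the censuses at their full
reference scale (10⁴ random realizations; 50 evolved realizations of
`N = 10³` members for 10³ generations), the variance ratio at 10⁵
peptides, the extreme-value comparison at 10⁴ simulated minima, and the
condensation curves at 200 disorder realizations per level count up to
`n = 80000`.  Module tests use smaller sizes chosen so that each
statistical assertion still has at least a few standard errors of slack.
Disorder averages beyond these sizes change nothing qualitatively; the
experiment functions expose all counts as arguments.

## Known limitations

* The Gumbel and condensation formulas are `n → ∞` limits; at the level
  counts of realistic surfaces their finite-size error is larger than the
  Monte-Carlo error of desk-scale simulation (numbers above).
* The 4-letter evolution alphabet carries the small-alphabet artifacts
  described earlier; evolved-census fractions inherit them.
* Affinity optimisation itself is believed hard for intermediate `ξ`; the
  package only ever *samples* and *evolves*, it does not attempt exact
  ground-state search over sequences.
* Homodimer critical temperatures use the homodimer level count
  `nP(nP−1) + 2nP` in `T_c`, a convention choice for a quantity the model
  defines only for heterodimers.
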