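---
title: "Modelling DNA fragment rejoining by Ku-dependent NHEJ"
author: "NHEJsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DNA fragment rejoining by Ku-dependent NHEJ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NHEJsim)
```

## The model

Ionizing radiation cuts chromosomal DNA into fragments. In the Ku-dependent
non-homologous end-joining (NHEJ) pathway, the Ku70/Ku80 heterodimer is the
first repair factor to load onto a free double-strand end; once both
partner ends carry Ku, two fragments can be ligated. NHEJsim implements a
deliberately reduced reaction network that keeps only this first, Ku-binding
step and abstracts every later factor (DNA-PKcs, XRCC4/LigIV, XLF) into the
ligation event itself. The point of the reduction is to expose how the
*length spectrum* of the initial fragments — which differs strongly between
high-LET radiation such as Fe ions and low-LET radiation such as gamma rays
— controls the kinetics of rejoining.

Three irreversible reaction classes act on a multiset of fragments:

1. **Recruitment.** A generic repair protein `E` (Ku) binds a FREE fragment
   end at propensity `kf * nE / V` per end. Ku is abundant, so its copy
   number `nE` is constant; recruitment never depletes it. Because Ku must
   thread onto the duplex and translocate inward, a fragment needs a
   minimum length `Lmin` to hold one Ku at all, and a critical length `Lc`
   to hold two Ku simultaneously, one per end. `siteCapacity()` maps length
   to 0, 1 or 2 binding ends accordingly. Capacity-0 fragments are
   *irreparable*: they can never enter the network.
2. **Joining.** Any two BOUND ends on *distinct* fragments ligate at
   propensity `kj / V` per bound-end pair (a pair of fragments with `b_i`
   and `b_j` bound ends contributes `b_i * b_j` elementary pairings, which
   the channel enumeration aggregates into one channel of propensity
   `(kj/V) * b_i * b_j`). The joined product has the summed length. What
   happens to the Ku molecules at the junction depends on the partners:
   * **short + short** (both capacity 1): the junction Ku pair becomes a
     *double residue* `R` that sterically blocks both ends of the product;
   * **short + long**: a *single residue* `r` blocks the product end on the
     short partner's side — the junction lies within a Ku footprint of that
     end — while the long partner's far end is inherited unchanged;
   * **long + long**: the junction is far from both ends, so the residue is
     inert and is dropped from the bookkeeping.
3. **Release.** A residue is cleared at first-order rate `kr`, freeing the
   end(s) it blocks. A double residue `R` is one physical Ku pair and is
   removed by a *single* release event that frees both ends at once.

The state is a multiset of fragments with per-end status
(FREE/BOUND/BLOCKED) plus residue tokens; total base pairs are conserved by
every reaction, and each join reduces the fragment count by exactly one, so
a run from `M0` countable fragments to a single product contains exactly
`M0 - 1` joins. The **rejoining time** is the elapsed time until the
countable-fragment count first reaches one, i.e. the timestamp of the last
join; trailing release events do not extend it.

Because the network has small copy numbers (tens to hundreds of fragments
per nucleus), we simulate it exactly with Gillespie's direct method rather
than with rate equations: the waiting time is exponential with the total
propensity, and the channel is selected by a single uniform draw scanning
the cumulative propensity.

## Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `kf` | Ku recruitment rate constant | volume/time | 1 |
| `nE` | Ku copy number (constant) | count | 1 |
| `kj` | end-joining rate constant | volume/time | 1 |
| `kr` | residue release rate | 1/time | 1 |
| `Lmin` | minimum length for one Ku | bp | 20 |
| `Lc` | critical length for two Ku | bp | 42 |
| `V` | nuclear volume | volume | 1 |

The length thresholds come from Ku biochemistry: roughly 20 bp of duplex
are needed for efficient binding of one heterodimer, and a 42 bp duplex can
hold two heterodimers, one per end. Both are configuration-exposed because
they are biological estimates, not constants of nature.

Absolute rate constants for the recruitment, joining and release steps are
not identifiable from published foci kinetics without fitting, which this
package deliberately does not do. All three default to 1, and time and
volume are treated as arbitrary consistent units: the dynamics depend only
on the pseudo-first-order combinations `a = kf*nE/V` (per free end),
`b = kj/V` (per bound-end pair) and `kr`, so every result in this package
is covariant under a joint rescaling of time and volume. Users who think in
pseudo-first-order terms should keep `nE = 1` and fold the Ku concentration
into `kf`; `nE` is kept as an explicit factor only so that recruitment
remains visibly a second-order reaction affected by `V`.

## Initial distributions: what the generators emulate

The generators produce the initial fragment-length spectra the ensemble
experiments need:

* `fixedLengthDistribution(M0, n)` — all fragments the same length; the
  cleanest probe of the length thresholds.
* `uniformRandomDistribution()` — `k` distinct lengths with uniform counts,
  a generic "mixed damage" spectrum.
* `twoClassDistribution()` / `radiationPreset()` — a short class (below
  `Lc`) and a long class. The presets encode the radiation-quality
  difference at 1 Gy: Fe ions (high LET, clustered energy deposition along
  the particle track) yield **30%** short fragments, gamma rays (low LET)
  **3%**. The class split is a *deterministic* apportionment
  (`round(M0 * pShort)`, remainder long) so the preset fractions are exact
  and testable; only the lengths within each class are sampled (uniformly
  on `[Lmin, Lc-1]` and `[Lc, 3000]` bp by default — configuration-exposed
  choices, since measured small-fragment spectra below a few hundred bp are
  not available).
* `fractionPairDistribution(M0, q1, q2)` — three bands: very short
  fragments in `[Lmin, ceiling(Lc/2))`, whose pairwise joins still fall
  short of `Lc` and therefore require *repeated* residue releases; short
  fragments in `[ceiling(Lc/2), Lc)`; and long fragments. The band split at
  `Lc/2` is chosen precisely because it separates fragments by whether one
  join suffices to reach double-Ku capacity — the mechanism behind the
  second jump in the mean-rejoining-time-versus-length curve.
* `addIrreparable(dist, pIrr)` — appends capacity-0 fragments (below
  `Lmin`) for comparison with focus-decay experiments, again by
  deterministic apportionment.

What the synthetic spectra do **not** emulate: track-structure physics (no
Monte-Carlo prediction of fragment spectra from particle tracks), sequence
content, complex chemically-modified ends, inter-chromosomal structure, or
spatial proximity of ends (the model is well-mixed). Passing tests
therefore demonstrate properties of the reaction network under idealized
spectra, not quantitative agreement with any measured repair curve.

## The stochastic engine and reproducibility

Channels are enumerated in a fixed, documented order — RECRUIT channels by
(fragment position, end index), JOIN channels by lexicographic fragment
pair, RELEASE channels by ascending residue-token id — and the
direct-method selection scans the cumulative propensity with a single
uniform draw (`rexp` for the waiting time first, then `runif`). The
production loop in `simulateRejoining()` performs this scan blockwise in
O(n) using aggregate totals (`a * nFree`, `(kj/V)(B^2 - sum(b^2))/2`,
`kr * nTokens`); a test asserts channel-for-channel agreement between the
fast scan and the literal enumerated scan. When a fragment has two bound
ends, the joining end is taken to be the lower-indexed one; both ends are
BOUND in that case, so the choice cannot affect the distribution of
outcomes.

Every ensemble routine derives the seed of replicate `i` as
`deriveSeed(masterSeed, i)`, a fixed affine congruential mix modulo
`2^31 - 1`, so a replicate's stream does not depend on how many replicates
run, and every table is bit-reproducible from its master seed. Sweep point
`p` uses the sub-master `deriveSeed(masterSeed, 7919 p)` and surface grid
point `g` uses `deriveSeed(masterSeed, 104729 g)` to keep streams disjoint.

Degenerate inputs are handled explicitly: a single-fragment distribution
completes at time 0 with no events; a state with positive countable count
but zero total propensity terminates as `"stalled"` (possible only in
comparison mode, e.g. a distribution of only irreparables); an event whose
precondition fails (recruiting a non-FREE end, joining a non-BOUND end,
releasing a dead token) raises a contract error rather than silently
corrupting the state, since it can only arise from an enumeration bug.
Joining a fragment to itself (circularization) is disallowed: the network
only ever joins two distinct fragments.

## The exact oracle

For systems of at most 4 countable fragments, `enumerateStateSpace()`
expands every reachable state breadth-first using the *same* update rules
as the engine, so transition rates equal channel propensities by
construction. States are canonicalized — fragments unordered, end labels
sorted within a fragment, residue tokens distinguished only as single (`r`)
versus double (`R`) — which is a strong lumping of the chain (propensities
depend only on status counts), so mean first-passage times are preserved.
`exactMeanRejoiningTime()` solves the standard first-passage linear system
over transient states by dense LU; absorption is defined on
countable-fragment count = 1, matching the rejoining-time definition, so
releases after the final join are excluded. For two one-site fragments the
chain collapses to three sequential exponentials with mean
`3/(2a) + 1/b`, which `closedFormTwoShort()` provides as an independent
analytic anchor; the test suite requires solver/closed-form agreement to
1e-10 relative and engine/solver agreement within three standard errors at
10^4 replicates on four fixtures.

## Ensemble experiment sizes

The suite and the acceptance script run ensembles sized to finish in
minutes on one core while keeping every statistical check at a 3-standard-
error tolerance: 10^4 replicates for the oracle comparisons, 500 replicates
per sweep point for the monotonicity battery, 5 sampled distributions × 40
replicates per fraction-surface grid point (M0 = 20), and 100 replicates
for the kinetics curves (60 countable fragments, grid `[0, 40]`). Published
studies of this model family use larger ensembles (150 samples per point
and thousands of sampled distributions); all sizes here are arguments, so
scaling up is one call away. The 3-SE bands are the package's own
acceptance convention — the model makes no claim about tolerances.

For the kinetics comparison the irreparable admixture is set to 30% for the
Fe-like preset and 5% for the gamma-like preset. These are the package's
reading of clustered-damage estimates — for high-LET particles upwards of
30% of double-strand breaks form close enough together to produce
sub-nucleosomal fragments, against below 5% for low-LET photons — and they
produce the expected biphasic shape: a fast phase from long-fragment joins
(no release step), a slow phase from residue-gated short-fragment joins,
and a plateau at the irreparable fraction.

## Known limitations

* One generic protein species; no downstream NHEJ factors, no B-NHEJ, no
  homologous recombination, and no competition between pathways.
* All three reactions irreversible. Real Ku binding is reversible with a
  slow off-rate; the irreversible model is the small-off-rate limit and can
  differ quantitatively.
* Well-mixed kinetics: no spatial correlation between ends that were
  adjacent on the chromosome, so the model cannot distinguish correct from
  incorrect rejoining partners.
* Exact solutions only for toy systems (≤ 4 fragments); at realistic `M0`
  the state space is combinatorial and only the stochastic engine applies.
* Absolute times are in model units; mapping to hours requires fitting
  `kf`, `kj`, `kr` to data, which is out of scope.

## A worked example

```{r example, eval = FALSE}
p <- SimParams()
fe <- radiationPreset("fe_ion", M0 = 200, seed = 1)
shortFraction(fe, p)                       # exactly 0.30
tr <- simulateRejoining(fe, p, seed = 1)
rejoiningTime(tr)
s <- replicateTimes(fixedLengthDistribution(10, 30), p,
  nSamples = 150, masterSeed = 1)
meanTime(s)
exactMeanRejoiningTime(fixedLengthDistribution(2, 30), p)  # 2.5
```
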