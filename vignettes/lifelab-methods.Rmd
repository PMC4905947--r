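---
title: "lifelab: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lifelab: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifelab)
```

## The two rule sets

Conway's Game of Life runs on a square grid of two-state cells. Its update
rules are totalistic over the Moore 8-neighbourhood: a live cell survives
with two or three live neighbours and otherwise dies (isolation at one
neighbour or none, overpopulation beginning at exactly four); an empty cell
becomes live with exactly three live neighbours. `lifelab` keeps these
*conditional* rules explicit as a `life_rule` object (default `B3/S23`),
separate from the *existential* decisions — which cells exist at generation
zero — that are supplied by patterns, fixtures or seeded soups. The package
is built around that separation because it is the interesting one for
developmental modelling: one set of rules creates the initial material, a
different set regulates what the material does, and the observed forms are
the joint product of both.

The engine is sparse: the universe is the set of live coordinates, and a
step examines only live cells and their neighbours (the candidate-set
method). This is exactly equivalent to a dense scan — the test suite proves
it against a naive boolean-matrix engine on seeded random soups — but
permits an unbounded plane. Updates are synchronous; the generation counter
increments by exactly one per step, and each step reports its birth and
death sets, whose sizes satisfy the conservation identity
`pop(t+1) = pop(t) + births − deaths` on every trajectory the package
produces.

Two topologies are supported. The infinite plane is the default and is the
right setting for classifying a single form. The bounded torus exists for
ecosystem-scale experiments, where stabilization must be a well-defined
event: a torus has finitely many states, so a global cycle is guaranteed
within the reachable-state budget. Torus wrap applies to neighbour lookup
only. Rules with birth on zero neighbours are rejected on the infinite
plane (they would fill it instantly) and handled by full-grid enumeration
on the torus.

## The emergent-form taxonomy

The classifier implements the taxonomy of forms that emerge from the rules:

* **still life** — invariant under one step;
* **oscillator** — returns to its initial state after a minimal period of
  two or more, with no net displacement;
* **spaceship** — returns to its initial state up to a nonzero translation;
* **dies out** — the live set empties;
* **unresolved** — no recurrence within the generation budget.

Two modes are deliberately distinct, because "is periodic" and "becomes
periodic" are different questions. `classify_exact()` watches for the first
recurrence of the *initial* translation-canonical state; `classify_fate()`
hashes every state seen and reports the first cycle entered, plus the
transient length. The L-tromino illustrates the difference: as given it
never recurs (`classify_exact` reports `unresolved`), but after one step it
has grown a fourth cell that binds it into a block, so `classify_fate`
reports a still life with transient 1. Cycle detection is by hash map
rather than Floyd/Brent cycle-finding: one pass recovers both transient and
period, and memory is bounded by the generation budget, which is the
practical constraint here.

States are compared by a translation-canonical perfect hash (live set
normalized to its bounding-box origin); displacement is read off the drift
of the bounding-box origin at first recurrence. Because the search stops at
the *first* hit, reported periods are minimal by construction, and reported
speeds can never exceed one cell per generation per axis.

The default classification budget is 1000 generations, chosen to exceed any
oscillator period the package's experiments encounter by a wide margin
while keeping per-object cost trivial. The object extractor links live
cells at Chebyshev distance at most `link_radius`, default 1
(8-connectivity), which matches visual object identity. The radius is a
real parameter, not a formality: the minimal-population phases of the
heavier spaceships carry a nose cell at Chebyshev distance 2 from the hull,
so a census of those exact phases needs `link_radius = 2` to see one object
per ship; the package leaves the default at 1 and lets the caller widen it
where closely adjacent pseudo-objects belong together.

An enumeration the classifier settles empirically: of the two free
triominoes, the straight row is a period-2 oscillator (the blinker) and the
L-tromino becomes a still life — so *neither* dies, and adhesion into the
block is not the only way three cells survive.

## The experiment harness

`make_soup()` produces reproducible random initial conditions. Bernoulli
mode fills each cell independently at a given density; scribble mode
emulates a hand-drawn analog shape by seeded random walks (uniform over the
8 directions, stroke length twice the grid perimeter, the aggregate path
clamped onto the grid). A hand scribble is irreproducible by nature, so the
walk's distribution is fixed and documented; what matters for the
experiments is preserved — a connected, blob-like initial form whose
decisive details are not evident by inspection. All stochastic operations
are pure functions of their seed and restore the caller's RNG state.

`free_evolution()` records a census per generation: population, the step's
births and deaths, object count, and per-kind object tallies. Per-object
classification inside the census uses a 20-generation budget by default:
ash objects (blocks, blinkers, small still lifes) resolve instantly, while
large active blobs are honestly reported `unresolved` rather than chased at
every generation. The reference soup experiment — 32×32 torus, density
0.35, seed 42, 125 generations — is frozen as a golden-master CSV; its
population/births/deaths trajectory is additionally verified against the
independent dense engine at test time. These problem sizes (16×16 oracle
soups, a 32×32 reference run, 4×4 tori for the exhaustive-stabilization
property) were chosen to exercise every code path at desk scale.

Global stabilization (`detect_stabilization()`) hashes the
translation-*sensitive* state: at ecosystem scale position is meaningful,
so a lone glider drifting forever never "stabilizes", while object
classification remains translation-canonical at organism scale. Escape
detection reports a mover at the first generation its bounding box clears
the watched region (expanded by a margin), requiring a crossing from the
previous generation so a ship travelling away is reported once.
`collide()` is deterministic given patterns and offset; on the infinite
plane a surviving mover keeps the global state from repeating, and the
outcome is then reported as unresolved-within-budget with the final census
attached — which is the honest answer, not a failure mode.

`box_counting_dimension()` estimates the Minkowski dimension of a live set
from occupied-box counts over a ladder of box sizes, by least squares on
log(count) against log(1/size). It recovers 2 for filled squares, 1 for
lines and 0 for a point exactly; on ash it is a descriptive statistic whose
value depends on the size ladder supplied, and the per-size counts are
returned so the fit can be inspected.

## Morphogen dynamics on a ring of cells

The second laboratory is linear stability analysis of `m` morphogens
reacting within, and diffusing between, `N` cells arranged in a ring — the
discrete cellular case, not the continuous circle, matching the package's
cell-grid framing; the continuum limit is the standard
`sin² → (wavelength)⁻²` correspondence and is not implemented. Writing `J`
for the reaction Jacobian at the homogeneous equilibrium and `μ` for the
per-morphogen exchange rates, a perturbation with wavenumber `k` evolves
under the mode matrix

```
M_k = J − 4 sin²(πk/N) · diag(μ),   k = 0, …, N−1,
```

the circulant eigenstructure of nearest-neighbour coupling on a ring. Modes
`k` and `N−k` are conjugate and identical in spectrum; the package computes
one half and mirrors the other, and tests assert the symmetry.

Each mode is classed on two axes. Temporal: *stationary* when the dominant
eigenvalue (largest real part) is real within tolerance, *oscillatory* when
it is complex. Wavelength: *extremely long* at `k = 0` (or `k/N` within a
configurable fraction, default 0.05), *extremely short* at `k = ⌊N/2⌋` (or
within the complementary fraction, default 0.45), *finite* between. The
qualitative categories carry no canonical numeric boundary, so the
fractions are parameters with documented defaults rather than constants.
Tolerances (`1e-9` by default) are taken relative to the mode matrix's
Frobenius norm, so classification does not depend on the overall scale of
the model. The system's class is its dominant mode's class, ties broken
toward the smallest wavenumber — a growing stationary mode at finite `k` is
the classic diffusion-driven (Turing) instability, the analogue of a still
life crystallizing out of uniformity; a growing oscillatory mode is a wave
instability, the analogue of a blinker.

`scan_for_oscillatory_finite()` probes a structural claim: that
finite-wavelength oscillatory instability requires at least three
morphogens. For two morphogens with diagonal diffusion this is provable in
the package's setting — when a 2×2 mode matrix has complex eigenvalues
their real part is half its trace, which diffusion only lowers, while the
undiffused `k = 0` mode always carries at least half the trace of `J` — so
the scan's zero count at `m = 2` is expectation, not accident. At `m = 3`
such instabilities exist but are rare under uniform sampling of Jacobians
in `[−1,1]` and diffusions in `[0,1]` (measured hit rate of order 4·10⁻⁴),
so the scan defaults matter: the test suite uses 10,000 samples at `m = 2`
and 20,000 at `m = 3`, and freezes one found three-morphogen model as a
reproducible fixture. The scan is evidence, not proof, for `m ≥ 3`; for
`m = 1` a real scalar cannot have a complex eigenvalue, and the count is
zero trivially.

## Numerical and interface choices

* Coordinates are 0-based, x rightward, y downward; patterns normalize to
  their bounding-box origin. Cell sets are packed into doubles
  (`(x+2²⁰)·2²¹ + (y+2²⁰)`), exact far beyond any reachable extent, for
  hashing and matching.
* RLE follows the Golly/LifeWiki dialect: header optional on read and
  emitted on write, `#` comments tolerated, body lines wrapped at 70
  characters without splitting runs, parse errors located by line and
  column. Plaintext treats blank lines as rows of dead cells. Round-trips
  preserve cell sets exactly.
* The fixture library carries the canonical forms in their standard
  minimal-population phases (block, blinker, L-tromino, glider, LWSS,
  MWSS, HWSS, R-pentomino), each verified by simulation in the test suite.
* The command line (`exec/lifelab`, subcommands `simulate`, `classify`,
  `soup`, `collide`, `ring`) is a thin wrapper over the exported functions;
  every subcommand is deterministic given its config file, and rule strings
  are accepted in B/S notation only.

## Limitations

The engine is a plain sparse implementation: no Hashlife-style
acceleration, no multi-state cells, no non-totalistic rules. The classifier
works at desk scale; it does not attempt exhaustive spaceship searches or
unbounded-growth proofs, and a pattern that outlives its budget is reported
`unresolved`, never guessed. Soups emulate random and scribbled initial
conditions, not any empirical distribution of biological configurations —
what passing tests establish is internal consistency of the machinery
(engine ≡ oracle, conservation, reproducibility, frozen reference runs),
not correspondence to any particular organism. The ring analysis is linear:
it classifies instabilities of the homogeneous state and says nothing about
the nonlinear patterns they grow into.
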