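---
title: "Randomized bond alternation for large conjugated systems: models, parameters and design choices"
author: "kekule package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomized bond alternation for large conjugated systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kekule)
```

## The assignment problem

A molecular connectivity with elements and valences determines, for
every atom, a *π-deficiency*: the number of extra bond-order units it
must receive beyond single bonds and hydrogens,

$$d(a) \;=\; \mathrm{val}(a) - n_\mathrm{H}(a) - \deg(a),$$

with unresolved (aromatic) bonds counted at order 1.  Aromatic carbons
have $d = 1$; the sp carbons of acetylene linkers have $d = 2$;
saturated atoms and trivalent nitrogen with three single bonds have
$d = 0$.  A Kekulé structure is an assignment of π-orders
$x_e \in \{0, 1, 2\}$ to the unresolved bonds with
$\sum_{e \ni a} x_e = d(a)$ for every atom — a capacitated
$b$-matching.  Deficiencies outside $\{0, 1, 2\}$ are rejected rather
than guessed: the model covers double, triple and cumulated bonds, and
nothing else claims to be supported.

Two structural laws are useful throughout.  *Parity*: each edge unit
satisfies two demand units, so a connected π-system with odd total
deficiency has no assignment; the unmatched-atom count of any
alternation pass over it is odd.  *Conservation*: kekulization never
adds or removes atoms, so molecular formulas are invariant — unmatched
atoms are "removed" by re-randomization and repair, never by deletion.

## The randomized algorithm

One *pass* of the kekulizer interleaves two mechanisms:

* **Forced-move propagation.**  An atom whose free capacity
  ($\sum_{e}\min(2, d_\mathrm{rem}(\text{partner}))$ over its
  unassigned edges) equals its remaining demand has exactly one valid
  extension; a worklist applies such moves immediately.  This is the
  alternation mechanism proper: placing one double bond forces a
  single/double alternation outward along every affected ring or
  chain until a genuine choice appears.
* **Random bond selection.**  When nothing is forced, the next atom in
  a uniformly shuffled visiting order places π-order on an eligible
  incident edge, with ties among edges broken by a second shuffled
  priority.  A $d = 2$ atom prefers one π-order-2 edge (a triple bond)
  when its partner can also accept two units, else two π-order-1
  edges (a cumulene) — an arbitrary but fixed tie-break; validity is
  indifferent to it.

A pass typically leaves a handful of atoms unmatched, independent of
structure size (a few per hundred thousand atoms on the nanotube and
graphyne families).  These are removed by **alternating-walk repair**:
a breadth-first search from each unmatched atom along walks that
alternate increasable ($x_e < 2$) and decreasable ($x_e > 0$) edges,
ending at another unmatched atom; applying $+1/-1$ along the walk
satisfies both endpoints and leaves interior atoms unchanged.  This is
augmentation for capacitated matching, without blossom handling — a
missed walk through an odd cycle is not an error, it simply leaves the
atom unmatched.  Only then is a full reshuffle charged as the next
*iteration*.  We read the repeated-trial statistics of this class of
algorithms — average shuffle counts near 1.00 side by side with
nonzero "unmatched before removal" histograms — as implying exactly
this structure: removal happens inside an iteration, restarts are the
exception.  The pure restart strategy remains available
(`kekulize_config(augment = FALSE)`) and is measurably worse on every
family; a unit test pins that ordering.

On exhaustion of the shuffle budget the **exact backtracker** decides
existence.  It is a depth-first search over per-atom demand
satisfaction with (i) most-constrained-first selection, ties broken
toward recently touched atoms to keep the search local on lattices,
(ii) forward capacity pruning and unique-extension propagation,
(iii) odd-component parity pruning, and (iv) geometric restarts: a
node budget that doubles across deterministically shuffled
relabellings of the π-system, so one unlucky early commitment cannot
pin the search in an exponential subtree.  A verdict is only ever
reported by a completed search, so exactness is preserved; the stack
is explicit, so π-systems of $10^5$ atoms cannot overflow the C stack.
The search is worst-case exponential — it is the fallback, not the
default path, and a guaranteed-polynomial matching algorithm is
deliberately out of scope.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_iterations` | 300 | shuffles before deciding non-existence (approximate path) or invoking the exact fallback |
| `seed` | none | every shuffle and every aza placement derives from it; identical (structure, seed, config) gives identical results |
| `exact_fallback` | `TRUE` | prove non-existence instead of presuming it |
| `augment` | `TRUE` | unmatched-atom removal by alternating walks |

The 300-shuffle cutoff is the benchmark convention for deciding that a
Kekulé structure "does not exist" on the approximate path; with the
fallback enabled it is merely the switch-over point.  Reported
`unmatched_first_pass` is always the count after the first pass and
before any removal, so trial histograms are comparable across
configurations.

## The structure generators

The generators are first-class, tested code: they define the study
conditions under which the kekulizer is validated, and their defaults
are the benchmark compositions.  The unit cells were designed to
satisfy the benchmark composition laws, ring content and
kekulizability, and those laws — not pictorial detail — are what the
tests pin.

* **Nanotube** — armchair C[12,12]: a honeycomb "brick" lattice wrapped
  into a 24-atom circumference, $6n$ axial columns; armchair end atoms
  carry one H each.  $C_{144n}H_{48}$.
* **Graphene** — open 12-row × $12n$-column strip; every edge atom
  carries $3 - \deg$ hydrogens and the two degree-1 attachment-point
  carbons gain one more on termination.  $C_{144n}H_{12n+26}$.
* **GY1** — γ-graphyne ribbon (rings on a triangular superlattice, all
  adjacent pairs joined by –C≡C–), 6 rings tall, $2n$ wide, the 22 end
  junction positions methyl-terminated.  $C_{136n}H_{8n+66}$.  Under
  this lattice the end-cap composition is forced uniquely by the
  composition law, which is why methyl (and not methylene or
  acetylene-H) caps appear.
* **GY7** — the same lattice 16 rings tall, one column per unit; each
  end exposes 31 positions terminated by a fixed mix of =CH₂ caps,
  –C≡CH stubs and bare CH.  $C_{188n}H_{4n+82}$.
* **Graphyne nanotube** — GY7 made vertically periodic by acetylene
  bridges (edge hydrogens replaced by vertically bonded carbons).
  $C_{192n}H_{72}$.
* **Polycyclopentadiene** — $30n$ five-membered rings joined by
  junctions cycling 2,1,2 bonds; linear ends are hydrogen-capped
  ($+4$ H), cyclic joins straight, Möbius joins crisscross (same
  formula and degree sequence, different edge set).
  $C_{150n}H_{50n(+4)}$.
* **Fullerenes** — C20 (dodecahedron) and C60 (truncated icosahedron)
  from exact golden-ratio coordinates; larger cages are isomer-specific
  and must be read from molfiles.  **Porphine** is a hardcoded
  $C_{20}H_{14}N_4$ fixture with two pyrrole-type (N–H, $d=0$) and two
  pyridine-type ($d=1$) nitrogens.
* **Aza substitution** replaces $k$ uniformly chosen hydrogen-free
  carbons by trivalent N; an N whose deficiency drops to zero keeps
  three explicit single bonds.  Odd $k$ warns: the parity law
  guarantees failure.

What the generated structures do *not* emulate: real geometry (the
coordinates, where present, are schematic), defects, charges,
isotopes, heteroatoms beyond C/H/N, and isomer diversity.  Passing
tests therefore demonstrate correctness of the assignment machinery on
ideal lattices, not robustness to the noise of experimental structure
files.

## Numerical and I/O choices

Deterministic seeding uses R's RNG with save/restore, so library calls
never perturb a session's random stream.  Per-trial seeds in
`run_trials()` are derived from the master seed by a counter-based
linear map within the 32-bit range, making trials order-insensitive.
For aza families the default draws a fresh nitrogen placement per
trial (the statistics then describe the family of random aza-analogs);
`aza_per_trial = FALSE` freezes one placement.

Molfile input maps bond type 4 to "unresolved"; types 1–3 are taken as
resolved.  Implicit hydrogens are inferred from the valence deficit,
reserving one unit for atoms in the π-system; files containing any
explicit hydrogen are taken to have all hydrogens explicit.  This
inference cannot distinguish an aromatic CH from a bare sp carbon in a
type-4 file, so round trips of hydrogen-bearing aromatic structures
should use `explicit_h = TRUE` (the writer can expand hydrogens to
explicit atoms); kekulized files round-trip exactly.  V3000 is
selected automatically beyond 999 atoms or bonds.  The `.cc1` dialect
is intentionally unsupported.

## Problem sizes used in the test suite

Composition laws are asserted at chain lengths 1–3, 10, 100 (unit
tests) and up to $10^4$ (acceptance tests; the largest generated
structure is the $1.9\times10^6$-atom GY7 at $n = 10^4$).  Kekulé
existence is exercised for every family at $n \le 10$ with the exact
fallback, at $n = 1000$ (144,000 atoms) for the nanotube, and against
a brute-force enumeration oracle on 500 random π-systems of ≤ 14
atoms.  Repeated-trial statistics use 1000 trials for C60 and
porphine.  These sizes were chosen to pin every composition law at
several independent chain lengths while keeping the default suite in
the tens of seconds.

## Known limitations

* The exact fallback is exponential in the worst case; its restart
  schedule makes feasible lattice instances fast in practice but gives
  no guarantee.
* Alternating-walk repair is blossom-free and may miss augmenting
  walks through odd cycles; this costs iterations (polycyclopentadienes
  restart more than benzenoids) but never correctness.
* Unmatched-atom histograms depend on the exact shuffle stream; they
  are comparable in magnitude and parity across implementations of
  this algorithm family, not entry for entry.
* Elements beyond C, N and H are accepted through the extensible
  valence map but untested; charges, radicals and isotopes are out of
  the data model.
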