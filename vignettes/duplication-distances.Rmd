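---
title: "Duplication distances: models, algorithms and design notes"
author: "dupdist maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplication distances: models, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupdist)
```

## The biological problem

Large segmental duplications (low-copy repeats) in mammalian genomes are
typically mosaics of smaller repeated units ("duplicons").  A parsimonious
way to explain how such a mosaic block arose is to model its construction
as a series of copy-and-paste events: substrings of a fixed, unchanging
source sequence are repeatedly copied and inserted into an initially
empty target until the observed block is assembled.  The *duplication
distance* from a source `x` to a target `y` is the minimum number — or,
with affine costs, the minimum total cost — of such duplicate operations.
This package implements that distance and four extensions (deletions
inside the copied string, inversion of the copied string, both combined,
and in-place inversion of an internal substring of the copy) as exact
dynamic programs with optimal-scenario traceback, together with a
brute-force oracle, an equivalent context-free-grammar formulation, and
seeded generators of synthetic instances.

The unit of analysis is a string of duplicon identifiers, not raw
nucleotides: each character stands for an elementary repeated segment,
and a signed character carries its genomic orientation.

## The model

A *duplicate operation* copies a substring `x[s..t]` of the immutable
source and pastes it at position `p` of the growing target `z`
(`z[1..p-1] x[s..t] z[p..]`).  Because previously pasted characters are
never reordered, each operation's contribution appears in the final
target as a subsequence, and the subsequences contributed by distinct
operations are pairwise *non-overlapping*: for any two, one lies entirely
before, entirely after, or strictly between two consecutive characters of
the other.  This non-overlapping property is what makes an efficient
recurrence possible — once we fix the operation that generated `y[1]`,
the stretches of `y` between that operation's characters become
independent subproblems.

The recurrence tracks two quantities: the unrestricted distance
`d(x, y)` over intervals of `y`, and the restricted distance
`d_i(x, y)` in which `y[1]` is generated by source position `i`.  Writing
`Δ1 + ℓΔ2` for the affine cost of copying `ℓ` characters:

* **case 1** — `y[1]` is the last character of its copy:
  `Δ1 + Δ2 + d(x, y[2..])`;
* **case 2** — the copy continues with `x[i+1]` generating some `y[j]`
  (`j > 1`, `y[j] = x[i+1]`): `Δ2 + d(x, y[2..j-1]) + d_{i+1}(x, y[j..])`.

`d(x, y)` minimizes `d_i` over all `i` with `x[i] = y[1]`; the distance
is *undefined* when some character of `y` never occurs in `x`.

The four extensions reuse this skeleton:

* **duplicate-delete** (`"dupdel"`): the next retained character may sit
  at any `k > i`, paying `(k-i)Δ2 + Φ(k-i-1)` — deleted characters still
  pay the per-character affine term because the operation physically
  copies the whole span, and each internally deleted run of length `g`
  costs `Φ(g)`.  `Φ` must be non-decreasing and subadditive; under those
  conditions free-standing deletions of the intermediate target never
  beat deletions fused into the copying operation, which is why the
  recurrence only prices fused operations.
* **duplicate-invert** (`"dupinv"`): signed strings; a copy may be
  inverted (order reversed, all signs flipped) before pasting, at affine
  cost `Θ1 + ℓΘ2`.  An inverted chain starting at `x[i]` continues with
  `-x[i-1]`; the implementation expresses this elegantly as a forward
  chain along `invert(x)`.
* **duplicate-invert-delete** (`"dupinvdel"`): both mechanisms; the
  reverse chain jumps to any `k < i`, paying `(i-k)Θ2 + Φ(i-k-1)`.
* **substring inversion** (`"dupsubinv"`): for every span `(s, t)` of the
  source (plus the identity), the string `x^{s,t}` with that span
  inverted in place is a separate copying template; an operation using
  template `(s, t)` pays a one-off `Θ(t-s+1)` on top of its `Δ`-affine
  cost.  The surcharge is levied exactly once per operation, at the
  case-1 branch that every operation's chain reaches exactly once, which
  keeps the state Markovian.  Spans not intersecting the copied region
  are not pruned: with `Θ` non-negative and non-decreasing they are never
  optimal, so pruning would only complicate the code.

### Sign handling

Unsigned input is lifted to all-`+` orientation, so one representation
serves everywhere.  The two deletion-free-of-inversion models (`"dup"`,
`"dupdel"`) are *sign-free*: they match symbols ignoring orientation, and
a replayed scenario reproduces the target's symbols with the source's
signs.  A consequence worth knowing: on signed input a sign-free distance
can be smaller than its sign-respecting counterpart (it solves an easier
matching problem), so model-containment comparisons across the two
families are only meaningful on unsigned instances.  Within each family,
enlarging the operation set never increases the distance.

## Tunable parameters

| parameter | meaning | default |
|---|---|---|
| `dupOpen` (Δ1), `dupExt` (Δ2) | affine duplicate cost, per op / per copied character | 1, 0 |
| `invOpen` (Θ1), `invExt` (Θ2) | affine duplicate-invert cost | = Δ1, Δ2 |
| `phi` (Φ) | cost of one internally deleted run of length g | `"unit"`: 1 per run |
| `theta` (Θ) | in-place substring-inversion surcharge | `"zero"` |

All costs are unitless "operation cost" — with the defaults every
operation costs 1 and distances count operations.  Affine `phi = c(a, b)`
(cost `a + b·g`) is validated exactly (non-negativity of both parameters
already implies monotone + subadditive); arbitrary cost functions are
only spot-checked on lengths 1..16 and the constructor warns accordingly.

## Numerical choices

Costs are doubles; all minimizations and tie-breaks compare with an
absolute tolerance of `1e-9`, which is far below any meaningful cost
difference at the problem sizes involved and makes traceback tie-breaking
deterministic.  Traceback prefers terminating an operation over extending
it, then the smallest split position `j`, then the smallest source index
— so repeated runs emit byte-identical scenarios.  The recursion guards
its depth (option `dupdist.maxDepth`, default 5000) and fails with a
clear message rather than exhausting the C stack on extreme targets.
Coordinates are 1-based inclusive throughout, matching both the standard
sequence-analysis convention in this ecosystem and the natural reading of
the paste operation `z[1..p-1] · copy · z[p..]`.

## The oracle, and why it is independent

The dynamic programs' recurrences are intricate enough that they are
gated on an exhaustive brute force.  The oracle does not share the
interval recurrence: it enumerates *set partitions* of the target's
positions, keeps those whose parts are pairwise non-overlapping, asks for
each part whether a single operation of the variant can paste exactly
that subsequence (and at what minimum cost), and minimizes the summed
costs.  Soundness comes from the non-overlapping property; completeness
from the observation that any non-overlapping family can be realized by
pasting parts in order of their first position.  The partition search is
exponential and therefore guarded to `|y| ≤ 7`, `|x| ≤ 5`.

A second, even more literal search mode replays *unfused* duplicate and
delete operations over intermediate strings (bounded uniform-cost search,
intermediate length capped at `|y| +` a configurable budget, with an
explicit cost ceiling).  It returns `NA` — never a wrong number — when
the bounds are exhausted.  Its agreement with the fused-operation oracle
is the empirical face of the canonicalization argument, which
`canonicalizeScenario()` also implements constructively: wholly deleted
contributions are dropped, deleted prefixes/suffixes are simply never
generated, and an internally deleted run (which can affect at most one
operation, by non-overlap) is fused into that operation as a deletion
gap.

## The grammar view

For fixed `x`, the grammar with productions
`S -> x_i S x_{i+1} S ... x_j S` (for all spans `i ≤ j`) plus `S -> ε`
derives exactly the strings buildable from `x`, and a parse of `y` with
the minimum number of nontrivial productions has exactly
`d(x, y)` of them under unit costs.  `minProductionParse()` reuses the
distance traceback rather than a generic chart parser: the recurrence
*is* the parse, with the case-2 split supplying the subtree between
consecutive copied characters and the case-1 suffix supplying the
trailing slot.

## Synthetic data

`randomSignedString()` draws uniform symbols with an orientation-flip
probability; `randomScenario()` draws valid operations of a variant
(uniform spans; internal deletions keep both span endpoints so operations
stay canonical; uniform insertion slots) and replays them.  Its product
is a *certified upper bound*: the true distance can only be smaller,
with equality guaranteed for a single deletion-free duplicate.  Small
alphabets (the default is three symbols) make operations share symbols,
so optima usually undercut the generated cost and the programs are
exercised nontrivially.  The generator emulates the combinatorics of the
model only — uniform spans and insertion points, not the empirical length
or copy-number distributions of real duplicon blocks, and no sequence
divergence after copying.  Green property tests therefore certify the
algorithms, not the biological fidelity of any particular instance.

## Problem sizes used by the test suite

The exhaustive gate runs every source up to length 4 against every
target up to length 5 over a three-letter alphabet; since all distances
are invariant under alphabet relabelling, sources are enumerated up to
relabelling (22 canonical sources × 364 targets × five variants × two
cost configurations, every value checked against the partition oracle).
Signed behaviour is covered by 200 seeded random signed pairs under the
same double check.  The unfused-search comparison runs exhaustively at
the sizes its state space explores comfortably (sources to length 3,
targets to length 4, two-letter alphabet, plus seeded signed cases for
the inversion variant).  Property sweeps (bounds, symmetry, containment,
non-overlap, traceback consistency) use 100–1000 seeded instances each.
These sizes were chosen as the smallest grids that exercise every branch
of every recurrence; enlarging them multiplies runtime without adding
new structure.

## Known limitations

* The source never mutates, and inversions apply only to duplicated
  material (at most one in-place span per operation in the
  `"dupsubinv"` variant) — richer variants (e.g. inverting only a prefix
  or suffix of the copy) are not implemented.
* The distances are asymmetric by construction (source to target); no
  phylogeny construction is provided.
* The exponential oracle and the bounded unfused search are validation
  tools, not production solvers; they refuse or return `NA` outside
  their guards.
* Complexity scales as `O(|y|² μ(x))` states for the contiguous-copy
  variants, with `O(|x|)` work per state for the deletion variants and an
  extra `|x|²` factor of templates for the substring-inversion variant
  (`μ(x)` = maximal character multiplicity); very long targets will feel
  the quadratic table first.
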