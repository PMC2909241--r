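---
title: "Designing sequences for 3-noncrossing RNA pseudoknot structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing sequences for 3-noncrossing RNA pseudoknot structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkinv)
```

## The problem

Pseudoknots — cross-serial base pairs — are functionally important across
tRNAs, RNase P, telomerase and ribosomal RNA, ribosomal frameshifting
elements and viral UTRs, yet most sequence-design (inverse-folding) tools
only handle noncrossing secondary structures. `pkinv` performs inverse
folding for the class of structures that covers most natural pseudoknots:
diagrams over positions 1..n with vertex degree at most one, no three
mutually crossing arcs (*3-noncrossing*), minimum arc-length four, and
every stack of at least three pairs (*3-canonical*). Given a target $T$
in this class, the task is to find a sequence $s$ over $\{A,C,G,U\}$ whose
minimum-free-energy (mfe) structure equals $T$ exactly.

The existence of such sequences is plausible on combinatorial grounds:
the number of admissible structures grows much more slowly than the
number of sequences, so the preimage of a structure under the folding map
(its *neutral network*) is typically large. The search exploits this by
moving through the set $C[T]$ of $T$-compatible sequences — sequences
carrying one of the six admissible pairs A-U, U-A, G-C, C-G, G-U, U-G on
every arc — which is a product of small "cubes": four choices per
unpaired position, six per arc.

## Loop decomposition

Every 3-noncrossing structure decomposes uniquely into loops:

* **hairpin** — an arc whose interior is entirely unpaired;
* **interior** — two nested arcs with only unpaired positions between
  them (stacked pairs are the zero-unpaired special case);
* **multi** — a closing arc over two or more branch substructures (or one
  substructure that is not simply a stem);
* **pseudoknot** — an irreducible set of mutually crossing arcs: its
  dependency graph (arcs as vertices, edges between crossing arcs) is
  connected, and every member is a *minimal* crossing arc for some arc
  under the nesting order. Unpaired positions inside the pseudoknot span
  that no other loop claims belong to the pseudoknot.

`decompose()` implements this by ownership: each hairpin/interior/multi
loop is attributed to its closing arc, classified innermost-first; arcs
left over assemble into pseudoknot loops as connected components of the
crossing graph. On structures without crossings this reduces exactly to
the classical secondary-structure decomposition, which the tests assert.

The nesting order on crossing sets is taken as containment:
$\alpha' \prec \alpha$ iff $\alpha'$ lies strictly inside $\alpha$, so
the minimal crossing arcs are the innermost members of each crossing
bundle. This reproduces the expected behaviour on crossing stems (the
innermost arc of a stem is the only minimal one) and keeps stacked copies
of a crossing arc in interior loops.

```{r decompose}
T <- parse_structure("(((..[[[..)))..]]]")
decompose(T)
```

## The energy model and the reference oracle

The search needs a folding oracle: any function `(s, N)` returning the
`N` energetically best admissible structures for `s`, mfe first. The
reference oracle enumerates *every* 3-noncrossing canonical structure of
the given length — structures are unions of maximal stacks, so the
enumeration places stacks subject to disjointness, non-merging and the
crossing bound — and scores each with an additive loop-based energy in
dimensionless units:

| term | value |
|------|-------|
| stacked adjacent pair | $-(w_1+w_2)/2$, $w(\mathrm{GC})=3$, $w(\mathrm{AU})=2$, $w(\mathrm{GU})=1$ |
| hairpin loop | $+3$ |
| interior loop | $+0.5$ per unpaired member |
| multi-loop | $+4$ |
| pseudoknot loop | $+7$ |

The weights mirror the relative magnitudes of nearest-neighbour stacking
rules: G-C stacks are worth roughly 1.5 A-U stacks, wobble pairs are
weak, and pseudoknots carry a stiff entropic penalty so that they only
win when well stacked. The model is deliberately simple — it is a
*reference* oracle whose virtue is exhaustiveness: every reported mfe
structure is certified against the full enumeration, and ties are broken
lexicographically on the arc list so repeated calls are bit-identical.
The exhaustive limit is $n \le 26$ (the admissible class stays in the low
tens of thousands of structures there because stacks need at least three
pairs and arcs length at least four); beyond it a user-supplied oracle —
e.g. an adapter around an external pseudoknot folder — can be plugged
into every search function.

Energies are computed twice over, on purpose: `energy()` sums per-loop
terms from a fresh `decompose()`, while the oracle uses cached stack-level
loop statistics; their agreement on random structures is part of the test
suite.

## The search

`inverse_fold()` proceeds in three stages.

**Start.** `make_start()` draws a compatible sequence uniformly: each
unpaired position uniform over four bases, each arc uniform over the six
pairs.

**Adjustment against competitors** (`adjust_seq()`). The current
sequence is folded with `N = 50` suboptimals. Each arc $a$ of each
suboptimal is *perturbed*: the nine placements moving either endpoint by
at most one position, plus removal of $a$, giving ten variant structures
per arc. Variants that are inconsistent (a doubly paired position),
incompatible with the current sequence, or equal to the target are
discarded; the survivors form the competitor set. The mutation step then
visits every position where some competitor pairs differently from the
target: unpaired target positions are re-drawn among bases that cannot
bind any conflicting competitor partner; paired positions are handled
once, at the arc's left endpoint, re-drawing the whole pair among the
five alternatives, preferring choices that break every conflicting
competitor. Because competitors are compatible with the current sequence,
a position faces at most two distinct partner bases and a fully breaking
choice exists; when later mutations re-enable a competitor anyway, it is
left to the energy criterion to eliminate it. A mutant is kept if its mfe
distance to the target is within `window = 5` of the best distance seen;
otherwise the mutation step is retried (at most 5 times) and the best
variant is kept. The loop runs at most $\max(50, n)$ iterations — a bound
that scales with target size while keeping a floor for short targets —
and returns the best sequence encountered.

**Interval-wise local search** (`local_search()`). The loops, widened to
the full stems that close them, are ordered linearly — nested before
enclosing, earlier start first — and each loop contributes its span and
the span extended by adjacent unpaired positions to a sequence of
intervals ending in $[1, n]$. Any interval that would cut a crossing arc
is extended to cover it, so subsequences always contain whole loop
groups; for densely knotted targets the interval list can collapse to
$[1, n]$ alone. Within an interval the subsequence is folded on its own
and compared to the target restricted to the interval; only mismatching
positions and their neighbours are touched, in random order. Strict
improvements are always accepted; moves that worsen the distance by less
than the window are accepted with probability `p_accept = 0.1` (an escape
hatch from local minima); among equal-distance candidates the one with
the lowest mfe energy wins. An interval stops at distance zero or after
`10 × interval length` phases.

A design is reported as a success only when the final sequence's mfe
structure equals the target *exactly*; the result also carries the final
structure distance and energy so failures are informative.

## Reproducibility and tuning

All stochastic choices run off R's global RNG; `search_config(seed =)`
pins a run, and identical (target, seed) pairs reproduce byte-identical
results. The tunable constants — suboptimal list size `N` (50), distance
window (5), uphill acceptance probability (0.1), mutation retries (5),
adjustment iterations ($\max(50, n)$), local-search phase budget
(10 per position) — are all surfaced in `search_config()` with the
defaults above.

## What the synthetic generator emulates

`random_structure()` draws valid targets by placing hairpin stems into
free intervals (with occasional nesting, giving interior and multi-loops)
and, when `allow_pseudoknot = TRUE`, an H-type crossing stem pair about
half of the time — the canonical pseudoknot geometry of viral UTRs and
frameshifting elements, and the smallest one expressible at these
lengths ($n \ge 12$). It aims at validity, determinism under a seed and
coverage of all four loop types, *not* at uniformity over the structure
class, and it produces neither bulged multi-knot hybrids beyond two
crossing stems nor the long-range tertiary motifs of natural RNAs.
Consequently, the end-to-end success rate measured on these targets
(at least 90% over 50 generated targets with $n \le 24$ under the
reference oracle, which the acceptance script recomputes) speaks to the
search machinery under a controlled energy model, not to design accuracy
under experimentally fitted thermodynamics or at natural-RNA lengths.

## Numerical and degenerate-input choices

* Coordinates are 1-based with closed intervals; the empty structure is
  valid at every length and folds with energy 0.
* Equal energies are ordered lexicographically on the sorted arc list,
  making `fold()` deterministic; the empty structure precedes ties.
* Whitespace in dot-bracket input is ignored; `.` is accepted for `:`.
  Bracket families on output are assigned greedily in the order
  `()`, `[]`, `{}`; three families always suffice for 3-noncrossing
  structures under this scheme.
* Wobble pairs G-U/U-G have *two* compatible neighbours at Hamming
  distance one (G-U borders both A-U and G-C coordinate-wise), while
  Watson-Crick pairs have exactly one; the neighbourhood size is five for
  every pair.
* Validator parameters (`min_arc_length`, `sigma`, `k`) are carried by
  each structure, so sub-canonical illustrative diagrams remain
  constructible with `validate = FALSE` while the search entry points
  insist on fully valid targets.

## Known limitations

The reference oracle is exhaustive and therefore exponential: it is the
right tool up to $n \approx 26$ and a certification device, not a folding
algorithm for long sequences. The energy model is a calibrated toy;
designs destined for the bench should be re-scored with an
experimentally parameterized pseudoknot folder via the oracle interface.
Sequence-level constraints (GC content, forbidden motifs) and
multi-target design are out of scope.
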