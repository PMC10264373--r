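---
title: "Extracting and auditing elementary flux modes with piefm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and auditing elementary flux modes with piefm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piefm)
```

## The model

A metabolic network is a triple (M, R, S): internal metabolites, reactions,
and the stoichiometric matrix S with one row per metabolite and one column
per reaction. After every reversible reaction is decoupled into a forward
and a backward irreversible copy, the admissible steady-state flux
distributions form the polyhedral cone

$$C = \{v \in \mathbb{R}^R \;:\; S v = 0,\; v \ge 0\}.$$

The support of a mode $v$ is the set of reactions with nonzero flux. An
elementary flux mode (EFM) is a mode of minimal support; the EFMs are the
extreme rays of $C$, and they are finite in number. The package relies
throughout on the algebraic characterization: $v$ is elementary iff the
submatrix of $S$ restricted to the support's columns (and the metabolite
rows touched by them) has rank $|\mathrm{supp}(v)| - 1$. That test is both
the correctness filter for every vector the extractor produces and the
engine of the brute-force enumeration oracle.

Two preprocessing assumptions are enforced rather than hoped for: all
reactions irreversible (`split_reversible()`) and non-blocked
(`remove_blocked()`). Splitting creates one artifact per reversible
reaction — the futile two-cycle on its forward/backward pair, which passes
the rank test but is meaningless — and collections therefore reject futile
pairs by default while `keep_futile = TRUE` retains them for diagnostics;
enumeration results also report how many were seen, so both conventions of
counting are available.

## Extraction: LP seeding plus simplex pivoting

Linear programming produces EFMs cheaply: minimizing
$f = \sum_i a_i v[i]$ with $a_i \ge 0$ over $C$ together with a single
*positive seed constraint* $\sum_{i \in T_1} v[i] = 1$ yields a vertex of
the constrained cone, which after scaling is an EFM. Pure LP sampling,
however, is biased toward short EFMs and recomputes the same optima over
and over. The extraction algorithm therefore runs in two phases.

**Seeding.** One LP per reaction $r$ (constraint $v[r] = 1$, random
positive objective coefficients) guarantees every non-blocked reaction is
covered by at least one EFM; then `n_seed_lps` further LPs seeded on the
biomass reaction diversify the collection around the flux states of
biological interest. Every solve updates an occurrence counter keyed by
support; duplicates are counted, not re-stored. When no biomass reaction
is available the biomass pass falls back to uniformly random singleton
seeds — a documented deviation switch rather than silent behavior, since
fixtures often have no meaningful biomass.

**Expansion.** The queue repeatedly selects the *least recomputed*
unexplored EFM (ties broken by earliest discovery — occurrence counts are
an inverse density estimate, so rarely seen EFMs sit in poorly explored
regions of the cone). For the selected EFM $E'$ the exploration LP

$$\min \sum_{i \notin \mathrm{supp}(E')} v[i]
 \quad\text{s.t.}\quad S v = 0,\;\; \sum_{i \in I} v[i] = 1,\;\; v \ge 0,$$

with $I$ the originally-irreversible reactions of the support, has optimum
0 attained exactly at $E'$. From the optimal tableau, each nonbasic
variable defines an entering direction; a pivot is accepted only when the
pivot element is nonzero *and* the minimum-ratio test is attained at the
leaving row, so every accepted pivot lands on a feasible adjacent basic
solution — a neighboring vertex of the cone, hence a new EFM. (Accepting
infeasible pivots and filtering afterwards was the open alternative; it
was rejected because the vertex guarantee only holds for feasible pivots,
and the rank test would silently discard the rest, wasting the pivot
budget.) Candidates are still verified with the rank test before storage;
failures are counted and logged, never stored.

An EFM whose support contains no originally-irreversible reaction cannot
be anchored ($I = \emptyset$); such EFMs are skipped and tallied in the
trace. Stopping criteria are `max_efms`, `max_time`, and queue
exhaustion. Exhaustion is an honest stop, not a completeness theorem: on
every bundled fixture the exhausted collection equals the exact
enumeration (the test suite asserts this), but the claim is empirical.

**Why a bespoke simplex.** The expansion step needs the optimal tableau
and basis, which off-the-shelf solvers do not expose portably. The package
implements a dense two-phase tableau simplex with Bland's anti-cycling
rule: deterministic entering/leaving choices make whole runs reproducible
bit for bit given the RNG seed. Equalities are handled with phase-1
artificial variables, which are driven out of the basis (redundant rows
dropped) and never re-enter. Degenerate vertices have several bases; since
the support, not the basis, identifies an EFM, pivots that change basis
but not support are folded away by support-level deduplication. Dense
tableaus are adequate at the intended scale (up to a few thousand
reactions); a sparse revised simplex would be an optimization, not a
correctness change.

## Exact enumeration and its oracle

`enumerate_ddm()` is a double-description enumerator: start from the unit
rays of the positive orthant and impose one metabolite balance at a time,
keeping rays on the hyperplane and combining adjacent plus/minus pairs.
Adjacency uses the combinatorial zero-set test; rows are processed in
order of fewest plus–minus combinations, the standard heuristic for
limiting intermediate blow-up, with a configurable ray cap that turns
blow-up into an explicit resource error. `enumerate_bruteforce()` is the
deliberately independent oracle: it scans support subsets directly,
accepting a support iff the rank condition holds and the 1-dimensional
kernel admits a sign-constant vector nonzero on the whole support. The two
routes share no geometry code, so their agreement on every fixture is a
meaningful cross-validation, not a tautology.

## Representativeness and stability metrics

For an ordered extraction stream the package computes: the running mean
support length; the per-reaction proportions $p(r)$; the mean relative
error $\mathrm{mre}(p_{est}, p_{ref}) = \frac{1}{|R'|} \sum_{r \in R'}
|p_{est}(r) - p_{ref}(r)| / p_{ref}(r)$ (always in absolute value);
the $d$-offset stability trace comparing $p_k$ with $p_{k-d}$; the count
of reactions compatible with a chosen reaction (typically biomass) as a
variability measure; the Jaccard distance between consecutive EFMs; and a
sort-based simulation of length-ordered (k-shortest / k-largest)
extraction for bias studies. Representativeness requires a full reference
enumeration; stability does not, which is exactly why it matters at
genome scale — it is a necessary but not sufficient condition for
representativeness, and its failure is a proof of non-representativeness.

Decisions the definitions leave open, and how they were fixed:

* *Stability prefixes.* $p_k$ is computed over the first $k$ EFMs and
  compared against the first $k - d$; checkpoints start at $k \ge 2d$ so
  the reference prefix is at least as large as the offset. Reactions with
  $p_{k-d}(r) = 0$ have no defined relative error; they are dropped from
  that checkpoint's average and their count reported alongside the value.
* *Stopping rule.* `stopping_index()` returns the first checkpoint
  starting an uninterrupted run of `consecutive` values below
  `threshold`; defaults 0.05 and 3. The threshold matches the level at
  which a stability trace is conventionally read as flat; the run length
  guards against a single lucky checkpoint.
* *Coupling correction.* Partially coupled reactions (identical
  EFM-membership patterns over a complete enumeration) inflate proportion
  errors in groups. Both corrections are available: dropping every member
  of a non-singleton class (the default, matching an analysis restricted
  to non-partially-coupled reactions) or keeping one representative per
  class.
* *Offsets.* `d` is user-set; 2000 is a sensible core-scale default and
  10000 a genome-scale one, matching the scale at which proportion
  estimates move. The checkpoint grid defaults to every 500 EFMs.

## Numerical choices

| Quantity | Value | Where |
|---|---|---|
| simplex zero / pivot tolerance | 1e-9 | entering tests, pivot elements |
| feasibility tolerance | 1e-7 | basic solutions, ratio ties |
| support tolerance | 1e-7 | on the canonical max = 1 scale |
| rank threshold | singular values > 1e-9 × largest | `is_efm()` |
| blocked-reaction tolerance | 1e-9 | boxed FVA-style LP optimum |
| random objective coefficients | uniform on [0.1, 1] | seeding/exploration |

Blocked detection maximizes each flux inside the unit box
$0 \le v \le 1$ (the cone is scale-invariant, so the box only bounds the
LP); reactions seen active in an earlier optimum are skipped. The
coefficient range's lower bound keeps objectives away from zero weights,
which would reintroduce ties and degenerate optima. Canonical scale is
max-component = 1, making the support tolerance meaningful across EFMs of
very different magnitudes. The EFM identity key is the frozen support
set: over a fixed elementary support the solution space is
one-dimensional, so flux values add no identity information and are kept
for reporting only.

## What the synthetic fixtures do and do not emulate

`make_chain()`, `make_fan()`, `make_diamond()` and the seeded
`make_random()` generator produce small mass-balanced irreversible
networks with integer stoichiometries in {−2, −1, 1, 2}, guaranteed
import/export routes, and blocked reactions removed — exactly the
preprocessed form the algorithms assume, with EFM sets small enough for
exhaustive ground truth. The test and acceptance runs use fixtures of at
most 15 reactions, 25 random draws, and around a thousand seeded LPs;
those sizes keep every ground-truth comparison exact. What the fixtures
do not emulate: genome-scale dimensions, realistic sparsity patterns and
coupling structure, compartments, non-integer stoichiometry, or flux
bounds beyond reversibility. Passing tests therefore certify algorithmic
correctness (agreement with exact enumeration, the vertex/EFM contract,
metric identities, determinism), not performance or statistical behavior
on real genome-scale models, where only the stability machinery — which
needs no reference enumeration — carries over unchanged.

## Known limitations

* The double-description enumerator works in floating point; with the
  small-integer fixtures this is exact in practice, but adversarial
  stoichiometries could defeat the tolerances. Exact rational arithmetic
  is a possible extension.
* Completeness of the expansion phase on queue exhaustion is empirical.
* Dense tableaus make genome-scale extraction slow (hours, as expected
  for this class of method); the package targets correctness and
  auditability first.
* Split-space reporting: EFMs are reported over the split (all
  irreversible) reaction set; recombining to signed reversible fluxes is
  out of scope.
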