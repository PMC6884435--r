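---
title: "Secure two-party clustering of nurse-patient facing times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secure two-party clustering of nurse-patient facing times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wardmpc)
```

## The problem

A hospital ward equipped with a real-time locating system (RTLS) observes,
every few seconds, which zone every tagged person is in.  Clustering nurses
by how often and how long they are co-located with patients of different
types is a simple, useful workflow statistic -- but staff location data is
privacy-sensitive, so the premise here is that it is *split*: the hospital
holds only patient tag records, a labour union holds only nurse tag records,
and neither party may see the other's raw data.  `wardmpc` implements the
resulting analysis twice, over the same algorithmic skeleton:

1. a **plaintext reference**: facing-time table construction and an
   integer-only k-means variant, and
2. a **two-party secure computation** of exactly the same functions over
   additive secret shares, whose only revealed outputs are the final cluster
   membership matrix and a one-bit convergence flag.

Exact equivalence of the two executions -- bit for bit, for every seed -- is
the package's central correctness property, and the test suite enforces it
end to end.

## Data model

Raw RTLS data is a table of `(tagID, tagRole, time, zID)` records on a fixed
sampling grid (default every 4 s).  Each party locally condenses its records
into **periods**: maximal stays `[st, et)` of one tag in one zone.  Two
conventions are ours to fix, since only the notion of "continuous stay in one
zone" is given:

* a record at time `t` is credited with the full sampling slot `[t, t + dt)`,
  so a period's end is the last observed timestamp plus the sampling
  interval -- this avoids zero-length periods and makes every overlap a
  count of shared slots times `dt`;
* a tracking gap (missing grid record) *closes* the period rather than
  bridging it: absence of evidence of presence is treated conservatively.

The **facing-time table** has one row per nurse and one column per (patient
type, duration bin).  Iterating over all (nurse period, patient period)
pairs, a pair in the same zone with overlap
`ov = min(et_1, et_2) - max(st_1, st_2) > 0` adds one count to the cell for
that nurse, the patient's type, and `ov`'s duration bin.  The counting unit
is deliberately the *pair*: a nurse who leaves a patient's zone and returns
has two shorter interactions, not one long one.  Bins are left-open and
right-closed -- an overlap of exactly 10 s falls in the 0-10 s bin -- with
the last bin unbounded; the default boundaries are 10, 30 and 60 s.  Touching
intervals (overlap 0) are not counted.

## The clustering variant

Rows of the table are integer vectors `y_i` in dimension
`m = n_types * n_bins`.  The algorithm is fixed-iteration Lloyd k-means with
four modifications that make it implementable over secret shares:

**Rational centroids.**  Every centroid is stored as an integer numerator
vector `x` with a single positive integer denominator `w` (value `x / w`).
Means of integer points are exactly representable, so no fixed- or
floating-point arithmetic is ever needed.

**Division-free comparisons.**  With scores
`s(y, c) = sum_l (x_l^2 - 2 w x_l y_l)`, squared Euclidean distances satisfy
`d^2(y, c) = sum(y^2) + s(y, c) / w^2`, hence

```
d^2(y, c) <= d^2(y, c~)   <=>   w~^2 * s(y, c) <= w^2 * s(y, c~)
```

an integer-only comparison.  `centroid_score()` and `closer_or_equal()`
expose this identity; the suite checks it against an independent exact
rational oracle on 10^5 random triples including ties and negative scores.

**Assignment via a membership matrix.**  `M[i, j] = 1` iff centroid `j` is
closer-or-equal to every other centroid for point `i` (a product of pairwise
comparison bits), followed by a uniqueness pass that keeps only the
lowest-indexed minimiser, so rows sum to exactly 1.  Ties therefore always
resolve to the lower cluster index.

**Self-inclusion updates.**  Each centroid is unconditionally added to its
own cluster: `x' = w * sum_i M[i,j] y_i + x`, `w' = w * (n_j + 1)`.  An
empty cluster (`n_j = 0`) then simply keeps its centroid -- no division by
zero, no data-dependent branch, nothing revealed.  The plaintext path
reduces `x'/w'` by their gcd after every round; the secure path cannot
(reduction requires seeing the values), which is why denominators grow by a
factor `<= Nn + 1` per round and why the circuit has a bit budget (below).
Membership is unaffected: the comparison identity is invariant under
positive scaling of `(x, w)`.

Initial centroids are `k` data points drawn uniformly *without* replacement
from a public seed -- the draw is made in the clear by the analyst party, so
the plaintext and secure paths share it verbatim.  Sampling without
replacement avoids coincident initial centroids; the tie rule handles
coincident *data* points regardless.  The iteration count is fixed (default
5); a single convergence check after the last round compares the last two
assignments.  With one iteration there is no previous assignment and the
flag is reported as 0.  Only `M` and this flag are ever returned -- centroids
would leak aggregate location behaviour and are not part of the output.

`strict_lloyd` mode (plain means, empty clusters keep their centroid) exists
as a testing aid because it carries the classical guarantee that the
within-cluster sum of squares never increases; the suite verifies that with
exact rational arithmetic.  The self-inclusion variant deliberately trades
that textbook monotonicity for obliviousness.

## The secret-sharing layer

Values live in a prime field `F_p`; integers in `[-M, M]`, `2M < p`, embed
as residues with the upper half of the field representing negatives.  A
secret is split into two uniformly random summands, one per party.  The
layer provides:

* **Linear gates** (add, subtract, public constants) -- local.
* **Multiplication** via trusted-dealer Beaver triples: one precomputed
  shared `(a, b, ab)` per product; the parties open the uniformly masked
  differences `u - a` and `v - b` only.
* **Comparison** `lt(u, v, bits)`: with both secrets in
  `[-2^(bits-1), 2^(bits-1))`, the shifted difference
  `z = u - v + 2^bits` is opened under the statistical mask
  `r' + 2^bits r''`, where `r'` is a dealer-shared random `bits`-bit value
  with shared bit decomposition and `r''` has `kappa` uniform bits.  The
  opened value's low bits are compared against the shared bits of `r'` with
  a prefix-OR circuit (2*bits - 1 triples), which resolves the borrow and
  yields the high bit of `z`.  Correctness requires
  `2^(bits + kappa + 2) <= p`, enforced at configuration time.
* **Derived gates**: `ge = 1 - lt`; `eq` from two comparisons and one
  product; `smin(a, b) = a*eps + b*(1 - eps)` with `eps = (a < b)`, and the
  mirrored `smax`.
* **A randomised zero test**: multiply by a dealer-supplied uniform nonzero
  element and open -- the opening is zero iff the secret is, and uniform
  otherwise, so the convergence check reveals exactly one bit.

The default field is the Mersenne prime `p = 2^127 - 1` with `kappa = 40`
statistical security, leaving 84 bits of comparison range.  A 64-bit preset
(`p = 2^64 - 59`) is provided to match the field size of the deployment this
package models; at 40-bit security it leaves only 21 comparison bits, and
the budget planner rejects realistic clustering circuits on it -- we treat
how the original deployment fitted five iterations of denominator growth
into 64 bits as an open question and default to the larger field.

**Security model.**  This is a *semi-honest, trusted-dealer* simulation: the
preprocessing (triples, comparison masks) comes from a deterministic
counter-mode dealer, both parties run in one process, and there are no
authentication MACs.  That is a deliberate downgrade from a maliciously
secure SPDZ-style deployment, whose guarantees live in the framework rather
than the algorithm; what is preserved -- and testable -- is the
share-compute-reveal semantics, the gate contracts, the communication
pattern, and what is revealed.  Every opening is logged: the suite checks
that masked openings are statistically indistinguishable across different
inputs (chi-square), that the gate-invocation trace depends only on public
shape parameters, and that the only non-masked reveals are the final
membership matrix and the convergence bit.  The dealer tape is virtual:
material is addressed by a `(seed, counter)` pair, so any run can be
replayed exactly from its seed, and the planner's counts say how much tape a
circuit consumes before it runs.

## The secure pipeline

Phase 1 mirrors the table construction pair by pair: a zone-equality bit
(`eq`), the overlap via `smin`/`smax`, a positivity bit (`ge(ov, 1)`), and
per-bin indicators from comparisons of `ov` against the public bin
boundaries (the indicators sum to the positivity bit, so each qualifying
pair contributes exactly one count).  Zone equality multiplied by the bin
indicator is accumulated into the addressed cell.

Cell addressing has two modes.  Under the default **public** addressing,
each nurse period carries a public pseudonymous nurse index and each patient
period a public type: the output table is keyed by these anyway, so the
leakage is limited to per-pseudonym period counts, and phase-1 cost stays
linear in the number of pairs.  The **oblivious** mode replaces the indices
by shared one-hot vectors at a multiplicative cost of `n_types * Nn` extra
products per pair-bin; it exists because the original system's addressing
choice is not determinable and the two modes bracket the design space.

Phase 2 runs the clustering on the still-shared table: scores, comparison
bits, membership entries, cluster sizes and centroids all remain shared.
Comparison bit-lengths are not the field-wide default but per-wire-class
bounds from `plan_budget()`: zones need 5 bits, timestamps 13, and the
k-means comparisons `bitlength(w^2 * s_max) + 1` bits, where the worst case
after `t` update rounds is computed exactly from
`w_t <= (Nn + 1)^t` and the corresponding numerator and score bounds, with
the public per-cell bound `y <= nP * pP`.  The planner also reports the
exact number of Beaver triples, shared random bits and mask blocks both
phases will consume -- the suite asserts the runtime dealer counters equal
these predictions -- and refuses shapes whose comparison inputs exceed the
field's headroom.

## What the simulator emulates

`sim_config()` defaults describe the simulated ward the package targets:
15 zones, one hour of observation at 4 s sampling, 120 nurses, 5 patient
types with 7 patients each, nurse stays of at most 120 s, patient stays up
to the full hour.  Stay durations are uniform on the sampling grid up to the
role's maximum and consecutive stays move to a uniformly chosen *different*
zone, so ground-truth stays are exactly the maximal periods the extractor
should recover -- the suite checks that expanding the ground truth
reproduces the emitted records.  Only the caps and counts are given by the
setting; the uniform-duration, uniform-zone choices are ours, picked as the
simplest model satisfying the stated constraints.  An optional dropout rate
thins records to exercise the gap rule.

The simulator makes no attempt at realistic ward geometry, shift structure,
correlated nurse-patient assignment, or RTLS physics (multipath, tag read
errors).  Passing tests therefore demonstrate *algorithmic* correctness and
secure-execution equivalence on data with the right shape and scale -- not
that the clustering is clinically meaningful on real wards.

## Numerical choices and sizes

All integer arithmetic is exact at every size: a small signed bignum kernel
(base-1e9 limbs, Barrett reduction for the fixed modulus) backs both the
field layer and the plaintext rational-centroid arithmetic, so there is no
tolerance anywhere -- every test compares exactly.  Shares travel between R
and the kernel as numeric limb matrices; one R object per share vector keeps
multi-million-share runs cheap for the garbage collector.

Default problem sizes used by the test suite: the ward-scale plaintext run
uses the full default configuration (120 nurses, 35 patients, one hour;
about 7,000 nurse periods and 600,000 period pairs); the secure runs use a
reduced preset (7 nurses, 21 patients, the same hour; roughly 20,000 shared
pairs and 4 million Beaver triples) plus batches of randomised small
instances (4-12 nurses, up to 8 periods per side) for the equivalence and
oracle checks.

## Known limitations

* Semi-honest, trusted-dealer security only; no malicious security, no real
  network transport, exactly two parties.
* The secure path cannot reduce centroid fractions, so the iteration count
  is bounded by field headroom; the planner makes the bound explicit rather
  than working around it.  Because the per-cell bound must be *public*, the
  planner uses the coarse `y <= nP * pP`, under which the full-ward
  clustering circuit (120 nurses, five iterations) exceeds even the 127-bit
  field; five iterations fit at small-cohort scale (e.g. 7 nurses over a
  full hour), and larger cohorts need fewer iterations or a tighter agreed
  public bound on cell counts.
* Public addressing leaks per-pseudonym and per-type period counts (chosen
  deliberately; the oblivious mode removes it at quadratic cost).
* Revealing the membership matrix itself is the analysis's stated output;
  what it discloses about individuals is a policy question outside the
  package's scope.
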