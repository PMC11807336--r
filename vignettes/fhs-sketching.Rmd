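---
title: "Fractional hitting set sketching: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional hitting set sketching: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhsketch)
```

## The sampling model

Given a DNA sequence, every k-mer contains `w = k - m + 1` m-mers; the
**minimizer** of a k-mer is the m-mer with the smallest hash (leftmost wins
ties). A run of consecutive k-mers sharing one minimizer *occurrence* is a
**super-k-mer**; the longest possible super-k-mer has length `2k - m`,
contains `w` k-mers, and is called **maximal** — its minimizer is the suffix
of its first k-mer and the prefix of its last.

A scheme that selects m-mers so that every k-mer contains a selected one is
a universal hitting set. `fhsketch` relaxes this: an m-mer is **small** when
its hash falls below a threshold `t`, and only k-mers containing a small
m-mer (equivalently: whose minimizer is small) are sampled. If a single
m-mer is small with probability `p`, a k-mer with distinct m-mers is covered
with probability

```
f = 1 - (1 - p)^w
```

so to sample a target fraction `f` (subsampling rate `s = 1/f`) the
threshold is set from `p = 1 - (1 - f)^(1/w)`. This selection is
near-uniform over the k-mer space (it is exactly uniform over k-mers with
distinct m-mers, and k-mers with repeated m-mers are a vanishing fraction
once `m` exceeds about `3 log4(w)`), which is what makes the sampled sets
usable for Jaccard and containment estimation: the sampled intersection over
the sampled union estimates the true index, and because sampled k-mers are
stored *exactly*, the reported indexes are the exact indexes of the sampled
subsets — there are no hash-collision false positives.

Sampled k-mers are stored as super-k-mers grouped into **partitions** keyed
by minimizer. Maximal super-k-mers in a partition all have the minimizer at
offset `k - m`, so the minimizer is stored once per partition and omitted
from each maximal record, giving the `4(k-m)/(k-m+1)` bits-per-k-mer cost
that `encoding_costs()` tabulates. Comparisons walk only the partitions
present in both sketches; a partition unique to one input cannot contain
shared k-mers and is skipped.

## Closed-form theory and what simulation can confirm

The theory module implements leading-term expressions:

* `density_bound(f, w) = 2f/(w+1)` — expected selected occurrences per
  m-mer position; at `f = 1` this is the classical random-order minimizer
  density.
* `restricted_density_factor(f) = 2(f + (1-f)ln(1-f))/f^2` — the density
  factor on covered sequence, falling from 2 at `f = 1` towards the optimal
  1 as `f -> 0`.
* `maximal_fraction(f, w)` — expected share of maximal super-k-mers,
  `1/4 + 1/(2w) + 1/(4w^2)` at `f = 1` and tending to 1 as `f -> 0`.
* `uhs_density_bound(f, d_U) = f * d_U` when candidate minimizers are
  restricted to a hitting set of density `d_U`.

All of these omit `o(1/w)` corrections, and two consequences matter for
testing. First, the restricted-density expression describes an ensemble of
*fully covered* sequences, which cannot be sampled directly at realistic
sizes (a 5 Mbp sequence is fully covered with probability essentially 0
for `f < 1`); the package's finite analog — selected occurrences per m-mer
position inside maximal runs of consecutive covered k-mers — sits *below*
the expression for `f < 1`, so the suite asserts it one-sidedly as an upper
bound plus three standard errors. Second, the maximal-proportion expression
carries corrections of order `0.1/w`: at `w = 17`, simulation (confirmed by
an independent pure-R sliding-minimum oracle) gives 0.2725 at `f = 1`
against the closed-form 0.2803. Tests therefore check the formula's exact
algebraic identities, its monotone behavior in `f`, and agreement with
measurement at the few-percent level rather than at sampling precision.
Coverage (`f = 1 - (1-p)^w`) is exact and is tested two-sidedly; because
covered flags of overlapping k-mers are strongly autocorrelated (one small
m-mer covers `w` k-mers), standard errors for coverage are computed from
disjoint block means, not from a plain binomial formula.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 31 | k-mer length (bases); 63 for longer-range comparisons |
| `m` | 15 | minimizer length (bases); partitions are keyed by m-mers |
| `s` (or `f`) | 1000 | subsampling rate `1/f`; 1000 keeps ~0.1% of k-mers |
| `seed` | 42 | seed of the m-mer hash; sketches are only comparable at equal seeds |
| `canonical` | `FALSE` | strand-symmetric hashing `min(h(x), h(rc(x)))` |
| `order` | `"hash"` | `"lex"` substitutes the lexicographic order (worked examples) |
| `uhs_mode` | `"none"` | `"decycling"` restricts candidates to a decycling set |
| `min_abundance` | 1 | build-time count cutoff for read inputs |

Defaults mirror common practice for genome-scale sketching (`k = 31`,
`m = 15`, rate 1000). The canonical mode exists for real genome comparisons
where strand is arbitrary; note that taking the minimum of two hashes makes
an m-mer small with probability close to `2p` rather than `p`, so the
calibration `f = 1 - (1-p)^w` is stated for the default non-canonical mode
and coverage under `canonical = TRUE` is correspondingly higher.

## Numerical and representation choices

* **Hash space.** m-mers are 2-bit packed and mixed by a seeded 64-bit
  finalizer; the exposed hash keeps the top 53 bits so values are exact in
  an R double, and thresholds are `t = round(p * 2^53)`. Any uniform space
  gives the same distributional behavior. Under the lexicographic order the
  "hash" is the packed value itself on `[0, 4^m)`.
* **Smallness convention.** Hashes are 0-based, so `hash < t` holds with
  probability exactly `t / space`.
* **Tie-breaking.** Equal minimizer hashes resolve to the leftmost
  occurrence — deterministic and standard for minimizer implementations.
  Ties are essentially impossible under the 53-bit hash but routine under
  the lexicographic order.
* **Super-k-mer boundaries** follow the minimizer *occurrence* (position),
  not its value: two consecutive k-mers belong to the same super-k-mer only
  when the same m-mer occurrence is their minimizer. The `2k - m` length
  bound only holds under this convention.
* **Non-ACGT characters** split sequences; each fragment of length at
  least `k` is processed independently. Coordinates are 0-based, half-open.
* `restricted_density_factor()` is evaluated directly with `log1p` for
  numerical stability, by a series for `f < 1e-3` (the direct form cancels
  catastrophically), and as the analytic-continuation value 2 at `f = 1`.
* **Encoding costs** evaluate the printed formulas with a real-valued
  `log2`, not a ceiling: integer-rounding the length field would change
  the `with_length` cost by up to ~0.1 bits/k-mer, and the formulas are
  compared against measured file sizes only as a bracket.
* **Log-abundance quantization** stores `round(16 * log2(count))` in one
  byte (saturating at 255), i.e. under 5% relative decode error across
  five orders of magnitude; `super_avg` stores the arithmetic mean of a
  record's k-mer counts rounded half-to-even to avoid upward bias.
* **Greedy reassembly** (after abundance filtering, and during every build
  for per-partition dedup): chains are seeded at k-mers with the minimizer
  as suffix — these are the only possible left ends of maximal records —
  and extended rightwards while the successor k-mer of the same occurrence
  is present; leftover k-mers start chains at their leftmost available
  position. This recovers every intact maximal super-k-mer exactly and is
  within `k - 1` bases of the optimal grouping on the subsets enumerable
  by brute force, though global optimality is not claimed.
* **Sketch files** use a little-endian binary layout (magic `FHSK`,
  version byte, parameter header, partitions in ascending packed-minimizer
  order). The threshold is re-derived from `f` on read and checked against
  the stored value, so header corruption is detected. Gzip is optional and
  off by default.

## What the simulator does and does not emulate

`random_sequence()` draws i.i.d. uniform bases — the model under which the
closed forms are derived. `synthetic_pair()` plants a shared core with
private flanks and an independently mutated copy, then *recomputes* the true
Jaccard/containment/angular values by brute-force k-mer enumeration, so
estimator tests compare against exact truth rather than construction
parameters. `simulate_reads()` draws uniform read starts with i.i.d.
substitution errors. None of these reproduce repeat structure, skewed base
composition, indels, or coverage biases of real libraries; passing tests
certify the sampling mathematics and the exactness of the data structures,
not robustness to genomic repetitiveness (where k-mer multiplicities, not
the sampling scheme, dominate estimator behavior).

Problem sizes used by the suite were chosen to give at least ~10^4–10^5
selected events per stochastic check: 2–5 Mbp for density and coverage
measurements (20 Mbp for the rate-1000 calibration and the storage-cost
bracket, where selected events are 1000-fold sparser), 50 synthetic pairs
for the oracle-equivalence sweep, and 30 hash seeds for the estimator-bias
check.

## Known limitations

* Sketches are strand-naive by default; compare `canonical = TRUE`
  sketches only with each other.
* The decycling option implements the single embedding-criterion set (with
  a minimal-rotation fallback for zero-embedding rotation classes);
  stronger double-decycling constructions are out of scope.
* Comparisons materialize one partition pair at a time in R; the package
  targets desk-scale collections (tens of Mbp per input), not
  hundred-thousand-genome indexing.
* `f = 1` sketches of very large inputs hold every distinct k-mer in
  memory; full-fraction mode is intended for validation and small inputs.
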