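---
title: "Multi-order subsequence seeding: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-order subsequence seeding: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subseedr)
```

## Why subsequence seeds

Seeding turns a long DNA sequence into short strings (seeds) that can be
matched across sequences in constant time through a hash table. Substring
seeds (k-mers) work superbly at low error rates but collapse on noisy long
reads: a single edit destroys every k-mer covering it, so two length-n
strings with edit distance $e$ are only guaranteed to share a substring of
length $(n - ke)$-ish, which quickly becomes useless. Subsequences are far
more robust: two length-$n$ strings with edit distance $e$ always share a
subsequence of length at least $n - e$, and conversely two strings sharing a
length-$k$ subsequence have edit distance at most $2(n - k)$. A
MinHash-style scheme — map each window to its minimal length-$k$
subsequence under a pseudo-random total order over $\Sigma^k$ — therefore
produces seed collisions with probability close to the Jaccard similarity
of the two subsequence sets: strictly positive for similar strings, near
zero for unrelated ones.

The expensive part is the argmin over the exponentially large subsequence
set. This package implements a family of $k$ jointly defined orders
$\pi_1,\dots,\pi_k$ (the ABCk orders) under which all $k$ argmins are
computed together by one dynamic program, so a single pass yields up to $k$
independent-behaving seeds per window ("repeats" boost sensitivity as
roughly $1-(1-p)^t$ without extra passes).

## The score model

Nine integer tables govern the orders: forward $A_F, B_F, C_F$, reverse
$A_R, B_R, C_R$ and pivot $A_P, B_P, C_P$. For a part string
$s_1\cdots s_l$ the forward pair $(\psi_F, \omega_F)$ evolves as

$$\psi_F(s_1\cdots s_l) = (\psi_F(s_1\cdots s_{l-1}) + C_F[l][s_l]) \bmod d,$$
$$\omega_F(s_1\cdots s_l) = \omega_F(s_1\cdots s_{l-1})\cdot B_F[l][\psi_F][s_l]_1 + A_F[l][\psi_F][s_l]\cdot B_F[l][\psi_F][s_l]_2,$$

from $(0,0)$ for the empty string, and symmetrically for the reverse pair
with the reverse tables. Order $\pi_i$ scores a length-$k$ string $z$ by
using $z_i$ as a pivot: the characters left of the pivot are scored
pivot-outward with the reverse recurrence, the right part with the forward
recurrence, and the pivot tables combine the two:

$$\psi_i(z) = (\psi_R + C_P[i][z_i] + \psi_F) \bmod d, \qquad
\omega_i(z) = \omega_R \cdot B_P[i][z_i]_1 + A_P[i][z_i] + \omega_F \cdot B_P[i][z_i]_2.$$

$z$ ranks before $z'$ under $\pi_i$ iff $\psi_i(z) < \psi_i(z')$, or the
residues tie and $\omega_i(z) > \omega_i(z')$. The $\pm 1$ sign pairs, the
modular residue and the pivot split all serve one purpose: making the
ranking of similar strings incoherent, so that the family behaves like a
random permutation.

## The dynamic program

For each window, and for each pivot position $q$, the package fills two DP
families over (position, part length $j$, residue $v$): reverse-part states
covering the prefix left of $q$ and forward-part states covering the suffix
right of it. Because the $\omega$ update multiplies by $\pm 1$, each state
carries *both* the minimum and the maximum achievable $\omega$ — a sign
flip downstream exchanges which extreme wins. The combine step then scans,
for every order $i$, all pivots and residue splits $(v_L, v_R)$, forming
$\psi = (v_L + C_P[i][x_q] + v_R) \bmod d$ and maximizing $\omega$ over the
sign-selected extremes. The $d$ residue lanes are independent in every
transition and are kept contiguous in memory (the innermost array axis), so
the compiler can vectorize across them; no explicit SIMD intrinsics are
used. Per-window cost is $O(n^2 k d)$ with shared structure across the $k$
orders; correctness, not the constant, is the binding contract — every
record is testable against a brute-force argmin over all
$\binom{n}{k}$ candidate subsequences, and the test suite does exactly
that at three parameter scales.

### Exact arithmetic

$A$-entries are drawn uniformly from $[0, 2^{40})$. Scores accumulate at
most $k + 1$ such terms with $\pm1$ multipliers, so $|\omega| \le
(k+1)\,2^{40}$, which stays exactly representable in IEEE doubles for
every supported $k$; all score comparisons are exact integer comparisons.

### Ties, and why the tie rule is strand-aware

Distinct strings can tie exactly in $(\psi, \omega)$. With plain random
tables this is astronomically rare, but reverse-complement-symmetric tables
(below) *force* algebraic identities — the reverse score of a symbol equals
the forward score of its complement — so two distinct candidates tie with
probability on the order of $1/(2d)$ per residue coincidence, independent
of the 40-bit score range. A fixed tie rule is therefore part of the
contract:

* ties are broken toward the lexicographically smaller string (symbols
  compared in alphabet order); with rc-symmetric tables the smaller
  *canonical* string $\min(z, \mathrm{rc}(z))$ takes priority, because a
  plain lexicographic preference is not invariant under reverse
  complementation and would silently break the strand-symmetry guarantee
  precisely on tied windows;
* among position tuples spelling the winning string, the lexicographically
  smallest tuple is reported — equivalently, the greedy leftmost embedding
  of the string into the window.

Inside the DP every extreme carries the exact base-$|\Sigma|$ code of the
lexicographically smallest string achieving it plus a flag marking whether
two distinct strings achieve it; windows where such a flag touches the
optimum are re-resolved against the enumeration oracle. Because a
structural tie touches roughly 1% of window-orders under symmetric tables,
this per-tie re-resolution is capped at $\binom{n}{k} \le 2\cdot 10^4$;
beyond that the DP's lex-min answer stands, so at large $n$ a rare tied
window can emit a strand-inconsistent key — immaterial for the stochastic
experiments run at those sizes, while every exact-equality guarantee in the
test suite operates below the cap.
The codes are exact in 64-bit integers for $k \le 26$ on DNA, which is the
seeder's supported range. One residual case is not handled: if a string
*and its own reverse complement* both achieve the optimum with exactly
equal scores, the canonical index of the emitted key can differ between the
two strands. This requires a second independent exact coincidence and was
never observed in testing.

## Reverse-complement symmetry

`generate_symmetric_tables()` constrains the tables so that
$\pi_i(z) = \pi_{k-i+1}(\overline{z})$ for every $z$: reverse tables mirror
forward tables under the complement, and pivot entries at position
$k-i+1$ for the complement symbol copy those at position $i$ (for $B_P$
with swapped sign components). Consequently the $i$-th seed of a window is
the reverse complement of the $(k-i+1)$-th seed of the window's reverse
complement, and after canonicalization (`canonicalize_rc()`: key =
lexicographic min of seed and its reverse complement, order index flipped
accordingly) a window and its reverse complement produce identical key
multisets — one seeding run covers both strands. The construction samples
the free half of each constrained pair and fills the mirror, which
maximizes entropy subject to the constraints; the complement map must be a
fixed-point-free involution, so DNA works and alphabets with
self-complementary symbols are rejected (plain tables accept any alphabet).

## The substring-prefix variant

`seed_sequences(mode = "w")` concatenates the literal `k0`-length substring
at each start position with each subsequence seed of the following
length-n window, yielding seeds of length `k0 + k` (default
`k0 = floor(k/2)`). The contiguous prefix adds specificity the way
multi-window schemes built from k-mers do, while the subsequence suffix
retains error tolerance. Strand canonicalization is not defined for the
concatenated form and is refused.

## Synthetic data: what it emulates

The simulators generate every input the experiments need; their defaults
are the package's study conditions:

* `random_pair_with_edit_distance(n, e)` — pairs of length-$n$ strings at
  *verified* edit distance exactly $e$ (edits are placed at distinct random
  positions with balanced insertion/deletion counts, then the realized
  Levenshtein distance is checked with `utils::adist()` and the pair is
  resampled on shrinkage). Only the verified distance is contractual.
* `mutate_sequence(x, rate)` — the per-position error model: with
  probability `rate` a position receives an edit that is a substitution,
  insertion or deletion with probability `rate/3` each. Substituted
  positions remain aligned pairs in the emitted truth alignment; inserted
  characters go before the current position and are unaligned. Error rates
  of 0.05–0.15 correspond to the noisy-long-read regime.
* `make_overlap_readset()` — a random reference, reads extracted at
  recorded intervals with random strand and mutated copies; ground-truth
  overlapping pairs are interval overlaps of at least 15 bp.
* `estimate_collision_probability()` — the collision-probability experiment:
  desk-scale defaults of 2 000 pairs per edit-distance category (categories
  are exact edit distances) with $n = 20$, $k = 16$ ($k = 0.8\,n$, the
  regime where subsequence seeds shine), $d = 15$, repeat budgets
  $t \in \{1, 10, k\}$.

These generators emulate uniform random DNA with position-independent
errors. Real long reads have composition bias, repeats and bursty,
context-dependent errors; passing tests on this synthetic model
demonstrates correctness of the algorithms and the qualitative
sensitivity/precision behaviour, not performance guarantees on any
particular instrument's data.

## Measuring near-independence of the k orders

The $k$ orders share their forward and reverse functions, so they are not
formally independent; the design goal is that *in practice* $t$ of them
boost collisions as well as $t$ genuinely independent table sets. A note on
operationalizing this: comparing the observed $t$-repeat collision rate
against the closed form $1-(1-\hat p_1)^t$ is misleading, because the
collision probability varies across pairs within a category and by
Jensen's inequality $E[1-(1-p)^t] < 1-(1-E[p])^t$ — even perfectly
independent repeats fall systematically below the formula. The package
therefore measures independence the way the design goal is stated:
`estimate_collision_independent()` repeats single-order seeding with $t$
independently generated table sets, and the test suite requires the
multi-order estimate to match that reference within three combined
binomial standard errors per category. (The closed-form prediction is
still reported by the acceptance script for reference.)

## Evaluation metrics

* **Match precision** — true matches over all matches, where a match is
  true iff strictly more than half of its aligned character pairs occur in
  the truth alignment. Undefined (reported missing, not zero) without
  matches.
* **Segment sensitivity** — reads are cut into 200 bp segments; the metric
  is the fraction of segments containing the start of at least one true
  match. A final partial segment counts only if it is at least half a
  segment long (the handling of remainders is a package choice; results at
  multiples of 200 bp are unaffected).
* **Coverage** — the fraction of first-sequence characters lying under the
  span of any true (resp. false) match, with overlapping spans counted
  once (interval union via IRanges).
* **Overlap detection** — reads sharing at least one seed key become
  candidate pairs; sensitivity and precision are measured against
  interval-overlap ground truth (at least 15 bp). True pairs whose overlap
  is shorter than the window length n cannot contribute a shared window and
  bound the attainable sensitivity. High-frequency-seed
  filtering, chaining and alignment verification are deliberately out of
  scope so that seed quality is compared directly.

Match keying requires an equal order index (and table-set id when runs are
pooled): each order is an independent hash, and matching across orders
would inflate collisions beyond the model. Multiple matches of the same
seed at the same coordinates count as distinct (key, position) records.

## Numerical and interface choices

* Coordinates are 0-based in all tibbles and output files; the 1-based
  indexing of the score formulas is confined to the mathematics.
* Windows containing symbols outside the table alphabet (e.g. `N`) emit no
  seeds and are counted in a notice — the score tables are undefined there.
* With `t < k` only orders $1..t$ are computed.
* Serialization of tables is self-describing JSON with flattened integer
  arrays — human-inspectable and diffable; loading re-validates every
  invariant and names the offending field. `d` above 32 is a soft limit
  (warning only): nothing breaks mathematically, it is simply the range a
  lane-parallel implementation would vectorize best.
* Every stochastic function takes an explicit `rng_seed` and restores the
  global RNG state, so all results are reproducible from logged parameters.
* Table generation draws from R's Mersenne–Twister with fixed sample kind,
  so a seed yields identical tables across platforms.

## Problem sizes used in the tests

The test suite verifies the DP against brute force at
$(n,k,d) \in \{(8,4,2), (10,5,3), (12,6,4)\}$ with 500 windows each (exact,
no tolerance), strand symmetry at $k=6, d=4$ over 500 windows, and the
collision experiment at the desk-scale conditions above; the acceptance
script re-runs the same computations from scratch. These sizes keep the
full enumeration oracle exact and affordable; the DP itself is the same
code path at every scale.

## Known limitations

* No chaining, extension, mapping quality or assembly; the package stops
  at seeds, matches and their evaluation.
* The seeder supports $k \le 26$ on DNA (exact 64-bit tie codes); the
  score functions themselves accept any $k$ up to the double-precision
  bound.
* Windows are processed independently; the cross-window subproblem sharing
  that amortizes the per-window cost is an optimization behind the same
  contract, not implemented here.
* Protein (or other) alphabets are supported in plain mode only; strand
  symmetry requires a fixed-point-free complement.
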