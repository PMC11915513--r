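---
title: "Search schemes: construction, metrics and lossless execution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Search schemes: construction, metrics and lossless execution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(searchschemes)
```

## The problem

Approximate string matching asks for all substrings of a text $T$ within
Hamming or edit distance $k$ of a query $Q$. With a bidirectional FM-index
the query need not be matched left to right: a match can start anywhere in
the query and grow by single-character extensions to the left or right. A
*search scheme* exploits this. The query is cut into $p$ contiguous parts;
each *search* of the scheme is a triplet $(\pi, L, U)$ where $\pi$ permutes
the parts (obeying the *connectivity property*, so each next part is
adjacent to the range already matched) and $L$, $U$ are monotone cumulative
lower/upper bounds on the errors accumulated after each part. Searches that
begin with exactly matched parts prune the index traversal drastically; a
set of searches is *complete* when every distribution of up to $k$ errors
over the parts (*error configuration*) satisfies the bounds of at least one
search, which makes the combined search lossless. If no configuration is
covered twice the scheme is *non-redundant*, and under Hamming distance
every occurrence is then reported exactly once.

The package constructs schemes for the classical filtration strategies —
plain backtracking, pigeonhole and a tightened variant, the suffix filter's
strong-match staircase, 01\*0 seeds and their merged form — plus a
matrix-based heuristic for arbitrary $k$; it verifies validity,
completeness and redundancy by exhaustive configuration enumeration; it
scores schemes by node count and weighted node count; and it executes them
on a reference bidirectional FM-index with a brute-force oracle as ground
truth.

## Coverage checking

`check_scheme()` enumerates configurations and tests each against each
search's cumulative bounds. Two enumeration modes exist because the
literature is ambiguous: the formal definition distributes *exactly* $k$
errors, but the published coverage sets for the worked examples include
configurations with fewer errors. The default mode is therefore `"atmost"`
(all sums $0..k$), which is also the property that makes execution
lossless for reads that happen to contain fewer than $k$ errors; `"exact"`
is available for the literal definition. Enumeration is guarded by a
ceiling (default $5\times 10^6$ configurations) against combinatorial
blow-up.

One caption-level discrepancy is worth recording: the published coverage
listing for the third pigeonhole search at $k = 2$ includes $(0,0,2)$,
which contradicts that search's own bounds (its seed part is part 2 with
upper bound 0). The value forced by the definition is $(2,0,0)$; the tests
assert the corrected set.

## The matrix construction heuristic

`scheme_heuristic(k, p)` ($p > k$) emits $k+1$ searches with orders
$\pi_i = (i, \dots, p-1, i-1, \dots, 0)$ and lower bounds
$L_i = (0^{\,p-i-1}, (k-i)^{\,i+1})$. Upper bounds derive from a
$(k+1)\times p$ allowance matrix $M$: its top-left $k\times k$ block holds
$(j - i) \bmod k$ (row $j$, column $i$), its last row holds $k$, and
columns $\ge k$ hold $k - j$. Two remarks on choices the construction
leaves open:

* **The block formula.** The generating expression is stated elsewhere
  with a plus sign, but only $(j-i) \bmod k$ reproduces the worked
  $k = 3$ matrix (whose first row starts $0, 2, 1$); the two coincide at
  $k = 2$. The implementation follows the worked example.

* **Column repair.** $M$ must be row-monotone away from each row's
  diagonal entry. Offending columns are repaired left to right by
  permuting their entries in rows $0..k-1$ (diagonal entry fixed). The
  procedure as published does not say which of several admissible
  permutations to take, and the choice matters: a plain lexicographic
  tie-break yields incomplete schemes at $k = 4$ and invalid ones from
  $k = 5$ on, because it fills early rows greedily and eventually forces a
  permutation of the fixed right block. We enumerated every admissible
  repair sequence for $k = 4, 5$ and found that all completeness-preserving
  fixpoints share one structure; the implementation therefore prefers the
  candidate that hands the displaced values, in decreasing order, to row 0
  first, then to the rows below the diagonal from the bottom up, then to
  the rows above the diagonal from the top down. This candidate is always
  admissible, reproduces the published $k = 3$ adjustment verbatim, and
  keeps the emitted schemes valid and complete at $p \in
  \{k+1, k+2, k+3\}$ for every $k$ we tested (exhaustively to $k = 8$ in
  the test suite; `scripts/completeness_sweep.R` extends the check to
  $k = 15$, which takes on the order of an hour). A lexicographic
  fallback remains for hand-crafted matrices.

As a decisive cross-check, with this repair rule the node counts of the
heuristic schemes at $p = k+1, k+2, k+3$ match the published evaluation
table cell for cell (after mantissa rounding) for $k = 1..6$.

```{r heuristic}
scheme_heuristic(3, 5)
```

## Node count and weighted node count

The *node count* upper-bounds the search steps: the total number of nodes
of the backtracking tries traversed by all searches, assuming every branch
exists. Per search, the per-part bounds are inflated to one value per query
character along the search order (`inflate_bounds()`); a character can add
at most one Hamming mismatch, so Hamming upper bounds additionally grow by
at most one per level, and a part's lower bound applies only at its final
character (it is enforceable only once the part is complete — the worked
all-zero example cannot discriminate this convention, so it is documented
here). The count table obeys
$n(l,d) = n(l-1,d) + b\,n(l-1,d-1)$ restricted to the inflated window,
with branch factor $b = \sigma - 1$ for Hamming distance. For edit
distance $b = 2\sigma$ ($\sigma-1$ substitutions, $\sigma$ insertions, one
deletion, each consuming one level and one error): this is the unique
simple recurrence that reproduces the entire published backtracking column
($|Q| = 50$, $\sigma = 4$; exactly 10250 at $k = 1$), which is asserted in
the tests. Counts are exact integers (stored as doubles; exact through
$2^{53}$, far beyond the $\sim 3\times 10^{13}$ reached at $k = 6$).

The node count ignores that a text of length $|T|$ realizes at most
$|T| - l$ distinct $l$-mers while the trie offers $\sigma^l$ branches, so
beyond the depth threshold $l^* = \lceil \log_\sigma |T| \rceil$ most
branches die out. The *weighted node count* keeps levels $\le l^*$
unweighted and scales deeper levels by a per-node weight; the default
policy is $\min(1, (|T|-l)/\sigma^l)$, the realizable branch fraction. The
exact published weighting expression is not available in the text we work
from (it lives in a figure body and an appendix), so the policy is
pluggable (`weighted_node_count(..., policy = )`) and the published
weighted table is treated as a qualitative, not bit-exact, reference. The
qualitative conclusion is robustly reproduced: at $k = 1$, $|Q| = 50$,
$|T| = 3\times 10^9$ the plain node count puts backtracking within a
factor 2 of every partitioned strategy, while the weighted count separates
it by more than an order of magnitude (about $23\times$ under the default
policy; the published figures show about $34\times$).

```{r metrics}
node_count(scheme_backtracking(1), 50, sigma = 4, distance = "edit")
weighted_node_count(scheme_backtracking(1), 50, 4, "edit", 3e9)
weighted_node_count(scheme_pigeonhole(1), uniform_partition(50, 2),
                    4, "edit", 3e9)
```

## Execution and the occurrence convention

`fm_index()` indexes the text and its reverse (suffix arrays by prefix
doubling, $O(n \log^2 n)$, adequate for the desk-scale texts this
reference implementation targets) with a single sentinel that is
lexicographically smallest; occurrences never span it. `scheme_search()`
runs each search by seeding at its first part and extending character-wise,
branching over match/substitution (Hamming) or
match/substitution/insertion/deletion (edit), pruning on the inflated
upper bound at each query position and checking lower bounds at part
boundaries. Insertions at a part boundary may be attributed to either
adjacent part (both branches are explored), which is required for edit
losslessness when the optimal alignment places an indel exactly on a
boundary.

Edit distance needs an occurrence convention: the same text position can
be reached via several alignments, and a window whose first or last
character is an *inserted* character (relative to some optimal alignment)
shrinks to a better window when trimmed. A search that never extends in
one direction — backtracking is the extreme case — cannot place
window-edge insertions on that side, so such trimmable windows are
exactly where raw outputs of different complete schemes disagree. The
package therefore canonicalizes: hits are deduplicated per $(start, end)$
keeping the minimal error count, and a window $(s, e, d)$ is dropped when
$dist(T_{s+1..e}, Q) = d-1$ or $dist(T_{s..e-1}, Q) = d-1$ (true distances
by dynamic programming). The same filter is applied to
`brute_force_search()`, making oracle comparisons well-defined;
`raw = TRUE` bypasses all of this for redundancy studies. Coordinates are
0-based and half-open — the underlying problem statement fixes no
convention, so this is a documented artifact choice.

## The synthetic data generator

`simulate_text()` draws i.i.d. uniform characters over $\{A,C,G,T\}$ —
the text model of the reference evaluation, which used a random 3 Gb
string precisely because it lacks the self-similarity of a real genome.
`simulate_reads()` samples windows and applies exactly $e$ mutations
(mismatching positions for Hamming; substitution/insertion/deletion
operations drawn uniformly for edit, with the window length adjusted so
reads keep their nominal length). Random edits can cancel, so every read
is verified against its origin window by dynamic programming and
re-sampled when the achieved distance is smaller (bounded retries, default
100 — the reference read simulator's internal mechanism is not described,
so the generator is specified by its contract: exact distance,
determinism under a seed).

What passing the oracle-equivalence tests on these instances shows — and
what it does not: on i.i.d. text, occurrences cluster tightly around each
read's origin window and repeats are short, so the tests probe the
executor's correctness (branching, bounds, bidirectional bookkeeping,
canonicalization) across thousands of read/scheme/distance combinations.
They do not probe behaviour on self-similar references (long repeats,
low-complexity regions), where correctness is unchanged but hit counts
explode and the weighted node count would need a self-similarity-aware
text model; that regime is out of scope.

## Problem sizes and numerical choices

The test suite checks completeness exhaustively for every generator at
$k = 1..6$ and for the heuristic at $p = k+2$ up to $k = 8$
($C(18,10) = 43758$ configurations), and runs the execution-vs-oracle
comparison on a 10 kb text with 100 reads of length 50 per condition
($k \in \{0,1,2\}$, both distances, every generator) — sizes chosen so the
whole suite completes in about a minute on one CPU while still exercising
every code path at the scale the reference evaluation prescribes for
reads. Weighted counts are floating point; tests compare them at a
relative tolerance of $10^{-9}$. Node counts are exact integers.
`scripts/acceptance.R` re-derives the headline numbers (node-count table
mantissas, completeness fractions, oracle agreement, weighted-count
ratios) from scratch under a caller-supplied seed.

## Known limitations

* The FM-index is a readable reference implementation (R, integer rank
  tables), not a high-performance mapper: texts beyond a few megabases
  and banded-matrix edit execution are out of scope.
* Optimum-scheme computation by integer linear programming is out of
  scope; externally published schemes can be loaded from the canonical
  JSON format via `read_scheme()` but are not derived here.
* The weighted node count models an i.i.d. text; self-similar references
  need a different weight policy (pluggable, but none is shipped).
* Reverse-complement search is the caller's responsibility.
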