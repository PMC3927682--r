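---
title: "All-mapping short reads with q-gram prefix filtering"
author: "allmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{All-mapping short reads with q-gram prefix filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allmapr)
```

## The problem

An *all-mapper* reports every location in a reference genome where a short
DNA read aligns within a distance threshold $k$ — not merely the best hit.
This matters wherever secondary mapping locations carry signal: repeat and
structural-variation analysis, copy-number inference, or any downstream
model that weighs mapping ambiguity.  The cost of completeness is that every
candidate location must be verified, so the art is in generating as few
false candidates as possible without ever losing a true one.

`allmapr` implements the complete pipeline in that style: an inverted index
of overlapping q-grams of the reference, frequency-optimal selection of
non-overlapping *prefix grams* per read, a vote-based candidate filter that
exploits one extra prefix gram, indel-aware relaxations, and banded
semi-global verification that emits SAM records with CIGAR strings.  A read
simulator with recorded ground truth and an exhaustive brute-force oracle
mapper round out the package so that every guarantee can be tested.

## Count filtering and prefix grams

The overlapping q-grams of a sequence $s$, $G(s)$, are obtained by sliding a
window of length $q$; repeated grams are kept, ordered by offset.  A single
substitution touches at most $q$ overlapping grams, so two length-$|r|$
strings within Hamming distance $k$ share at least

$$T = |G(r)| - kq = |r| - q + 1 - kq$$

grams.  *Count filtering* scans the normalized inverted list of every gram
of the read (the list of genome start positions, shifted by the gram's read
offset so that entries become hypothesized alignment starts) and keeps
locations reaching $T$ votes.  It is exact but touches all $|r|-q+1$ lists.

*Prefix filtering* touches far fewer.  With non-overlapping grams a
substitution ruins at most one gram, so any window within Hamming distance
$k$ retains at least one of $k+1$ non-overlapping grams — the union of their
normalized lists is a lossless candidate set.  Choosing the grams whose
inverted lists are shortest minimizes that union; `select_prefix_grams()`
finds the optimum with a dynamic program over the gram multiset,

$$M(i,j) = \min\{M(i,j-1),\; M(i-1,j) + L[j+(i-1)q]\},$$

with $M(0,j)=0$, $M(i,0)=\infty$ and goal $M(c,\,|G(r)|-(c-1)q)$, where
$L[n]$ is the list length of the $n$-th gram.  The table is stated in the
literature for $c=k+1$; the recurrence is count-agnostic, so we parameterize
it by $c$ and use the same code for $c=k+2$.  Traceback prefers the leftmost
placement achieving the optimum, which makes selection deterministic.  Grams
containing `N` get infinite effective length and are picked only if
unavoidable, in which case selection fails over to the next weaker path.

## The additional prefix gram

Selecting $k+2$ non-overlapping grams buys a much stronger filter: at most
$k$ grams can be altered, so a true window retains at least **two** intact
grams.  Equivalently, taking all $k+2$ leave-one-out subsets of size $k+1$,
a true location must lie in every subset's union, and the intersection of
those unions is exactly the union of pairwise intersections of the
individual lists.  Rather than intersecting lists pairwise, a single
multiway merge tallies votes and keeps locations with at least two
(`additional_prefix_candidates()`); the test suite checks the merge against
the set-algebra formula directly.  Votes are counted per gram *occurrence*:
a gram repeated in the read contributes one list per offset.

```{r lemma-demo}
idx <- build_index(c(chr1 = "CCAGTAATGCTGTTG"), q = 3)
sel <- select_prefix_grams("AGTAATCTGTTG", idx, count = 3)  # k + 2 for k = 1
sel$picks
additional_prefix_candidates(sel, idx, k = 1, mode = "edit")
```

## Supporting insertions and deletions

Under edit distance two complications arise.  First, an indel *between* two
intact grams shifts their hypothesized starts apart, so neither location
reaches two votes.  The fix is the *singleton-pair relaxation*: two
locations with one vote each, from different gram occurrences, whose
difference is at most $k$, are both admitted (the example above: locations 2
and 3).  Two intact grams separated by at most $k$ indels always differ by
at most $k$ in normalized position, so the relaxation restores losslessness
of the vote rule for the surviving-gram pair.  Pairs are evaluated pairwise,
not chained transitively.

Second, indels *before* any matched gram shift the true start into
$[l-k, l+k]$ and the true end into $[c-k, c+k]$, where $l$ is the candidate
start and $c = l + |r| - 1$.  Verifying the full window $[l-k, c+k]$ costs
alignment time at both ends, so verification uses a two-window heuristic:

1. window $[l, c+k]$, *anchored* at $l$ — leading reference bases may be
   skipped but are charged against the threshold (and stripped from the
   reported alignment), so effectively only starts at or just after $l$ are
   reachable;
2. only if window 1 yields nothing, window $[l-k, c]$ with a *free* start —
   every offset is tried as an alignment start and the recovered start is
   $l-k$ plus the number of skipped leading bases.

Mappings that start before $l$ and at the same time end after $c$ can escape
both windows; that loss is deliberate and, on random genomes, rare.  The
acceptance suite measures it against the exhaustive oracle and certifies
that **every** miss lies outside both windows of every candidate — never a
verification defect.

### Verification as a complete per-start scan

A design choice worth recording: both windows are implemented as *per-start*
banded scans rather than a single dynamic program with one traceback per end
offset.  A single traceback drops co-optimal alignments that share an end
but differ in start (two distance-1 alignments ending on the same base, say)
and would make misses impossible to attribute cleanly.  Scanning each start
with its own banded (half-width $k$) alignment costs
$O((|r|+k)\,|r|\,(2k+1))$ per window — negligible at short-read scale — and
makes each window's output exactly its coverage set, which is what the
miss-certification argument above relies on.  Cell values saturate at $k+1$
(Ukkonen cut-off); within-band ties in traceback prefer diagonal over
deletion over insertion, and among co-minimal end offsets the
lexicographically smallest CIGAR wins, so output is deterministic.  CIGARs
use the classic `M` for both match and mismatch.

## The mapper

`map_read()` maps both the read and its reverse complement.  Per
orientation the filter path is chosen by the gram budget
$\lfloor |r|/q \rfloor$: at least $k+2$ non-overlapping grams enable the
additional-prefix filter; exactly $k+1$ falls back to the pigeonhole union;
fewer still degrades to verifying every genome position (safe, unfiltered —
meant for degenerate inputs, not production).  The budget is evaluated per
read, not from the first read only, which is strictly safer for
variable-length input.  Results are merged across strands, deduplicated by
(reference, start, strand) keeping the smallest distance, and sorted.  With
the optional *m-mapping* cap, reads with more than $m$ distinct locations
are suppressed entirely and counted in the log.  Mapping quality is the
constant 255 — an all-mapper does not rank — and the edit distance is
reported in the `NM` tag; among a read's records the lowest-coordinate one
is primary, the rest carry the secondary flag.

Defaults: $q = 11$, the published sweet spot for 100 bp reads against
mammalian-scale genomes (a read then holds nine non-overlapping grams —
enough for $k \le 7$).  The index packs grams as 2-bit codes; windows
containing `N` are not indexed, `N` never matches anything, and candidate
windows never span two reference sequences.  Coordinates are 0-based
internally and 1-based in SAM.

## The simulator and the oracle

`random_genome()` draws i.i.d. uniform bases — by design.  The filter
guarantees under test are combinatorial (pigeonhole arguments over gram
counts), not error-model-dependent, so a uniform genome with uniformly
placed substitutions/indels (`sample_reads()`, which records exact origins
and error counts) exercises them fully.  What uniform genomes do *not*
emulate is the repeat structure of real genomes: candidate-list loads, the
filtration advantage of the extra gram, and the frequency-optimal selection
payoff are all *understated* at desk scale, and mapping-ambiguity behaviour
(m-mapping) is exercised only by planted duplicates.  Passing tests
demonstrate correctness contracts, not genome-scale performance.

`oracle_map()` is the gold standard: an exhaustive scan of every start
position on both strands, Hamming by direct counting, edit by a plain
unbanded semi-global DP anchored at each start — deliberately a second,
independent implementation, cross-checked in the unit tests against
`utils::adist`.

One scale choice follows from this: the filtration-ratio experiment (1,000
reads of 100 bp against a 100 kb genome, $k=2$) uses $q=5$, not the default
11.  Gram load scales as $N/4^q$; 11-grams on 100 kb are essentially all
unique (load 0.02), a regime in which no candidate filter has anything to
do, while 5-grams carry an expected load of ~100 locations — the same order
that 11-grams face on a $3\times10^9$ bp genome.  Problem sizes throughout
the test suite (genomes of 2–5 kb for oracle comparisons, 100 kb for the
filtration experiment, 100–200 random instances per property) were chosen
as the smallest that exercise every code path with non-trivial list loads.

## Numerical and degenerate-input choices

* Normalized locations that would be negative are dropped: no full-length
  read window starts there, and the $\pm k$ shift is handled later by
  verification, which clamps windows at sequence bounds.
* A location admitted both by votes and by a singleton pair keeps its vote
  count and loses the singleton flag; candidates are deduplicated before
  verification.
* Reads shorter than $q$ are reported unmapped with a warning; malformed
  records are skipped with a warning.
* `map_all()` accepts a `workers` argument for interface compatibility but
  always executes single-threaded; its contract is byte-identical output
  for any worker count, which holds trivially.
* Index persistence (CLI `index` subcommand) is `saveRDS`; the contract is
  correctness of the rebuilt structure, not load time.

## Known limitations

* The two-window heuristic's loss is real, measured, and documented above;
  the package also reports "shadow" mappings (starts adjacent to a true
  alignment that still fall within $k$) only when a window covers them —
  the exhaustive oracle counts more of these than any windowed verifier
  reports.
* No paired-end logic, no base-quality model, no affine gaps, no
  compressed or disk-resident index.
* The degenerate full-scan path is quadratic in genome size and intended
  for tests and tiny references only.
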