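# allmapr

An **all-mapper** for short DNA reads in R: it reports *every* mapping
location of a read within a Hamming or edit distance threshold *k*, not just
the best one.  All-mapping matters wherever secondary hits carry signal —
repeat analysis, structural variation, copy-number work — and its cost is
dominated by how many candidate locations must be verified.  `allmapr`
implements a candidate filter that keeps that number small without losing
true mappings, plus everything around it: FASTA/FASTQ input, SAM output with
CIGAR strings, a ground-truth read simulator, and an exhaustive brute-force
oracle mapper for evaluation.

## The method

* **q-gram inverted index.**  Every overlapping q-gram (default q = 11) of
  the reference is indexed with its sorted start locations I(g).  Shifting a
  list by the gram's offset in the read turns entries into hypothesized
  alignment starts (*normalized* lists).
* **Count filtering.**  Two length-|r| strings within Hamming distance k
  share at least `T = |r| − q + 1 − kq` overlapping grams; locations reaching
  T votes across all normalized lists survive (exact, but touches every
  list).
* **Optimal prefix grams.**  A substitution ruins at most one
  *non-overlapping* gram, so any true window keeps ≥ 1 of k+1 such grams.
  A dynamic program `M(i,j) = min{M(i,j−1), M(i−1,j) + L[j+(i−1)q]}` selects
  the non-overlapping grams with minimal summed inverted-list lengths.
* **The additional prefix gram.**  Selecting **k+2** non-overlapping grams,
  a true window keeps ≥ 2 of them — only locations voted by at least two
  normalized lists survive, equivalently the union of pairwise intersections
  of the lists, computed by one multiway merge.  Under edit distance, two
  single-vote locations within k of each other (from different grams) are
  both admitted, because indels between intact grams shift their votes
  apart.
* **Two-window banded verification.**  For candidate start l and nominal end
  c = l + |r| − 1, indels move true starts into [l−k, l+k] and ends into
  [c−k, c+k].  Verification runs a banded semi-global alignment first on
  [l, c+k] anchored at l, and only if that yields nothing on [l−k, c] with a
  free start.  Mappings that start before l *and* end after c can escape
  both windows; the test suite measures this loss against the oracle and
  certifies every miss as exactly that geometry.

## Worked example

```r
library(allmapr)
genome <- random_genome(50000, n_sequences = 2, seed = 42)
idx <- build_index(genome, q = 11)
idx
#> genome_index: q = 11, 2 sequence(s), 49679 distinct gram(s), 49980 indexed window(s)

reads <- sample_reads(genome, n = 5, read_length = 100,
                      max_sub = 2, max_ins = 1, max_del = 1, seed = 43)
reports <- map_all(reads, idx, k = 4, mode = "edit")
reports[[1]]
#> mapping_report 'read_00001': 3 mapping(s)
#>    ref pos strand distance      cigar
#> 1 chr2 438      -        2 1D23M1I76M
#> 2 chr2 439      -        1   23M1I76M
#> 3 chr2 440      -        2 1I22M1I76M
```

The first read was simulated from chr2, 0-based position 439, reverse
strand, with one inserted base (`reads[1, c("ref","start","strand","ins")]`
confirms this).  The mapper recovers that origin at distance 1 with CIGAR
`23M1I76M` — 23 aligned bases, the inserted read base, 76 more aligned
bases — plus the two adjacent starts that also align within k = 4.
`write_sam(reports, idx, "out.sam")` emits these as SAM records: 1-based
positions, flag 16 for the reverse strand (sequence stored
reverse-complemented), the lowest-coordinate record primary and the others
flagged secondary, distances in the `NM` tag.

The same pipeline is scriptable from a shell via `exec/allmapr`:

```sh
exec/allmapr simulate --length 50000 --reads 1000 --read-length 100 \
    --max-sub 2 --max-ins 1 --max-del 1 --seed 7 --out-prefix sim
exec/allmapr index --ref sim.fa --q 11 --out ref.idx
exec/allmapr map --index ref.idx --reads sim.fastq --k 4 --mode edit -o out.sam
```

The `map` log reports reads processed, candidates generated, candidates
verified, and reads suppressed by the optional `-m` cap.

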