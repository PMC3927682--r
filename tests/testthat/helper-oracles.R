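# Independent pure-R oracles and small fixture builders used across tests.
# These deliberately avoid the package's own kernels: Hamming counts come
# from character-vector comparison, edit distances from utils::adist.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# all 0-based starts in `genome` (named vector, forward strand only) whose
# window is within Hamming distance k of `read`
r_hamming_scan <- function(read, chrom, k) {
  m <- nchar(read)
  rv <- strsplit(read, "", fixed = TRUE)[[1]]
  gv <- strsplit(chrom, "", fixed = TRUE)[[1]]
  n <- length(gv)
  if (n < m) return(integer(0))
  starts <- 0:(n - m)
  d <- vapply(starts, function(p) sum(rv != gv[(p + 1):(p + m)]), integer(1))
  starts[d <= k]
}

# minimal semi-global distance of read against prefixes of window, anchored
# at window offset s (0-based), computed with utils::adist
r_anchored_dist <- function(read, window, s) {
  sub <- substring(window, s + 1)
  ends <- vapply(0:nchar(sub), function(e) substr(sub, 1, e), character(1))
  min(adist(read, ends))
}

# brute-force minimum of summed list lengths over all placements of `count`
# non-overlapping grams of `read` (enumeration, for small reads only)
brute_min_total <- function(read, index, count) {
  q <- index$q
  L <- allmapr:::.window_list_lengths(read, index)
  G <- length(L)
  best <- Inf
  rec <- function(i, from, tot) {
    if (tot >= best) return()
    if (i == count) { best <<- tot; return() }
    if (from > G) return()
    for (j in from:G) rec(i + 1L, j + q, tot + L[j])
  }
  rec(0L, 1L, 0)
  best
}

# build a prefix_selection by hand from explicit offsets of a read
make_selection <- function(read, offsets, index) {
  q <- index$q
  grams <- substring(read, offsets + 1L, offsets + q)
  len <- vapply(grams, function(g) gram_count(index, g), integer(1))
  structure(list(picks = data.frame(offset = offsets, gram = grams,
                                    len = len, stringsAsFactors = FALSE),
                 total = sum(len)),
            class = "prefix_selection")
}

# Certify that an edit-mode miss is a blind spot of the two-window
# verification heuristic: for every candidate l of the read's orientation,
# the missed mapping (global start s0, end e0, distance d0) must lie outside
# window 1's coverage (s >= l, end <= c+k, charge d0 + s0 - l <= k), and
# window 2 (start >= l-k, end <= c) must either not have run (window 1 found
# matches) or not cover it.  The canonical documented loss --- start before
# l and end after c --- is the leading special case.
certify_miss <- function(seq_oriented, index, k, s0, e0, d0) {
  gen <- allmapr:::.candidates_for(seq_oriented, index, k, "edit")
  m <- nchar(seq_oriented)
  for (l in unique(gen$cand$location)) {
    cc <- l + m - 1
    w1_covers <- s0 >= l && e0 <= cc + k && d0 + (s0 - l) <= k
    if (w1_covers) return(FALSE)
    si <- allmapr:::.seq_of(index, l)
    if (si < 1) next
    seq_end <- index$seq_offsets[si] + index$seq_lengths[si] - 1
    if (l > seq_end) next
    w1_end <- min(cc + k, seq_end)
    w1 <- banded_semiglobal(seq_oriented,
                            allmapr:::.genome_window(index, l, w1_end), k,
                            free_start = FALSE)
    w1_found <- !is.null(w1)
    w2_covers <- s0 >= l - k && e0 <= cc
    if (!w1_found && w2_covers) return(FALSE)
  }
  TRUE
}

# compare a mapping_report against the oracle for one read; returns list of
# key sets (oracle, mapped) on (ref, start, strand)
mapping_keys <- function(report, orc) {
  list(mapped = paste(report$results$ref, report$results$pos,
                      report$results$strand),
       oracle = paste(orc$ref, orc$start, orc$strand))
}
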