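# Candidate verification: Hamming comparison, banded semi-global alignment,
# and the two-window heuristic for edit distance.

#' Verify a candidate by Hamming comparison
#'
#' Compares the read against the genome window starting at `l`.  Windows that
#' run off the candidate's sequence yield no result.
#'
#' @param read Base string.
#' @param index A `genome_index` built from sequences (not from bare lists).
#' @param l Global 0-based candidate start.
#' @param k Hamming distance threshold.
#' @return One-row data frame `start`, `distance`, `cigar` (a full-length
#'   match run), or `NULL` when out of bounds or above threshold.
#' @export
hamming_verify <- function(read, index, l, k) {
  read <- toupper(read)
  m <- nchar(read)
  si <- .seq_of(index, l)
  if (si < 1L) return(NULL)
  seq_end <- index$seq_offsets[si] + index$seq_lengths[si] - 1
  if (l + m - 1 > seq_end) return(NULL)
  d <- cpp_hamming(read, .genome_window(index, l, l + m - 1))
  if (d > k) return(NULL)
  data.frame(start = l, distance = d, cigar = paste0(m, "M"),
             stringsAsFactors = FALSE)
}

#' Banded semi-global alignment of a read against a reference window
#'
#' The read is aligned end to end; the window end is free, and every end
#' offset whose distance is at most `k` is reported with its traceback CIGAR.
#' Every window offset is tried as an anchored start of a banded (half-width
#' `k`) alignment, so co-optimal alignments at distinct starts are never
#' lost to traceback tie-breaking.  With `free_start = FALSE` the window
#' start is the anchor: a start at offset `s` is admitted only when its `s`
#' skipped leading window bases, charged as deletions, still fit the
#' threshold together with the alignment distance (`d_s + s <= k`); the
#' reported distance is `d_s` with the charge stripped.  With
#' `free_start = TRUE` every start with `d_s <= k` is admitted.  CIGAR uses
#' `M` for match and mismatch; traceback prefers diagonal over deletion over
#' insertion, and among co-minimal end offsets the lexicographically
#' smallest CIGAR wins.
#'
#' @param read Base string (non-empty).
#' @param window Base string.
#' @param k Edit distance threshold (band half-width).
#' @param free_start Whether leading window bases are free (see above).
#' @return `NULL` when no alignment has distance <= k, else a list with
#'   `distance` (minimum), `end_offset` (0-based inclusive window offset of
#'   the best hit's last consumed base), `cigar` (best hit), and `hits`
#'   (data frame `start`, `end`, `distance`, `cigar`, one row per distinct
#'   start).
#' @export
banded_semiglobal <- function(read, window, k, free_start = FALSE) {
  stopifnot(nchar(window) >= 1, nchar(read) >= 1, k >= 0)
  hits <- cpp_semiglobal(toupper(read), toupper(window), as.integer(k),
                         isTRUE(free_start))
  if (!nrow(hits)) return(NULL)
  best <- which.min(hits$distance)
  list(distance = hits$distance[best],
       end_offset = hits$end[best],
       cigar = hits$cigar[best],
       hits = hits)
}

#' Global (end-to-end) edit distance between two sequences
#'
#' Plain unbanded Levenshtein distance; unit costs, `N` matches nothing.
#'
#' @param a,b Base strings.
#' @return Integer distance.
#' @export
global_edit_distance <- function(a, b) {
  cpp_global_edit(toupper(a), toupper(b))
}

#' Verify a candidate under edit distance with the two-window heuristic
#'
#' With candidate start `l` and nominal end `c = l + |read| - 1`, indels can
#' shift a true mapping's start into `[l-k, l+k]` and its end into
#' `[c-k, c+k]`.  Searching the full window `[l-k, c+k]` at both ends is
#' wasteful, so verification first runs the banded semi-global aligner on
#' `[l, c+k]` anchored at `l`; only if that window yields no mapping does it
#' retry on `[l-k, c]` with a free start (the recovered start is `l-k` plus
#' the number of leading reference bases skipped).  Mappings that start
#' before `l` and end after `c` can escape both windows; that loss is
#' deliberate.  Windows are clamped to the candidate's sequence bounds.
#'
#' @param read Base string.
#' @param index A `genome_index` with sequence content.
#' @param l Global 0-based candidate start.
#' @param k Edit distance threshold.
#' @return Data frame `start` (global 0-based), `distance`, `cigar`, one row
#'   per distinct alignment start found; zero rows when none.
#' @export
verify_candidate <- function(read, index, l, k) {
  read <- toupper(read)
  m <- nchar(read)
  empty <- data.frame(start = numeric(0), distance = integer(0),
                      cigar = character(0), stringsAsFactors = FALSE)
  si <- .seq_of(index, l)
  if (si < 1L) return(empty)
  seq_start <- index$seq_offsets[si]
  seq_end <- seq_start + index$seq_lengths[si] - 1
  if (l > seq_end) return(empty)
  cc <- l + m - 1
  # window 1: [l, c+k], anchored at l
  w1_end <- min(cc + k, seq_end)
  if (w1_end >= l) {
    res <- banded_semiglobal(read, .genome_window(index, l, w1_end), k,
                             free_start = FALSE)
    if (!is.null(res)) {
      return(data.frame(start = l + res$hits$start,
                        distance = res$hits$distance,
                        cigar = res$hits$cigar, stringsAsFactors = FALSE))
    }
  }
  # window 2: [l-k, c], free start
  w2_start <- max(seq_start, l - k)
  w2_end <- min(cc, seq_end)
  if (w2_end >= w2_start) {
    res <- banded_semiglobal(read, .genome_window(index, w2_start, w2_end), k,
                             free_start = TRUE)
    if (!is.null(res)) {
      return(data.frame(start = w2_start + res$hits$start,
                        distance = res$hits$distance,
                        cigar = res$hits$cigar, stringsAsFactors = FALSE))
    }
  }
  empty
}
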