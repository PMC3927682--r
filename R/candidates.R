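# Candidate generation from normalized inverted lists.
#
# Three schemes, in increasing selectivity:
#   * naive count filtering over ALL overlapping grams (the reference oracle
#     for the Hamming case),
#   * the union of k+1 non-overlapping prefix grams (pigeonhole baseline and
#     fallback), and
#   * the additional-prefix filter: k+2 non-overlapping grams, keep locations
#     voted by at least two lists, with a singleton-pair relaxation under
#     edit distance.

#' Count-filtering threshold
#'
#' Two length-`|r|` strings within Hamming distance k share at least
#' `|r| - q + 1 - k q` overlapping q-grams, because one substitution touches
#' at most q of them.
#'
#' @param read_length Read length.
#' @param q Gram length.
#' @param k Distance threshold.
#' @return The threshold `T` (may be <= 0, in which case the filter is
#'   vacuous).
#' @examples
#' count_threshold(17, 5, 2)  # 3
#' @export
count_threshold <- function(read_length, q, k) {
  stopifnot(read_length >= q)
  as.integer(read_length - q + 1 - k * q)
}

#' Count location multiplicities across normalized inverted lists
#'
#' The shared core of count filtering and the additional-prefix merge: a
#' single pass over the concatenation of the sorted lists tallies how many
#' lists contain each location.
#'
#' @param normalized_lists List of sorted numeric vectors (one per gram
#'   occurrence; each list contributes at most one vote per location).
#' @param min_count Keep locations voted at least this many times.
#' @return Data frame `location`, `votes`, sorted by location.
#' @export
count_locations <- function(normalized_lists, min_count) {
  locs <- unlist(normalized_lists, use.names = FALSE)
  if (!length(locs)) {
    return(data.frame(location = numeric(0), votes = integer(0)))
  }
  tab <- table(locs)
  keep <- tab >= min_count
  data.frame(location = as.numeric(names(tab)[keep]),
             votes = as.integer(tab[keep]), row.names = NULL)
}

#' Naive count filtering over all overlapping grams of a read
#'
#' Scans every normalized inverted list of the read (a repeated gram counts
#' as a separate list per occurrence) and keeps locations appearing in at
#' least `T = count_threshold(...)` of them.  Exact for Hamming distance;
#' used as a reference filter, not the production path.
#'
#' @param read Base string.
#' @param index A `genome_index`.
#' @param k Hamming distance threshold; `count_threshold` must be positive.
#' @return Data frame `location`, `votes`.
#' @export
naive_count_filter <- function(read, index, k) {
  read <- toupper(read)
  T_ <- count_threshold(nchar(read), index$q, k)
  if (T_ <= 0) {
    stop("count filtering is vacuous for these parameters (threshold <= 0)")
  }
  grams <- extract_overlapping_grams(read, index$q)
  lists <- lapply(seq_len(nrow(grams)), function(i) {
    normalize_list(lookup_gram(index, grams$gram[i]), grams$offset[i])
  })
  out <- count_locations(lists, T_)
  out$singleton_pair <- rep(FALSE, nrow(out))
  out
}

# normalized lists for the picks of a prefix_selection
.selection_lists <- function(selection, index) {
  lapply(seq_len(nrow(selection$picks)), function(i) {
    normalize_list(lookup_gram(index, selection$picks$gram[i]),
                   selection$picks$offset[i])
  })
}

#' Candidates from the union of k+1 non-overlapping prefix grams
#'
#' At most k substitutions alter at most k non-overlapping grams, so at least
#' one of k+1 survives: the union of their normalized lists is a lossless
#' Hamming candidate set.  This is the fallback when a read is too short for
#' the k+2 filter.
#'
#' @param selection A `prefix_selection` with `k + 1` picks.
#' @param index A `genome_index`.
#' @return Data frame `location`, `votes`, `singleton_pair` (all `FALSE`).
#' @export
prefix_union_candidates <- function(selection, index) {
  out <- count_locations(.selection_lists(selection, index), 1L)
  out$singleton_pair <- rep(FALSE, nrow(out))
  out
}

#' Candidates from k+2 prefix grams, at least two matching lists
#'
#' With k+2 non-overlapping grams, at most k can be altered, so a true match
#' keeps at least two intact: only locations voted by two or more normalized
#' lists survive.  Equivalently, the survivors are the union of pairwise
#' intersections of the lists; the implementation is a single multiway merge.
#' Under edit distance, indels between two intact grams shift their
#' hypothesized starts apart, so additionally any two single-vote locations
#' from different gram occurrences within `k` of each other are both admitted
#' (flagged `singleton_pair`).
#'
#' @param selection A `prefix_selection` with `k + 2` picks.
#' @param index A `genome_index`.
#' @param k Distance threshold.
#' @param mode `"hamming"` or `"edit"` (enables the singleton-pair
#'   relaxation).
#' @return Data frame `location`, `votes`, `singleton_pair`, sorted and
#'   deduplicated.
#' @export
additional_prefix_candidates <- function(selection, index, k,
                                         mode = c("hamming", "edit")) {
  mode <- match.arg(mode)
  lists <- .selection_lists(selection, index)
  locs <- unlist(lists, use.names = FALSE)
  src <- rep(seq_along(lists), lengths(lists))
  if (!length(locs)) {
    return(data.frame(location = numeric(0), votes = integer(0),
                      singleton_pair = logical(0)))
  }
  ord <- order(locs)
  locs <- locs[ord]
  src <- src[ord]
  runs <- rle(locs)
  votes <- runs$lengths
  uloc <- runs$values
  keep <- votes >= 2L
  out <- data.frame(location = uloc[keep], votes = votes[keep],
                    singleton_pair = rep(FALSE, sum(keep)))
  if (mode == "edit" && k >= 1) {
    singles <- which(votes == 1L)
    if (length(singles) >= 2L) {
      sloc <- uloc[singles]
      ssrc <- src[cumsum(votes)[singles]]  # source list of each singleton
      admit <- logical(length(singles))
      for (i in seq_along(singles)) {
        j <- i - 1L
        while (j >= 1L && sloc[i] - sloc[j] <= k) {
          if (ssrc[j] != ssrc[i]) { admit[i] <- TRUE; admit[j] <- TRUE }
          j <- j - 1L
        }
      }
      if (any(admit)) {
        out <- rbind(out,
                     data.frame(location = sloc[admit],
                                votes = rep(1L, sum(admit)),
                                singleton_pair = rep(TRUE, sum(admit))))
      }
    }
  }
  out <- out[order(out$location), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Number of (k+1)-subsets of k+2 grams
#'
#' Documents the derivation of the two-vote rule: each of the `k + 2` ways of
#' leaving one gram out yields a lossless k+1 union, and a true match must lie
#' in all of them, i.e. in at least two of the individual lists.
#'
#' @param k Distance threshold (>= 0).
#' @return `k + 2`.
#' @export
subset_count <- function(k) {
  stopifnot(k >= 0)
  as.integer(choose(k + 2, k + 1))
}
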