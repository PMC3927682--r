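# Frequency-optimal selection of non-overlapping prefix q-grams of a read.
#
# A substitution changes at most one non-overlapping gram, so any genome
# window within Hamming distance k of the read keeps at least one of k+1
# (and at least two of k+2) non-overlapping grams intact.  Selecting the
# grams with the lowest summed inverted-list lengths minimises the candidate
# workload; the dynamic program below finds that optimum.

#' Maximum number of mutually non-overlapping q-grams in a read
#'
#' @param read_length Read length in bases.
#' @param q Gram length (>= 1).
#' @return `floor(read_length / q)`.
#' @examples
#' max_nonoverlapping_grams(100, 11)  # 9
#' @export
max_nonoverlapping_grams <- function(read_length, q) {
  stopifnot(q >= 1)
  as.integer(read_length %/% q)
}

#' Select `count` non-overlapping grams minimising summed list lengths
#'
#' Dynamic program over the ordered gram multiset of the read.  With `L[n]`
#' the inverted-list length of the n-th gram, the table
#' `M(i, j) = min(M(i, j-1), M(i-1, j) + L[j + (i-1) q])` (with `M(0, j) = 0`
#' and `M(i, 0) = Inf`) gives the minimal total for `i` non-overlapping grams;
#' the goal cell is `M(count, |G(r)| - (count-1) q)`.  Traceback prefers the
#' leftmost placement achieving the optimum.  Grams containing N have
#' infinite effective list length and are selected only if unavoidable, in
#' which case selection fails.
#'
#' @param read Base string.
#' @param index A `genome_index`.
#' @param count Number of grams to select (typically `k + 2` or `k + 1`).
#' @return An object of class `prefix_selection`: list with `picks` (data
#'   frame `offset`, `gram`, `len`) and `total`.
#' @export
select_prefix_grams <- function(read, index, count) {
  stopifnot(count >= 1)
  q <- index$q
  read <- toupper(read)
  if (max_nonoverlapping_grams(nchar(read), q) < count) {
    stop(not_enough_grams(sprintf(
      "read of length %d holds %d non-overlapping %d-grams; %d requested",
      nchar(read), max_nonoverlapping_grams(nchar(read), q), q, count)))
  }
  L <- .window_list_lengths(read, index)
  G <- length(L)
  W <- G - (count - 1L) * q
  # M[i+1, j+1] corresponds to M(i, j); row 0 is zeros
  M <- matrix(Inf, nrow = count + 1L, ncol = W + 1L)
  M[1L, ] <- 0
  for (i in seq_len(count)) {
    taken <- M[i, 2:(W + 1L)]
    cand <- taken + L[(1:W) + (i - 1L) * q]
    M[i + 1L, 2:(W + 1L)] <- cummin(cand)
  }
  total <- M[count + 1L, W + 1L]
  if (!is.finite(total)) {
    stop(not_enough_grams("no N-free placement of the requested grams exists"))
  }
  # traceback, leftmost placement: slide left while the optimum persists
  offsets <- integer(count)
  j <- W
  for (i in count:1) {
    while (j > 1L && M[i + 1L, j] == M[i + 1L, j + 1L]) j <- j - 1L
    offsets[i] <- j + (i - 1L) * q - 1L  # 0-based gram offset
  }
  grams <- substring(read, offsets + 1L, offsets + q)
  picks <- data.frame(offset = offsets, gram = grams,
                      len = L[offsets + 1L], stringsAsFactors = FALSE)
  structure(list(picks = picks, total = total), class = "prefix_selection")
}

#' @export
print.prefix_selection <- function(x, ...) {
  cat(sprintf("prefix_selection: %d gram(s), summed list length %g\n",
              nrow(x$picks), x$total))
  print(x$picks)
  invisible(x)
}

#' Classic prefix filtering: the k*q+1 least frequent overlapping grams
#'
#' Any window within Hamming distance k of the read shares at least
#' `|G(r)| - k q` grams with it, so it must contain at least one of any
#' `k q + 1` grams of the read; taking the least frequent ones minimises the
#' candidate union.  Ties broken by smaller read offset.
#'
#' @param read Base string.
#' @param index A `genome_index`.
#' @param k Hamming distance threshold.
#' @return Data frame with columns `offset`, `gram`, `len`.
#' @export
classic_prefix_grams <- function(read, index, k) {
  stopifnot(k >= 0)
  q <- index$q
  read <- toupper(read)
  need <- k * q + 1L
  L <- .window_list_lengths(read, index)
  if (length(L) < need) {
    stop(not_enough_grams(sprintf(
      "read has %d overlapping grams; %d needed", length(L), need)))
  }
  ord <- order(L, seq_along(L))[seq_len(need)]
  ord <- sort(ord)
  data.frame(offset = ord - 1L,
             gram = substring(read, ord, ord + q - 1L),
             len = L[ord], stringsAsFactors = FALSE)
}
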