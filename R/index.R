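# Overlapping q-gram inverted index of a reference genome.
#
# Grams are hashed as 2-bit-per-base packed integers (A=0, C=1, G=2, T=3),
# stored as doubles so codes are exact for q <= 26.  Windows containing an N
# are not indexed.  Locations live in a single concatenated 0-based coordinate
# space; per-sequence offsets map back to chromosome coordinates.

.base_vals <- c(A = 0, C = 1, G = 2, T = 3)

#' Pack the overlapping grams of a sequence into base-4 integer codes
#'
#' Windows containing any character outside `ACGT` (for instance `N`) get an
#' `NA` code.
#'
#' @param s Base string.
#' @param q Gram length.
#' @return Numeric vector of length `max(0, nchar(s) - q + 1)`.
#' @keywords internal
gram_codes <- function(s, q) {
  n <- nchar(s)
  W <- n - q + 1
  if (W < 1) return(numeric(0))
  b <- unname(.base_vals[strsplit(s, "", fixed = TRUE)[[1]]])
  pow <- 4^((q - 1):0)
  codes <- numeric(W)
  for (j in seq_len(q)) codes <- codes + b[j:(W + j - 1)] * pow[j]
  codes
}

.gram_code <- function(g) {
  v <- unname(.base_vals[strsplit(g, "", fixed = TRUE)[[1]]])
  if (anyNA(v)) return(NA_real_)
  sum(v * 4^((length(v) - 1):0))
}

#' Enumerate the overlapping q-grams of a sequence
#'
#' Slides a window of length `q` over `s`.  Repeated grams are kept as
#' distinct entries: the gram multiset is ordered by read offset.
#'
#' @param s Base string.
#' @param q Gram length (>= 1).
#' @return A data frame with columns `offset` (0-based) and `gram`.
#' @examples
#' extract_overlapping_grams("ACCTACCT", 3)
#' @export
extract_overlapping_grams <- function(s, q) {
  if (!is.numeric(q) || length(q) != 1L || q < 1) {
    stop("`q` must be a single integer >= 1")
  }
  q <- as.integer(q)
  n <- nchar(s)
  W <- n - q + 1
  if (W < 1) {
    return(data.frame(offset = integer(0), gram = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(offset = 0:(W - 1),
             gram = substring(s, 1:W, q:(W + q - 1)),
             stringsAsFactors = FALSE)
}

#' Build an overlapping q-gram inverted index of a genome
#'
#' Every N-free window of length `q` in every sequence is indexed under its
#' packed gram code; each gram's inverted list is the strictly increasing list
#' of its 0-based start locations in the concatenated coordinate space.
#'
#' @param sequences Named character vector of reference sequences (upper-case
#'   `ACGTN`), or a `Biostrings::DNAStringSet`.
#' @param q Gram length, default 11.
#' @return An object of class `genome_index`.
#' @examples
#' idx <- build_index(c(chr1 = "ACCTACCT"), q = 3)
#' lookup_gram(idx, "CCT")  # c(1, 4)
#' @export
build_index <- function(sequences, q = 11L) {
  if (!is.numeric(q) || length(q) != 1L || q < 1 || q > 26) {
    stop("`q` must be a single integer in [1, 26]")
  }
  q <- as.integer(q)
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(toupper(as.character(sequences)),
                                 names(sequences))
  }
  sequences <- toupper(unlist(as.list(sequences)))
  if (length(sequences) && is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  lens <- if (length(sequences)) nchar(sequences) else integer(0)
  offsets <- if (length(sequences)) cumsum(c(0, lens[-length(lens)])) else integer(0)

  all_codes <- numeric(0)
  all_pos <- numeric(0)
  for (i in seq_along(sequences)) {
    codes <- gram_codes(sequences[[i]], q)
    ok <- which(!is.na(codes))
    all_codes <- c(all_codes, codes[ok])
    all_pos <- c(all_pos, offsets[i] + ok - 1)
  }
  ord <- order(all_codes, all_pos)
  all_codes <- all_codes[ord]
  all_pos <- all_pos[ord]
  keys <- unique(all_codes)
  key_counts <- tabulate(match(all_codes, keys), nbins = length(keys))
  key_starts <- cumsum(c(1L, key_counts[-length(key_counts)]))

  structure(list(q = q,
                 seq_names = names(sequences),
                 seq_offsets = as.numeric(offsets),
                 seq_lengths = as.numeric(lens),
                 genome = paste(sequences, collapse = ""),
                 keys = keys,
                 key_starts = as.integer(key_starts),
                 key_counts = as.integer(key_counts),
                 loc = all_pos),
            class = "genome_index")
}

#' Build an index directly from explicit inverted lists
#'
#' Constructs a `genome_index` whose inverted lists are supplied by the caller
#' instead of being derived from a genome.  Useful for experiments with
#' published index excerpts; such an index supports candidate generation but
#' not verification (it carries no genome sequence).
#'
#' @param lists Named list: gram string -> strictly increasing integer vector
#'   of 0-based locations.
#' @param q Gram length; defaults to the length of the first gram.
#' @return A `genome_index` with `genome = NULL`.
#' @export
index_from_lists <- function(lists, q = nchar(names(lists)[1])) {
  stopifnot(is.list(lists), length(lists) >= 1, !is.null(names(lists)))
  if (any(nchar(names(lists)) != q)) stop("all grams must have length q")
  bad <- vapply(lists, function(v) is.unsorted(v, strictly = TRUE),
                logical(1))
  if (any(bad)) stop("inverted lists must be strictly increasing")
  codes <- vapply(names(lists), .gram_code, numeric(1))
  if (anyNA(codes)) stop("grams must be over {A,C,G,T}")
  ord <- order(codes)
  counts <- lengths(lists)[ord]
  structure(list(q = as.integer(q),
                 seq_names = character(0),
                 seq_offsets = numeric(0),
                 seq_lengths = numeric(0),
                 genome = NULL,
                 keys = codes[ord],
                 key_starts = as.integer(cumsum(c(1L, counts[-length(counts)]))),
                 key_counts = as.integer(counts),
                 loc = as.numeric(unlist(lists[ord], use.names = FALSE))),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("genome_index: q = %d, %d sequence(s), %d distinct gram(s), %d indexed window(s)\n",
              x$q, length(x$seq_names), length(x$keys), length(x$loc)))
  invisible(x)
}

#' Look up the inverted list of a gram
#'
#' @param index A `genome_index`.
#' @param g Gram string of length `index$q`.
#' @return Sorted numeric vector of 0-based locations; empty when absent.
#' @export
lookup_gram <- function(index, g) {
  if (nchar(g) != index$q) stop("gram length must equal index q")
  code <- .gram_code(toupper(g))
  if (is.na(code)) return(numeric(0))
  i <- findInterval(code, index$keys)
  if (i == 0L || index$keys[i] != code) return(numeric(0))
  index$loc[seq.int(index$key_starts[i], length.out = index$key_counts[i])]
}

#' Inverted-list length of a gram
#'
#' @inheritParams lookup_gram
#' @return Integer count (0 when absent).
#' @export
gram_count <- function(index, g) {
  length(lookup_gram(index, g))
}

# inverted-list lengths for all windows of a read, vectorised;
# windows containing N get Inf so the gram selector avoids them
.window_list_lengths <- function(read, index) {
  codes <- gram_codes(read, index$q)
  if (!length(codes)) return(numeric(0))
  i <- findInterval(codes, index$keys)
  i1 <- pmax(i, 1L)
  len <- ifelse(i > 0L & index$keys[i1] == codes, index$key_counts[i1], 0)
  len[is.na(codes)] <- Inf
  as.numeric(len)
}

#' Normalize an inverted list relative to a gram's read offset
#'
#' Subtracting the read offset turns gram start locations into hypothesized
#' alignment starts.  Entries that would become negative (no full-length read
#' window exists there) are dropped.
#'
#' @param locations Sorted numeric vector of genome locations.
#' @param read_offset 0-based offset of the gram in the read.
#' @return Sorted numeric vector of hypothesized alignment starts.
#' @examples
#' normalize_list(c(105, 118), 13)  # c(92, 105)
#' @export
normalize_list <- function(locations, read_offset) {
  stopifnot(read_offset >= 0)
  out <- locations - read_offset
  out[out >= 0]
}

# index of the sequence containing global location l (0 when before all)
.seq_of <- function(index, l) {
  findInterval(l, index$seq_offsets)
}

# substring of the concatenated genome, clamped, 0-based [from, to]
.genome_window <- function(index, from, to) {
  substr(index$genome, from + 1, to + 1)
}
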