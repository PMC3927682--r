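# End-to-end all-mapping of reads: strand handling, gram-availability gate,
# filter-path selection, verification, deduplication, m-mapping cap.

#' Reverse complement of a DNA string
#'
#' @param s Base string over `ACGTN` (other characters become `N`).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(s) {
  cpp_revcomp(toupper(s))
}

# generate candidate locations for one oriented read; returns list with the
# candidate data frame and the filter path taken
.candidates_for <- function(seq, index, k, mode) {
  nmax <- max_nonoverlapping_grams(nchar(seq), index$q)
  if (nmax >= k + 2) {
    sel <- tryCatch(select_prefix_grams(seq, index, k + 2L),
                    allmapr_not_enough_grams = function(e) NULL)
    if (!is.null(sel)) {
      return(list(cand = additional_prefix_candidates(sel, index, k, mode),
                  path = "k+2"))
    }
  }
  if (nmax >= k + 1) {
    sel <- tryCatch(select_prefix_grams(seq, index, k + 1L),
                    allmapr_not_enough_grams = function(e) NULL)
    if (!is.null(sel)) {
      return(list(cand = prefix_union_candidates(sel, index), path = "k+1"))
    }
  }
  # degenerate path: too few grams to filter; every within-sequence start is
  # a candidate (safe but unfiltered, intended for short reads / small refs)
  m <- nchar(seq)
  locs <- unlist(lapply(seq_along(index$seq_offsets), function(i) {
    last <- index$seq_lengths[i] - m + k
    if (last < 0) return(numeric(0))
    index$seq_offsets[i] + 0:min(last, index$seq_lengths[i] - 1)
  }), use.names = FALSE)
  list(cand = data.frame(location = locs,
                         votes = rep(1L, length(locs)),
                         singleton_pair = rep(FALSE, length(locs))),
       path = "scan")
}

#' Map a single read to all its locations within distance k
#'
#' Both the read and its reverse complement are mapped.  Per orientation, if
#' the read holds at least `k + 2` non-overlapping grams, candidates come
#' from the additional-prefix filter; with only `k + 1`, from the pigeonhole
#' union fallback; with fewer still, every genome position is verified
#' (degenerate safety path).  Candidates are then verified (Hamming
#' comparison, or the two-window banded aligner in edit mode), merged across
#' strands and deduplicated by (reference, start, strand) keeping the
#' smallest distance.
#'
#' @param read Base string, or a one-row data frame with columns `id`, `seq`
#'   and optionally `qual`.
#' @param index A `genome_index` with sequence content.
#' @param k Distance threshold (>= 0).
#' @param mode `"hamming"` or `"edit"`.
#' @param m Optional m-mapping cap: reads with more than `m` distinct mapping
#'   locations are suppressed (no records emitted, `suppressed_by_m` set).
#' @return A `mapping_report`: list with `id`, `seq`, `qual`, `results` (data
#'   frame `ref`, `pos` 0-based within `ref`, `strand`, `distance`, `cigar`),
#'   `unmapped`, `suppressed_by_m`, and counters `n_candidates`,
#'   `n_verified`.
#' @export
map_read <- function(read, index, k, mode = c("hamming", "edit"), m = NULL) {
  mode <- match.arg(mode)
  stopifnot(k >= 0)
  if (is.data.frame(read)) {
    id <- read$id[1]
    qual <- if ("qual" %in% names(read)) read$qual[1] else NA_character_
    seq <- toupper(read$seq[1])
  } else {
    id <- "read"
    qual <- NA_character_
    seq <- toupper(read)
  }
  empty <- data.frame(ref = character(0), pos = numeric(0),
                      strand = character(0), distance = integer(0),
                      cigar = character(0), stringsAsFactors = FALSE)
  report <- list(id = id, seq = seq, qual = qual, results = empty,
                 unmapped = TRUE, suppressed_by_m = FALSE,
                 n_candidates = 0L, n_verified = 0L)
  class(report) <- "mapping_report"
  if (nchar(seq) < index$q) {
    warning(sprintf("read '%s' is shorter than q = %d; reported unmapped",
                    id, index$q))
    return(report)
  }
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    gen <- .candidates_for(s, index, k, mode)
    cand <- unique(gen$cand$location)
    report$n_candidates <- report$n_candidates + length(cand)
    for (l in cand) {
      hits <- if (mode == "hamming") {
        hamming_verify(s, index, l, k)
      } else {
        verify_candidate(s, index, l, k)
      }
      if (!is.null(hits) && nrow(hits)) {
        report$n_verified <- report$n_verified + nrow(hits)
        hits$strand <- strand
        rows[[length(rows) + 1L]] <- hits
      }
    }
  }
  if (!length(rows)) return(report)
  res <- do.call(rbind, rows)
  res <- res[order(res$start, res$strand, res$distance, res$cigar), ,
             drop = FALSE]
  res <- res[!duplicated(res[, c("start", "strand")]), , drop = FALSE]
  si <- .seq_of(index, res$start)
  res <- data.frame(ref = index$seq_names[si],
                    pos = res$start - index$seq_offsets[si],
                    strand = res$strand, distance = res$distance,
                    cigar = res$cigar, stringsAsFactors = FALSE)
  row.names(res) <- NULL
  if (!is.null(m) && nrow(res) > m) {
    report$suppressed_by_m <- TRUE
    return(report)
  }
  report$results <- res
  report$unmapped <- FALSE
  report
}

#' @export
print.mapping_report <- function(x, ...) {
  state <- if (x$suppressed_by_m) "suppressed (m-mapping cap)"
           else if (x$unmapped) "unmapped"
           else sprintf("%d mapping(s)", nrow(x$results))
  cat(sprintf("mapping_report '%s': %s\n", x$id, state))
  if (nrow(x$results)) print(x$results)
  invisible(x)
}

#' Map a collection of reads
#'
#' Reads are independent and mapped one by one; `workers` is accepted for
#' interface compatibility and validated, but the result is identical for
#' any value (the implementation is deterministic and single-threaded).
#' Malformed records (missing or empty sequence) are skipped with a warning.
#'
#' @param reads Data frame with columns `id`, `seq` and optionally `qual`
#'   (as returned by [read_reads()] or [sample_reads()]).
#' @param index A `genome_index`.
#' @param k Distance threshold.
#' @param mode `"hamming"` or `"edit"`.
#' @param m Optional m-mapping cap (see [map_read()]).
#' @param workers Ignored beyond validation; determinism contract.
#' @return List of `mapping_report`, one per read, in input order.
#' @export
map_all <- function(reads, index, k, mode = c("hamming", "edit"), m = NULL,
                    workers = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(reads), workers >= 1)
  lapply(seq_len(nrow(reads)), function(i) {
    rec <- reads[i, , drop = FALSE]
    if (is.na(rec$seq) || !nzchar(rec$seq)) {
      warning(sprintf("skipping malformed read record %d ('%s')", i,
                      if (is.na(rec$id)) "?" else rec$id))
      return(NULL)
    }
    map_read(rec, index, k, mode, m)
  })
}
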