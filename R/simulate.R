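# Synthetic data: random genomes, mutated reads with recorded ground truth,
# and a brute-force full-sensitivity oracle mapper.

.BASES <- c("A", "C", "G", "T")

# run code with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a random genome
#'
#' Bases are i.i.d. uniform over `ACGT`; deterministic for a given seed.
#'
#' @param length Total genome length in bases (>= 1), split evenly across
#'   sequences (the last sequence absorbs the remainder).
#' @param n_sequences Number of sequences.
#' @param seed Optional RNG seed; the caller's RNG state is preserved.
#' @return Named character vector of sequences.
#' @export
random_genome <- function(length, n_sequences = 1L, seed = NULL) {
  stopifnot(length >= 1, n_sequences >= 1, length >= n_sequences)
  .with_seed(seed, {
    per <- length %/% n_sequences
    lens <- rep(per, n_sequences)
    lens[n_sequences] <- length - per * (n_sequences - 1L)
    seqs <- vapply(lens, function(n) {
      paste(sample(.BASES, n, replace = TRUE), collapse = "")
    }, character(1))
    stats::setNames(seqs, paste0("chr", seq_len(n_sequences)))
  })
}

# apply ndel deletions, nins insertions, nsub substitutions to a base vector;
# substitutions always change the base and hit distinct positions
.mutate <- function(bases, nsub, nins, ndel) {
  if (ndel > 0) {
    bases <- bases[-sample.int(length(bases), ndel)]
  }
  if (nins > 0) {
    for (i in seq_len(nins)) {
      pos <- sample.int(length(bases) + 1L, 1L) - 1L
      bases <- append(bases, sample(.BASES, 1L), after = pos)
    }
  }
  if (nsub > 0) {
    pos <- sample.int(length(bases), nsub)
    for (p in pos) bases[p] <- sample(setdiff(.BASES, bases[p]), 1L)
  }
  bases
}

#' Sample reads from a genome with planted errors
#'
#' Read origins are uniform over all valid windows and both strands.  Error
#' counts are drawn uniformly within the per-type budgets; deletions remove
#' reference bases and insertions add read bases, so the consumed reference
#' span is `read_length + deletions - insertions`.  The exact truth (origin,
#' strand, error counts) is recorded per read.
#'
#' @param genome Named character vector of sequences.
#' @param n Number of reads.
#' @param read_length Read length in bases.
#' @param max_sub,max_ins,max_del Per-read error budgets (each count is drawn
#'   uniformly from 0 to its budget).
#' @param seed Optional RNG seed.
#' @return Data frame with columns `id`, `seq`, `qual`, `ref`, `start`
#'   (0-based within `ref`, forward-strand coordinates of the consumed
#'   window), `strand`, `sub`, `ins`, `del`.
#' @export
sample_reads <- function(genome, n, read_length, max_sub = 0L, max_ins = 0L,
                         max_del = 0L, seed = NULL) {
  lens <- nchar(genome)
  stopifnot(n >= 1, read_length >= 1, max_sub >= 0, max_ins >= 0,
            max_del >= 0)
  # worst case consumes read_length + max_del reference bases; a read cannot
  # consist entirely of inserted bases
  if (read_length + max_del > max(lens) || max_ins >= read_length) {
    stop("infeasible error budgets for this read length and genome")
  }
  .with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      nsub <- sample.int(max_sub + 1L, 1L) - 1L
      nins <- sample.int(max_ins + 1L, 1L) - 1L
      ndel <- sample.int(max_del + 1L, 1L) - 1L
      span <- read_length + ndel - nins
      ok <- which(lens >= span)
      ri <- ok[sample.int(length(ok), 1L)]
      start <- sample.int(lens[ri] - span + 1L, 1L) - 1L
      window <- substr(genome[[ri]], start + 1L, start + span)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") window <- revcomp(window)
      bases <- .mutate(strsplit(window, "", fixed = TRUE)[[1]],
                       nsub, nins, ndel)
      out[[i]] <- data.frame(
        id = sprintf("read_%05d", i),
        seq = paste(bases, collapse = ""),
        qual = strrep("I", read_length),
        ref = names(genome)[ri], start = start, strand = strand,
        sub = nsub, ins = nins, del = ndel, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Exhaustive full-sensitivity oracle mapper
#'
#' Scans every start position of every sequence on both strands.  Hamming
#' mode reports every window with at most `k` mismatches; edit mode reports
#' every start from which a semi-global alignment of the full read (start
#' anchored, end free) achieves distance at most `k`, computed by a plain
#' unbanded dynamic program.  This is the gold standard the production mapper
#' is measured against; it is complete by construction.
#'
#' @param read Base string.
#' @param genome Named character vector of sequences.
#' @param k Distance threshold.
#' @param mode `"hamming"` or `"edit"`.
#' @return Data frame `ref`, `start` (0-based), `end` (0-based inclusive end
#'   of the consumed reference span; smallest among co-minimal alignments),
#'   `strand`, `distance`.
#' @export
oracle_map <- function(read, genome, k, mode = c("hamming", "edit")) {
  mode <- match.arg(mode)
  read <- toupper(read)
  out <- list()
  for (ri in seq_along(genome)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") read else revcomp(read)
      hits <- cpp_oracle_scan(toupper(genome[[ri]]), s, as.integer(k),
                              mode == "edit")
      if (nrow(hits)) {
        out[[length(out) + 1L]] <- data.frame(
          ref = names(genome)[ri], start = hits$start, end = hits$end,
          strand = strand, distance = hits$distance,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(ref = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$ref, res$start, res$strand), , drop = FALSE]
  row.names(res) <- NULL
  res
}

#' Write a simulation truth table
#'
#' Tab-separated: read id, reference, 0-based start, strand, substitutions,
#' insertions, deletions.
#'
#' @param reads Data frame from [sample_reads()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(reads, path) {
  utils::write.table(reads[, c("id", "ref", "start", "strand", "sub", "ins",
                               "del")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
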