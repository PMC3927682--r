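# FASTA / FASTQ input and SAM output.

#' Read a reference genome from FASTA
#'
#' Multi-record, wrapped lines and CRLF tolerated; sequences are upper-cased.
#' Empty sequences are rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are the first header
#'   token), suitable for [build_index()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                error = function(e) {
                  stop("malformed FASTA in '", path, "': ",
                       conditionMessage(e), call. = FALSE)
                })
  if (!length(x)) stop("no sequences in '", path, "'")
  if (any(Biostrings::width(x) == 0)) {
    stop("empty sequence record in '", path, "'")
  }
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Read sequencing reads from FASTQ or FASTA
#'
#' The format is auto-detected from the first byte (`@` = FASTQ, `>` =
#' FASTA).  Qualities are preserved for FASTQ and `NA` for FASTA.
#'
#' @param path Path to the reads file.
#' @return Data frame with columns `id`, `seq`, `qual` (zero rows for an
#'   empty file).
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readChar(path, 1L, useBytes = TRUE)
  empty <- data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE)
  if (!length(first) || !nzchar(first)) return(empty)
  if (first == "@") {
    raw <- readLines(path, warn = FALSE)
    while (length(raw) && !nzchar(raw[length(raw)])) {
      raw <- raw[-length(raw)]
    }
    if (length(raw) %% 4L != 0L) {
      stop("truncated FASTQ quartet in '", path, "' at record ",
           length(raw) %/% 4L + 1L, call. = FALSE)
    }
    x <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq",
                                   with.qualities = TRUE),
      error = function(e) {
        stop("malformed FASTQ in '", path, "': ", conditionMessage(e),
             call. = FALSE)
      })
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  } else if (first == ">") {
    x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop("malformed FASTA in '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
    qual <- rep(NA_character_, length(x))
  } else {
    stop("unrecognised reads format in '", path,
         "' (expected FASTA or FASTQ)")
  }
  data.frame(id = sub("\\s.*$", "", names(x)),
             seq = toupper(as.character(x)),
             qual = qual, stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a genome to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = width)
  invisible(path)
}

#' Write reads to FASTQ
#'
#' @param reads Data frame with `id`, `seq`, `qual` (missing qualities are
#'   written as `I` runs).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  qual <- ifelse(is.na(reads$qual),
                 vapply(nchar(reads$seq),
                        function(n) strrep("I", n), character(1)),
                 reads$qual)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), con)
  }
  invisible(path)
}

# SAM flag bits
.FLAG_UNMAPPED <- 4L
.FLAG_REVERSE <- 16L
.FLAG_SECONDARY <- 256L

#' Write mapping reports as a SAM file
#'
#' Emits a valid header (`@HD`, one `@SQ` per reference sequence, `@PG`) and
#' one alignment line per mapping.  Internal 0-based starts become 1-based
#' `POS`.  Reverse-strand records carry the reverse-complemented read
#' sequence and reversed qualities; among a read's mappings the one with the
#' lowest coordinate is primary and the rest are flagged secondary.  Mapping
#' quality is the constant 255 (an all-mapper does not rank its hits) and the
#' distance is reported in the standard `NM` tag.  Unmapped reads are emitted
#' with the unmapped flag; reads suppressed by the m-mapping cap are omitted.
#'
#' @param reports List of `mapping_report` (as from [map_all()]); `NULL`
#'   entries are skipped.
#' @param index The `genome_index` the reads were mapped against.
#' @param path Output path.
#' @return Invisibly, the number of alignment lines written.
#' @export
write_sam <- function(reports, index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (i in seq_along(index$seq_names)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", index$seq_names[i],
                       as.integer(index$seq_lengths[i])), con)
  }
  writeLines(sprintf("@PG\tID:allmapr\tPN:allmapr\tVN:%s",
                     as.character(utils::packageVersion("allmapr"))), con)
  n_lines <- 0L
  for (rep_ in reports) {
    if (is.null(rep_) || rep_$suppressed_by_m) next
    qual_fwd <- if (is.na(rep_$qual)) "*" else rep_$qual
    if (rep_$unmapped) {
      writeLines(paste(rep_$id, .FLAG_UNMAPPED, "*", 0L, 0L, "*", "*", 0L,
                       0L, rep_$seq, qual_fwd, sep = "\t"), con)
      next
    }
    res <- rep_$results
    # primary = lowest coordinate (then forward strand first)
    ord <- order(match(res$ref, index$seq_names), res$pos,
                 res$strand != "+")
    res <- res[ord, , drop = FALSE]
    for (j in seq_len(nrow(res))) {
      fwd <- res$strand[j] == "+"
      flag <- 0L
      if (!fwd) flag <- flag + .FLAG_REVERSE
      if (j > 1L) flag <- flag + .FLAG_SECONDARY
      seq_out <- if (fwd) rep_$seq else revcomp(rep_$seq)
      qual_out <- if (is.na(rep_$qual)) "*"
                  else if (fwd) rep_$qual
                  else paste(rev(strsplit(rep_$qual, "", fixed = TRUE)[[1]]),
                             collapse = "")
      writeLines(paste(rep_$id, flag, res$ref[j], as.integer(res$pos[j]) + 1L,
                       255L, res$cigar[j], "*", 0L, 0L, seq_out, qual_out,
                       paste0("NM:i:", res$distance[j]), sep = "\t"), con)
      n_lines <- n_lines + 1L
    }
  }
  invisible(n_lines)
}
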