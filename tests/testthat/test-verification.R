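test_that("Hamming verification counts mismatches in place", {
  g <- c(chr1 = "ACGTACGTACGTACGT")
  idx <- build_index(g, q = 3)
  read <- "ACGTACGT"
  hit <- hamming_verify(read, idx, 0, 0)
  expect_equal(hit$distance, 0L)
  expect_equal(hit$cigar, "8M")
  # distance k+1 -> rejected (TTTTACGT vs ACGTACGT mismatches at 3 places)
  expect_null(hamming_verify("TTTTACGT", idx, 0, 2))
  expect_equal(hamming_verify("TTTTACGT", idx, 0, 3)$distance, 3L)
  # window past the sequence end -> no result, no error
  expect_null(hamming_verify(read, idx, 12, 8))
  set.seed(401)
  for (rep in 1:20) {
    gg <- c(chr1 = rand_seq(60))
    ii <- build_index(gg, q = 3)
    r <- rand_seq(20)
    p <- sample(0:40, 1)
    d_direct <- sum(strsplit(r, "")[[1]] !=
                    strsplit(substr(gg, p + 1, p + 20), "")[[1]])
    hit <- hamming_verify(r, ii, p, 20)
    expect_equal(hit$distance, d_direct)
  }
})

test_that("banded semi-global alignment reproduces the worked instances", {
  # read vs the genome window starting at location 2 of CCAGTAATGCTGTTG
  expect_equal(banded_semiglobal("AGTAATCTGTTG", "AGTAATGCTGTTG", 1)$distance,
               1L)
  # plain global distance to the length-14 subsequence at location 1
  expect_equal(global_edit_distance("GAAGATCTGCATAA", "AGAGATCTGCATAA"), 2L)
  # semi-global against the window at location 0 recovers distance 1
  expect_equal(banded_semiglobal("GAAGATCTGCATAA", "GAGAGATCTGCATAA",
                                 1)$distance, 1L)
  # identity at k = 0
  r <- "ACGTACGTT"
  res <- banded_semiglobal(r, r, 0)
  expect_equal(res$distance, 0L)
  expect_equal(res$cigar, "9M")
})

test_that("global edit distance agrees with an independent implementation", {
  set.seed(402)
  for (rep in 1:50) {
    a <- rand_seq(sample(5:30, 1))
    b <- rand_seq(sample(5:30, 1))
    expect_equal(global_edit_distance(a, b), as.integer(adist(a, b)))
  }
})

test_that("per-start distances agree with an adist oracle, banded or not", {
  set.seed(403)
  for (rep in 1:40) {
    m <- sample(8:18, 1)
    w <- sample(8:26, 1)
    k <- sample(0:3, 1)
    r <- rand_seq(m)
    win <- rand_seq(w)
    oracle <- vapply(0:w, function(s) r_anchored_dist(r, win, s), numeric(1))
    res <- banded_semiglobal(r, win, k, free_start = TRUE)
    got <- rep(NA_integer_, w + 1)
    if (!is.null(res)) got[res$hits$start + 1] <- res$hits$distance
    expect_equal(which(!is.na(got)) - 1, which(oracle <= k) - 1)
    expect_equal(got[!is.na(got)], as.integer(oracle[oracle <= k]))
  }
  # with k >= |read| the band is vacuous: every start is scored
  r <- rand_seq(6)
  win <- rand_seq(12)
  res <- banded_semiglobal(r, win, 6, free_start = TRUE)
  oracle <- vapply(0:12, function(s) r_anchored_dist(r, win, s), numeric(1))
  expect_equal(res$hits$distance, as.integer(pmin(oracle, 6))[oracle <= 6])
})

test_that("anchored mode charges and strips leading reference skips", {
  # exact copy one base into the window: found at start 1 with the one-base
  # skip charged against the threshold, then stripped from the result
  res <- banded_semiglobal("CGTACG", "ACGTACG", 1, free_start = FALSE)
  expect_true(any(res$hits$start == 1 & res$hits$distance == 0))
  # the same skip does not fit a zero threshold
  res0 <- banded_semiglobal("CGTACG", "ACGTACG", 0, free_start = FALSE)
  expect_true(is.null(res0) || !any(res0$hits$start == 1))
})

test_that("emitted CIGAR strings are consistent with read and span", {
  set.seed(404)
  cigar_sums <- function(cg) {
    ops <- gregexpr("[0-9]+[MID]", cg)[[1]]
    parts <- regmatches(cg, gregexpr("[0-9]+[MID]", cg))[[1]]
    n <- as.integer(sub("[MID]", "", parts))
    type <- sub("[0-9]+", "", parts)
    c(read = sum(n[type %in% c("M", "I")]),
      ref = sum(n[type %in% c("M", "D")]))
  }
  for (rep in 1:30) {
    m <- sample(10:20, 1)
    k <- sample(1:3, 1)
    win <- rand_seq(m + 2 * k)
    # derive the read from the window so alignments within k exist
    rv <- strsplit(substr(win, k + 1, k + m), "", fixed = TRUE)[[1]]
    if (k >= 2) rv <- rv[-sample(m, 1)]                     # one deletion
    pos <- sample(length(rv), 1)
    rv[pos] <- sample(setdiff(c("A", "C", "G", "T"), rv[pos]), 1)
    r <- paste(rv, collapse = "")
    m <- nchar(r)
    res <- banded_semiglobal(r, win, k, free_start = TRUE)
    expect_false(is.null(res))
    for (j in seq_len(nrow(res$hits))) {
      s <- cigar_sums(res$hits$cigar[j])
      expect_equal(unname(s["read"]), m)
      expect_equal(unname(s["ref"]),
                   res$hits$end[j] - res$hits$start[j] + 1)
      expect_lte(res$hits$distance[j], k)
    }
  }
})

test_that("the two-window heuristic recovers indel-shifted mappings", {
  # deletion in the genome before the matched grams: candidate 1, true start 0
  idxb <- build_index(c(chr1 = "GAGAGATCTGCATAA"), q = 3)
  hits <- verify_candidate("GAAGATCTGCATAA", idxb, 1, 1)
  expect_true(any(hits$start == 0 & hits$distance == 1))
  # insertion in the read before the matched grams: candidate 0, true start 1
  idxc <- build_index(c(chr1 = "AGAAGATCTGCATAA"), q = 3)
  hits2 <- verify_candidate("GAGAGATCTGCATAA", idxc, 0, 1)
  expect_true(any(hits2$start == 1 & hits2$distance == 1))
  # exact candidate at k = 0
  g <- c(chr1 = "TTTTACGTACGTTTTT")
  idx <- build_index(g, q = 3)
  hits3 <- verify_candidate("ACGTACGT", idx, 4, 0)
  expect_equal(hits3$start, 4)
  expect_equal(hits3$distance, 0L)
})
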