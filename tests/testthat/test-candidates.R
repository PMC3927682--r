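test_that("the count-filtering threshold follows |r|-q+1-kq", {
  expect_equal(count_threshold(17, 5, 2), 3L)
  expect_equal(count_threshold(100, 11, 0), 90L)
  expect_equal(count_threshold(12, 5, 2), -2L)
})

test_that("counting over the published normalized lists keeps 105 only", {
  # inverted lists I(ACGGT) = {105, 118}, I(CGGTC) = {106}; the read's gram
  # occurrences sit at offsets 0, 1 and 13, so the normalized lists are
  # {105, 118}, {105} and {92, 105}; with T = 3 only location 105 survives
  nl <- list(normalize_list(c(105, 118), 0),
             normalize_list(c(106), 1),
             normalize_list(c(105, 118), 13))
  expect_equal(nl[[2]], 105)
  expect_equal(nl[[3]], c(92, 105))
  surv <- count_locations(nl, count_threshold(17, 5, 2))
  expect_equal(surv$location, 105)
  expect_equal(surv$votes, 3L)
  # 92 and 118 are pruned
  all_counts <- count_locations(nl, 1L)
  expect_equal(all_counts$votes[all_counts$location %in% c(92, 118)],
               c(1L, 1L))
})

test_that("naive count filtering is lossless and self-consistent", {
  set.seed(301)
  g <- random_genome(1200, 1, seed = 77)
  idx <- build_index(g, q = 4)
  # exact read recovers exactly its own copies at k = 0
  p <- 200
  read <- substr(g[[1]], p + 1, p + 30)
  surv <- naive_count_filter(read, idx, 0)
  expect_equal(surv$location, r_hamming_scan(read, g[[1]], 0))
  # with planted substitutions every true match survives
  for (rep in 1:5) {
    k <- 2
    rv <- strsplit(read, "", fixed = TRUE)[[1]]
    for (e in sample(30, k)) rv[e] <- sample(setdiff(c("A","C","G","T"), rv[e]), 1)
    mut <- paste(rv, collapse = "")
    surv <- naive_count_filter(mut, idx, k)
    expect_true(all(r_hamming_scan(mut, g[[1]], k) %in% surv$location))
  }
  # 11 bp read, q = 4, k = 2: threshold 11-4+1-8 = 0 is vacuous
  expect_error(naive_count_filter(substr(read, 1, 11), idx, 2), "vacuous")
})

test_that("the k+1 union is the union of the selected normalized lists", {
  idx <- index_from_lists(list(AAACC = c(10, 50), CCGGT = c(30, 70),
                               GGTTT = c(90)))
  read <- paste0("AAACC", "CCGGT", "GGTTT")
  sel <- make_selection(read, c(0L, 5L, 10L), idx)
  out <- prefix_union_candidates(sel, idx)
  expect_equal(out$location, sort(c(10, 50, 25, 65, 80)))
  expect_equal(sum(out$votes), 5L)  # disjoint lists: sizes add up
  # k = 0: single selected gram
  sel0 <- make_selection(read, 0L, idx)
  expect_equal(prefix_union_candidates(sel0, idx)$location, c(10, 50))
})

test_that("two intact grams admit a candidate; indel shifts admit pairs", {
  # genome CCAGTAATGCTGTTG, read AGTAATCTGTTG, edit threshold 1: the G
  # inserted in the genome between the matched grams splits the votes, so
  # locations 2 and 3 each get one vote and are rescued as a singleton pair
  idx <- build_index(c(chr1 = "CCAGTAATGCTGTTG"), q = 3)
  read <- "AGTAATCTGTTG"
  sel <- select_prefix_grams(read, idx, 3)  # k+2 grams for k = 1
  edit <- additional_prefix_candidates(sel, idx, 1, "edit")
  expect_setequal(edit$location, c(2, 3))
  expect_true(all(edit$singleton_pair))
  expect_true(all(edit$votes == 1L))
  ham <- additional_prefix_candidates(sel, idx, 1, "hamming")
  expect_equal(nrow(ham), 0L)
})

test_that("a unanimous location carries k+2 votes and no singleton flag", {
  k <- 2
  read <- paste0("AAAAA", "CCCCC", "GGGGG", "TTTTT")
  # plant location 500 in every list, shifted by each gram's read offset so
  # all four normalized lists vote for 500
  lists2 <- list(AAAAA = 500, CCCCC = 505, GGGGG = 510, TTTTT = 515)
  idx2 <- index_from_lists(lists2)
  sel2 <- make_selection(read, c(0L, 5L, 10L, 15L), idx2)
  out <- additional_prefix_candidates(sel2, idx2, k, "edit")
  expect_equal(out$location, 500)
  expect_equal(out$votes, 4L)
  expect_false(out$singleton_pair)
})

test_that("merge output equals the union of pairwise intersections", {
  set.seed(302)
  for (rep in 1:20) {
    k <- sample(1:3, 1)
    nlists <- k + 2
    lists <- lapply(seq_len(nlists), function(i) {
      sort(sample(0:120, sample(5:25, 1)))
    })
    # direct evaluation of the set-algebra formula
    pairs <- combn(nlists, 2)
    formula_set <- sort(unique(unlist(lapply(seq_len(ncol(pairs)), function(c_) {
      intersect(lists[[pairs[1, c_]]], lists[[pairs[2, c_]]])
    }))))
    merged <- count_locations(lists, 2L)
    expect_equal(merged$location, formula_set)
    # refinement: every two-vote candidate lies in the union of any k+1 lists
    for (drop in seq_len(nlists)) {
      union_rest <- unique(unlist(lists[-drop]))
      expect_true(all(merged$location %in% union_rest))
    }
  }
})

test_that("the k+2 filter keeps every Hamming-k match (small scale)", {
  set.seed(303)
  for (rep in 1:15) {
    g <- random_genome(sample(1000:3000, 1), 1, seed = 400 + rep)
    idx <- build_index(g, q = 5)
    k <- sample(1:3, 1)
    rlen <- sample(40:50, 1)
    p <- sample(0:(nchar(g[[1]]) - rlen), 1)
    rv <- strsplit(substr(g[[1]], p + 1, p + rlen), "", fixed = TRUE)[[1]]
    for (e in sample(rlen, k)) rv[e] <- sample(setdiff(c("A","C","G","T"), rv[e]), 1)
    read <- paste(rv, collapse = "")
    sel <- select_prefix_grams(read, idx, k + 2L)
    cand <- additional_prefix_candidates(sel, idx, k, "hamming")
    matches <- r_hamming_scan(read, g[[1]], k)
    expect_true(all(matches %in% cand$location))
    # and the naive count filter's survivors at distance <= k are kept too
    T_ <- count_threshold(rlen, 5, k)
    if (T_ > 0) {
      naive <- naive_count_filter(read, idx, k)
      naive_true <- intersect(naive$location, matches)
      expect_true(all(naive_true %in% cand$location))
    }
  }
})

test_that("the lemma's leave-one-out subset count is k+2", {
  expect_equal(subset_count(1), 3L)
  expect_equal(subset_count(0), 2L)
  expect_equal(subset_count(5), 7L)
})
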