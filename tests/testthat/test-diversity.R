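sp2 <- function(...) {
  seqs <- c(...)
  species_alignment(seqs, setNames(rep("sp1", length(seqs)), names(seqs)))
}

test_that("pairwise_diff counts mismatches and honours deletion rules", {
  aln <- sp2(a = "AAA", b = "AAA")
  expect_equal(pairwise_diff(aln, "a", "b"), list(k = 0, m = 3))
  aln <- sp2(a = "AAA", b = "AAT")
  expect_equal(pairwise_diff(aln, "a", "b"), list(k = 1, m = 3))
  aln <- sp2(a = "AA-", b = "AAT")
  expect_equal(pairwise_diff(aln, "a", "b", "pairwise"), list(k = 0, m = 2))
  aln <- sp2(a = "---", b = "AAT", c = "AAT")
  expect_error(pairwise_diff(aln, "a", "b", "pairwise"), "undefined")
})

test_that("nucleotide diversity matches hand-computed and degenerate cases", {
  expect_equal(nucleotide_diversity(sp2(a = "ACGT", b = "ACGT", c = "ACGT")), 0)
  expect_equal(nucleotide_diversity(sp2(a = "AAAAAAAAAA", b = "AAAAAAAAAT")), 0.1)
  # diffs 1,2,1 over 3 pairs, L=3
  expect_equal(nucleotide_diversity(sp2(a = "AAA", b = "AAT", c = "ATT")), 4 / 9)
  expect_error(nucleotide_diversity(sp2(a = "AAA")), "2 samples")
  expect_error(nucleotide_diversity(sp2(a = "NNN", b = "AAA")), "undefined")
})

test_that("pi equals the brute-force enumeration on random alignments", {
  set.seed(42)
  for (r in 1:60) {
    x <- random_alignment(n = sample(2:6, 1), L = sample(15:40, 1),
                          missing_rate = 0.08)
    aln <- as_aln(x)
    for (del in c("complete", "pairwise")) {
      mine <- tryCatch(nucleotide_diversity(aln, del), error = function(e) NA)
      theirs <- tryCatch(oracle_pi(x$mat, del), error = function(e) NA)
      if (!is.na(mine) && !is.na(theirs))
        expect_equal(mine, theirs, tolerance = 1e-12)
    }
  }
})

test_that("pi is invariant to sample order and bounded; 2-sample pi is Hamming", {
  set.seed(7)
  for (r in 1:20) {
    x <- random_alignment(n = 5, L = 25, missing_rate = 0.05)
    aln <- as_aln(x)
    perm <- sample(rownames(x$mat))
    aln2 <- species_alignment(x$mat[perm, ], x$species)
    p1 <- nucleotide_diversity(aln); p2 <- nucleotide_diversity(aln2)
    expect_equal(p1, p2)
    expect_gte(p1, 0); expect_lte(p1, 1)
  }
  x <- random_alignment(n = 2, L = 30, missing_rate = 0)
  aln <- as_aln(x)
  expect_equal(nucleotide_diversity(aln),
               mean(x$mat[1, ] != x$mat[2, ]))
})

test_that("sliding windows tile the alignment and agree with global pi", {
  set.seed(3)
  x <- random_alignment(n = 4, L = 1000, missing_rate = 0.02)
  aln <- as_aln(x)
  tr <- sliding_window_pi(aln, window = 600, step = 200)
  expect_equal(tr$start, c(0, 200, 400))
  expect_equal(tr$end, c(600, 800, 1000))
  # constant alignment: all-zero track
  cst <- species_alignment(matrix("A", 3, 700,
                                  dimnames = list(c("a", "b", "c"), NULL)),
                           c(a = "x", b = "x", c = "x"))
  expect_true(all(sliding_window_pi(cst)$pi == 0))
  # single window spanning L equals global pi
  one <- sliding_window_pi(aln, window = 1000, step = 1000)
  expect_equal(nrow(one), 1)
  expect_equal(one$pi, nucleotide_diversity(aln))
  expect_error(sliding_window_pi(aln, window = 2000), "exceeds")
})

test_that("top_variable_regions sorts, merges overlaps, matches a sort oracle", {
  tr <- sliding_window_pi(as_aln(random_alignment(n = 3, L = 1000)), 600, 200)
  tr$pi <- c(0.1, 0.0, 0.0)
  expect_equal(top_variable_regions(tr, 1)$start, 0)
  # adjacent overlapping top windows merged once
  tr$pi <- c(0.2, 0.19, 0.01)
  m <- top_variable_regions(tr, 2)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end, m$pi), c(0, 800, 0.2))
  # non-overlapping case equals brute-force sort
  set.seed(9)
  x <- random_alignment(n = 4, L = 3000, missing_rate = 0)
  track <- sliding_window_pi(as_aln(x), window = 300, step = 300)
  got <- top_variable_regions(track, 3)
  ord <- track[order(-track$pi, track$start), ][1:3, ]
  expect_equal(got$pi, ord$pi)
  expect_setequal(got$start, ord$start)
})

test_that("segregating sites counts polymorphic columns, excluding missing states", {
  expect_equal(segregating_sites(sp2(a = "ACGT", b = "ACGT")), 0)
  expect_equal(segregating_sites(sp2(a = "AAA", b = "AAT", c = "ATT")), 2)
  # column {A, N, A} is not segregating, and is dropped entirely under
  # complete deletion
  aln <- sp2(a = "AAC", b = "NAC", c = "AAG")
  expect_equal(segregating_sites(aln, "pairwise"), 1)
  expect_equal(segregating_sites(aln, "complete"), 1)
  set.seed(11)
  for (r in 1:30) {
    x <- random_alignment(n = 4, L = 30, missing_rate = 0.1)
    expect_equal(segregating_sites(as_aln(x), "complete"),
                 oracle_seg_sites(x$mat))
  }
})
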