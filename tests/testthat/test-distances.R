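one_sp <- function(seqs) {
  species_alignment(seqs, setNames(rep("s", length(seqs)), names(seqs)))
}

test_that("p-distance handles identity, simple mismatch and degenerate overlap", {
  aln <- one_sp(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(p_distance(aln, "a", "b"), 0)
  aln <- one_sp(c(a = paste(rep("A", 100), collapse = ""),
                  b = paste(c(rep("A", 99), "T"), collapse = "")))
  expect_equal(p_distance(aln, "a", "b"), 0.01)
  aln <- one_sp(c(a = "--AA", b = "TT--", c = "AAAA"))
  expect_warning(d <- p_distance(aln, "a", "b"), "undefined")
  expect_true(is.na(d))
})

test_that("k2p distance matches direct evaluation of the Kimura formula", {
  aln <- one_sp(c(a = "ACGT", b = "ACGT"))
  expect_equal(k2p_distance(aln, "a", "b"), 0)
  # 1 transition (A->G) in 100 sites: P=0.01, Q=0
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 99), "G"), collapse = "")
  aln <- one_sp(c(a = s1, b = s2))
  expect_equal(k2p_distance(aln, "a", "b"), -0.5 * log(0.98 * sqrt(1)),
               tolerance = 1e-12)
  # saturation boundary: P=0.5, Q=0 -> 1-2P-Q = 0
  s3 <- paste(rep(c("A", "G"), 50), collapse = "")
  s4 <- paste(rep(c("G", "A"), 50), collapse = "")
  aln <- one_sp(c(a = s3, b = s4))
  expect_warning(d <- k2p_distance(aln, "a", "b"), "saturated")
  expect_true(is.na(d))
})

test_that("k2p and p distances match brute-force oracles on random pairs", {
  set.seed(21)
  for (r in 1:60) {
    x <- random_alignment(n = 2, L = sample(20:60, 1), missing_rate = 0.1)
    aln <- as_aln(x)
    mine <- suppressWarnings(k2p_distance(aln, 1, 2))
    theirs <- oracle_k2p(x$mat, 1, 2)
    expect_equal(mine, theirs, tolerance = 1e-12)
    ok <- x$mat[1, ] %in% VALID & x$mat[2, ] %in% VALID
    if (any(ok))
      expect_equal(p_distance(aln, 1, 2),
                   mean(x$mat[1, ok] != x$mat[2, ok]), tolerance = 1e-12)
  }
})

test_that("distance_matrix is symmetric, zero-diagonal, permutation-consistent", {
  set.seed(22)
  x <- random_alignment(n = 5, L = 60, missing_rate = 0.05)
  aln <- as_aln(x)
  dm <- suppressWarnings(distance_matrix(aln, "k2p"))
  expect_equal(dm$d, t(dm$d))
  expect_true(all(diag(dm$d) == 0))
  perm <- sample(rownames(x$mat))
  dm2 <- suppressWarnings(distance_matrix(species_alignment(x$mat[perm, ], x$species), "k2p"))
  expect_equal(dm2$d[rownames(dm$d), colnames(dm$d)], dm$d)
})

test_that("K2P >= p-distance entrywise, agreeing with an independent engine", {
  set.seed(23)
  x <- random_alignment(n = 6, L = 200, missing_rate = 0)
  aln <- as_aln(x)
  dk <- suppressWarnings(distance_matrix(aln, "k2p")$d)
  dp <- distance_matrix(aln, "p")$d
  expect_true(all(dk >= dp - 1e-12, na.rm = TRUE))
  # cross-check both models against ape's implementations; where the K2P
  # formula is undefined we report NA while ape reports NaN/Inf
  bin <- ape::as.DNAbin(tolower(x$mat))
  ak <- unname(as.matrix(ape::dist.dna(bin, "K80")))
  expect_identical(unname(is.na(dk) | !is.finite(dk)),
                   is.na(ak) | !is.finite(ak))
  fin <- is.finite(ak)
  expect_equal(unname(dk)[fin], ak[fin], tolerance = 1e-10)
  expect_equal(unname(dp), unname(as.matrix(ape::dist.dna(bin, "raw"))),
               tolerance = 1e-10)
})

test_that("barcode gap test applies the strict min-inter > max-intra rule", {
  # clear gap: tiny intra, large inter -> all pass
  aln <- species_alignment(
    c(x1 = "AAAAAAAAAA", x2 = "AAAAAAAAAC", y1 = "GGGGGGGGGG", y2 = "GGGGGGGGGT"),
    c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y"))
  g <- barcode_gap_test(distance_matrix(aln, "p"))
  expect_true(all(g$pass))
  # an intra pair exceeding min inter fails that species
  aln2 <- species_alignment(
    c(x1 = "AAAAAAAAAA", x2 = "AAAAATTTTT", y1 = "AAAAAAAAAC"),
    c(x1 = "X", x2 = "X", y1 = "Y"))
  g2 <- barcode_gap_test(distance_matrix(aln2, "p"))
  expect_false(g2$pass[g2$species == "X"])
  expect_true(g2$single_sample[g2$species == "Y"])
  expect_equal(g2$max_intra[g2$species == "Y"], 0)
})

test_that("barcode gap min/max match exhaustive enumeration on random inputs", {
  set.seed(24)
  for (r in 1:40) {
    x <- random_alignment(n = sample(4:7, 1), L = 40, n_species = sample(2:3, 1),
                          missing_rate = 0)
    aln <- as_aln(x)
    dm <- distance_matrix(aln, "p")
    got <- barcode_gap_test(dm)
    want <- oracle_gap(dm$d, x$species)
    for (i in seq_len(nrow(got))) {
      s <- got$species[i]
      expect_equal(got$max_intra[i], unname(want[[s]]["max_intra"]))
      expect_equal(got$min_inter[i], unname(want[[s]]["min_inter"]))
      expect_equal(got$pass[i],
                   want[[s]]["min_inter"] > want[[s]]["max_intra"],
                   ignore_attr = TRUE)
    }
  }
})
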