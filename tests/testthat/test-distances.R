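test_that("k-mer distance matches hand-enumerated word multisets", {
  expect_equal(kmer_distance("ACGTA", "ACGTT", k = 2), 0.25)
  expect_equal(kmer_distance("AAAAAA", "CCCCCC", k = 2), 1.0)
  set.seed(5)
  s <- random_seq(40)
  expect_equal(kmer_distance(s, s, k = 6), 0)
  expect_error(kmer_distance("ACG", "ACGTACGT", k = 6), "k")
})

test_that("k-mer distance is symmetric and bounded on random pairs", {
  set.seed(11)
  for (i in 1:25) {
    s1 <- random_seq(sample(10:60, 1))
    s2 <- mutate_at(s1, sample(nchar(s1), sample(0:4, 1)))
    d12 <- kmer_distance(s1, s2, k = 4)
    expect_equal(d12, kmer_distance(s2, s1, k = 4))
    expect_gte(d12, 0)
    expect_lte(d12, 1)
  }
})

test_that("alignment scores match the brute-force enumerator on every short pair", {
  # small but dense sample; the exhaustive sweep runs in the acceptance suite
  set.seed(21)
  mk <- function(n) vapply(seq_len(n),
    function(i) random_seq(sample(1:6, 1), c("A", "C")), "")
  s1 <- mk(150); s2 <- mk(150)
  for (x in c(TRUE, FALSE)) for (r454 in c(TRUE, FALSE)) {
    gap <- tscotu:::max_score_gap_cpp(s1, s2, 1, -1, -10, -1, x, r454)
    expect_equal(gap, 0)
  }
})

test_that("alignment reproduces the worked examples", {
  a <- nw_align("ACGT", "ACGT")
  expect_equal(a$score, 4)
  expect_equal(a$a1, "ACGT")

  a <- nw_align("ACGTACGT", "ACGACGT")
  expect_equal(a$score, -3)   # seven matches and one opened gap
  expect_equal(nchar(a$a1), 8)
  expect_equal(sort(c(a$a1, a$a2)), sort(c("ACGTACGT", "ACG-ACGT")))

  # the returned alignment attains the claimed score under the run scorer
  set.seed(31)
  for (i in 1:20) {
    s1 <- random_seq(sample(5:40, 1))
    s2 <- mutate_at(s1, sample(nchar(s1), sample(0:3, 1)))
    for (pf in c("illumina", "454")) {
      p <- alignment_params(platform = pf)
      a <- nw_align(s1, s2, p)
      sc <- tscotu:::score_alignment_cpp(a$a1, a$a2, 1, -1, -10, -1,
                                         p$free_end_gaps, pf == "454")
      expect_equal(a$score, sc)
    }
  }
})

test_that("alignment scores agree with Biostrings pairwiseAlignment", {
  # independent implementation of the same affine model: gapOpening 9 +
  # gapExtension 1 per column makes an L-run cost 10 + (L - 1)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  set.seed(41)
  for (i in 1:25) {
    s1 <- random_seq(sample(15:40, 1))
    s2 <- random_seq(sample(15:40, 1))
    if (i %% 2 == 0) s2 <- mutate_at(s1, sample(nchar(s1), 2))
    ref <- Biostrings::pairwiseAlignment(s1, s2, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 9, gapExtension = 1,
                                         scoreOnly = TRUE)
    expect_equal(nw_align(s1, s2)$score, ref)
  }
})

test_that("NW distance follows the platform gap-counting conventions", {
  expect_equal(nw_distance("ACGTACGTAC", "ACGTTCGTAC"), 0.1)
  expect_equal(nw_distance("ACGT----AC", "ACGTTTTTAC"), 0.4)
  expect_equal(nw_distance("ACGT----AC", "ACGTTTTTAC",
                           params = alignment_params(platform = "454")),
               0.1)
  expect_equal(nw_distance("--ACGT", "TTACGT"), 0)
  # without end-gap exclusion the terminal columns count
  p_nox <- alignment_params(free_end_gaps = FALSE)
  expect_equal(nw_distance("--ACGT", "TTACGT", params = p_nox), 2 / 6)
  expect_error(nw_distance("AC-T", "AC"), "equal length")
  expect_error(nw_distance("A-GT", "A-TT"), "gaps in both")
})

test_that("454 distance never exceeds the Illumina distance of one alignment", {
  set.seed(51)
  p454 <- alignment_params(platform = "454")
  for (i in 1:30) {
    s1 <- random_seq(sample(20:60, 1))
    s2 <- random_seq(sample(20:60, 1))
    a <- nw_align(s1, s2)
    expect_lte(nw_distance(a$a1, a$a2, params = p454),
               nw_distance(a$a1, a$a2))
  }
})

test_that("gap-free equal-length pairs reduce to normalized Hamming distance", {
  set.seed(61)
  for (i in 1:20) {
    s1 <- random_seq(60)
    nm <- sample(0:3, 1)
    s2 <- mutate_at(s1, sample(60, nm))
    d <- nw_pair_distance(s1, s2)
    expect_equal(d, nm / 60)
    expect_equal(d, nw_pair_distance(s2, s1))
    expect_equal(d, direct_distance(s1, s2))
  }
})

test_that("sparse all-pairs stores prescreened distances and counts alignments", {
  set.seed(71)
  s <- random_seq(100)
  tags <- dereplicate(c(rep(s, 3), rep(mutate_at(s, 7), 2)))
  ds <- sparse_distances(tags)
  expect_equal(nrow(ds$entries), 1)
  expect_equal(ds$entries$d, 0.01)
  expect_equal(ds$n_alignments, 1)

  # disjoint 6-mer sets: the prescreen rejects, no alignment is run
  tags2 <- dereplicate(c(strrep("AC", 30), strrep("GT", 30)))
  ds2 <- sparse_distances(tags2)
  expect_equal(nrow(ds2$entries), 0)
  expect_equal(ds2$n_alignments, 0)
  expect_equal(ds2$n_pairs, 1)
})

test_that("the sparse set round-trips through the 3-column text dialect", {
  set.seed(81)
  s <- random_seq(80)
  seqs <- c(s, mutate_at(s, 1:2), mutate_at(s, 5), random_seq(80))
  ds <- sparse_distances(dereplicate(seqs))
  f <- withr::local_tempfile()
  write_sparse(ds, f)
  back <- read_sparse(f, n_tags = ds$n_tags, cap = ds$cap)
  expect_equal(back$entries$i, ds$entries$i)
  expect_equal(back$entries$j, ds$entries$j)
  expect_equal(back$entries$d, ds$entries$d, tolerance = 1e-6)
  # 0-based on disk
  first <- scan(f, what = numeric(), n = 2, quiet = TRUE)
  expect_equal(first, c(ds$entries$i[1] - 1, ds$entries$j[1] - 1))
})
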