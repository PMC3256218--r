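# run the second stage on a hand-built tag table: `haotu` gives the stage-1
# assignment of the abundant prefix, everything else is rare
stage2_fixture <- function(seqs, abundance, haotu, d = 0.03, batch = 10,
                           shortcut = FALSE) {
  tags <- data.frame(seq = seqs, abundance = abundance,
                     rank = seq_along(seqs) - 1L,
                     exemplar_id = paste0("t", seq_along(seqs)),
                     stringsAsFactors = FALSE)
  nA <- length(haotu)
  run_stage2(tags, nA, haotu, rep("direct", nA), abundance,
             sp = search_params(d = d, batch = batch, shortcut = shortcut),
             trace = TRUE)
}

test_that("the direct comparison walks 5' to 3' and handles unequal lengths", {
  expect_equal(direct_distance("ACGTACGTAC", "ACGTACGTAC"), 0)
  s <- strrep("A", 100)
  expect_equal(direct_distance(mutate_at(s, c(10, 60)), s), 0.02)
  # length difference counts as mismatches over the longer length
  expect_equal(direct_distance("ACGTACGTAC", "ACGTACGT"), 0.2)
  # one internal indel frame-shifts the tail: far above any threshold
  set.seed(201)
  t <- random_seq(100)
  indel <- paste0(substr(t, 1, 49), substr(t, 51, 100))
  expect_gt(direct_distance(indel, t), 0.3)
})

test_that("the shortcut places by strict inequality against representatives", {
  set.seed(202)
  h1 <- random_seq(100); h2 <- random_seq(100)
  res <- stage2_fixture(c(h1, h2, mutate_at(h1, 1:2)),
                        c(50, 40, 1), haotu = c(1L, 2L), shortcut = TRUE)
  expect_equal(res$n_shortcut, 1L)
  expect_equal(res$index$tag_otu[3], 1L)
  expect_equal(res$index$via[3], "precluster2")
  expect_equal(res$n_align, 0)

  # a tag at exactly d misses the shortcut (strict <) but the greedy NW
  # search still places it (non-strict <=)
  res <- stage2_fixture(c(h1, mutate_at(h1, 1:3)), c(50, 1), haotu = 1L,
                        shortcut = TRUE)
  expect_equal(res$n_shortcut, 0L)
  expect_equal(res$index$tag_otu[2], 1L)
  expect_gt(res$n_align, 0)
})

test_that("a shortcut placement always satisfies the NW threshold", {
  set.seed(203)
  cfg <- mock_config(n_templates = 5, template_length = 80, n_reads = 800,
                     seed = 203)
  gen <- generate_reads(generate_templates(cfg), cfg)
  fit <- tsc(gen$reads, cutoff = 3)
  placed <- which(fit$tags$via == "precluster2")
  expect_gt(length(placed), 0)
  for (t in utils::head(placed, 25)) {
    rep_seq <- fit$otus$representative[fit$tags$otu[t]]
    expect_lte(nw_pair_distance(fit$tags$seq[t], rep_seq), fit$d)
  }
})

test_that("an unmatched rare tag founds a new LAOTU (case 1)", {
  set.seed(204)
  res <- stage2_fixture(c(random_seq(100), random_seq(100)), c(50, 1),
                        haotu = 1L)
  expect_equal(res$trace$case, 1L)
  expect_equal(sum(res$index$otu_kind == "L"), 1L)
  expect_equal(sum(res$index$otu_kind == "H"), 1L)
})

test_that("hits confined to one OTU join it (case 2)", {
  set.seed(205)
  h <- random_seq(100)
  res <- stage2_fixture(c(h, mutate_at(h, 1:2)), c(50, 1), haotu = 1L)
  expect_equal(res$trace$case, 2L)
  expect_equal(res$index$tag_otu[2], 1L)
})

test_that("hits in several HAOTUs join the heaviest without merging (case 3)", {
  set.seed(206)
  t1 <- random_seq(100)
  t2 <- mutate_at(t1, 1:5)              # d(t1, t2) = 0.05
  q <- mutate_at(t1, 1:3)               # d(q, t1) = 0.03, d(q, t2) = 0.02
  expect_equal(nw_pair_distance(q, t1), 0.03)
  expect_equal(nw_pair_distance(q, t2), 0.02)
  res <- stage2_fixture(c(t1, t2, q), c(50, 80, 1), haotu = c(1L, 2L))
  expect_equal(res$trace$case, 3L)
  expect_equal(res$index$tag_otu[3], 2L)          # heavier hit tag wins
  expect_equal(sum(res$index$otu_alive), 2L)      # HAOTUs never merge
})

test_that("hits in several LAOTUs merge them (case 4)", {
  set.seed(207)
  far <- random_seq(100)
  l1 <- random_seq(100)
  l2 <- mutate_at(l1, 1:6)              # 0.06 apart: two separate LAOTUs
  q <- mutate_at(l1, 1:3)               # within 0.03 of both
  res <- stage2_fixture(c(far, l1, l2, q), c(50, 2, 2, 1), haotu = 1L)
  expect_equal(res$trace$case, c(1L, 1L, 4L))
  expect_equal(sum(res$index$otu_alive), 2L)      # HAOTU + merged LAOTU
  merged <- res$index$tag_otu[c(2, 3, 4)]
  expect_equal(length(unique(merged)), 1L)
  expect_equal(res$index$otu_kind[merged[1]], "L")
})

test_that("mixed hits fold LAOTUs into the heaviest HAOTU (case 5)", {
  set.seed(208)
  h <- random_seq(100)
  l <- mutate_at(h, 1:6)                # 0.06 from the HAOTU: a LAOTU
  q <- mutate_at(h, 1:3)                # 0.03 from both
  res <- stage2_fixture(c(h, l, q), c(50, 2, 1), haotu = 1L)
  expect_equal(res$trace$case, c(1L, 5L))
  expect_equal(sum(res$index$otu_alive), 1L)      # count dropped by one
  expect_equal(unique(res$index$tag_otu), 1L)
  expect_equal(res$index$otu_kind[1], "H")
})

test_that("an empty rare set leaves the stage-1 OTUs untouched", {
  gen <- small_mock()
  fit1 <- tsc(gen$reads, cutoff = 1)
  expect_equal(fit1$counters$n_rare, 0L)
  expect_equal(fit1$counters$nw_stage2, 0)
  expect_equal(fit1$counters$n_laotu, 0L)
})

test_that("stage 2 preserves the partition and never merges HAOTUs", {
  gen <- small_mock()
  fit <- tsc(gen$reads, cutoff = 4)
  expect_true(tsc_validate(fit))
  expect_equal(sum(fit$otus$n_reads), nrow(gen$reads))
  # HAOTU count after stage 2 equals the stage-1 count: every HAOTU id
  # present among abundant tags survives to the end
  expect_equal(fit$counters$n_haotu,
               length(unique(fit$tags$otu[fit$tags$via %in%
                                          c("direct", "precluster1")])))
})

test_that("the batched search agrees with an exhaustive search on clean data", {
  gen <- small_mock()
  f_batched <- tsc(gen$reads, cutoff = 3, batch = 10, shortcut = FALSE)
  f_exhaust <- tsc(gen$reads, cutoff = 3, batch = 10000, shortcut = FALSE)
  expect_equal(f_batched$otus$n_reads, f_exhaust$otus$n_reads)
  expect_equal(f_batched$tags$otu, f_exhaust$tags$otu)
  expect_lt(f_batched$counters$nw_stage2, f_exhaust$counters$nw_stage2)
})
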