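test_that("preclustering absorbs near-identical lower-frequency tags", {
  set.seed(101)
  s <- random_seq(200)
  v <- mutate_at(s, 1:2)                  # d = 0.01
  tags <- dereplicate(rep(c(s, v), c(100, 5)))
  pre <- precluster_denoise(tags)
  expect_equal(nrow(pre$seeds), 1)
  expect_equal(pre$seeds$abundance, 105)  # add-abundance mode
  expect_equal(pre$n_merged, 1)

  lit <- precluster_denoise(tags, accumulate = "literal")
  expect_equal(lit$seeds$abundance, 101)  # printed behavior: +1 per merge
  expect_equal(which(is.na(lit$merged_into)), which(is.na(pre$merged_into)))
})

test_that("mutually distant tags all survive preclustering", {
  set.seed(102)
  seqs <- replicate(5, random_seq(100))
  tags <- dereplicate(rep(seqs, 5:1))
  pre <- precluster_denoise(tags)
  expect_equal(nrow(pre$seeds), 5)
  expect_equal(pre$n_merged, 0)
  expect_true(all(is.na(pre$merged_into)))
})

test_that("a sequential pass never revisits absorbed tags (chain case)", {
  set.seed(103)
  x <- random_seq(200)
  y <- mutate_at(x, 1:3)        # d(x, y) = 0.015
  z <- mutate_at(y, 11:13)      # d(y, z) = 0.015, d(x, z) = 0.03
  expect_equal(nw_pair_distance(x, z), 0.03)
  tags <- dereplicate(rep(c(x, y, z), c(10, 5, 2)))
  pre <- precluster_denoise(tags)
  # y absorbed by x; z survives: d(x, z) > 0.02 and y is no longer a seed
  expect_equal(pre$seeds$seq, c(x, z))
  expect_equal(pre$seeds$abundance, c(15, 2))
})

test_that("precluster conserves total abundance in add-abundance mode", {
  set.seed(104)
  base <- replicate(4, random_seq(150))
  seqs <- c(base, unlist(lapply(base, function(s)
    replicate(3, mutate_at(s, sample(150, sample(1:5, 1)))))))
  tags <- dereplicate(rep(seqs, sample(1:20, length(seqs), replace = TRUE)))
  pre <- precluster_denoise(tags)
  expect_equal(sum(pre$seeds$abundance), sum(tags$abundance))
})

test_that("the three-seed fixture separates the linkage criteria", {
  # d(1,2) = 0.02, d(1,3) = 0.02, d(2,3) = 0.05, threshold 0.03
  D <- matrix(c(0, 0.02, 0.02,
                0.02, 0, 0.05,
                0.02, 0.05, 0), 3, 3)
  expect_equal(oracle_agglomerate(D, 0.03, "sl"), c(1, 1, 1))
  expect_equal(oracle_agglomerate(D, 0.03, "cl"), c(1, 1, 2))
  expect_equal(oracle_agglomerate(D, 0.03, "al"), c(1, 1, 2))

  seeds <- data.frame(seq = c("A", "B", "C"), abundance = c(3, 2, 1))
  ds <- dense_as_sparse(D, cap = 0.10)
  expect_equal(hierarchical_cluster(seeds, ds, 0.03, "sl"), c(1, 1, 1))
  expect_equal(hierarchical_cluster(seeds, ds, 0.03, "cl"), c(1, 1, 2))
  # after {1,2} merge at 0.02, mean distance to 3 is 0.035 > 0.03
  expect_equal(hierarchical_cluster(seeds, ds, 0.03, "al"), c(1, 1, 2))
  expect_equal(hierarchical_cluster(seeds[1, ], dense_as_sparse(
    matrix(0, 1, 1)), 0.03, "al"), 1L)
})

test_that("linkage implementations match the brute-force oracle", {
  set.seed(105)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- round(runif(n * (n - 1) / 2, 0.005, 0.2), 4)
    D <- D + t(D)
    d <- runif(1, 0.02, 0.15)
    ds <- dense_as_sparse(D, cap = 1)
    seeds <- data.frame(seq = replicate(n, random_seq(10)),
                        abundance = rep(1, n))
    for (mode in c("cl", "al", "sl")) {
      got <- hierarchical_cluster(seeds, ds, d, mode)
      want <- oracle_agglomerate(D, d, mode)
      expect_true(same_partition(got, want),
                  info = sprintf("mode %s rep %d", mode, rep))
    }
  }
})

test_that("single linkage equals graph components over stored edges", {
  set.seed(106)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    m <- sample(1:(2 * n), 1)
    i <- sample(n - 1, m, replace = TRUE)
    j <- pmin(i + sample(n, m, replace = TRUE), n)
    keep <- i < j
    e <- data.frame(i = i[keep], j = j[keep], d = runif(sum(keep), 0, 0.1))
    ds <- structure(list(entries = e, cap = 0.1, n_tags = n),
                    class = "sparse_dist")
    d <- runif(1, 0, 0.1)
    got <- hierarchical_cluster(data.frame(seq = rep("A", n)), ds, d, "sl")
    g <- igraph::graph_from_edgelist(
      as.matrix(e[e$d <= d, c("i", "j")]), directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::gorder(g))
    want <- igraph::components(g)$membership
    expect_true(same_partition(got, want))
  }
})

test_that("SL OTU counts are monotone in the threshold and CL refines SL", {
  set.seed(107)
  base <- replicate(5, random_seq(100))
  seqs <- c(base, unlist(lapply(base, function(s)
    replicate(4, mutate_at(s, sample(100, sample(1:4, 1)))))))
  tags <- dereplicate(rep(seqs, sample(1:10, length(seqs), replace = TRUE)))
  ds <- sparse_distances(tags)
  counts <- vapply(c(0.01, 0.03, 0.05, 0.08), function(d)
    max(hierarchical_cluster(tags, ds, d, "sl")), 1L)
  expect_true(all(diff(counts) <= 0))

  cl <- hierarchical_cluster(tags, ds, 0.03, "cl")
  sl <- hierarchical_cluster(tags, ds, 0.03, "sl")
  # every CL cluster lies inside one SL cluster
  expect_true(all(tapply(sl, cl, function(x) length(unique(x))) == 1))
})

test_that("a threshold beyond the sparse cap is refused", {
  ds <- dense_as_sparse(matrix(0, 2, 2), cap = 0.1)
  expect_error(
    hierarchical_cluster(data.frame(seq = c("A", "B")), ds, 0.2, "cl"),
    "cap")
})
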