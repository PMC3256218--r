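# Shared helpers: random sequences, mutation, a brute-force agglomeration
# oracle, and cached fixtures for the slower end-to-end checks.

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# substitute bases at the given positions (deterministic: next base cyclically)
mutate_at <- function(seq, pos) {
  bases <- c("A", "C", "G", "T")
  s <- strsplit(seq, "")[[1]]
  s[pos] <- bases[(match(s[pos], bases)) %% 4 + 1]
  paste(s, collapse = "")
}

# brute-force agglomerative clustering oracle on a dense matrix: at each
# step recompute every between-cluster criterion from scratch (max of all
# pairs for CL, mean of all pairs for AL, min for SL), merge the smallest
# if it is <= d, ties to the smallest (i, j).  Independent of the
# Lance-Williams implementation under test.
oracle_agglomerate <- function(D, d, method = c("cl", "al", "sl")) {
  method <- match.arg(method)
  crit_fun <- switch(method, cl = max, al = mean, sl = min)
  clusters <- as.list(seq_len(nrow(D)))
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
      crit <- crit_fun(D[clusters[[i]], clusters[[j]]])
      if (crit < best) { best <- crit; bi <- i; bj <- j }
    }
    if (best > d) break
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  memb <- integer(nrow(D))
  for (i in seq_along(clusters)) memb[clusters[[i]]] <- i
  match(memb, unique(memb))
}

# wrap a dense symmetric matrix as the sparse set the package consumes
dense_as_sparse <- function(D, cap = 1) {
  n <- nrow(D)
  idx <- which(upper.tri(D) & D <= cap, arr.ind = TRUE)
  structure(list(entries = data.frame(i = idx[, 1], j = idx[, 2],
                                      d = D[idx]),
                 cap = cap, n_tags = n, n_alignments = NA_real_,
                 n_pairs = NA_real_, n_prescreen_pass = NA_real_),
            class = "sparse_dist")
}

same_partition <- function(a, b) {
  length(a) == length(b) && all(match(a, unique(a)) == match(b, unique(b)))
}

# fixtures shared between tests; built once per session
.fixture_cache <- new.env(parent = emptyenv())

small_mock <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- mock_config(n_templates = 6, template_length = 80,
                       n_reads = 1500, seed = 303)
    tm <- generate_templates(cfg)
    gen <- generate_reads(tm, cfg)
    .fixture_cache$small <- c(gen, list(templates = tm, cfg = cfg))
  }
  .fixture_cache$small
}

acceptance_mock <- function() {
  if (is.null(.fixture_cache$acc)) {
    cfg <- mock_config(seed = 101)  # defaults: K = 43, 50k reads, 0.03 screen
    tm <- generate_templates(cfg)
    gen <- generate_reads(tm, cfg)
    .fixture_cache$acc <- c(gen, list(templates = tm, cfg = cfg))
  }
  .fixture_cache$acc
}

# reads of each OTU must map to exactly one template, templates to one OTU
contamination_count <- function(fit, truth) {
  tmpl <- truth$template_id[match(fit$read_ids, truth$read_id)]
  otu <- fit$tags$otu[fit$read_tag]
  cross <- table(otu, tmpl)
  sum(rowSums(cross > 0) > 1) + sum(colSums(cross > 0) > 1)
}
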