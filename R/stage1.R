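# Stage 1: denoising precluster + hierarchical clustering of abundant tags.

#' Single-linkage denoising precluster of the abundant group
#'
#' One sequential pass over the abundance-sorted tags: the most abundant
#' unabsorbed tag serves as seed, and every remaining lower-ranked tag
#' within \code{threshold} NW distance of it is absorbed (removed from the
#' candidate list and never re-examined); then the next surviving tag
#' seeds, and so on.  This removes sequencing/PCR 'noise' variants, which
#' are highly similar to but less abundant than their parent tags, before
#' the formal clustering.
#'
#' On absorption the seed's abundance grows either by the absorbed tag's
#' full abundance (\code{accumulate = "abundance"}, the default, which
#' conserves read counts) or literally by 1 (\code{"literal"}).  Both
#' modes produce identical memberships; only seed weighting differs.
#'
#' @param abundant abundant-group tags, sorted by abundance descending.
#' @param threshold absorption distance (default 0.02).
#' @param align an [alignment_params()] object.
#' @param kmer a [kmer_params()] object (pairs failing the prescreen are
#'   assumed to exceed the threshold).
#' @param dset optional precomputed [sparse_distances()] over
#'   \code{abundant} (cap must be >= threshold); computed if missing.
#' @param accumulate abundance accumulation mode, \code{"abundance"} or
#'   \code{"literal"}.
#' @return A list of class \code{"precluster"} with \code{seeds} (tag
#'   data.frame with post-merge abundances, original abundances in
#'   \code{abundance0}), \code{merged_into} (integer vector over input
#'   rows: the seed row each absorbed tag merged into, NA for seeds),
#'   \code{n_merged} and \code{mode}.
#' @export
precluster_denoise <- function(abundant, threshold = 0.02,
                               align = alignment_params(),
                               kmer = kmer_params(), dset = NULL,
                               accumulate = c("abundance", "literal")) {
  accumulate <- match.arg(accumulate)
  n <- nrow(abundant)
  if (is.null(dset)) {
    if (n > 1)
      dset <- sparse_distances(abundant, kmer = kmer, align = align,
                               cap = max(threshold, 0.10))
  } else if (dset$cap < threshold) {
    stop("sparse distance cap (", dset$cap, ") is below the precluster ",
         "threshold (", threshold, ")")
  }
  if (any(diff(abundant$abundance) > 0))
    stop("abundant tags must be sorted by abundance descending")

  merged_into <- rep(NA_integer_, n)
  ab <- abundant$abundance
  if (n > 1 && nrow(dset$entries)) {
    e <- dset$entries[dset$entries$d <= threshold, , drop = FALSE]
    # adjacency restricted to later (lower-frequency) ranks
    adj <- split(e$j, factor(e$i, levels = seq_len(n)))
    absorbed <- rep(FALSE, n)
    for (i in seq_len(n)) {
      if (absorbed[i]) next
      nb <- adj[[i]]
      nb <- nb[!absorbed[nb]]
      if (length(nb)) {
        absorbed[nb] <- TRUE
        merged_into[nb] <- i
        gain <- if (accumulate == "abundance")
          sum(abundant$abundance[nb]) else length(nb)
        ab[i] <- ab[i] + gain
      }
    }
  }
  keep <- is.na(merged_into)
  seeds <- abundant[keep, , drop = FALSE]
  seeds$abundance0 <- seeds$abundance
  seeds$abundance <- ab[keep]
  rownames(seeds) <- NULL
  structure(list(seeds = seeds, merged_into = merged_into,
                 n_merged = sum(!keep), mode = accumulate),
            class = "precluster")
}

# union-find with path compression; edges as i/j integer vectors
.components <- function(n, i, j) {
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (t in seq_along(i)) {
    ra <- find(i[t]); rb <- find(j[t])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# dense agglomeration, complete or average linkage, cut at threshold d.
# Merges greedily by smallest current criterion while it is <= d; equal
# criteria merge the pair with the smaller (i, j) rank indices.  AL uses
# the size-weighted Lance-Williams update, identical to the mean over all
# between-cluster pairs.
.agglomerate <- function(D, d, method) {
  n <- nrow(D)
  lab <- seq_len(n)          # cluster label per item
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  diag(D) <- Inf
  D[lower.tri(D)] <- Inf     # keep (i < j) in the upper triangle
  while (sum(active) > 1L) {
    mn <- min(D)
    if (mn > d) break
    hit <- which(D == mn, arr.ind = TRUE, useNames = FALSE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    ks <- which(active); ks <- ks[ks != i & ks != j]
    if (length(ks)) {
      dik <- ifelse(ks < i, D[cbind(ks, i)], D[cbind(i, ks)])
      djk <- ifelse(ks < j, D[cbind(ks, j)], D[cbind(j, ks)])
      new <- if (method == "cl") pmax(dik, djk)
             else (sizes[i] * dik + sizes[j] * djk) / (sizes[i] + sizes[j])
      D[cbind(pmin(ks, i), pmax(ks, i))] <- new
    }
    D[j, ] <- Inf; D[, j] <- Inf
    active[j] <- FALSE
    sizes[i] <- sizes[i] + sizes[j]
    lab[lab == j] <- i
  }
  match(lab, unique(lab))
}

#' Agglomerative clustering of precluster seeds into HAOTUs
#'
#' Cuts an agglomerative clustering of the surviving seeds at distance
#' \code{d}.  Single linkage (SL) is the connected components of the graph
#' with stored edges at or below \code{d}; complete linkage (CL) merges
#' two clusters only when the maximum pairwise distance between them is at
#' or below \code{d}; average linkage (AL) uses the arithmetic mean of all
#' between-cluster pairwise distances.  Pairs absent from the sparse set
#' (rejected by the k-mer prescreen or above the cap) are valued at
#' \code{cap + 0.01}, i.e. definitely above any usable threshold.
#'
#' @param seeds seed tags (the \code{seeds} element of a
#'   [precluster_denoise()] result, or any tag data.frame).
#' @param dset a [sparse_distances()] set over \code{seeds}, in seed row
#'   order.
#' @param d clustering threshold; must not exceed \code{dset$cap}.
#' @param mode \code{"cl"}, \code{"al"} or \code{"sl"}.
#' @return An integer vector of cluster memberships (1-based, numbered by
#'   first appearance in seed order), one per seed.
#' @export
hierarchical_cluster <- function(seeds, dset, d = 0.03,
                                 mode = c("cl", "al", "sl")) {
  mode <- match.arg(mode)
  n <- if (is.data.frame(seeds)) nrow(seeds) else length(seeds)
  if (n == 0) return(integer(0))
  if (d > dset$cap)
    stop("threshold d = ", d, " exceeds the sparse matrix cap (", dset$cap,
         "); recompute distances with a larger cap")
  e <- dset$entries
  if (mode == "sl") {
    e <- e[e$d <= d, , drop = FALSE]
    return(.components(n, e$i, e$j))
  }
  fill <- dset$cap + 0.01
  D <- matrix(fill, n, n)
  if (nrow(e)) {
    D[cbind(e$i, e$j)] <- e$d
    D[cbind(e$j, e$i)] <- e$d
  }
  .agglomerate(D, d, mode)
}
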