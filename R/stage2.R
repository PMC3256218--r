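# Stage 2: greedy assignment of rare tags into existing OTUs or new LAOTUs.

# internal OTU index: a plain list tracking, over the full tag table,
#   tag_otu  integer OTU id per placed tag (NA unplaced)
#   via      placement route per tag: direct | precluster1 | precluster2 |
#            greedy
#   otu_kind "H" (HAOTU, created in stage 1) or "L" (LAOTU)
#   otu_alive logical; LAOTUs merged away are dead
#   otu_rep  tag index of the representative (heaviest member; ties go to
#            the lexicographically smaller sequence)
#   weight   effective abundance per tag (seeds carry precluster-merged
#            abundance in add-abundance mode)
.index_new <- function(n_tags, weight, seqs) {
  list(tag_otu = rep(NA_integer_, n_tags),
       via = rep(NA_character_, n_tags),
       otu_kind = character(0), otu_alive = logical(0),
       otu_rep = integer(0), weight = weight, seqs = seqs)
}

.index_new_otu <- function(index, kind, tag, via) {
  id <- length(index$otu_kind) + 1L
  index$otu_kind[id] <- kind
  index$otu_alive[id] <- TRUE
  index$otu_rep[id] <- tag
  index$tag_otu[tag] <- id
  index$via[tag] <- via
  index
}

.index_add_tag <- function(index, tag, otu, via) {
  index$tag_otu[tag] <- otu
  index$via[tag] <- via
  r <- index$otu_rep[otu]
  w <- index$weight
  if (w[tag] > w[r] || (w[tag] == w[r] && index$seqs[tag] < index$seqs[r]))
    index$otu_rep[otu] <- tag
  index
}

# merge OTUs `src` into `target` (all LAOTUs by construction)
.index_merge <- function(index, src, target) {
  src <- setdiff(src, target)
  index$tag_otu[index$tag_otu %in% src] <- target
  index$otu_alive[src] <- FALSE
  cand <- c(index$otu_rep[target], index$otu_rep[src])
  w <- index$weight[cand]
  best <- cand[order(-w, index$seqs[cand])][1]
  index$otu_rep[target] <- best
  index
}

#' Alignment-free shortcut placement of a rare tag (precluster 2)
#'
#' Compares the rare tag base by base against the representatives of the
#' current OTUs, scanned in OTU-creation order, and returns the first OTU
#' whose representative has direct distance strictly below \code{d} (see
#' [direct_distance()]).  A hit places the tag without any NW alignment;
#' since the direct distance upper-bounds the NW distance, any such
#' placement also satisfies the NW threshold.
#'
#' @param seq the rare tag's sequence.
#' @param index an OTU index (internal; see [run_stage2()]).
#' @param d distance threshold.
#' @return The OTU id (integer) or NULL when no representative qualifies.
#' @keywords internal
#' @export
precluster2_shortcut <- function(seq, index, d) {
  alive <- which(index$otu_alive)
  if (!length(alive)) return(NULL)
  reps <- index$seqs[index$otu_rep[alive]]
  hit <- direct_scan_cpp(seq, reps, d)
  if (hit == 0L) NULL else alive[hit]
}

#' Greedy k-mer-ordered assignment of one rare tag
#'
#' Ranks all placed tags by k-mer distance to the query (candidates failing
#' the \code{f_max} prescreen are excluded), then evaluates NW distances in
#' batches of \code{sp$batch}; after any batch containing at least one hit
#' (NW distance <= \code{sp$d}) the next batch is evaluated, and the search
#' stops at the first hit-free batch.  The accumulated hit set H decides
#' among five cases:
#' \enumerate{
#'   \item H empty: the tag founds a new LAOTU.
#'   \item H touches one OTU: the tag joins it.
#'   \item H touches two or more HAOTUs only: the tag joins the HAOTU of
#'     the most abundant hit tag; HAOTUs are never merged.
#'   \item H touches two or more LAOTUs only: those LAOTUs and the tag
#'     merge into one LAOTU.
#'   \item H touches both kinds: all hit LAOTUs merge into the HAOTU of
#'     the most abundant hit tag, which also receives the tag.
#' }
#'
#' @param tag index (1-based row) of the rare tag in the full tag table.
#' @param index the OTU index.
#' @param sp a [search_params()] object.
#' @param align an [alignment_params()] object.
#' @param prof k-mer profile store over the full tag table (internal).
#' @param f_max k-mer prescreen limit.
#' @return A list with the updated \code{index}, the applied \code{case}
#'   (1-5), and \code{n_align}, the NW alignments spent.
#' @keywords internal
#' @export
greedy_assign <- function(tag, index, sp, align, prof, f_max = 0.5) {
  placed <- which(!is.na(index$tag_otu))
  n_align <- 0L
  H <- integer(0)
  if (length(placed)) {
    kd <- kmer_query_cpp(prof, tag, placed)
    keep <- kd <= f_max
    cand <- placed[keep][order(kd[keep], placed[keep])]
    p <- .ap_args(align)
    pos <- 1L
    while (pos <= length(cand)) {
      batch <- cand[pos:min(pos + sp$batch - 1L, length(cand))]
      dd <- nw_distance_many_cpp(index$seqs[tag], index$seqs[batch],
                                 p$a, p$b, p$g, p$e, p$x, p$r454)
      n_align <- n_align + length(batch)
      hits <- batch[dd <= sp$d]
      H <- c(H, hits)
      if (!length(hits)) break
      pos <- pos + sp$batch
    }
  }
  if (!length(H)) {
    index <- .index_new_otu(index, "L", tag, "greedy")
    return(list(index = index, case = 1L, n_align = n_align))
  }
  otus <- sort(unique(index$tag_otu[H]))
  kinds <- index$otu_kind[otus]
  if (length(otus) == 1L) {
    index <- .index_add_tag(index, tag, otus, "greedy")
    return(list(index = index, case = 2L, n_align = n_align))
  }
  if (all(kinds == "H")) {
    hh <- H[index$otu_kind[index$tag_otu[H]] == "H"]
    best <- hh[order(-index$weight[hh], index$tag_otu[hh])][1]
    index <- .index_add_tag(index, tag, index$tag_otu[best], "greedy")
    return(list(index = index, case = 3L, n_align = n_align))
  }
  if (all(kinds == "L")) {
    target <- otus[1]
    index <- .index_merge(index, otus, target)
    index <- .index_add_tag(index, tag, target, "greedy")
    return(list(index = index, case = 4L, n_align = n_align))
  }
  hh <- H[index$otu_kind[index$tag_otu[H]] == "H"]
  best <- hh[order(-index$weight[hh], index$tag_otu[hh])][1]
  target <- index$tag_otu[best]
  index <- .index_merge(index, otus[kinds == "L"], target)
  index <- .index_add_tag(index, tag, target, "greedy")
  list(index = index, case = 5L, n_align = n_align)
}

#' Run the second clustering stage
#'
#' Processes the rare tags in abundance-descending order.  Each tag first
#' tries the alignment-free shortcut ([precluster2_shortcut()]); on a miss
#' it goes through the greedy k-mer-ordered NW search ([greedy_assign()]).
#' Tags placed into an OTU immediately become searchable targets for
#' subsequent rare tags.
#'
#' @param tags full tag table (abundant then rare, global abundance order).
#' @param n_abundant number of abundant tags (the first rows of
#'   \code{tags}).
#' @param stage1_otu integer OTU id per abundant tag (from stage 1).
#' @param stage1_via placement route per abundant tag (\code{"direct"} or
#'   \code{"precluster1"}).
#' @param weight effective abundance per tag.
#' @param sp a [search_params()] object.
#' @param align an [alignment_params()] object.
#' @param kmer a [kmer_params()] object.
#' @param trace logical; record the case applied per rare tag.
#' @return A list with the final OTU \code{index}, counters
#'   (\code{n_align}, \code{n_shortcut}, \code{case_counts}) and, when
#'   \code{trace} is set, a per-rare-tag trace data.frame.
#' @keywords internal
#' @export
run_stage2 <- function(tags, n_abundant, stage1_otu, stage1_via, weight,
                       sp = search_params(), align = alignment_params(),
                       kmer = kmer_params(), trace = FALSE) {
  n <- nrow(tags)
  index <- .index_new(n, weight, tags$seq)
  if (n_abundant > 0) {
    index$tag_otu[seq_len(n_abundant)] <- stage1_otu
    index$via[seq_len(n_abundant)] <- stage1_via
    n_otus <- max(stage1_otu)
    index$otu_kind <- rep("H", n_otus)
    index$otu_alive <- rep(TRUE, n_otus)
    index$otu_rep <- vapply(seq_len(n_otus), function(o) {
      m <- which(stage1_otu == o)
      m[order(-weight[m], tags$seq[m])][1]
    }, integer(1))
  }
  rare_idx <- if (n_abundant < n) seq.int(n_abundant + 1L, n) else integer(0)
  n_align <- 0
  n_shortcut <- 0L
  cases <- integer(5)
  tr <- if (trace) vector("list", length(rare_idx)) else NULL
  prof <- if (length(rare_idx))
    kmer_profiles_cpp(tags$seq, kmer$k) else NULL
  for (t in rare_idx) {
    hit <- if (sp$shortcut) precluster2_shortcut(tags$seq[t], index, sp$d)
           else NULL
    if (!is.null(hit)) {
      index <- .index_add_tag(index, t, hit, "precluster2")
      n_shortcut <- n_shortcut + 1L
      if (trace) tr[[t - n_abundant]] <-
        data.frame(tag = t, case = NA_integer_, otu = hit,
                   route = "precluster2")
    } else {
      res <- greedy_assign(t, index, sp, align, prof, kmer$f_max)
      index <- res$index
      n_align <- n_align + res$n_align
      cases[res$case] <- cases[res$case] + 1L
      if (trace) tr[[t - n_abundant]] <-
        data.frame(tag = t, case = res$case, otu = index$tag_otu[t],
                   route = "greedy")
    }
  }
  list(index = index, n_align = n_align, n_shortcut = n_shortcut,
       case_counts = cases,
       trace = if (trace) do.call(rbind, tr) else NULL)
}
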