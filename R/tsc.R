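# Two-stage clustering of amplicon tags into OTUs.

#' Two-stage clustering of amplicon reads into OTUs
#'
#' Clusters amplicon reads into operational taxonomic units (OTUs) at a
#' pairwise Needleman-Wunsch distance threshold, in two stages.  Reads are
#' first dereplicated into unique tags and split at an abundance cutoff.
#' Stage 1 computes the sparse pairwise NW distance matrix of the abundant
#' tags (k-mer prescreened), absorbs near-identical lower-frequency tags
#' into their parents with one round of sequential single-linkage
#' preclustering at \code{precluster_d}, and clusters the surviving seeds
#' agglomeratively (complete, average or single linkage) at \code{d},
#' yielding HAOTUs.  Stage 2 places the rare tags, in abundance order,
#' either through an alignment-free direct-comparison shortcut against OTU
#' representatives or through a greedy k-mer-ordered batched NW search
#' with a five-case merge rule (see [greedy_assign()]); rare tags may
#' found and merge LAOTUs but never merge HAOTUs.
#'
#' @param input a FASTA file path, a character vector of sequences, or a
#'   data.frame with columns \code{id} and \code{seq}.
#' @param cutoff minimum tag abundance for the stage-1 (hierarchical)
#'   group; default 3.  A cutoff of 1 sends every tag through stage 1 and
#'   is meant for algorithm study, not for real samples.
#' @param d OTU distance threshold (default 0.03).
#' @param linkage stage-1 agglomeration: \code{"al"}, \code{"cl"} or
#'   \code{"sl"}.
#' @param align an [alignment_params()] object.
#' @param kmer a [kmer_params()] object.
#' @param batch stage-2 NW batch size (default 10).
#' @param shortcut enable the stage-2 alignment-free shortcut (default
#'   TRUE).
#' @param cap sparse-matrix storage cap (default 0.10; must be >= d).
#' @param precluster_d stage-1 denoising precluster distance (default
#'   0.02).
#' @param precluster accumulation mode, \code{"abundance"} (default;
#'   conserves read counts) or \code{"literal"} (seed abundance grows by 1
#'   per absorbed tag).
#' @param allow_ambiguous keep reads with IUPAC ambiguity codes.
#' @param trace record the stage-2 case applied per rare tag.
#' @return An object of class \code{"tsc"}: a list with \code{otus} (one
#'   row per OTU: \code{id}, \code{kind} = HAOTU/LAOTU, \code{n_tags},
#'   \code{n_reads}, \code{representative}), \code{tags} (per-tag table
#'   with \code{otu} and placement \code{via}), \code{read_tag} (tag row
#'   per input read), \code{read_ids}, \code{counters} and the call
#'   parameters.
#' @examples
#' cfg <- mock_config(n_templates = 4, n_reads = 300, seed = 7)
#' gen <- generate_reads(generate_templates(cfg), cfg)
#' fit <- tsc(gen$reads, cutoff = 2)
#' fit
#' @export
tsc <- function(input, cutoff = 3, d = 0.03, linkage = c("al", "cl", "sl"),
                align = alignment_params(), kmer = kmer_params(),
                batch = 10, shortcut = TRUE, cap = 0.10,
                precluster_d = 0.02,
                precluster = c("abundance", "literal"),
                allow_ambiguous = FALSE, trace = FALSE) {
  linkage <- match.arg(linkage)
  precluster <- match.arg(precluster)
  cl <- match.call()
  if (d > cap) stop("d must not exceed the sparse matrix cap")
  looks_like_path <- is.character(input) && length(input) == 1 &&
    (grepl("[/\\\\]", input) || grepl("\\.(fa|fasta|fna|txt)$", input,
                                      ignore.case = TRUE))
  reads <- if (looks_like_path || (is.character(input) &&
               length(input) == 1 && file.exists(input)))
    read_fasta(input, allow_ambiguous = allow_ambiguous)
  else if (is.character(input))
    data.frame(id = paste0("read", seq_along(input)), seq = toupper(input),
               stringsAsFactors = FALSE)
  else input
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  if (nrow(reads) == 0) stop("no reads in input")
  if (anyDuplicated(reads$id)) stop("read ids must be unique")

  tags <- dereplicate(reads)
  if (any(nchar(tags$seq) < kmer$k))
    stop("all sequences must be at least k = ", kmer$k, " bases long")
  split <- split_by_cutoff(tags, cutoff)
  nA <- nrow(split$abundant)
  nU <- nrow(tags)

  # stage 1 -----------------------------------------------------------------
  sp1 <- search_params(d = d, batch = batch, shortcut = shortcut)
  weight <- tags$abundance
  if (nA > 0) {
    dset <- sparse_distances(split$abundant, kmer = kmer, align = align,
                             cap = max(cap, precluster_d))
    pre <- precluster_denoise(split$abundant, threshold = precluster_d,
                              align = align, kmer = kmer, dset = dset,
                              accumulate = precluster)
    seed_rows <- which(is.na(pre$merged_into))
    # distances restricted to surviving seeds, reindexed to seed order
    e <- dset$entries
    smap <- match(seq_len(nA), seed_rows)
    keep <- !is.na(smap[e$i]) & !is.na(smap[e$j])
    sdset <- structure(list(entries = data.frame(i = smap[e$i[keep]],
                                                 j = smap[e$j[keep]],
                                                 d = e$d[keep]),
                            cap = dset$cap, n_tags = length(seed_rows),
                            n_alignments = dset$n_alignments,
                            n_pairs = dset$n_pairs,
                            n_prescreen_pass = dset$n_prescreen_pass),
                       class = "sparse_dist")
    memb <- hierarchical_cluster(pre$seeds, sdset, d = d, mode = linkage)
    stage1_otu <- integer(nA)
    stage1_otu[seed_rows] <- memb
    stage1_otu[!is.na(pre$merged_into)] <-
      stage1_otu[pre$merged_into[!is.na(pre$merged_into)]]
    stage1_via <- ifelse(is.na(pre$merged_into), "direct", "precluster1")
    weight[seed_rows] <- pre$seeds$abundance
    n_haotu <- max(memb)
    nw1 <- dset$n_alignments
    n_merged <- pre$n_merged
  } else {
    stage1_otu <- integer(0)
    stage1_via <- character(0)
    n_haotu <- 0L
    nw1 <- 0
    n_merged <- 0L
  }

  # stage 2 -----------------------------------------------------------------
  s2 <- run_stage2(tags, nA, stage1_otu, stage1_via, weight, sp = sp1,
                   align = align, kmer = kmer, trace = trace)
  index <- s2$index

  # compact OTU ids to 1..K in creation order
  alive <- which(index$otu_alive)
  newid <- rep(NA_integer_, length(index$otu_alive))
  newid[alive] <- seq_along(alive)
  tags$otu <- newid[index$tag_otu]
  tags$via <- index$via
  read_tag <- match(reads$seq, tags$seq)
  reads_per_otu <- as.integer(
    rowsum(tags$abundance, tags$otu)[as.character(seq_along(alive)), 1])
  otus <- data.frame(id = seq_along(alive),
                     kind = ifelse(index$otu_kind[alive] == "H", "HAOTU",
                                   "LAOTU"),
                     n_tags = as.integer(table(factor(tags$otu,
                                                levels = seq_along(alive)))),
                     n_reads = reads_per_otu,
                     representative = tags$seq[index$otu_rep[alive]],
                     stringsAsFactors = FALSE)

  counters <- list(n_reads = nrow(reads), n_tags = nU, n_abundant = nA,
                   n_rare = nU - nA, precluster_merges = n_merged,
                   nw_stage1 = as.double(nw1),
                   nw_stage2 = as.double(s2$n_align),
                   shortcut_placements = s2$n_shortcut,
                   stage2_cases = s2$case_counts,
                   n_haotu = sum(otus$kind == "HAOTU"),
                   n_laotu = sum(otus$kind == "LAOTU"))
  structure(list(otus = otus, tags = tags, read_tag = read_tag,
                 read_ids = reads$id, counters = counters,
                 d = d, cutoff = cutoff, linkage = linkage,
                 params = list(align = align, kmer = kmer, batch = batch,
                               shortcut = shortcut, cap = cap,
                               precluster_d = precluster_d,
                               precluster = precluster),
                 trace = s2$trace, call = cl),
            class = "tsc")
}

#' @export
print.tsc <- function(x, ...) {
  co <- x$counters
  cat("Two-stage OTU clustering (d = ", x$d, ", linkage = ",
      toupper(x$linkage), ", cutoff = ", x$cutoff, ")\n", sep = "")
  cat("  reads:             ", co$n_reads, "\n", sep = "")
  cat("  unique tags:       ", co$n_tags, " (", co$n_abundant,
      " abundant / ", co$n_rare, " rare)\n", sep = "")
  cat("  precluster merges: ", co$precluster_merges, "\n", sep = "")
  cat("  NW alignments:     ", format(co$nw_stage1, big.mark = ","),
      " (stage 1) + ", format(co$nw_stage2, big.mark = ","),
      " (stage 2)\n", sep = "")
  cat("  shortcut placements: ", co$shortcut_placements, "\n", sep = "")
  cat("  OTUs:              ", nrow(x$otus), " (", co$n_haotu, " HAOTU / ",
      co$n_laotu, " LAOTU)\n", sep = "")
  invisible(x)
}

#' @method summary tsc
#' @export
summary.tsc <- function(object, n = 10, ...) {
  print(object)
  sizes <- object$otus$n_reads
  cat("\nOTU read-count distribution:\n")
  print(summary(sizes))
  top <- object$otus[order(-object$otus$n_reads), ][seq_len(min(n,
                                                      nrow(object$otus))), ]
  cat("\nLargest OTUs:\n")
  print(top[, c("id", "kind", "n_tags", "n_reads")], row.names = FALSE)
  invisible(object)
}

#' Rank-abundance plot of the clustered OTUs
#'
#' @param x a \code{"tsc"} object.
#' @param ... passed to [graphics::plot()].
#' @method plot tsc
#' @export
plot.tsc <- function(x, ...) {
  sizes <- sort(x$otus$n_reads, decreasing = TRUE)
  graphics::plot(seq_along(sizes), sizes, log = "y", type = "b", pch = 16,
                 cex = 0.6, xlab = "OTU rank", ylab = "reads per OTU",
                 main = sprintf("%d OTUs at d = %g (%s)", length(sizes),
                                x$d, toupper(x$linkage)), ...)
  invisible(x)
}

#' Read ids per OTU
#'
#' @param x a \code{"tsc"} object.
#' @return A list, one character vector of read ids per OTU.
#' @export
otu_members <- function(x) {
  stopifnot(inherits(x, "tsc"))
  otu_per_read <- x$tags$otu[x$read_tag]
  split(x$read_ids, factor(otu_per_read, levels = x$otus$id))
}

#' Check the partition and conservation invariants of a clustering
#'
#' Verifies that every input read (and unique tag) belongs to exactly one
#' OTU, that OTU read counts sum to the input read count, that every OTU
#' is non-empty and its representative is one of its member tags.
#'
#' @param x a \code{"tsc"} object.
#' @return TRUE invisibly; a failed invariant raises an error describing
#'   it.
#' @export
tsc_validate <- function(x) {
  stopifnot(inherits(x, "tsc"))
  if (anyNA(x$tags$otu)) stop("unplaced tags found")
  if (!all(x$tags$otu %in% x$otus$id)) stop("tag assigned to unknown OTU")
  if (anyNA(x$read_tag)) stop("read not mapped to a tag")
  if (sum(x$otus$n_reads) != x$counters$n_reads)
    stop("OTU read counts do not sum to the input read count")
  if (any(x$otus$n_tags < 1)) stop("empty OTU found")
  rep_otu <- x$tags$otu[match(x$otus$representative, x$tags$seq)]
  if (!identical(rep_otu, x$otus$id))
    stop("an OTU representative is not a member of its OTU")
  m <- otu_members(x)
  ids <- sort(unlist(m, use.names = FALSE))
  if (!identical(ids, sort(x$read_ids)))
    stop("OTU membership is not a partition of the read ids")
  invisible(TRUE)
}

#' Write clustering outputs to disk
#'
#' Writes (a) OTU membership in the mothur list dialect — one line
#' \code{label <tab> numOtus <tab> comma-joined read ids, one field per
#' OTU}; (b) a representative FASTA with headers
#' \code{>OTU_<id>;size=<reads>}; (c) a per-OTU abundance TSV; and,
#' when present, (d) the stage-2 trace log.
#'
#' @param x a \code{"tsc"} object.
#' @param dir output directory (created if missing).
#' @param label distance label for the list file (default the clustering
#'   threshold).
#' @return Invisibly, the paths written.
#' @export
write_tsc <- function(x, dir, label = format(x$d)) {
  stopifnot(inherits(x, "tsc"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- otu_members(x)
  listfile <- file.path(dir, "otus.list")
  line <- paste(c(label, length(m),
                  vapply(m, paste, "", collapse = ",")), collapse = "\t")
  writeLines(line, listfile)
  repfile <- file.path(dir, "otus.rep.fasta")
  set <- Biostrings::DNAStringSet(x$otus$representative)
  names(set) <- sprintf("OTU_%d;size=%d", x$otus$id, x$otus$n_reads)
  Biostrings::writeXStringSet(set, repfile)
  tabfile <- file.path(dir, "otus.tsv")
  utils::write.table(x$otus, tabfile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(listfile, repfile, tabfile)
  if (!is.null(x$trace)) {
    tracefile <- file.path(dir, "stage2.trace.tsv")
    utils::write.table(x$trace, tracefile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, tracefile)
  }
  invisible(paths)
}

#' Validate written outputs against an input FASTA
#'
#' Re-reads a membership list file written by [write_tsc()] and checks
#' that it partitions the read ids of the input exactly once.
#'
#' @param dir output directory holding \code{otus.list}.
#' @param input the input FASTA path (or a data.frame of reads).
#' @return TRUE invisibly; inconsistencies raise an error.
#' @export
validate_outputs <- function(dir, input) {
  listfile <- file.path(dir, "otus.list")
  if (!file.exists(listfile)) stop("no otus.list under ", dir)
  fields <- strsplit(readLines(listfile)[1], "\t", fixed = TRUE)[[1]]
  if (length(fields) < 3) stop("malformed list file")
  n_otus <- as.integer(fields[2])
  members <- fields[-(1:2)]
  if (length(members) != n_otus)
    stop("list file declares ", n_otus, " OTUs but has ", length(members),
         " member fields")
  ids <- unlist(strsplit(members, ",", fixed = TRUE), use.names = FALSE)
  reads <- if (is.character(input)) read_fasta(input,
                                               allow_ambiguous = TRUE)
           else input
  if (anyDuplicated(ids)) stop("a read id appears in more than one OTU")
  if (!setequal(ids, reads$id) || length(ids) != nrow(reads))
    stop("membership does not partition the input read ids")
  invisible(TRUE)
}
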