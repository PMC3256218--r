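#' k-mer distance between two sequences
#'
#' The k-mer distance is 1 minus the number of shared overlapping k-words
#' (counting multiplicity) divided by \code{min(|s1|, |s2|) - k + 1}.  It is
#' 0 for identical sequences, 1 when no word is shared, and is used as a
#' cheap prescreen: pairs whose k-mer distance exceeds \code{f_max} are
#' assumed to be far beyond any clustering threshold and are never aligned.
#'
#' @param s1,s2 DNA strings of length >= k.
#' @param k word length (default 6).
#' @return The k-mer distance, a number in \[0, 1\].
#' @examples
#' kmer_distance("ACGTA", "ACGTT", k = 2)   # 0.25
#' @export
kmer_distance <- function(s1, s2, k = 6) {
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be a positive integer")
  if (nchar(s1) < k || nchar(s2) < k)
    stop("sequences must be at least k = ", k, " bases long")
  kmer_distance_cpp(s1, s2, k)
}

#' Global pairwise alignment of two sequences
#'
#' Computes the optimal global alignment under affine gap scoring (see
#' [alignment_params()] for the platform-specific gap and end-gap
#' conventions).  Traceback ties are broken deterministically: prefer a
#' substitution column, then a gap in the second sequence, then a gap in
#' the first.
#'
#' @param s1,s2 non-empty DNA strings.
#' @param params an [alignment_params()] object.
#' @return A list of class \code{"nw_alignment"} with the two equal-length
#'   gapped strings \code{a1}, \code{a2} and the alignment \code{score}.
#' @examples
#' nw_align("ACGTACGT", "ACGACGT")          # one internal gap, score -3
#' @export
nw_align <- function(s1, s2, params = alignment_params()) {
  if (!nzchar(s1) || !nzchar(s2)) stop("sequences must be non-empty")
  a <- .ap_args(params)
  res <- nw_align_cpp(toupper(s1), toupper(s2), a$a, a$b, a$g, a$e, a$x,
                      a$r454)
  structure(list(a1 = res$a1, a2 = res$a2, score = res$score,
                 params = params),
            class = "nw_alignment")
}

#' @export
print.nw_alignment <- function(x, ...) {
  cat(x$a1, "\n", x$a2, "\n", sep = "")
  cat("score:", x$score, "\n")
  invisible(x)
}

#' Needleman-Wunsch distance of an aligned pair
#'
#' Converts an alignment into a distance in \[0, 1\].  When end gaps are
#' free (\code{free_end_gaps}), terminal gap columns are trimmed first.
#' On the Illumina platform the distance is (substitutions + gap columns)
#' divided by the trimmed alignment length; on the 454 platform each gap
#' run counts once, so continuous indels (typical homopolymer errors) are
#' a single difference.  An alignment whose trimmed length is zero (one
#' sequence entirely overhanging the other) has distance 1.
#'
#' @param aligned an \code{"nw_alignment"} from [nw_align()], or a gapped
#'   string (in which case \code{a2} must be the matching gapped string).
#' @param a2 second gapped string when \code{aligned} is a character.
#' @param params an [alignment_params()] object.
#' @return The distance, a number in \[0, 1\].
#' @examples
#' nw_distance("ACGT----AC", "ACGTTTTTAC")                          # 0.4
#' nw_distance("ACGT----AC", "ACGTTTTTAC",
#'             params = alignment_params(platform = "454"))         # 0.1
#' @export
nw_distance <- function(aligned, a2 = NULL, params = alignment_params()) {
  if (inherits(aligned, "nw_alignment")) {
    a1 <- aligned$a1
    a2 <- aligned$a2
    if (!is.null(aligned$params)) params <- aligned$params
  } else {
    a1 <- aligned
    if (is.null(a2)) stop("supply the second gapped string")
  }
  if (nchar(a1) != nchar(a2))
    stop("aligned sequences must have equal length")
  p <- .ap_args(params)
  aln_distance_cpp(a1, a2, p$a, p$b, p$g, p$e, p$x, p$r454)
}

#' Pairwise NW distance of two unaligned sequences
#'
#' Convenience wrapper: aligns with [nw_align()] and converts with
#' [nw_distance()] in one call.
#'
#' @inheritParams nw_align
#' @return The NW distance in \[0, 1\].
#' @export
nw_pair_distance <- function(s1, s2, params = alignment_params()) {
  if (!nzchar(s1) || !nzchar(s2)) stop("sequences must be non-empty")
  p <- .ap_args(params)
  nw_pair_distance_cpp(toupper(s1), toupper(s2), p$a, p$b, p$g, p$e, p$x,
                       p$r454)
}

#' Sparse all-vs-all NW distances with k-mer prescreening
#'
#' Computes pairwise NW distances for every tag pair whose k-mer distance
#' is at most \code{f_max}, and stores those at or below \code{cap}.
#' Absent pairs are interpreted as distance > cap.  The default cap of
#' 0.10 stores enough of the matrix for clustering thresholds up to 0.10.
#'
#' @param tags dereplicated tags from [dereplicate()] (or a character
#'   vector of sequences).
#' @param kmer a [kmer_params()] object.
#' @param align an [alignment_params()] object.
#' @param cap maximum stored distance (default 0.10).
#' @return A list of class \code{"sparse_dist"} with \code{entries} (a
#'   data.frame of 1-based tag ranks \code{i} < \code{j} and distance
#'   \code{d}), \code{cap}, \code{n_tags}, and the counters
#'   \code{n_alignments} (NW alignments actually performed),
#'   \code{n_pairs} and \code{n_prescreen_pass}.
#' @export
sparse_distances <- function(tags, kmer = kmer_params(),
                             align = alignment_params(), cap = 0.10) {
  seqs <- if (is.character(tags)) tags else tags$seq
  if (!is.numeric(cap) || cap <= 0) stop("cap must be positive")
  p <- .ap_args(align)
  res <- sparse_pairs_cpp(seqs, kmer$k, kmer$f_max, p$a, p$b, p$g, p$e,
                          p$x, p$r454, cap)
  structure(list(entries = data.frame(i = res$i, j = res$j, d = res$d),
                 cap = cap, n_tags = length(seqs),
                 n_alignments = res$n_alignments,
                 n_pairs = res$n_pairs,
                 n_prescreen_pass = res$n_prescreen_pass),
            class = "sparse_dist")
}

#' @export
print.sparse_dist <- function(x, ...) {
  cat("Sparse NW distance set: ", nrow(x$entries), " stored pairs among ",
      x$n_tags, " tags (cap ", x$cap, ")\n", sep = "")
  cat(format(x$n_alignments, big.mark = ","), "NW alignments performed;",
      format(x$n_pairs, big.mark = ","), "candidate pairs\n")
  invisible(x)
}

#' Export a sparse distance set as 3-column text
#'
#' Writes whitespace-separated lines \code{i j d} with 0-based tag ranks
#' (the ESPRIT/mothur column-distance dialect), so external clustering
#' tools can consume the matrix.
#'
#' @param dset a \code{"sparse_dist"} from [sparse_distances()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_sparse <- function(dset, path) {
  stopifnot(inherits(dset, "sparse_dist"))
  e <- dset$entries
  writeLines(sprintf("%d %d %.6f", e$i - 1L, e$j - 1L, e$d), path)
  invisible(path)
}

#' Import a sparse distance set from 3-column text
#'
#' @param path file of whitespace-separated \code{i j d} lines with
#'   0-based ranks.
#' @param n_tags number of tags the ranks refer to.
#' @param cap the storage cap the file was produced with.
#' @return A \code{"sparse_dist"} object (alignment counters are NA).
#' @export
read_sparse <- function(path, n_tags, cap = 0.10) {
  cols <- utils::read.table(path, col.names = c("i", "j", "d"),
                            colClasses = c("integer", "integer", "numeric"))
  if (nrow(cols) && any(cols$i >= cols$j))
    stop("expected 0-based ranks with i < j")
  structure(list(entries = data.frame(i = cols$i + 1L, j = cols$j + 1L,
                                      d = cols$d),
                 cap = cap, n_tags = as.integer(n_tags),
                 n_alignments = NA_real_, n_pairs = NA_real_,
                 n_prescreen_pass = NA_real_),
            class = "sparse_dist")
}

#' Alignment-free direct distance (precluster 2 comparison)
#'
#' Compares two sequences base by base from the 5' end and counts all
#' mismatches; a length difference adds one mismatch per overhanging base
#' and the denominator is the longer length.  This upper-bounds the NW
#' distance, so a direct distance below the clustering threshold places a
#' tag without any alignment.
#'
#' @param s1,s2 non-empty DNA strings.
#' @return The direct distance in \[0, 1\].
#' @export
direct_distance <- function(s1, s2) {
  direct_distance_cpp(toupper(s1), toupper(s2))
}
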