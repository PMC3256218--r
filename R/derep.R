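#' Read amplicon sequences from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file of finished amplicon tags.
#' Sequences are uppercased.  By default any record containing a character
#' outside A/C/G/T is rejected with an error naming the record, because the
#' pipeline assumes pre-filtered tags; with \code{allow_ambiguous = TRUE}
#' such records are kept and every base pair involving an ambiguity code is
#' treated as a mismatch downstream.
#'
#' @param path path to a FASTA file.
#' @param allow_ambiguous keep records with IUPAC ambiguity codes
#'   (default FALSE).
#' @return A data.frame with columns \code{id} and \code{seq}, one row per
#'   record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acgt", ">b", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, allow_ambiguous = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- names(set)
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  if (length(seqs)) {
    if (any(!nzchar(ids)))
      stop("malformed FASTA: record ", which(!nzchar(ids))[1],
           " has an empty header")
    empty <- !nzchar(seqs)
    if (any(empty))
      stop("malformed FASTA: record '", ids[which(empty)[1]],
           "' has an empty sequence")
    bad <- grepl("[^ACGT]", seqs)
    if (any(bad) && !allow_ambiguous)
      stop("record '", ids[which(bad)[1]], "' contains non-ACGT characters; ",
           "use allow_ambiguous = TRUE to keep ambiguity codes")
  }
  data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
}

#' Collapse reads into unique tags
#'
#' Dereplicates a set of reads into unique tags, each carrying its read
#' multiplicity (abundance), sorted from high to low abundance.  Abundance
#' ties are broken by the lexicographically smaller sequence, which makes
#' the output independent of input read order.
#'
#' @param reads a data.frame with columns \code{id} and \code{seq} (as
#'   returned by [read_fasta()]), or a character vector of sequences.
#' @return A data.frame of class \code{"tsc_tags"} with columns \code{seq},
#'   \code{abundance}, \code{rank} (0-based position in the sorted order)
#'   and \code{exemplar_id} (id of the first read carrying the sequence).
#' @examples
#' dereplicate(c("ACGT", "ACGT", "AAAA"))
#' @export
dereplicate <- function(reads) {
  if (is.character(reads))
    reads <- data.frame(id = paste0("read", seq_along(reads)), seq = reads,
                        stringsAsFactors = FALSE)
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  if (nrow(reads) == 0) {
    out <- data.frame(seq = character(), abundance = integer(),
                      rank = integer(), exemplar_id = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("tsc_tags", "data.frame")
    return(out)
  }
  first <- !duplicated(reads$seq)
  ab <- table(factor(reads$seq, levels = reads$seq[first]))
  tags <- data.frame(seq = reads$seq[first],
                     abundance = as.integer(ab),
                     exemplar_id = reads$id[first],
                     stringsAsFactors = FALSE)
  ord <- order(-tags$abundance, tags$seq, method = "radix")
  tags <- tags[ord, , drop = FALSE]
  tags$rank <- seq_len(nrow(tags)) - 1L
  rownames(tags) <- NULL
  tags <- tags[, c("seq", "abundance", "rank", "exemplar_id")]
  class(tags) <- c("tsc_tags", "data.frame")
  tags
}

#' Split tags into abundant and rare groups
#'
#' Divides abundance-sorted tags into the abundant group (abundance at or
#' above the cutoff), clustered hierarchically in stage 1, and the rare
#' group (below the cutoff), assigned greedily in stage 2.  A cutoff of 1
#' puts every tag into the abundant group.
#'
#' @param tags dereplicated tags from [dereplicate()].
#' @param cutoff minimum abundance for the abundant group, an integer >= 1
#'   (default 3).
#' @return A list of class \code{"tag_split"} with elements \code{abundant},
#'   \code{rare} (both tag data.frames preserving the global order) and
#'   \code{cutoff}.
#' @examples
#' tags <- dereplicate(rep(c("ACGT", "AAAA", "TTTT"), c(5, 3, 1)))
#' split_by_cutoff(tags, 3)
#' @export
split_by_cutoff <- function(tags, cutoff = 3) {
  cutoff <- as.integer(cutoff)
  if (is.na(cutoff) || cutoff < 1) stop("cutoff must be an integer >= 1")
  stopifnot(is.data.frame(tags))
  hi <- tags$abundance >= cutoff
  structure(list(abundant = tags[hi, , drop = FALSE],
                 rare = tags[!hi, , drop = FALSE],
                 cutoff = cutoff),
            class = "tag_split")
}

#' Write dereplicated tags as a size-annotated FASTA file
#'
#' Headers follow the usearch-style size annotation
#' \code{>exemplar_id;size=abundance}.
#'
#' @param tags dereplicated tags from [dereplicate()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_derep_fasta <- function(tags, path) {
  set <- Biostrings::DNAStringSet(tags$seq)
  names(set) <- paste0(tags$exemplar_id, ";size=", tags$abundance)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
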