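#' Alignment scoring parameters
#'
#' Parameterizes the affine-gap global (Needleman-Wunsch) alignment and the
#' distance convention derived from it.  A gap run of length L — terminal
#' runs included — is scored \code{gap_open + (L - 1) * ext}, where the
#' extension value \code{ext} is \code{gap_extend} on the Illumina platform
#' and 0 on 454 (a 454 run costs the opening penalty once, however long:
#' a single indel, matching homopolymer-dominated 454 errors).  In the
#' distance, the 454 model likewise counts each gap run once while the
#' Illumina model counts every gap column (substitution-dominated errors).
#' With \code{free_end_gaps}, terminal gap columns are excluded from the
#' distance: they are trimmed before differences are counted and do not
#' enter the denominator.
#'
#' @param match match score (default +1).
#' @param mismatch mismatch score (default -1); ambiguity codes never match.
#' @param gap_open gap opening score, must be <= 0 (default -10).
#' @param gap_extend gap extension score, must be <= 0 (default -1).
#' @param free_end_gaps logical; exclude terminal gap columns from
#'   distances (default TRUE).
#' @param platform \code{"illumina"} (per-column gap counting) or
#'   \code{"454"} (per-run gap counting, free extensions).
#' @return An object of class \code{"alignment_params"}.
#' @examples
#' alignment_params()
#' alignment_params(platform = "454")
#' @export
alignment_params <- function(match = 1, mismatch = -1, gap_open = -10,
                             gap_extend = -1, free_end_gaps = TRUE,
                             platform = c("illumina", "454")) {
  platform <- match.arg(platform)
  stopifnot(is.numeric(match), is.numeric(mismatch), is.numeric(gap_open),
            is.numeric(gap_extend))
  if (gap_open > 0) stop("gap_open must be <= 0")
  if (gap_extend > 0) stop("gap_extend must be <= 0")
  if (match <= mismatch) stop("match score must exceed mismatch score")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 free_end_gaps = isTRUE(free_end_gaps), platform = platform),
            class = "alignment_params")
}

#' k-mer prescreening parameters
#'
#' The k-mer distance is a cheap proxy used to skip hopeless alignments:
#' pairs with k-mer distance above \code{f_max} are assumed to exceed any
#' usable clustering threshold and their NW distance is never computed.
#'
#' @param k word length (default 6).
#' @param f_max maximum k-mer distance admitted to NW computation
#'   (default 0.5).
#' @return An object of class \code{"kmer_params"}.
#' @export
kmer_params <- function(k = 6, f_max = 0.5) {
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be a positive integer")
  if (!is.numeric(f_max) || f_max < 0 || f_max > 1)
    stop("f_max must be in [0, 1]")
  structure(list(k = k, f_max = f_max), class = "kmer_params")
}

#' Stage-2 greedy search parameters
#'
#' @param d assignment distance threshold (default 0.03).
#' @param batch number of NW distances evaluated per batch in the k-mer
#'   ordered search (default 10); the search continues past a batch only if
#'   that batch contained at least one hit.
#' @param shortcut logical; enable the alignment-free direct-comparison
#'   precluster before the greedy search (default TRUE).
#' @return An object of class \code{"search_params"}.
#' @export
search_params <- function(d = 0.03, batch = 10, shortcut = TRUE) {
  batch <- as.integer(batch)
  if (is.na(batch) || batch < 1) stop("batch must be >= 1")
  if (!is.numeric(d) || d <= 0 || d >= 1) stop("d must be in (0, 1)")
  structure(list(d = d, batch = batch, shortcut = isTRUE(shortcut)),
            class = "search_params")
}

# internal: alignment_params -> argument list for the C++ kernels
.ap_args <- function(ap) {
  stopifnot(inherits(ap, "alignment_params"))
  list(a = ap$match, b = ap$mismatch, g = ap$gap_open, e = ap$gap_extend,
       x = ap$free_end_gaps, r454 = identical(ap$platform, "454"))
}
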