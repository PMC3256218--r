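# Mock amplicon library generator: known templates, skewed abundances,
# bounded-distance noise reads, with ground truth for accuracy experiments.

#' Configuration for a synthetic mock amplicon library
#'
#' The generator emulates a clone-library mock community: \code{n_templates}
#' known template sequences, well separated in NW distance, are amplified
#' into reads with a skewed (power-law) abundance distribution and per-base
#' substitution/indel noise; reads farther than \code{max_noise_dist} from
#' their parent template are resampled, emulating the distance screens
#' applied to published mock datasets.  The default rates are
#' substitution-dominated (Illumina-like) and are set so that singleton
#' plus doubleton tags make up roughly 80 percent of the unique tags, the
#' upper end of the regime characteristic of real amplicon libraries, while
#' keeping repeated (multi-copy) error variants rare enough that the known
#' community is recoverable exactly at abundance cutoff 2.
#'
#' @param n_templates number of templates K (default 43, a classic mock
#'   design).
#' @param template_length template length in bases (default 80, V6-like).
#' @param min_template_dist minimum pairwise NW distance between templates
#'   (default 0.10); must exceed \code{max_noise_dist} — and exceeds twice
#'   it by default, which makes reads identifiable to their parent.
#' @param n_reads number of reads to emit (default 50000).
#' @param abundance power-law exponent (a single number; template i gets
#'   weight i^-exponent, default 1.5) or an explicit length-K weight
#'   vector.
#' @param sub_rate,ins_rate,del_rate per-base error probabilities
#'   (defaults 0.001, 2e-4, 2e-4).
#' @param max_noise_dist screening cap on read-to-parent NW distance
#'   (default 0.03).
#' @param align alignment parameters used for the screen and for template
#'   separation checks.
#' @param seed RNG seed (default 1).
#' @return A list of class \code{"mock_config"}.
#' @export
mock_config <- function(n_templates = 43, template_length = 80,
                        min_template_dist = 0.10, n_reads = 50000,
                        abundance = 1.5, sub_rate = 0.001,
                        ins_rate = 2e-4, del_rate = 2e-4,
                        max_noise_dist = 0.03,
                        align = alignment_params(), seed = 1) {
  stopifnot(n_templates >= 1, template_length >= 20, n_reads >= 1)
  if (min_template_dist <= max_noise_dist)
    stop("min_template_dist must exceed max_noise_dist")
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates >= 1)) stop("rates must be in [0, 1)")
  if (length(abundance) > 1 && length(abundance) != n_templates)
    stop("explicit abundance vector must have one weight per template")
  structure(list(n_templates = as.integer(n_templates),
                 template_length = as.integer(template_length),
                 min_template_dist = min_template_dist,
                 n_reads = as.integer(n_reads), abundance = abundance,
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, max_noise_dist = max_noise_dist,
                 align = align, seed = as.integer(seed)),
            class = "mock_config")
}

#' Generate well-separated template sequences
#'
#' Draws random templates by rejection sampling: a candidate is kept only
#' if its NW distance to every accepted template is at least
#' \code{min_template_dist}.  Reproducible from the config seed.
#'
#' @param cfg a [mock_config()].
#' @param max_tries rejection-sampling budget per template (default 200).
#' @return A character vector of K templates named \code{T001}, ...
#' @export
generate_templates <- function(cfg, max_tries = 200) {
  stopifnot(inherits(cfg, "mock_config"))
  set.seed(cfg$seed)
  p <- .ap_args(cfg$align)
  out <- character(cfg$n_templates)
  for (i in seq_len(cfg$n_templates)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- paste(sample(c("A", "C", "G", "T"), cfg$template_length,
                           replace = TRUE), collapse = "")
      sep <- TRUE
      if (i > 1) {
        dd <- nw_distance_many_cpp(cand, out[seq_len(i - 1)], p$a, p$b,
                                   p$g, p$e, p$x, p$r454)
        sep <- all(dd >= cfg$min_template_dist)
      }
      if (sep) { out[i] <- cand; ok <- TRUE; break }
    }
    if (!ok)
      stop("could not place template ", i, " at minimum distance ",
           cfg$min_template_dist, " within ", max_tries,
           " tries; use longer templates or fewer of them")
  }
  names(out) <- sprintf("T%03d", seq_len(cfg$n_templates))
  out
}

#' Generate mock reads with ground truth
#'
#' Template weights follow the configured abundance model; every template
#' is guaranteed at least one read, and the remainder is multinomial.
#' Each read copies its template and applies per-base substitutions and
#' indels; reads exceeding \code{max_noise_dist} NW distance from their
#' parent are resampled (the screen emulating published "97up"-style mock
#' datasets).
#'
#' @param templates templates from [generate_templates()].
#' @param cfg the same [mock_config()].
#' @return A list with \code{reads} (data.frame \code{id}, \code{seq}),
#'   \code{truth} (data.frame \code{read_id}, \code{template_id}) and
#'   \code{template_counts}.
#' @export
generate_reads <- function(templates, cfg) {
  stopifnot(inherits(cfg, "mock_config"),
            length(templates) == cfg$n_templates)
  set.seed(cfg$seed + 1L)
  K <- cfg$n_templates
  w <- if (length(cfg$abundance) == 1)
    seq_len(K)^(-cfg$abundance) else cfg$abundance
  w <- w / sum(w)
  n <- cfg$n_reads
  extra <- max(n - K, 0L)
  counts <- rep(1L, K)
  if (extra > 0)
    counts <- counts + as.integer(stats::rmultinom(1, extra, w))
  if (n < K) counts <- as.integer(stats::rmultinom(1, n, w))
  parent <- sample(rep.int(seq_len(K), counts))  # shuffle read order
  p <- .ap_args(cfg$align)
  res <- mutate_reads_cpp(unname(templates), parent, cfg$sub_rate,
                          cfg$ins_rate, cfg$del_rate, p$a, p$b, p$g, p$e,
                          p$x, p$r454, cfg$max_noise_dist, 50L)
  ids <- sprintf("R%06d", seq_len(n))
  list(reads = data.frame(id = ids, seq = as.character(res$reads),
                          stringsAsFactors = FALSE),
       truth = data.frame(read_id = ids,
                          template_id = names(templates)[parent],
                          stringsAsFactors = FALSE),
       template_counts = stats::setNames(counts, names(templates)))
}

#' Write a mock fixture to disk
#'
#' Emits \code{reads.fasta}, the ground truth \code{truth.tsv} (read_id,
#' template_id), \code{templates.fasta} and a flat \code{manifest.txt}
#' (key=value lines) sufficient to regenerate the fixture exactly.
#'
#' @param cfg a [mock_config()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the list from [generate_reads()] plus
#'   \code{templates}.
#' @export
write_mock_fixture <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  templates <- generate_templates(cfg)
  gen <- generate_reads(templates, cfg)
  tset <- Biostrings::DNAStringSet(templates)
  Biostrings::writeXStringSet(tset, file.path(dir, "templates.fasta"))
  rset <- Biostrings::DNAStringSet(gen$reads$seq)
  names(rset) <- gen$reads$id
  Biostrings::writeXStringSet(rset, file.path(dir, "reads.fasta"))
  utils::write.table(gen$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  man <- c(n_templates = cfg$n_templates,
           template_length = cfg$template_length,
           min_template_dist = cfg$min_template_dist,
           n_reads = cfg$n_reads,
           abundance = paste(cfg$abundance, collapse = ","),
           sub_rate = cfg$sub_rate, ins_rate = cfg$ins_rate,
           del_rate = cfg$del_rate, max_noise_dist = cfg$max_noise_dist,
           platform = cfg$align$platform, seed = cfg$seed)
  writeLines(paste0(names(man), "=", unname(man)),
             file.path(dir, "manifest.txt"))
  invisible(c(gen, list(templates = templates)))
}
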