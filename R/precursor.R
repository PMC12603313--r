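# miRNA precursor candidate identification: locate the mature miRNA, fold
# the locus, require the miRNA to sit in the stem of a stem-loop, and apply
# the precursor-miRNA expression-correlation filter.

#' Locate a mature miRNA within a transcript
#'
#' Finds all occurrences of the mature miRNA in the transcript with U/T
#' equivalence; exact matching by default (`max_mismatch = 0`), with a
#' mismatch allowance for degraded assemblies. Transcripts without any
#' occurrence are discarded upstream of precursor folding.
#'
#' @param transcript transcript row (from [read_fasta()]) or nucleotide
#'   string.
#' @param mirna mature miRNA sequence (RNA or DNA alphabet, typically
#'   19-24 nt).
#' @param max_mismatch maximum number of mismatches (default 0).
#' @return `data.frame` with 0-based half-open `start`/`end` spans, one row
#'   per occurrence.
#' @export
locate_mature <- function(transcript, mirna, max_mismatch = 0) {
  stopifnot(max_mismatch >= 0)
  seq <- if (is.data.frame(transcript)) transcript$seq[1] else transcript
  seq <- .to_dna(seq)
  pat <- .to_dna(mirna)
  if (nchar(pat) > nchar(seq)) {
    return(data.frame(start = integer(), end = integer()))
  }
  m <- Biostrings::matchPattern(pat, Biostrings::DNAString(seq),
                                max.mismatch = max_mismatch)
  data.frame(start = IRanges::start(m) - 1L, end = IRanges::end(m))
}

#' Fold an RNA window by maximum base pairing
#'
#' Nussinov-style dynamic program: the maximum-cardinality nested set of
#' Watson-Crick plus G:U pairs with hairpin loops of at least `min_loop`
#' unpaired bases. This deliberately replaces thermodynamic energy
#' minimisation with an oracle-verifiable pairing model; the stem/loop
#' membership question asked of it is robust to the energy model for
#' designed constructs. Traceback is deterministic (prefer leaving the
#' 5'-most base unpaired, then the smallest pairing partner).
#'
#' @param seq RNA (or DNA) string; length at most `max_window`.
#' @param min_loop minimum hairpin loop size (default 3).
#' @param max_window guard against accidental whole-genome folds
#'   (default 400); raise it explicitly for longer windows.
#' @return Object of class `"fold_result"`: list with `seq` (RNA), dot-
#'   bracket `structure`, `pairs` (two-column 1-based matrix, i < j),
#'   `n_pairs` and `energy_proxy` (= `n_pairs`).
#' @examples
#' fold_window("GGGAAACCC")
#' @export
fold_window <- function(seq, min_loop = 3, max_window = 400) {
  stopifnot(min_loop >= 3)
  rna <- .to_rna(seq)
  .check_rna(rna, "fold window")
  if (nchar(rna) > max_window) {
    stop("window of ", nchar(rna), " nt exceeds max_window = ", max_window,
         "; raise max_window to fold longer sequences", call. = FALSE)
  }
  res <- .nussinov_fold(rna, as.integer(min_loop))
  pairs <- res$pairs + 1L                       # 1-based
  colnames(pairs) <- c("i", "j")
  structure(list(seq = rna, structure = res$structure, pairs = pairs,
                 n_pairs = res$n_pairs, energy_proxy = res$n_pairs),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("Fold of %d nt: %d pairs (maximum base pairing, WC + G:U)\n",
              nchar(x$seq), x$n_pairs))
  if (nchar(x$seq) <= 80) {
    cat(" ", x$seq, "\n ", x$structure, "\n")
  }
  invisible(x)
}

#' Assess whether a mature miRNA lies within the stem of a stem-loop
#'
#' Given a fold of the candidate window and the miRNA span within it, the
#' miRNA is *in the stem* when (i) at least `min_paired_frac` of its bases
#' are paired, (ii) none of its bases pairs with another base of the span
#' itself, (iii) all pairing partners lie on one side of the span (the
#' opposite arm), and (iv) the pairs are nested in stem order (partner
#' positions strictly decrease along the miRNA). Candidates whose miRNA
#' sits in a loop, spans an arm/loop junction, or folds onto itself fail.
#'
#' @param fold `"fold_result"` for the window (see [fold_window()]).
#' @param span 0-based half-open miRNA span *within the window*, as a
#'   two-element vector `c(start, end)`.
#' @param cfg configuration; uses `min_paired_frac`.
#' @return Object of class `"precursor_candidate"`: list with `in_stem`,
#'   `paired_fraction`, `arm` (`"5p"`, `"3p"`, `"spanning"` or `"unpaired"`),
#'   `star_span` (0-based half-open extent of the partner arm with the
#'   conventional 2-nt offset at its 3' end, or `NULL`), plus the inputs.
#' @export
assess_stem_membership <- function(fold, span, cfg = miraux_config()) {
  n <- nchar(fold$seq)
  if (span[1] < 0 || span[2] > n || span[2] <= span[1]) {
    stop("miRNA span [", span[1], ", ", span[2],
         ") lies outside the folded window of ", n, " nt", call. = FALSE)
  }
  pos <- seq(span[1] + 1L, span[2])             # 1-based window positions
  partner <- rep(NA_integer_, n)
  if (nrow(fold$pairs) > 0) {
    partner[fold$pairs[, 1]] <- fold$pairs[, 2]
    partner[fold$pairs[, 2]] <- fold$pairs[, 1]
  }
  part <- partner[pos]
  paired <- !is.na(part)
  paired_fraction <- mean(paired)
  self_paired <- any(part[paired] %in% pos)
  pp <- part[paired]
  arm <- if (!any(paired)) "unpaired"
         else if (self_paired) "spanning"
         else if (all(pp > span[2])) "5p"
         else if (all(pp <= span[1])) "3p"
         else "spanning"
  stem_ordered <- !any(paired) || all(diff(pp) < 0)  # nested along the miRNA
  in_stem <- paired_fraction >= cfg$min_paired_frac && !self_paired &&
             arm %in% c("5p", "3p") && stem_ordered
  star_span <- NULL
  if (any(paired) && !self_paired && arm %in% c("5p", "3p")) {
    # partner-arm extent with the canonical 2-nt 3' offset of the star strand
    star_span <- c(min(pp) - 1L, min(max(pp) + 2L, n))
  }
  structure(list(in_stem = in_stem, paired_fraction = paired_fraction,
                 arm = arm, star_span = star_span, span = span, fold = fold),
            class = "precursor_candidate")
}

#' @export
print.precursor_candidate <- function(x, ...) {
  cat(sprintf("Precursor candidate: in_stem %s (paired fraction %.2f, arm %s)\n",
              x$in_stem, x$paired_fraction, x$arm))
  invisible(x)
}

#' Spearman correlation filter for precursor-miRNA pairs
#'
#' Computes the Spearman rank correlation (average ranks for ties) between a
#' mature miRNA's RPM profile and a candidate precursor's FPKM profile over
#' paired samples. The pair passes when rho strictly exceeds the threshold.
#' Zero variance in either profile leaves rho undefined (flagged, fails).
#'
#' @param mirna_rpm,precursor_fpkm numeric vectors over the same samples
#'   (length >= 3).
#' @param threshold pass threshold, strict `>` (default 0.5).
#' @return One-row `data.frame` with `rho`, `n_samples`, `passes`,
#'   `flagged`.
#' @export
correlate_expression <- function(mirna_rpm, precursor_fpkm, threshold = 0.5) {
  stopifnot(length(mirna_rpm) == length(precursor_fpkm),
            length(mirna_rpm) >= 3)
  if (sd(mirna_rpm) == 0 || sd(precursor_fpkm) == 0) {
    return(data.frame(rho = NA_real_, n_samples = length(mirna_rpm),
                      passes = FALSE, flagged = TRUE))
  }
  rho <- cor(mirna_rpm, precursor_fpkm, method = "spearman")
  data.frame(rho = rho, n_samples = length(mirna_rpm),
             passes = rho > threshold, flagged = FALSE)
}

#' Identify miRNA precursor candidates in a transcript set
#'
#' For every transcript x miRNA combination: locate the mature sequence
#' ([locate_mature()]), fold a window of `cfg$flank` nt context on each side
#' ([fold_window()]), and assess stem membership
#' ([assess_stem_membership()]). Windowing bounds the folding cost relative
#' to folding whole transcripts and is configurable.
#'
#' @param transcripts transcript table from [read_fasta()].
#' @param mirnas miRNA table from [read_fasta()] (ids + sequences).
#' @param cfg configuration, see [miraux_config()].
#' @return `data.frame` with one row per located occurrence: transcript and
#'   miRNA ids, transcript-level span, `in_stem`, `paired_fraction`, `arm`,
#'   the dot-bracket structure of the window, and star-span coordinates.
#' @export
find_precursors <- function(transcripts, mirnas, cfg = miraux_config()) {
  out <- list()
  for (ti in seq_len(nrow(transcripts))) {
    tseq <- transcripts$seq[ti]
    for (mi in seq_len(nrow(mirnas))) {
      hits <- locate_mature(tseq, mirnas$seq[mi],
                            max_mismatch = cfg$max_mismatch)
      if (nrow(hits) == 0) next
      for (h in seq_len(nrow(hits))) {
        w0 <- max(0L, hits$start[h] - cfg$flank)
        w1 <- min(nchar(tseq), hits$end[h] + cfg$flank)
        window <- substring(tseq, w0 + 1L, w1)
        fold <- fold_window(window, min_loop = cfg$min_loop,
                            max_window = max(cfg$max_window, nchar(window)))
        cand <- assess_stem_membership(
          fold, c(hits$start[h] - w0, hits$end[h] - w0), cfg)
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = transcripts$id[ti], mirna_id = mirnas$id[mi],
          mirna_start = hits$start[h], mirna_end = hits$end[h],
          window_start = w0, window_end = w1,
          in_stem = cand$in_stem, paired_fraction = cand$paired_fraction,
          arm = cand$arm,
          star_start = if (is.null(cand$star_span)) NA_integer_
                       else cand$star_span[1] + w0,
          star_end = if (is.null(cand$star_span)) NA_integer_
                     else cand$star_span[2] + w0,
          structure = fold$structure,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(transcript_id = character(), mirna_id = character(),
                      mirna_start = integer(), mirna_end = integer(),
                      window_start = integer(), window_end = integer(),
                      in_stem = logical(), paired_fraction = numeric(),
                      arm = character(), star_start = integer(),
                      star_end = integer(), structure = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
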