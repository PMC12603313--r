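# Complete-ORF finding and translation.

.codon_translate <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"          # ambiguity (N-containing codons) -> X
  aa
}

.is_stop <- function(codon) codon %in% c("TAA", "TAG", "TGA")

#' Find complete open reading frames
#'
#' Scans a transcript in three frames on one or both strands for ORFs that
#' start with `ATG`, end at a stop codon, and encode at least `min_aa`
#' residues. Every qualifying (start, first in-frame stop) pair is reported,
#' including nested ORFs sharing a stop. Codons containing `N` translate to
#' `X` and are never treated as start or stop codons.
#'
#' Coordinates are 0-based half-open on the reported strand (`cds_start` is
#' the first base of the `ATG`, `cds_end` one past the stop codon). The
#' terminal stop is not part of `aa_seq`.
#'
#' @param transcript a single-row transcript `data.frame` (from
#'   [read_fasta()]) or a nucleotide string.
#' @param min_aa minimum number of encoded residues (default 50, excluding
#'   the stop); spurious micro-ORFs are excluded by this floor.
#' @param strand `"both"` (default), `"+"` or `"-"`. mRNA-level analyses use
#'   `"+"` only.
#' @return A `data.frame` with columns `transcript_id`, `strand`, `frame`,
#'   `cds_start`, `cds_end`, `aa_seq`, `n_aa`, `complete`, sorted by
#'   decreasing ORF length. Zero rows when no ORF qualifies.
#' @examples
#' find_complete_orfs("ATGGCTTAA", min_aa = 1, strand = "+")
#' @export
find_complete_orfs <- function(transcript, min_aa = 50, strand = "both") {
  stopifnot(min_aa >= 1)
  strand <- match.arg(strand, c("both", "+", "-"))
  if (is.data.frame(transcript)) {
    id <- transcript$id[1]
    seq <- transcript$seq[1]
  } else {
    id <- "seq"
    seq <- transcript
  }
  seq <- .to_dna(seq)
  strands <- if (strand == "both") c("+", "-") else strand
  out <- list()
  for (st in strands) {
    s <- if (st == "+") seq else .revcomp(seq)
    n <- nchar(s)
    for (fr in 0:2) {
      n_codons <- (n - fr) %/% 3
      if (n_codons < 2) next
      starts_pos <- fr + 3 * (seq_len(n_codons) - 1)        # 0-based
      codons <- substring(s, starts_pos + 1, starts_pos + 3)
      stop_idx <- which(.is_stop(codons))
      atg_idx <- which(codons == "ATG")
      if (length(stop_idx) == 0 || length(atg_idx) == 0) next
      # first in-frame stop at or after each ATG
      nxt <- findInterval(atg_idx, stop_idx) + 1L
      ok <- nxt <= length(stop_idx)
      atg_idx <- atg_idx[ok]
      stops <- stop_idx[nxt[ok]]
      n_aa <- stops - atg_idx                                # stop excluded
      keep <- n_aa >= min_aa
      if (!any(keep)) next
      atg_idx <- atg_idx[keep]
      stops <- stops[keep]
      n_aa <- n_aa[keep]
      aa <- vapply(seq_along(atg_idx), function(k) {
        cds <- codons[atg_idx[k]:(stops[k] - 1)]
        paste(.codon_translate(cds), collapse = "")
      }, character(1))
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = id, strand = st, frame = fr,
        cds_start = starts_pos[atg_idx],
        cds_end = starts_pos[stops] + 3L,
        aa_seq = aa, n_aa = n_aa, complete = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(transcript_id = character(), strand = character(),
                      frame = integer(), cds_start = integer(),
                      cds_end = integer(), aa_seq = character(),
                      n_aa = integer(), complete = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$n_aa, res$strand, res$cds_start, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Longest complete ORF per transcript
#'
#' Convenience selector used by the classification stages: when a transcript
#' carries several complete ORFs, all are found by [find_complete_orfs()] and
#' the longest (ties: leftmost on the + strand) is retained, with the number
#' of alternatives recorded in `n_orfs`.
#'
#' @param transcripts transcript table from [read_fasta()].
#' @param min_aa minimum encoded length, see [find_complete_orfs()].
#' @param strand strand selection, default `"+"` (transcripts are mRNAs).
#' @return ORF table with one row per transcript that has a complete ORF.
#' @export
longest_orfs <- function(transcripts, min_aa = 50, strand = "+") {
  rows <- lapply(seq_len(nrow(transcripts)), function(k) {
    o <- find_complete_orfs(transcripts[k, ], min_aa = min_aa, strand = strand)
    if (nrow(o) == 0) return(NULL)
    o1 <- o[1, , drop = FALSE]
    o1$n_orfs <- nrow(o)
    o1$annotation <- transcripts$annotation[k]
    o1
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- find_complete_orfs("A", min_aa = 1)[0, ]
    out$n_orfs <- integer()
    out$annotation <- character()
    return(out)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
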