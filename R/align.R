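# Pairwise global alignment used for residue anchoring.

.subst_matrix <- function(params) {
  if (is.matrix(params$matrix)) return(params$matrix)
  name <- if (is.null(params$matrix)) "BLOSUM62" else params$matrix
  get(data(list = name, package = "Biostrings", envir = environment()))
}

#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment (via [Biostrings::pairwiseAlignment()])
#' returning an *alignment anchor*: the per-column correspondence between the
#' two sequences, used to transfer reference residue numbering onto a query.
#' A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param a,b amino-acid strings (reference and query). Symbols outside the
#'   20 standard residues plus `X` are rejected.
#' @param params list with elements `matrix` (substitution matrix name such
#'   as `"BLOSUM62"`, the default, or an explicit numeric matrix),
#'   `gap_open` (default 10) and `gap_extend` (default 1).
#' @param ref_id,query_id identifiers carried into the result.
#' @return An object of class `"alignment_anchor"`: a list with `score`,
#'   `identity` (fraction of matching residues over columns where both
#'   sequences have a residue), gapped alignment strings `ref_aln` /
#'   `query_aln`, and `pairs`, a `data.frame` mapping 1-based `ref_pos` to
#'   `query_pos` (`NA` where the reference residue faces a gap).
#' @examples
#' global_align("MKLV", "MKIV")$identity
#' @export
global_align <- function(a, b, params = list(), ref_id = "ref",
                         query_id = "query") {
  stopifnot(nzchar(a), nzchar(b))
  .check_aa(a, "first sequence")
  .check_aa(b, "second sequence")
  gap_open <- if (is.null(params$gap_open)) 10 else params$gap_open
  gap_extend <- if (is.null(params$gap_extend)) 1 else params$gap_extend
  mat <- .subst_matrix(params)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  ra <- as.character(Biostrings::alignedPattern(pa))
  qa <- as.character(Biostrings::alignedSubject(pa))
  rc <- strsplit(ra, "")[[1]]
  qc <- strsplit(qa, "")[[1]]
  ref_pos <- cumsum(rc != "-")
  query_pos <- cumsum(qc != "-")
  keep <- rc != "-"
  pairs <- data.frame(
    ref_pos = ref_pos[keep],
    query_pos = ifelse(qc[keep] == "-", NA_integer_, query_pos[keep]),
    ref_aa = rc[keep],
    query_aa = ifelse(qc[keep] == "-", "-", qc[keep]),
    stringsAsFactors = FALSE)
  both <- rc != "-" & qc != "-"
  identity <- if (any(both)) mean(rc[both] == qc[both]) else 0
  structure(list(ref_id = ref_id, query_id = query_id,
                 score = Biostrings::score(pa), identity = identity,
                 ref_aln = ra, query_aln = qa, pairs = pairs),
            class = "alignment_anchor")
}

#' @export
print.alignment_anchor <- function(x, ...) {
  cat(sprintf("Global alignment %s vs %s: score %.1f, identity %.3f over %d columns\n",
              x$ref_id, x$query_id, x$score, x$identity, nchar(x$ref_aln)))
  invisible(x)
}

# Query residues aligned to given 1-based reference positions ("-" for gap).
.query_at_ref <- function(anchor, ref_pos) {
  idx <- match(ref_pos, anchor$pairs$ref_pos)
  out <- anchor$pairs$query_aa[idx]
  out[is.na(out)] <- "-"
  out
}
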