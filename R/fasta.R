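#' Read transcripts from a FASTA file
#'
#' Parses a (nucleotide or protein) FASTA file into a transcript table. The
#' part of each description line after the first whitespace is stored as the
#' record's annotation (e.g. `"TIR1"`, `"ARF"`). For nucleotide input, uracil
#' is normalised to thymine so that all downstream coordinates refer to a
#' single DNA-alphabet representation; folding and target scoring convert back
#' to RNA internally.
#'
#' @param path path to a FASTA file.
#' @param type `"DNA"` (default; applies the U->T normalisation) or `"AA"`.
#' @return A `data.frame` with columns `id`, `seq` and `annotation`, one row
#'   per record. An empty file yields a zero-row table.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">t1 TIR1", "AUGGCUUAA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  hdr <- names(set)
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", hdr)
  ann <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  for (k in seq_along(seqs)) {
    if (is.na(ids[k]) || !nzchar(ids[k])) {
      stop("malformed header for record ", k, " in ", path, call. = FALSE)
    }
    if (!nzchar(seqs[k])) {
      stop("empty sequence for record ", k, " (", ids[k], ") in ", path,
           call. = FALSE)
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- if (type == "DNA") .to_dna(seqs) else toupper(seqs)
  data.frame(id = ids, seq = unname(seqs), annotation = unname(ann),
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param x a `data.frame` with columns `id`, `seq` and optionally
#'   `annotation`, as returned by [read_fasta()], or a named character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    x <- data.frame(id = names(x), seq = unname(x), annotation = "",
                    stringsAsFactors = FALSE)
  }
  ann <- if ("annotation" %in% names(x)) x$annotation else rep("", nrow(x))
  hdr <- ifelse(nzchar(ann), paste(x$id, ann), x$id)
  out <- character(2L * nrow(x))
  out[c(TRUE, FALSE)] <- paste0(">", hdr)
  out[c(FALSE, TRUE)] <- x$seq
  writeLines(out, path)
  invisible(path)
}
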