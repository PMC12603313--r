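# Position frequency matrices (sequence-logo precursors).

#' Build a position frequency matrix
#'
#' Counts symbols per column over a set of equal-length sequences (e.g.
#' mature miRNAs or their target sites), the tabular form of a sequence logo.
#'
#' @param seqs character vector of equal-length sequences.
#' @param alphabet ordered symbol set; every symbol occurring in `seqs` must
#'   be in it. Default RNA alphabet `A, C, G, U`.
#' @return Object of class `"pfm"`: list with `counts` (positions x symbols
#'   integer matrix), `freqs` (`counts / n_seqs`) and `n_seqs`.
#' @examples
#' build_pfm(c("AC", "AC"))
#' @export
build_pfm <- function(seqs, alphabet = c("A", "C", "G", "U")) {
  stopifnot(length(seqs) > 0)
  seqs <- toupper(chartr("T", "U", seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    stop("sequences must all have the same length (got lengths ",
         paste(sort(unique(lens)), collapse = ", "), ")", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(seqs, ""))
  bad <- setdiff(unique(as.vector(chars)), alphabet)
  if (length(bad) > 0) {
    stop("symbols outside the alphabet: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- t(apply(chars, 2, function(col) {
    table(factor(col, levels = alphabet))
  }))
  counts <- matrix(as.integer(counts), nrow = lens[1],
                   dimnames = list(NULL, alphabet))
  structure(list(counts = counts, freqs = counts / length(seqs),
                 n_seqs = length(seqs)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("Position frequency matrix: %d positions, %d sequences\n",
              nrow(x$counts), x$n_seqs))
  print(utils::head(x$counts, 5))
  if (nrow(x$counts) > 5) cat("...\n")
  invisible(x)
}

#' Export a position frequency matrix as TSV
#'
#' Rows are positions (1-based), columns the alphabet symbols.
#'
#' @param pfm object from [build_pfm()].
#' @param path output path.
#' @param what `"counts"` (default) or `"freqs"`.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path, what = c("counts", "freqs")) {
  what <- match.arg(what)
  m <- pfm[[what]]
  df <- data.frame(position = seq_len(nrow(m)), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
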