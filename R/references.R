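# Packaged reference proteins and their annotated spans.
#
# The shipped references are synthetic stand-ins: random protein backbones
# with the functionally characterised residues planted at their literature
# positions (AtTIR1 numbering for the receptor: orientation residues Lys-410,
# Ser-440, Gly-441, Ala-464, Phe-465; selectivity residues Cys-405, Ser-438,
# Leu-439, Ser-440, Ser-462, Arg-489). They carry the residue grammar needed
# by the classifiers, not the evolutionary context of the real proteins; see
# the methods vignette.

#' Load the packaged reference protein set
#'
#' Reads the synthetic reference proteins and their span/residue annotation
#' (F-box and LRR spans, binding-pocket and AC-domain residues for the
#' TIR1/AFB reference; DBD/DD/PB1 spans, canonical PB1 lysine column and OPCA
#' window for the ARF reference).
#'
#' @param fasta,config optional paths overriding the packaged files, e.g. to
#'   supply real curated references.
#' @return List of class `"reference_set"` with elements `tir` and `arf`.
#' @export
reference_set <- function(fasta = NULL, config = NULL) {
  if (is.null(fasta)) {
    fasta <- system.file("extdata", "reference_proteins_synthetic.fasta",
                         package = "miraux", mustWork = TRUE)
  }
  if (is.null(config)) {
    config <- system.file("extdata", "reference_config_synthetic.json",
                          package = "miraux", mustWork = TRUE)
  }
  seqs <- read_fasta(fasta, type = "AA")
  cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
  tir_seq <- seqs$seq[seqs$id == cfg$tir$id]
  arf_seq <- seqs$seq[seqs$id == cfg$arf$id]
  if (length(tir_seq) != 1 || length(arf_seq) != 1) {
    stop("reference FASTA does not contain the ids named in the reference ",
         "configuration", call. = FALSE)
  }
  ref <- list(
    tir = list(id = cfg$tir$id, seq = tir_seq,
               fbox = as.integer(cfg$tir$fbox), lrr = as.integer(cfg$tir$lrr),
               pocket = as.data.frame(cfg$tir$pocket),
               ac = as.data.frame(cfg$tir$ac)),
    arf = list(id = cfg$arf$id, seq = arf_seq,
               dbd = as.integer(cfg$arf$dbd), dd = as.integer(cfg$arf$dd),
               pb1 = as.integer(cfg$arf$pb1),
               pb1_k = as.integer(cfg$arf$pb1_k),
               opca = as.integer(cfg$arf$opca)))
  # self-consistency: annotated residues must match the shipped sequences
  pk <- ref$tir$pocket
  obs <- substring(tir_seq, pk$pos, pk$pos)
  if (any(obs != pk$aa)) {
    stop("reference configuration disagrees with the reference sequence at ",
         "pocket position(s) ", paste(pk$pos[obs != pk$aa], collapse = ", "),
         call. = FALSE)
  }
  ac <- ref$tir$ac
  obs <- substring(tir_seq, ac$pos, ac$pos)
  if (any(obs != ac$aa)) {
    stop("reference configuration disagrees with the reference sequence at ",
         "AC position(s) ", paste(ac$pos[obs != ac$aa], collapse = ", "),
         call. = FALSE)
  }
  if (substring(arf_seq, ref$arf$pb1_k, ref$arf$pb1_k) != "K") {
    stop("ARF reference: canonical PB1 lysine column does not hold K",
         call. = FALSE)
  }
  structure(ref, class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Reference set:\n")
  cat(sprintf("  TIR1/AFB: %s (%d aa), F-box %d-%d, LRR %d-%d, %d pocket + %d AC residues\n",
              x$tir$id, nchar(x$tir$seq), x$tir$fbox[1], x$tir$fbox[2],
              x$tir$lrr[1], x$tir$lrr[2], nrow(x$tir$pocket), nrow(x$tir$ac)))
  cat(sprintf("  ARF:      %s (%d aa), DBD %d-%d, DD %d-%d, PB1 %d-%d (K at %d, OPCA %d-%d)\n",
              x$arf$id, nchar(x$arf$seq), x$arf$dbd[1], x$arf$dbd[2],
              x$arf$dd[1], x$arf$dd[2], x$arf$pb1[1], x$arf$pb1[2],
              x$arf$pb1_k, x$arf$opca[1], x$arf$opca[2]))
  invisible(x)
}
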