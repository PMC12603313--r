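# Rule-based functional curation of TIR1/AFB receptor and ARF transcription
# factor candidates. Profile-HMM domain scans are replaced by identity-
# threshold alignment against packaged reference domains, which keeps every
# call deterministic and tunable; thresholds live in miraux_config().

.align_params <- function(cfg) {
  list(matrix = cfg$substitution_matrix, gap_open = cfg$gap_open,
       gap_extend = cfg$gap_extend)
}

.protein_seq <- function(p) {
  if (is.data.frame(p)) {
    list(id = p$transcript_id[1], aa = p$aa_seq[1],
         complete = isTRUE(p$complete[1]))
  } else {
    list(id = "protein", aa = as.character(p), complete = TRUE)
  }
}

# Align a reference domain segment into a query (pattern-global within
# subject-local); identity is counted over the full reference segment so that
# truncations lower it.
.domain_hit <- function(ref_seg, query, params) {
  mat <- .subst_matrix(params)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref_seg), Biostrings::AAString(query),
    substitutionMatrix = mat, gapOpening = params$gap_open,
    gapExtension = params$gap_extend, type = "global-local")
  rc <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  qc <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ref_pos <- cumsum(rc != "-")
  q_off <- IRanges::start(Biostrings::subject(pa)) - 1L
  query_pos <- cumsum(qc != "-") + q_off
  keep <- rc != "-"
  pairs <- data.frame(
    ref_pos = ref_pos[keep],
    query_pos = ifelse(qc[keep] == "-", NA_integer_, query_pos[keep]),
    ref_aa = rc[keep],
    query_aa = ifelse(qc[keep] == "-", "-", qc[keep]),
    stringsAsFactors = FALSE)
  list(identity = mean(pairs$query_aa == pairs$ref_aa),
       start = IRanges::start(Biostrings::subject(pa)),
       end = IRanges::end(Biostrings::subject(pa)),
       pairs = pairs)
}

#' Check conservation of reference-anchored residues in a query protein
#'
#' Transfers 1-based reference residue numbering onto a query through a
#' global alignment and reports, per position, the query residue facing that
#' reference column. A gap is reported as non-conserved with `query_aa "-"`.
#' The supplied expected residues are cross-checked against the reference
#' sequence itself, so silent numbering drift is a configuration error, not a
#' wrong answer.
#'
#' @param query query protein: an ORF table row or an amino-acid string.
#' @param ref reference protein sequence (string).
#' @param positions `data.frame` with columns `pos` (1-based reference
#'   position), `aa` (expected reference residue) and `role`.
#' @param cfg configuration, see [miraux_config()].
#' @param ref_name reference label carried into the report.
#' @param anchor optional precomputed [global_align()] result (reference as
#'   first sequence) to avoid re-aligning.
#' @return `data.frame` with columns `ref_name`, `ref_pos`, `ref_aa`,
#'   `query_aa`, `conserved`, `role`.
#' @export
anchor_residues <- function(query, ref, positions, cfg = miraux_config(),
                            ref_name = "ref", anchor = NULL) {
  q <- .protein_seq(query)
  ref_aa_obs <- substring(ref, positions$pos, positions$pos)
  if (any(ref_aa_obs != positions$aa)) {
    bad <- positions$pos[ref_aa_obs != positions$aa]
    stop("reference/position mismatch at ", ref_name, " position(s) ",
         paste(bad, collapse = ", "),
         ": expected residues do not match the reference sequence",
         call. = FALSE)
  }
  if (is.null(anchor)) {
    anchor <- global_align(ref, q$aa, .align_params(cfg),
                           ref_id = ref_name, query_id = q$id)
  }
  qaa <- .query_at_ref(anchor, positions$pos)
  data.frame(ref_name = ref_name, ref_pos = positions$pos,
             ref_aa = positions$aa, query_aa = qaa,
             conserved = qaa == positions$aa, role = positions$role,
             stringsAsFactors = FALSE)
}

#' Classify a candidate TIR1/AFB auxin receptor
#'
#' Reproduces the manual-revision funnel for F-box auxin receptors: an F-box
#' call (alignment identity over the reference F-box span), an LRR-ring
#' completeness check (aligned fraction of the reference LRR region; an
#' incomplete ring cannot close the auxin docking pocket), conservation of
#' the 11 binding-pocket residue checks (5 ligand-orientation + 6 ligand-
#' selectivity positions in AtTIR1 numbering; Ser-440 belongs to both sets),
#' and the three adenylate-cyclase key positions (first expected Asn). An AC
#' substitution is reported but does not revoke receptor status.
#'
#' @param p complete-ORF protein (ORF table row or amino-acid string).
#' @param refs reference set from [reference_set()].
#' @param cfg configuration, see [miraux_config()].
#' @return Object of class `"tir_afb_report"`: list with `protein_id`,
#'   `has_fbox`, `fbox_quality`, `lrr_coverage`, `pocket_checks`,
#'   `ac_checks`, `verdict` (one of `"receptor"`, `"incomplete"`,
#'   `"rejected"`) and `reason`.
#' @export
classify_tir_afb <- function(p, refs = reference_set(), cfg = miraux_config()) {
  q <- .protein_seq(p)
  if (!q$complete) {
    return(structure(list(protein_id = q$id, has_fbox = FALSE,
                          fbox_quality = NA_real_, lrr_coverage = NA_real_,
                          pocket_checks = NULL, ac_checks = NULL,
                          verdict = "rejected",
                          reason = "incomplete ORF"),
                     class = "tir_afb_report"))
  }
  ref <- refs$tir
  anchor <- global_align(ref$seq, q$aa, .align_params(cfg),
                         ref_id = ref$id, query_id = q$id)
  fbox_pos <- seq(ref$fbox[1], ref$fbox[2])
  fbox_aa <- .query_at_ref(anchor, fbox_pos)
  fbox_quality <- mean(fbox_aa == substring(ref$seq, fbox_pos, fbox_pos))
  has_fbox <- fbox_quality >= cfg$fbox_min_identity
  lrr_pos <- seq(ref$lrr[1], ref$lrr[2])
  lrr_coverage <- mean(.query_at_ref(anchor, lrr_pos) != "-")
  pocket <- anchor_residues(q$aa, ref$seq, ref$pocket, cfg,
                            ref_name = ref$id, anchor = anchor)
  ac <- anchor_residues(q$aa, ref$seq, ref$ac, cfg,
                        ref_name = ref$id, anchor = anchor)
  if (!has_fbox) {
    verdict <- "rejected"
    reason <- sprintf("F-box identity %.2f below %.2f", fbox_quality,
                      cfg$fbox_min_identity)
  } else if (lrr_coverage < cfg$lrr_min_coverage) {
    verdict <- "incomplete"
    reason <- sprintf("LRR coverage %.2f below %.2f: ring does not close",
                      lrr_coverage, cfg$lrr_min_coverage)
  } else {
    verdict <- "receptor"
    reason <- ""
  }
  structure(list(protein_id = q$id, has_fbox = has_fbox,
                 fbox_quality = fbox_quality, lrr_coverage = lrr_coverage,
                 pocket_checks = pocket, ac_checks = ac,
                 verdict = verdict, reason = reason),
            class = "tir_afb_report")
}

#' @export
print.tir_afb_report <- function(x, ...) {
  cat(sprintf("TIR1/AFB report for %s: verdict %s\n", x$protein_id, x$verdict))
  if (!is.null(x$pocket_checks)) {
    cat(sprintf("  F-box %s (identity %.2f), LRR coverage %.2f\n",
                if (x$has_fbox) "present" else "absent", x$fbox_quality,
                x$lrr_coverage))
    cat(sprintf("  pocket checks conserved: %d/%d, AC checks conserved: %d/%d\n",
                sum(x$pocket_checks$conserved), nrow(x$pocket_checks),
                sum(x$ac_checks$conserved), nrow(x$ac_checks)))
  }
  if (nzchar(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Scan for the ARF B3 DNA-binding motif SxxxxHGxxSxxR
#'
#' Slides a 13-residue window over the protein and reports the best match to
#' the motif (literal positions S, H, G, S, R; `x` positions free), allowing
#' up to `cfg$dbd_max_mismatch` substitutions at the literal positions so the
#' ARF17/18-type H->G variant is still detected and reported.
#'
#' @param p protein (ORF table row or amino-acid string).
#' @param cfg configuration, see [miraux_config()].
#' @return `NULL` when no window is within tolerance; otherwise a list with
#'   `start`, `end` (1-based), `window`, `n_mismatch` and `substitutions`
#'   (named character vector, e.g. `c(H = "G")`).
#' @examples
#' scan_dbd_motif("AASACDEHGKLSQWRAA")
#' @export
scan_dbd_motif <- function(p, cfg = miraux_config()) {
  q <- .protein_seq(p)
  aa <- q$aa
  n <- nchar(aa)
  if (n < 13) return(NULL)
  off <- c(1, 6, 7, 10, 13)
  expect <- c("S", "H", "G", "S", "R")
  lab <- c("S1", "H", "G", "S2", "R")
  starts <- seq_len(n - 12)
  mm <- integer(length(starts))
  for (k in seq_along(off)) {
    obs <- substring(aa, starts + off[k] - 1, starts + off[k] - 1)
    mm <- mm + (obs != expect[k])
  }
  best <- min(mm)
  if (best > cfg$dbd_max_mismatch) return(NULL)
  s <- starts[which.min(mm)]                 # leftmost best window
  obs <- substring(aa, s + off - 1, s + off - 1)
  subs <- setNames(obs[obs != expect], lab[obs != expect])
  list(start = s, end = s + 12L, window = substring(aa, s, s + 12L),
       n_mismatch = best, substitutions = subs)
}

#' Type the PB1 interaction domain of an ARF candidate
#'
#' Detects a PB1 region by aligning the packaged PB1 reference domain into
#' the query (identity over the reference span must reach
#' `cfg$pb1_min_identity`), then checks the two interaction faces: motif I is
#' present when the residue aligned to the canonical lysine column is K;
#' motif II (OPCA) when the window aligned to the reference OPCA span matches
#' the acidic pattern `D-x-[DE]-x-D` with at most one mismatch at the three
#' literal positions.
#'
#' @param p protein (ORF table row or amino-acid string).
#' @param refs reference set from [reference_set()].
#' @param cfg configuration, see [miraux_config()].
#' @return List with `type` (`"full"`, `"typeI_OPCA_only"`,
#'   `"typeII_lysine_only"` or `"absent"`), `motif_I`, `motif_II`,
#'   `identity`, and the query `start`/`end` of the detected region (`NA`
#'   when absent).
#' @export
type_pb1 <- function(p, refs = reference_set(), cfg = miraux_config()) {
  q <- .protein_seq(p)
  ref <- refs$arf
  seg <- substring(ref$seq, ref$pb1[1], ref$pb1[2])
  hit <- .domain_hit(seg, q$aa, .align_params(cfg))
  if (hit$identity < cfg$pb1_min_identity) {
    return(list(type = "absent", motif_I = FALSE, motif_II = FALSE,
                identity = hit$identity, start = NA_integer_,
                end = NA_integer_))
  }
  k_rel <- ref$pb1_k - ref$pb1[1] + 1L
  k_aa <- hit$pairs$query_aa[match(k_rel, hit$pairs$ref_pos)]
  motif_I <- identical(k_aa, "K")
  opca_rel <- seq(ref$opca[1], ref$opca[2]) - ref$pb1[1] + 1L
  opca_aa <- hit$pairs$query_aa[match(opca_rel, hit$pairs$ref_pos)]
  mm <- (opca_aa[1] != "D") + (!opca_aa[3] %in% c("D", "E")) +
        (opca_aa[5] != "D")
  motif_II <- mm <= 1
  type <- if (motif_I && motif_II) "full"
          else if (motif_II) "typeI_OPCA_only"
          else if (motif_I) "typeII_lysine_only"
          else "absent"
  list(type = type, motif_I = motif_I, motif_II = motif_II,
       identity = hit$identity, start = hit$start, end = hit$end)
}

#' Classify an ARF middle domain as activation or repression domain
#'
#' Computes the amino-acid composition of the middle-domain span and applies
#' the composition rule: an activation domain is glutamine-rich with Q, S and
#' L all among the most frequent residues; a repression domain is
#' proline/glycine-enriched with little glutamine. Anything else is reported
#' as `"unclassified"` rather than coerced.
#'
#' @param p protein (ORF table row or amino-acid string).
#' @param md_start,md_end 1-based span of the middle domain in the query
#'   (left flank: end of the DBD/DD block; right flank: PB1 start minus one,
#'   or the protein C-terminus when PB1 is absent). Use `NA` when a flank was
#'   not found.
#' @param cfg configuration; the rule uses `q_min`, `pg_min`, `top_k`,
#'   `md_min_len`.
#' @return List with `md_call` (`"activator"`, `"repressor"`,
#'   `"unclassified"` or `"none"`), `composition` (frequency vector over the
#'   20 standard residues, summing to 1) and `span`.
#' @export
classify_md <- function(p, md_start, md_end, cfg = miraux_config()) {
  q <- .protein_seq(p)
  if (is.na(md_start) || is.na(md_end)) {
    return(list(md_call = "none", composition = NULL,
                span = c(NA_integer_, NA_integer_)))
  }
  if (md_end < md_start || md_start < 1 || md_end > nchar(q$aa)) {
    stop("invalid middle-domain span [", md_start, ", ", md_end,
         "] for a protein of length ", nchar(q$aa), call. = FALSE)
  }
  if (md_end - md_start + 1 < cfg$md_min_len) {
    return(list(md_call = "none", composition = NULL,
                span = c(md_start, md_end)))
  }
  span <- substring(q$aa, md_start, md_end)
  chars <- strsplit(span, "")[[1]]
  chars <- chars[chars %in% .AA20]           # X and gaps excluded
  f <- as.vector(table(factor(chars, levels = .AA20))) / length(chars)
  names(f) <- .AA20
  # deterministic top-k: frequency descending, then alphabetical
  topk <- .AA20[order(-f, .AA20, method = "radix")][seq_len(cfg$top_k)]
  call <- if (f["Q"] >= cfg$q_min && all(c("Q", "S", "L") %in% topk)) {
    "activator"
  } else if (f["P"] + f["G"] >= cfg$pg_min && f["Q"] < cfg$q_min) {
    "repressor"
  } else {
    "unclassified"
  }
  list(md_call = call, composition = f, span = c(md_start, md_end))
}

#' Map domain presence to an ARF architecture class
#'
#' Deterministic mapping from domain flags to the architecture classes, with
#' the functional role the architecture implies: a DBD-only protein can mask
#' AuxRE elements; a PB1-only protein can terminate ARF-Aux/IAA
#' polymerisation; a DBD+MD protein without PB1 is auxin-independent
#' (ARF17/18-like).
#'
#' @param has_dbd,md_present,pb1_present logical domain flags
#'   (`pb1_present` means the PB1 typing is not `"absent"`).
#' @return List with `architecture` (one of `full_arf`, `dbd_only`,
#'   `pb1_only`, `no_pb1`, `no_dbd`) and `role_note`.
#' @export
assign_architecture <- function(has_dbd, md_present, pb1_present) {
  if (!has_dbd && pb1_present && !md_present) {
    return(list(architecture = "pb1_only",
                role_note = "modulates ARF-Aux/IAA polymerisation dynamics"))
  }
  if (!has_dbd) {
    return(list(architecture = "no_dbd",
                role_note = "no DNA-binding domain: not a transcription factor"))
  }
  if (md_present && pb1_present) {
    return(list(architecture = "full_arf",
                role_note = "complete domain set: canonical auxin response factor"))
  }
  if (md_present) {
    return(list(architecture = "no_pb1",
                role_note = "auxin-independent (ARF17/18-like, no Aux/IAA interaction)"))
  }
  if (pb1_present) {
    return(list(architecture = "dbd_only",
                role_note = "non-canonical: PB1 retained but middle domain absent"))
  }
  list(architecture = "dbd_only",
       role_note = "DBD only: can mask AuxRE elements")
}

#' Classify a candidate ARF transcription factor
#'
#' Full ARF curation: B3 DNA-binding motif scan ([scan_dbd_motif()]),
#' dimerisation-domain check (identity of the reference DD segment aligned
#' into the query), PB1 typing ([type_pb1()]), middle-domain composition
#' ([classify_md()]; the MD spans from the end of the DBD/DD block to the
#' PB1 start, or to the C-terminus when PB1 is absent), and the architecture
#' call ([assign_architecture()]).
#'
#' @param p complete-ORF protein (ORF table row or amino-acid string).
#' @param refs reference set from [reference_set()].
#' @param cfg configuration, see [miraux_config()].
#' @return Object of class `"arf_report"`: list with `protein_id`,
#'   `has_dbd`, `dbd_motif`, `has_dd`, `dd_identity`, `pb1` (typing list),
#'   `md` (composition list), `architecture`, `role_note`.
#' @export
classify_arf <- function(p, refs = reference_set(), cfg = miraux_config()) {
  q <- .protein_seq(p)
  ref <- refs$arf
  motif <- scan_dbd_motif(q$aa, cfg)
  has_dbd <- !is.null(motif)
  dd_seg <- substring(ref$seq, ref$dd[1], ref$dd[2])
  dd_hit <- .domain_hit(dd_seg, q$aa, .align_params(cfg))
  has_dd <- dd_hit$identity >= cfg$dd_min_identity
  pb1 <- type_pb1(q$aa, refs, cfg)
  pb1_present <- pb1$type != "absent"
  md_start <- NA_integer_
  md_end <- NA_integer_
  if (has_dbd) {
    dbd_seg <- substring(ref$seq, ref$dbd[1], ref$dbd[2])
    dbd_hit <- .domain_hit(dbd_seg, q$aa, .align_params(cfg))
    md_start <- max(dbd_hit$end, motif$end) + 1L
    md_end <- if (pb1_present) pb1$start - 1L else nchar(q$aa)
    if (!is.na(md_end) && md_end < md_start) {
      md_start <- NA_integer_
      md_end <- NA_integer_
    }
  }
  md <- classify_md(q$aa, md_start, md_end, cfg)
  arch <- assign_architecture(has_dbd, md$md_call %in%
                                c("activator", "repressor", "unclassified"),
                              pb1_present)
  structure(list(protein_id = q$id, has_dbd = has_dbd, dbd_motif = motif,
                 has_dd = has_dd, dd_identity = dd_hit$identity, pb1 = pb1,
                 md = md, architecture = arch$architecture,
                 role_note = arch$role_note),
            class = "arf_report")
}

#' @export
print.arf_report <- function(x, ...) {
  cat(sprintf("ARF report for %s: architecture %s\n", x$protein_id,
              x$architecture))
  cat(sprintf("  DBD motif %s%s, DD identity %.2f, PB1 %s, MD %s\n",
              if (x$has_dbd) "present" else "absent",
              if (x$has_dbd && length(x$dbd_motif$substitutions) > 0) {
                paste0(" (", paste(names(x$dbd_motif$substitutions),
                                   x$dbd_motif$substitutions, sep = "->",
                                   collapse = ", "), ")")
              } else "",
              x$dd_identity, x$pb1$type, x$md$md_call))
  cat(" ", x$role_note, "\n")
  invisible(x)
}

# Flatten report objects into one TSV-ready row each.
.tir_report_row <- function(x) {
  data.frame(protein_id = x$protein_id, has_fbox = x$has_fbox,
             fbox_quality = x$fbox_quality, lrr_coverage = x$lrr_coverage,
             pocket_conserved = if (is.null(x$pocket_checks)) NA_integer_
                                else sum(x$pocket_checks$conserved),
             pocket_total = if (is.null(x$pocket_checks)) NA_integer_
                            else nrow(x$pocket_checks),
             ac_conserved = if (is.null(x$ac_checks)) NA_integer_
                            else sum(x$ac_checks$conserved),
             verdict = x$verdict, reason = x$reason,
             stringsAsFactors = FALSE)
}

.arf_report_row <- function(x) {
  data.frame(protein_id = x$protein_id, has_dbd = x$has_dbd,
             dbd_substitutions = if (x$has_dbd &&
                                     length(x$dbd_motif$substitutions) > 0) {
               paste(names(x$dbd_motif$substitutions),
                     x$dbd_motif$substitutions, sep = "->", collapse = ",")
             } else "",
             has_dd = x$has_dd, dd_identity = x$dd_identity,
             pb1_type = x$pb1$type, md_call = x$md$md_call,
             md_len = if (is.na(x$md$span[1])) 0L
                      else x$md$span[2] - x$md$span[1] + 1L,
             architecture = x$architecture, role_note = x$role_note,
             stringsAsFactors = FALSE)
}

#' Classify a cohort of translated ORFs
#'
#' Routes each protein by its transcript annotation: TIR1/AFB-annotated
#' proteins go to [classify_tir_afb()], ARF-annotated proteins to
#' [classify_arf()]; Aux/IAA and unannotated records are passed through
#' unclassified (no degradome-confirmed miRNA-Aux/IAA pair exists to
#' calibrate rules for them).
#'
#' @param orfs ORF table from [longest_orfs()] (must carry `annotation`).
#' @param refs reference set from [reference_set()].
#' @param cfg configuration, see [miraux_config()].
#' @return List with `tir` and `arf` flattened report tables and
#'   `passthrough` (ids not routed to either classifier).
#' @export
classify_proteins <- function(orfs, refs = reference_set(),
                              cfg = miraux_config()) {
  is_tir <- grepl("TIR1|AFB", orfs$annotation, ignore.case = TRUE)
  is_arf <- grepl("ARF", orfs$annotation, ignore.case = TRUE) & !is_tir
  tir_rows <- lapply(which(is_tir), function(k) {
    .tir_report_row(classify_tir_afb(orfs[k, ], refs, cfg))
  })
  arf_rows <- lapply(which(is_arf), function(k) {
    .arf_report_row(classify_arf(orfs[k, ], refs, cfg))
  })
  list(tir = if (length(tir_rows)) do.call(rbind, tir_rows) else NULL,
       arf = if (length(arf_rows)) do.call(rbind, arf_rows) else NULL,
       passthrough = orfs$transcript_id[!is_tir & !is_arf])
}
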