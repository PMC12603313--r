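# miRNA target scoring, cleavage-site prediction and degradome confirmation.
#
# Scoring follows the de-facto plant small-RNA target convention: per-column
# penalties (mismatch 1, G:U 0.5, gap 2) doubled across miRNA positions 2-13
# (5'->3'), and the guided cleavage site opposite miRNA position 10. The tag
# 5' end is expected at the transcript nucleotide opposite miRNA position 10
# (1-based from the miRNA 5' end); degradome positions are 1-based on the
# + strand of the transcript.

.state_labels <- c("match", "GU", "mismatch", "gap")

#' Score miRNA:target-window complementarity
#'
#' Optimal gapped complementarity alignment of a miRNA against a transcript
#' window (antiparallel), minimising the position-weighted penalty.
#' Deterministic traceback (prefer paired columns, then consuming the miRNA).
#'
#' @param mirna mature miRNA, 5'->3' (RNA or DNA alphabet).
#' @param window transcript window, 5'->3'; its length must be within
#'   `max_bulge` of the miRNA length.
#' @param max_bulge maximum length difference accommodated by gaps
#'   (default 2).
#' @return Object of class `"target_site"`: list with `penalty`,
#'   `alignment` (`data.frame` of columns: miRNA position, window position in
#'   the original orientation, state among match/GU/mismatch/gap) and
#'   `cleavage_window_pos` (1-based window coordinate opposite miRNA
#'   position 10).
#' @examples
#' score_site("UGGAGCUCCCUUCAUUCCAAU",
#'            as.character(reverse_complement_rna("UGGAGCUCCCUUCAUUCCAAU")))
#' @export
score_site <- function(mirna, window, max_bulge = 2) {
  m <- .to_rna(mirna)
  w <- .to_rna(window)
  .check_rna(m, "miRNA")
  .check_rna(w, "target window")
  if (abs(nchar(w) - nchar(m)) > max_bulge) {
    stop("window length ", nchar(w), " outside miRNA length ", nchar(m),
         " +/- max_bulge = ", max_bulge, call. = FALSE)
  }
  res <- .site_align(m, w)
  aln <- data.frame(
    mirna_pos = ifelse(res$col_mirna == 0, NA_integer_, res$col_mirna),
    window_pos = ifelse(res$col_window_rev == 0, NA_integer_,
                        nchar(w) - res$col_window_rev + 1L),
    state = .state_labels[res$col_state + 1L],
    stringsAsFactors = FALSE)
  structure(list(penalty = res$penalty, alignment = aln,
                 cleavage_window_pos = res$cleavage_window_pos,
                 mirna = m, window = w),
            class = "target_site")
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf("Target site: penalty %.2f over %d columns; cleavage opposite miRNA position 10 at window position %s\n",
              x$penalty, nrow(x$alignment),
              ifelse(is.na(x$cleavage_window_pos), "NA",
                     x$cleavage_window_pos)))
  invisible(x)
}

#' Reverse complement on the RNA alphabet
#'
#' @param x RNA (or DNA) string.
#' @return RNA string, the reverse complement of `x`.
#' @export
reverse_complement_rna <- function(x) {
  .to_rna(.revcomp(x))
}

#' Scan transcripts for miRNA target sites
#'
#' Scores every window whose length is within `cfg$max_bulge` of the miRNA
#' length and keeps windows with penalty at most `cfg$max_penalty`.
#' Overlapping hits are deduplicated keeping the minimal penalty (ties:
#' leftmost, then shortest). The predicted cleavage position (transcript
#' coordinate opposite miRNA position 10) is attached to every retained
#' site.
#'
#' @param mirnas miRNA table from [read_fasta()] or a single named sequence.
#' @param transcripts transcript table from [read_fasta()].
#' @param cfg configuration; uses `max_bulge` and `max_penalty`.
#' @return `data.frame` with columns `mirna_id`, `transcript_id`,
#'   `site_start`, `site_end` (0-based half-open), `penalty`,
#'   `cleavage_pos` (1-based transcript coordinate).
#' @export
scan_targets <- function(mirnas, transcripts, cfg = miraux_config()) {
  stopifnot(cfg$max_penalty >= 0)
  if (is.character(mirnas)) {
    mirnas <- data.frame(id = names(mirnas), seq = unname(mirnas),
                         stringsAsFactors = FALSE)
  }
  out <- list()
  for (mi in seq_len(nrow(mirnas))) {
    m <- .to_rna(mirnas$seq[mi])
    for (ti in seq_len(nrow(transcripts))) {
      tr <- .to_rna(transcripts$seq[ti])
      hits <- .site_scan(m, tr, as.integer(cfg$max_bulge), cfg$max_penalty)
      if (nrow(hits) == 0) next
      # dedupe overlapping windows: minimal penalty, then leftmost, shortest
      hits <- hits[order(hits$penalty, hits$start0, hits$width), ,
                   drop = FALSE]
      kept <- logical(0)
      keep_rows <- integer(0)
      iv <- matrix(numeric(0), ncol = 2)
      for (r in seq_len(nrow(hits))) {
        s <- hits$start0[r]
        e <- s + hits$width[r]
        if (nrow(iv) == 0 || all(e <= iv[, 1] | s >= iv[, 2])) {
          keep_rows <- c(keep_rows, r)
          iv <- rbind(iv, c(s, e))
        }
      }
      hits <- hits[keep_rows, , drop = FALSE]
      for (r in seq_len(nrow(hits))) {
        win <- substring(tr, hits$start0[r] + 1L,
                         hits$start0[r] + hits$width[r])
        site <- score_site(m, win, max_bulge = cfg$max_bulge)
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = mirnas$id[mi], transcript_id = transcripts$id[ti],
          site_start = hits$start0[r],
          site_end = hits$start0[r] + hits$width[r],
          penalty = hits$penalty[r],
          cleavage_pos = if (is.na(site$cleavage_window_pos)) NA_integer_
                         else hits$start0[r] + site$cleavage_window_pos,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      penalty = numeric(), cleavage_pos = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$mirna_id, res$transcript_id, res$site_start,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a degradome tag table
#'
#' @param path TSV with columns `transcript_id`, `position` (1-based on the
#'   + strand) and `count`.
#' @return `data.frame` of per-transcript sparse profiles.
#' @export
read_degradome <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "count")
  if (!all(need %in% names(d))) {
    stop("degradome table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(d$count < 1)) stop("degradome counts must be >= 1", call. = FALSE)
  d
}

#' Categorise a predicted cleavage site against a degradome profile
#'
#' Standard degradome category ladder. With `r` the tag count at the
#' predicted cleavage position and the maximum/median taken over the
#' transcript's nonzero tag positions:
#' category 0: `r > 1` and `r` is the unique maximum; 1: `r > 1` and `r`
#' equals a shared maximum; 2: `r > 1` and `r` exceeds the median; 3:
#' `r > 1` and `r` is at most the median; 4: `r = 1`. When no tag falls at
#' the cleavage position there is no evidence (category `NA`).
#'
#' @param profile degradome rows for one transcript (columns `position`,
#'   `count`).
#' @param cleavage_pos 1-based predicted cleavage position.
#' @return One-row `data.frame` with `reads_at_site` and `category`
#'   (integer 0-4 or `NA`).
#' @export
categorise_cleavage <- function(profile, cleavage_pos) {
  stopifnot(sum(profile$count) >= 1)
  r <- profile$count[match(cleavage_pos, profile$position)]
  if (is.na(r) || r == 0) {
    return(data.frame(reads_at_site = 0L, category = NA_integer_))
  }
  if (r == 1) {
    return(data.frame(reads_at_site = 1L, category = 4L))
  }
  mx <- max(profile$count)
  med <- median(profile$count)
  cat_ <- if (r == mx && sum(profile$count == mx) == 1) 0L
          else if (r == mx) 1L
          else if (r > med) 2L
          else 3L
  data.frame(reads_at_site = as.integer(r), category = cat_)
}

#' Export a T-plot table for a confirmed site
#'
#' The tabular form of a T-plot: degradome tag counts by transcript
#' position with the predicted cleavage position flagged, ordered by
#' position.
#'
#' @param profile degradome rows for one transcript.
#' @param cleavage_pos 1-based predicted cleavage position.
#' @param path optional output TSV path.
#' @return The T-plot `data.frame` (`position`, `count`, `is_cleavage`);
#'   written to `path` when given.
#' @export
export_tplot <- function(profile, cleavage_pos, path = NULL) {
  tp <- data.frame(position = profile$position, count = profile$count,
                   is_cleavage = profile$position == cleavage_pos)
  tp <- tp[order(tp$position), , drop = FALSE]
  rownames(tp) <- NULL
  if (!is.null(path)) {
    write.table(tp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tp
}

#' Build the miRNA-target module network table
#'
#' Joins degradome-confirmed target sites with protein classification
#' annotations into one row per miRNA -> transcript edge (multi-target
#' edges allowed). Edges above `cfg$max_category` are dropped; sites
#' without degradome evidence are excluded. Targets lacking a
#' classification are kept with annotation `"unclassified"` and a warning.
#'
#' @param evidence `data.frame` of confirmed sites: the [scan_targets()]
#'   columns plus `category`.
#' @param annotations `data.frame` with `transcript_id` and `annotation`
#'   (e.g. receptor verdicts / ARF architectures).
#' @param cfg configuration; uses `max_category`.
#' @return `data.frame` sorted by (`mirna_family`, `transcript_id`) with
#'   columns `mirna_family`, `mirna_id`, `transcript_id`, `annotation`,
#'   `penalty`, `category`.
#' @export
build_module_table <- function(evidence, annotations, cfg = miraux_config()) {
  ev <- evidence[!is.na(evidence$category) &
                   evidence$category <= cfg$max_category, , drop = FALSE]
  fam <- regmatches(ev$mirna_id,
                    regexpr("[Mm][Ii][Rr]\\.?[0-9]+", ev$mirna_id))
  family <- rep("unknown", nrow(ev))
  has_fam <- grepl("[Mm][Ii][Rr]\\.?[0-9]+", ev$mirna_id)
  family[has_fam] <- toupper(sub("\\.", "", fam))
  idx <- match(ev$transcript_id, annotations$transcript_id)
  ann <- annotations$annotation[idx]
  if (any(is.na(idx))) {
    warning("no classification for transcript(s): ",
            paste(unique(ev$transcript_id[is.na(idx)]), collapse = ", "),
            "; annotated as 'unclassified'", call. = FALSE)
    ann[is.na(idx)] <- "unclassified"
  }
  out <- data.frame(mirna_family = family, mirna_id = ev$mirna_id,
                    transcript_id = ev$transcript_id, annotation = ann,
                    penalty = ev$penalty, category = ev$category,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_family, out$transcript_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
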