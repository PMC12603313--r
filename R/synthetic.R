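# Seeded synthetic-data generator. Produces every input the pipeline
# consumes with known ground truth: transcripts with planted domain
# architectures, hairpin precursors with controlled miRNA placement, target
# sites with arithmetically known penalties, degradome tag pools with
# controlled peak/noise structure, expression matrices with controlled
# Spearman correlation, and Ct tables with planted fold changes.
# Identical (seed, cfg) regenerates identical outputs.

# Fixed codon per amino acid: keeps ORF recovery deterministic (no
# codon-usage model).
.CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
            G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
            M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
            S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

.backtranslate <- function(aa) {
  codons <- .CODON[strsplit(aa, "")[[1]]]
  if (anyNA(codons)) stop("cannot back-translate non-standard residue",
                          call. = FALSE)
  paste(c(codons, "TAA"), collapse = "")
}

.rand_nt <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

.rand_aa <- function(n) paste(sample(.AA20, n, replace = TRUE),
                              collapse = "")

# Middle-domain residue pools. MDs are low-complexity domains; the pools are
# restricted to the enriched residues plus common fillers (no H/R/W/C etc.)
# so that composition, not rare-residue noise, drives the classification.
.MD_ALPHA <- list(
  activator = c(Q = 30, S = 25, L = 25, A = 4, T = 4, N = 3, E = 3, D = 3),
  repressor = c(S = 25, L = 20, P = 20, G = 15, A = 5, T = 5, N = 4, E = 3,
                D = 3, Q = 0.5))

#' Generate middle-domain sequences from the two composition families
#'
#' Draws per-sequence residue compositions from a Dirichlet distribution
#' centred on the activation-domain profile (Gln/Ser/Leu-rich) or the
#' repression-domain profile (Ser/Leu/Pro/Gly-rich, Gln-poor), then samples
#' residues. With `noise = 0` the mean profile is used deterministically.
#'
#' @param n number of sequences.
#' @param class `"activator"` or `"repressor"`.
#' @param len sequence length (default 120).
#' @param noise 1 for Dirichlet sampling (default), 0 for the deterministic
#'   mean profile.
#' @return Character vector of `n` middle-domain sequences.
#' @export
gen_md_sequences <- function(n, class = c("activator", "repressor"),
                             len = 120, noise = 1) {
  class <- match.arg(class)
  alpha <- .MD_ALPHA[[class]]
  vapply(seq_len(n), function(i) {
    p <- if (noise > 0) {
      g <- stats::rgamma(length(alpha), shape = alpha)
      g / sum(g)
    } else {
      alpha / sum(alpha)
    }
    if (noise > 0) {
      paste(sample(names(alpha), len, replace = TRUE, prob = p),
            collapse = "")
    } else {
      counts <- floor(p * len)
      rem <- len - sum(counts)
      if (rem > 0) {
        extra <- order(-(p * len - counts))[seq_len(rem)]
        counts[extra] <- counts[extra] + 1L
      }
      paste(rep(names(alpha), counts), collapse = "")
    }
  }, character(1))
}

.default_transcriptome_cfg <- function() {
  list(n_decoys = 10,
       tir_classes = c(intact = 3, truncated = 1, ac_edit = 1, no_fbox = 1),
       arf_classes = c(full_arf = 2, dbd_only = 2, pb1_only = 2,
                       no_pb1 = 2, no_dbd = 2),
       arf_md_class = "activator",
       md_noise = 0,
       utr_len = 30,
       decoy_orf_aa = 80)
}

#' Generate a synthetic transcriptome with planted protein classes
#'
#' Decoy transcripts carry random codon-structured ORFs; planted records are
#' built by back-translating edited copies of the packaged reference
#' proteins. TIR1/AFB classes: `intact` (the reference), `truncated`
#' (C-terminal 40% removed: the LRR ring cannot close), `ac_edit` (first AC
#' key position Asn -> Asp), `no_fbox` (F-box span randomised). ARF classes
#' plant the five domain architectures by concatenating reference DBD/DD and
#' PB1 segments with generated middle domains.
#'
#' @param cfg list of counts and options; defaults per
#'   `miraux:::.default_transcriptome_cfg`. Override any subset.
#' @param seed integer seed.
#' @param refs reference set from [reference_set()].
#' @return List with `transcripts` (FASTA-ready `data.frame`) and `truth`
#'   (`data.frame`: id, family, class, expected verdict/architecture).
#' @export
gen_transcriptome <- function(cfg = list(), seed = 1,
                              refs = reference_set()) {
  cfg <- utils::modifyList(.default_transcriptome_cfg(), cfg)
  set.seed(seed)
  tir <- refs$tir
  arf <- refs$arf
  dbd_seg <- substring(arf$seq, arf$dbd[1], arf$dbd[2])
  pb1_seg <- substring(arf$seq, arf$pb1[1], arf$pb1[2])
  recs <- list()
  truth <- list()
  add <- function(id, aa, annotation, family, class, expected) {
    utr5 <- .rand_nt(cfg$utr_len)
    utr3 <- .rand_nt(cfg$utr_len)
    recs[[length(recs) + 1L]] <<- data.frame(
      id = id, seq = paste0(utr5, .backtranslate(aa), utr3),
      annotation = annotation, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      id = id, family = family, class = class, expected = expected,
      stringsAsFactors = FALSE)
  }
  k <- 0
  for (cls in names(cfg$tir_classes)) {
    for (r in seq_len(cfg$tir_classes[[cls]])) {
      k <- k + 1
      aa <- switch(cls,
        intact = tir$seq,
        truncated = substring(tir$seq, 1, round(0.6 * nchar(tir$seq))),
        ac_edit = {
          s <- tir$seq
          pos <- tir$ac$pos[1]
          paste0(substring(s, 1, pos - 1), "D",
                 substring(s, pos + 1, nchar(s)))
        },
        no_fbox = {
          s <- tir$seq
          span <- tir$fbox
          paste0(substring(s, 1, span[1] - 1),
                 .rand_aa(span[2] - span[1] + 1),
                 substring(s, span[2] + 1, nchar(s)))
        })
      expected <- switch(cls, intact = "receptor", truncated = "incomplete",
                         ac_edit = "receptor", no_fbox = "rejected")
      add(sprintf("SYN_TIR_%03d", k), aa,
          paste("TIR1/AFB synthetic", cls), "tir", cls, expected)
    }
  }
  k <- 0
  for (cls in names(cfg$arf_classes)) {
    for (r in seq_len(cfg$arf_classes[[cls]])) {
      k <- k + 1
      md_class <- if (identical(cfg$arf_md_class, "mixed")) {
        if (r %% 2 == 1) "activator" else "repressor"
      } else cfg$arf_md_class
      md <- gen_md_sequences(1, md_class, noise = cfg$md_noise)
      aa <- switch(cls,
        full_arf = paste0("M", dbd_seg, md, pb1_seg),
        dbd_only = paste0("M", dbd_seg, substring(md, 1, 10)),
        pb1_only = paste0("M", substring(md, 1, 10), pb1_seg),
        no_pb1 = paste0("M", dbd_seg, md),
        no_dbd = paste0("M", md))
      add(sprintf("SYN_ARF_%03d", k), aa, paste("ARF synthetic", cls),
          "arf", cls, cls)
    }
  }
  for (d in seq_len(cfg$n_decoys)) {
    aa <- paste0("M", .rand_aa(cfg$decoy_orf_aa))
    add(sprintf("SYN_DECOY_%03d", d), aa, "decoy", "decoy", "decoy", "none")
  }
  list(transcripts = do.call(rbind, recs), truth = do.call(rbind, truth))
}

.default_precursor_cfg <- function() {
  list(n_5p = 13, n_3p = 12, n_outside = 25, arm_len = 30, flank_len = 60,
       mirna_len = 21)
}

#' Generate synthetic miRNA precursor candidates with known stem placement
#'
#' Builds designed stem-loop transcripts: a perfect complementary arm pair
#' around a short loop, embedded in flanking sequence. The mature miRNA is
#' placed in the 5' arm, the 3' arm, or (negative class) in an unpaired
#' pyrimidine region outside the stem-loop. Residue alphabets are
#' partitioned (purine-side arm A/G, pyrimidine-side arm U/C, flanks and
#' loop C/U) so that under maximum base pairing the planted stem is the
#' optimum and the placement ground truth is structurally unambiguous. A
#' long miRNA placed wholly inside a hairpin loop is deliberately not used
#' as the negative class: under the maximum-pairing objective such a miRNA
#' can displace stem pairs count-neutrally, so its structure is degenerate
#' (see the methods vignette).
#'
#' @param cfg list: `n_5p`, `n_3p`, `n_outside` counts, `arm_len`,
#'   `flank_len`, `mirna_len`.
#' @param seed integer seed.
#' @return List with `transcripts`, `mirnas` (FASTA-ready `data.frame`s) and
#'   `truth` (`transcript_id`, `mirna_id`, `placement`, `in_stem_expected`,
#'   `arm_expected`).
#' @export
gen_precursors <- function(cfg = list(), seed = 1) {
  cfg <- utils::modifyList(.default_precursor_cfg(), cfg)
  set.seed(seed)
  recs <- list()
  mirnas <- list()
  truth <- list()
  total <- c(`5p` = cfg$n_5p, `3p` = cfg$n_3p, outside = cfg$n_outside)
  k <- 0
  for (placement in names(total)) {
    for (r in seq_len(total[[placement]])) {
      k <- k + 1
      arm5 <- .rand_nt(cfg$arm_len, c("A", "G"))
      arm3 <- .revcomp(arm5)                       # over {T, C}
      flank5 <- .rand_nt(cfg$flank_len, c("C", "T"))
      flank3 <- .rand_nt(cfg$flank_len, c("C", "T"))
      loop <- "CCCCCCCC"
      if (placement == "outside") {
        mir <- .rand_nt(cfg$mirna_len, c("C", "T"))
        body <- paste0(arm5, loop, arm3, .rand_nt(12, c("C", "T")), mir)
      } else {
        if (placement == "5p") {
          mir <- substring(arm5, 3, 3 + cfg$mirna_len - 1)
        } else {
          mir <- substring(arm3, 4, 4 + cfg$mirna_len - 1)
        }
        body <- paste0(arm5, loop, arm3)
      }
      tid <- sprintf("SYN_PRE_%03d", k)
      mid <- sprintf("syn-miR%03d", k)
      recs[[k]] <- data.frame(
        id = tid, seq = paste0(flank5, body, flank3),
        annotation = paste("synthetic precursor", placement),
        stringsAsFactors = FALSE)
      mirnas[[k]] <- data.frame(id = mid, seq = mir,
                                annotation = "synthetic mature miRNA",
                                stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(
        transcript_id = tid, mirna_id = mid, placement = placement,
        in_stem_expected = placement != "outside",
        arm_expected = if (placement == "outside") NA_character_
                       else placement,
        stringsAsFactors = FALSE)
    }
  }
  list(transcripts = do.call(rbind, recs), mirnas = do.call(rbind, mirnas),
       truth = do.call(rbind, truth))
}

# Deterministic target-site construction: start from the perfect reverse
# complement and plant substitutions whose penalty contribution is known
# arithmetically (mismatch 1, G:U 0.5, doubled at miRNA positions 2-13).
.MISMATCH_BASE <- c(A = "A", C = "A", G = "A", T = "C")

.plant_site <- function(mirna_dna, penalty) {
  m <- nchar(mirna_dna)
  q <- strsplit(mirna_dna, "")[[1]]
  site <- strsplit(.revcomp(mirna_dna), "")[[1]]  # site[w - p + 1] faces q[p]
  stopifnot(penalty * 2 == round(penalty * 2))
  remaining <- penalty
  edits <- character(0)
  face <- function(p) m - p + 1                    # site index facing miRNA p
  # G:U edits at the reserved miRNA G positions (20, 21), 0.5 each.
  # Edits are spread out (seed region first, non-adjacent order): clustered
  # tail edits would admit a cheaper gapped re-alignment, making the
  # recorded penalty an overestimate of the optimum.
  gu_pool <- c(20L, 21L)
  mm_pool <- c(15L, 18L, 1L, 14L, 17L, 19L, 16L)   # weight-1 positions
  seed_pool <- c(3L, 7L, 11L, 5L, 9L, 13L, 2L, 6L, 10L, 4L, 8L, 12L)
  while (remaining >= 2 && length(seed_pool) > 0) {
    p <- seed_pool[1]; seed_pool <- seed_pool[-1]
    site[face(p)] <- .MISMATCH_BASE[[q[p]]]
    edits <- c(edits, sprintf("mm%d", p))
    remaining <- remaining - 2
  }
  while (remaining >= 1 && length(mm_pool) > 0) {
    p <- mm_pool[1]; mm_pool <- mm_pool[-1]
    site[face(p)] <- .MISMATCH_BASE[[q[p]]]
    edits <- c(edits, sprintf("mm%d", p))
    remaining <- remaining - 1
  }
  while (remaining >= 0.5 && length(gu_pool) > 0) {
    p <- gu_pool[1]; gu_pool <- gu_pool[-1]
    stopifnot(q[p] == "G")
    site[face(p)] <- "T"                           # G:U wobble
    edits <- c(edits, sprintf("gu%d", p))
    remaining <- remaining - 0.5
  }
  if (remaining > 0) {
    stop("cannot plant penalty ", penalty, " with the available positions",
         call. = FALSE)
  }
  list(site = paste(site, collapse = ""), edits = edits)
}

.default_target_cfg <- function() {
  list(site_penalties = c(0, 0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 4.5,
                          5, 5.5, 6, 6.5, 7, 5, 6, 8),
       n_mirnas = 3, transcript_len = 600, mirna_len = 21)
}

#' Generate transcripts with planted miRNA target sites of known penalty
#'
#' Each site starts from the perfect reverse complement of a miRNA and
#' receives substitution edits with arithmetically known penalty
#' contributions, then is embedded at a recorded position inside a random
#' decoy transcript. miRNA positions 20-21 are fixed to G so that 0.5-unit
#' (G:U) edits are always available.
#'
#' @param cfg list: `site_penalties` (one site per entry), `n_mirnas`,
#'   `transcript_len`, `mirna_len`.
#' @param seed integer seed.
#' @return List with `mirnas`, `transcripts` and `truth` (per site:
#'   `mirna_id`, `transcript_id`, `site_start`, `site_end` 0-based
#'   half-open, `penalty`, `cleavage_pos` 1-based).
#' @export
gen_targets <- function(cfg = list(), seed = 1) {
  cfg <- utils::modifyList(.default_target_cfg(), cfg)
  set.seed(seed)
  mirnas <- data.frame(
    id = sprintf("syn-miR%d", 100 + seq_len(cfg$n_mirnas)),
    seq = vapply(seq_len(cfg$n_mirnas), function(i) {
      paste0(.rand_nt(cfg$mirna_len - 2), "GG")
    }, character(1)),
    annotation = "synthetic mature miRNA", stringsAsFactors = FALSE)
  recs <- list()
  truth <- list()
  for (s in seq_along(cfg$site_penalties)) {
    mi <- ((s - 1) %% cfg$n_mirnas) + 1
    planted <- .plant_site(mirnas$seq[mi], cfg$site_penalties[s])
    w <- nchar(planted$site)
    pos0 <- sample(seq(50, cfg$transcript_len - w - 50), 1)
    tr <- paste0(.rand_nt(pos0), planted$site,
                 .rand_nt(cfg$transcript_len - pos0 - w))
    tid <- sprintf("SYN_TGT_%03d", s)
    recs[[s]] <- data.frame(id = tid, seq = tr,
                            annotation = "synthetic target",
                            stringsAsFactors = FALSE)
    truth[[s]] <- data.frame(
      mirna_id = mirnas$id[mi], transcript_id = tid,
      site_start = pos0, site_end = pos0 + w,
      penalty = cfg$site_penalties[s],
      cleavage_pos = pos0 + w - 10L + 1L,
      edits = paste(planted$edits, collapse = ","),
      stringsAsFactors = FALSE)
  }
  list(mirnas = mirnas, transcripts = do.call(rbind, recs),
       truth = do.call(rbind, truth))
}

.default_degradome_cfg <- function() {
  list(signal = 30, n_noise = 6, noise_max = 3)
}

#' Generate degradome tag pools for planted target sites
#'
#' For every confirmed edge, `signal` reads are placed at the recorded
#' cleavage position and `n_noise` single- to `noise_max`-read noise
#' positions are scattered uniformly elsewhere on the transcript. The
#' expected degradome category is derived from the drawn counts by a
#' literal transcription of the category definitions.
#'
#' @param site_truth `truth` table from [gen_targets()] (or any table with
#'   `transcript_id` and `cleavage_pos`).
#' @param transcript_len transcript length (single value or per-site).
#' @param cfg list: `signal` (reads at the cleavage site; recycled over
#'   sites), `n_noise`, `noise_max`.
#' @param seed integer seed.
#' @return List with `degradome` (TSV-ready `data.frame`) and `truth`
#'   (per site `reads_at_site` and `expected_category`).
#' @export
gen_degradome <- function(site_truth, transcript_len = 600, cfg = list(),
                          seed = 1) {
  cfg <- utils::modifyList(.default_degradome_cfg(), cfg)
  set.seed(seed)
  signal <- rep_len(cfg$signal, nrow(site_truth))
  lens <- rep_len(transcript_len, nrow(site_truth))
  rows <- list()
  truth <- list()
  for (s in seq_len(nrow(site_truth))) {
    cp <- site_truth$cleavage_pos[s]
    pool <- setdiff(seq_len(lens[s]), cp)
    np <- sort(sample(pool, cfg$n_noise))
    nc <- sample(seq_len(cfg$noise_max), cfg$n_noise, replace = TRUE)
    counts <- c(signal[s], nc)
    pos <- c(cp, np)
    rows[[s]] <- data.frame(transcript_id = site_truth$transcript_id[s],
                            position = pos, count = counts,
                            stringsAsFactors = FALSE)
    # literal transcription of the category ladder
    r <- signal[s]
    expected <- if (r == 0) NA_integer_
      else if (r == 1) 4L
      else if (r == max(counts) && sum(counts == max(counts)) == 1) 0L
      else if (r == max(counts)) 1L
      else if (r > median(counts)) 2L
      else 3L
    truth[[s]] <- data.frame(transcript_id = site_truth$transcript_id[s],
                             cleavage_pos = cp, reads_at_site = r,
                             expected_category = expected,
                             stringsAsFactors = FALSE)
  }
  deg <- do.call(rbind, rows)
  deg <- deg[order(deg$transcript_id, deg$position, method = "radix"), ]
  rownames(deg) <- NULL
  list(degradome = deg, truth = do.call(rbind, truth))
}

# All permutations of 1..n in lexicographic order (n <= 8 recommended).
.perm_mat <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- .perm_mat(n - 1L)
  np <- nrow(p)
  out <- matrix(0L, n * np, n)
  for (k in seq_len(n)) {
    rows <- ((k - 1L) * np + 1L):(k * np)
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[p], np, n - 1L)
  }
  out
}

# Rank permutation whose Spearman rho against 1..n is closest to target
# (ties: lexicographically smallest). Enumerates for n <= 8, greedy swap
# search otherwise.
.rank_coupling <- function(n, target) {
  if (n <= 8) {
    pm <- .perm_mat(n)
    s <- rowSums((pm - matrix(seq_len(n), nrow(pm), n, byrow = TRUE))^2)
    rho <- 1 - 6 * s / (n * (n^2 - 1))
    best <- which.min(abs(rho - target))
    return(list(perm = pm[best, ], rho = rho[best]))
  }
  perm <- seq_len(n)
  rho_of <- function(p) 1 - 6 * sum((p - seq_len(n))^2) / (n * (n^2 - 1))
  repeat {
    cur <- rho_of(perm)
    best_gain <- 0
    best_swap <- NULL
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        p2 <- perm
        p2[c(i, j)] <- p2[c(j, i)]
        gain <- abs(cur - target) - abs(rho_of(p2) - target)
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best_swap <- c(i, j)
        }
      }
    }
    if (is.null(best_swap)) break
    perm[best_swap] <- perm[rev(best_swap)]
  }
  list(perm = perm, rho = rho_of(perm))
}

.default_expression_cfg <- function() {
  list(pass_rhos = c(0.55, 0.6, 0.65, 0.7, 0.75, 0.8, 0.85, 0.9, 0.95),
       fail_rhos = c(-0.3, -0.1, 0, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4,
                     0.45, 0.45),
       n_decoys = 20, n_samples = 8)
}

#' Generate expression profiles with controlled Spearman correlation
#'
#' For each miRNA-precursor pair a target rho is planted by rank coupling:
#' the precursor profile's ranks are the permutation of the miRNA profile's
#' ranks whose Spearman coefficient is closest to the target (the achieved
#' rho is recorded; at n = 8 it is the exact minimiser over all rank
#' permutations). Decoy pairs plant near-zero correlation (targets drawn
#' uniformly in (-0.45, 0.45)); the decoy model controls correlation rather
#' than sampling independent profiles, so that the strict 0.5 filter's
#' behaviour on decoys reflects the threshold, not small-n sampling noise.
#' Values are lognormal magnitudes carrying the planted ranks.
#'
#' @param cfg list: `pass_rhos` (defaults: nine targets above 0.5, the
#'   study-scale pass set), `fail_rhos` (twelve below), `n_decoys`,
#'   `n_samples`.
#' @param seed integer seed.
#' @return List with `mirna_rpm` and `precursor_fpkm` matrices (pairs x
#'   samples, matched row order) and `truth` (`pair_id`, `target_rho`,
#'   `achieved_rho`, `is_decoy`, `expected_pass` at the strict 0.5 rule).
#' @export
gen_expression <- function(cfg = list(), seed = 1) {
  cfg <- utils::modifyList(.default_expression_cfg(), cfg)
  set.seed(seed)
  n <- cfg$n_samples
  decoy_targets <- runif(cfg$n_decoys, -0.45, 0.45)
  targets <- c(cfg$pass_rhos, cfg$fail_rhos, decoy_targets)
  is_decoy <- c(rep(FALSE, length(cfg$pass_rhos) + length(cfg$fail_rhos)),
                rep(TRUE, cfg$n_decoys))
  m_rpm <- matrix(0, length(targets), n)
  p_fpkm <- matrix(0, length(targets), n)
  truth <- list()
  for (k in seq_along(targets)) {
    rc <- .rank_coupling(n, targets[k])
    x <- sort(exp(rnorm(n, 4, 1)))               # miRNA RPM, ranks 1..n
    yv <- sort(exp(rnorm(n, 2, 1)))
    y <- yv[rc$perm]                              # precursor FPKM
    m_rpm[k, ] <- x
    p_fpkm[k, ] <- y
    truth[[k]] <- data.frame(
      pair_id = sprintf("pair_%03d", k), target_rho = targets[k],
      achieved_rho = rc$rho, is_decoy = is_decoy[k],
      expected_pass = rc$rho > 0.5, stringsAsFactors = FALSE)
  }
  rownames(m_rpm) <- rownames(p_fpkm) <- sprintf("pair_%03d",
                                                 seq_along(targets))
  colnames(m_rpm) <- colnames(p_fpkm) <- sprintf("S%d", seq_len(n))
  list(mirna_rpm = m_rpm, precursor_fpkm = p_fpkm,
       truth = do.call(rbind, truth))
}

.default_qpcr_cfg <- function() {
  list(fold_changes = c(gene_half = 0.5, gene_one = 1, gene_two = 2,
                        gene_four = 4),
       groups = c("control", "drought"), calibrator = "control",
       n_bio = 3, n_tech = 3, ct_sd = 0.1, ref_gene = "LlActin",
       ref_ct = 18, base_ct = 22)
}

#' Generate a qPCR Ct table with planted fold changes
#'
#' Three biological x three technical replicates per gene and group by
#' default, a constant-expression reference gene, Gaussian Ct noise, and
#' per-gene fold changes planted between the treatment group and the
#' calibrator (`Ct_treated = Ct_base - log2(fold)`).
#'
#' @param cfg list: `fold_changes` (named), `groups` (calibrator first is
#'   not required), `calibrator`, `n_bio`, `n_tech`, `ct_sd`, `ref_gene`,
#'   `ref_ct`, `base_ct`.
#' @param seed integer seed.
#' @return List with `qpcr` (table for [ddct()]) and `truth` (planted folds).
#' @export
gen_qpcr <- function(cfg = list(), seed = 1) {
  cfg <- utils::modifyList(.default_qpcr_cfg(), cfg)
  set.seed(seed)
  rows <- list()
  genes <- c(names(cfg$fold_changes), cfg$ref_gene)
  for (g in genes) {
    for (grp in cfg$groups) {
      true_ct <- if (g == cfg$ref_gene) {
        cfg$ref_ct
      } else if (grp == cfg$calibrator) {
        cfg$base_ct
      } else {
        cfg$base_ct - log2(cfg$fold_changes[[g]])
      }
      for (b in seq_len(cfg$n_bio)) {
        for (tr in seq_len(cfg$n_tech)) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, group = grp, bio_rep = b, tech_rep = tr,
            ct = true_ct + rnorm(1, 0, cfg$ct_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- data.frame(gene = names(cfg$fold_changes),
                      group = setdiff(cfg$groups, cfg$calibrator)[1],
                      planted_fold = unname(cfg$fold_changes),
                      stringsAsFactors = FALSE)
  list(qpcr = do.call(rbind, rows), truth = truth)
}

#' Generate the full synthetic input bundle
#'
#' Composes all generators under one master seed (sub-seeds are derived
#' deterministically) and optionally writes every input to `dir` in the
#' standard formats (FASTA/TSV) together with `ground_truth.json`.
#'
#' @param cfg named list of per-generator overrides: `transcriptome`,
#'   `precursors`, `targets`, `degradome`, `expression`, `qpcr`.
#' @param seed master integer seed.
#' @param dir optional output directory.
#' @param refs reference set from [reference_set()].
#' @return List with each generator's output plus `seed`.
#' @export
gen_bundle <- function(cfg = list(), seed = 1, dir = NULL,
                       refs = reference_set()) {
  sub <- function(k) as.integer((as.numeric(seed) * 101 + k) %% 2147483647)
  bundle <- list(
    transcriptome = gen_transcriptome(cfg$transcriptome %||% list(),
                                      sub(1L), refs),
    precursors = gen_precursors(cfg$precursors %||% list(), sub(2L)),
    targets = gen_targets(cfg$targets %||% list(), sub(3L)),
    expression = gen_expression(cfg$expression %||% list(), sub(4L)),
    qpcr = gen_qpcr(cfg$qpcr %||% list(), sub(5L)),
    seed = seed)
  tgt_cfg <- utils::modifyList(.default_target_cfg(), cfg$targets %||% list())
  bundle$degradome <- gen_degradome(bundle$targets$truth,
                                    tgt_cfg$transcript_len,
                                    cfg$degradome %||% list(), sub(6L))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(bundle$transcriptome$transcripts,
                file.path(dir, "transcripts.fasta"))
    write_fasta(bundle$precursors$transcripts,
                file.path(dir, "precursor_transcripts.fasta"))
    write_fasta(bundle$precursors$mirnas,
                file.path(dir, "precursor_mirnas.fasta"))
    write_fasta(bundle$targets$transcripts,
                file.path(dir, "target_transcripts.fasta"))
    write_fasta(bundle$targets$mirnas, file.path(dir, "target_mirnas.fasta"))
    write.table(bundle$degradome$degradome,
                file.path(dir, "degradome.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(bundle$qpcr$qpcr, file.path(dir, "qpcr.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(pair_id = rownames(bundle$expression$mirna_rpm),
                           bundle$expression$mirna_rpm),
                file.path(dir, "mirna_rpm.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(pair_id = rownames(bundle$expression$precursor_fpkm),
                           bundle$expression$precursor_fpkm),
                file.path(dir, "precursor_fpkm.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    truths <- list(transcriptome = bundle$transcriptome$truth,
                   precursors = bundle$precursors$truth,
                   targets = bundle$targets$truth,
                   degradome = bundle$degradome$truth,
                   expression = bundle$expression$truth,
                   qpcr = bundle$qpcr$truth, seed = seed)
    jsonlite::write_json(truths, file.path(dir, "ground_truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a
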