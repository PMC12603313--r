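# Independent brute-force oracles. These re-derive expected values from
# first principles (plain R, no shared code with the implementation paths
# they check).

# --- six-frame complete-ORF scanner ------------------------------------------

.oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

orf_oracle <- function(seq, min_aa, strand = "both") {
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  strands <- if (strand == "both") c("+", "-") else strand
  for (st in strands) {
    s <- if (st == "+") seq else .oracle_revcomp(seq)
    n <- nchar(s)
    for (start0 in 0:(n - 1)) {
      if (substring(s, start0 + 1, start0 + 3) != "ATG") next
      # walk codons until the first in-frame stop
      p <- start0
      repeat {
        p <- p + 3
        if (p + 3 > n) break
        codon <- substring(s, p + 1, p + 3)
        if (codon %in% stops) {
          n_aa <- (p - start0) / 3
          if (n_aa >= min_aa) {
            out[[length(out) + 1L]] <- data.frame(
              strand = st, cds_start = start0, cds_end = p + 3,
              n_aa = n_aa, stringsAsFactors = FALSE)
          }
          break
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(strand = character(), cds_start = integer(),
                      cds_end = integer(), n_aa = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$strand, res$cds_start), , drop = FALSE]
}

# --- global alignment score by exhaustive path enumeration (memoised) --------
# Gap convention as documented: a gap of length L costs open + L * ext.

nw_score_oracle <- function(a, b, mat, open = 10, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  # states: 1 = last column was a substitution, 2 = gap in b open,
  # 3 = gap in a open
  memo <- array(NA_real_, dim = c(n + 1, m + 1, 3))
  best <- function(i, j, state) {
    if (i == 0 && j == 0) return(if (state == 1) 0 else NEG)
    v <- memo[i + 1, j + 1, state]
    if (!is.na(v)) return(v)
    res <- NEG
    if (state == 1) {
      if (i > 0 && j > 0) {
        res <- max(best(i - 1, j - 1, 1), best(i - 1, j - 1, 2),
                   best(i - 1, j - 1, 3)) + mat[av[i], bv[j]]
      }
    } else if (state == 2) {          # consume a[i] against a gap
      if (i > 0) {
        res <- max(best(i - 1, j, 1) - open - ext,
                   best(i - 1, j, 3) - open - ext,
                   best(i - 1, j, 2) - ext)
      }
    } else {                           # consume b[j] against a gap
      if (j > 0) {
        res <- max(best(i, j - 1, 1) - open - ext,
                   best(i, j - 1, 2) - open - ext,
                   best(i, j - 1, 3) - ext)
      }
    }
    memo[i + 1, j + 1, state] <<- res
    res
  }
  max(best(n, m, 1), best(n, m, 2), best(n, m, 3))
}

# --- maximum nested base pairing by exhaustive recursion ---------------------

.oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

nussinov_oracle <- function(seq, min_loop = 3) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (.oracle_can_pair(s[i], s[k])) {
        v <- 1 + rec(i + 1, k - 1) + (if (k < j) rec(k + 1, j) else 0)
        if (v > best) best <- v
      }
    }
    best
  }
  n <- length(s)
  if (n < 2) return(0)
  rec(1, n)
}

# --- target-site penalty by exhaustive alignment enumeration -----------------
# Costs restated from the documented convention: WC 0, G:U 0.5, mismatch 1,
# gap 2; doubled for columns consuming a miRNA position in 2..13 (a window
# insertion is charged with the weight of the next miRNA position).

site_penalty_oracle <- function(mirna, window) {
  q <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  t_rev <- rev(strsplit(chartr("T", "U", toupper(window)), "")[[1]])
  m <- length(q); w <- length(t_rev)
  weight <- function(i) if (min(i, m) >= 2 && min(i, m) <= 13) 2 else 1
  col_cost <- function(i, j) {
    pr <- paste0(q[i], t_rev[j])
    base <- if (pr %in% c("AU", "UA", "CG", "GC")) 0
            else if (pr %in% c("GU", "UG")) 0.5
            else 1
    base * weight(i)
  }
  memo <- matrix(NA_real_, m + 1, w + 1)
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    v <- memo[i + 1, j + 1]
    if (!is.na(v)) return(v)
    res <- Inf
    if (i > 0 && j > 0) res <- min(res, rec(i - 1, j - 1) + col_cost(i, j))
    if (i > 0) res <- min(res, rec(i - 1, j) + 2 * weight(i))
    if (j > 0) res <- min(res, rec(i, j - 1) + 2 * weight(i + 1))
    memo[i + 1, j + 1] <<- res
    res
  }
  rec(m, w)
}

# --- degradome category ladder, literal transcription ------------------------

category_oracle <- function(positions, counts, cleavage_pos) {
  idx <- which(positions == cleavage_pos)
  r <- if (length(idx) == 0) 0 else counts[idx]
  if (r == 0) return(NA_integer_)
  if (r == 1) return(4L)
  mx <- max(counts)
  if (r == mx && sum(counts == mx) == 1) return(0L)
  if (r == mx) return(1L)
  if (r > median(counts)) return(2L)
  3L
}

# --- Spearman rho with average ranks, from the definition --------------------

spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# --- B3 motif window scan, brute force ---------------------------------------

dbd_scan_oracle <- function(aa, max_mismatch = 1) {
  v <- strsplit(aa, "")[[1]]
  n <- length(v)
  if (n < 13) return(NULL)
  off <- c(1, 6, 7, 10, 13); expect <- c("S", "H", "G", "S", "R")
  best_s <- NULL; best_mm <- Inf
  for (s in 1:(n - 12)) {
    mm <- sum(v[s + off - 1] != expect)
    if (mm < best_mm) { best_mm <- mm; best_s <- s }
  }
  if (best_mm > max_mismatch) return(NULL)
  list(start = best_s, n_mismatch = best_mm)
}

# --- random sequence helpers -------------------------------------------------

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                     replace = TRUE), collapse = "")
rand_protein <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), n,
               replace = TRUE), collapse = "")
}

identity_matrix_20 <- function() {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  m <- diag(length(aa))
  dimnames(m) <- list(aa, aa)
  m
}

blosum62 <- function() {
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
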