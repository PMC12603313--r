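# Expression normalisation and group statistics: FPKM, RPM, row Z-scores,
# 2^-ddCt relative expression, ANOVA + Tukey HSD with compact letters.

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM[f, s] = counts[f, s] / (total[s] / 1e6) / (length[f] / 1e3)`.
#'
#' @param counts non-negative count matrix (features x samples).
#' @param lengths feature lengths in nt, one per row of `counts`.
#' @return FPKM matrix with the dimensions and dimnames of `counts`.
#' @export
fpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts))
  if (any(lengths <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("zero library total in sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(sweep(counts, 2, totals / 1e6, "/"), 1, lengths / 1e3, "/")
}

#' Reads per million
#'
#' Length-free normalisation used for small RNAs:
#' `RPM[f, s] = counts[f, s] / (total[s] / 1e6)`.
#'
#' @param counts non-negative count matrix (features x samples).
#' @return RPM matrix; every column sums to 1e6.
#' @export
rpm <- function(counts) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("zero library total in sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(counts, 2, totals / 1e6, "/")
}

#' Row-wise Z-scores (heatmap normalisation)
#'
#' Centres and scales each row to mean 0 and population standard deviation 1
#' (divisor n, the heatmap convention). Constant rows are emitted as zeros
#' and flagged in the `"flagged_rows"` attribute.
#'
#' @param x numeric matrix.
#' @return Z-scored matrix with attribute `flagged_rows`.
#' @export
zscore_rows <- function(x) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  sdp <- sqrt(rowMeans((x - mu)^2))
  flagged <- sdp == 0
  sdp[flagged] <- 1
  z <- (x - mu) / sdp
  z[flagged, ] <- 0
  attr(z, "flagged_rows") <- which(flagged)
  z
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged on the Ct scale; per (group, biological
#' replicate) the gene Ct is normalised to the reference gene
#' (`dCt = Ct_gene - Ct_ref`), then to the mean dCt of the calibrator
#' group's biological replicates (`ddCt`), and the fold change is
#' `2^-ddCt`. Group summaries are the mean and sd of the per-replicate fold
#' changes. A (group, replicate) without a reference-gene measurement is
#' excluded with a warning.
#'
#' @param qpcr `data.frame` with columns `gene`, `group`, `bio_rep`,
#'   `tech_rep`, `ct` (cycles, > 0).
#' @param reference_gene id of the reference gene (e.g. actin).
#' @param calibrator calibrator group (fold change 1 by construction).
#' @return `data.frame` with one row per gene x group: `fold_change`
#'   (mean over biological replicates), `fold_sd`, `n_reps`, plus
#'   per-replicate folds in the `"replicates"` attribute.
#' @examples
#' q <- data.frame(gene = rep(c("g", "ref"), each = 2),
#'                 group = rep(c("treated", "control"), 2),
#'                 bio_rep = 1, tech_rep = 1, ct = c(20, 22, 18, 18))
#' ddct(q, "ref", "control")
#' @export
ddct <- function(qpcr, reference_gene, calibrator) {
  need <- c("gene", "group", "bio_rep", "tech_rep", "ct")
  stopifnot(all(need %in% names(qpcr)))
  if (any(qpcr$ct <= 0)) stop("Ct values must be > 0", call. = FALSE)
  if (!calibrator %in% qpcr$group) {
    stop("calibrator group ", sQuote(calibrator), " not present",
         call. = FALSE)
  }
  if (!reference_gene %in% qpcr$gene) {
    stop("reference gene ", sQuote(reference_gene), " not present",
         call. = FALSE)
  }
  # average technical replicates on the Ct scale
  ag <- stats::aggregate(ct ~ gene + group + bio_rep, data = qpcr,
                         FUN = mean)
  ref <- ag[ag$gene == reference_gene, ]
  genes <- setdiff(unique(ag$gene), reference_gene)
  rows <- list()
  reps_out <- list()
  for (g in genes) {
    gg <- ag[ag$gene == g, ]
    key <- paste(gg$group, gg$bio_rep)
    ref_ct <- ref$ct[match(key, paste(ref$group, ref$bio_rep))]
    if (any(is.na(ref_ct))) {
      warning("gene ", g, ": no reference-gene Ct for ",
              paste(key[is.na(ref_ct)], collapse = "; "),
              "; replicate(s) excluded", call. = FALSE)
      gg <- gg[!is.na(ref_ct), ]
      ref_ct <- ref_ct[!is.na(ref_ct)]
    }
    dct <- gg$ct - ref_ct
    cal_mean <- mean(dct[gg$group == calibrator])
    if (is.nan(cal_mean)) {
      stop("gene ", g, ": calibrator group has no usable replicates",
           call. = FALSE)
    }
    fold <- 2^(-(dct - cal_mean))
    for (grp in unique(gg$group)) {
      f <- fold[gg$group == grp]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, group = grp, fold_change = mean(f),
        fold_sd = if (length(f) > 1) sd(f) else NA_real_,
        n_reps = length(f), stringsAsFactors = FALSE)
    }
    reps_out[[g]] <- data.frame(group = gg$group, bio_rep = gg$bio_rep,
                                fold = fold, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "replicates") <- reps_out
  out
}

# Compact letter display by the insertion method over a pairwise
# significance matrix. Groups ordered by decreasing mean; groups not
# significantly different share a letter.
.compact_letters <- function(sig, order_by) {
  groups <- rownames(sig)
  ord <- order(-order_by)
  groups <- groups[ord]
  sig <- sig[ord, ord, drop = FALSE]
  # start with one letter containing all, then split on each significant pair
  cols <- list(rep(TRUE, length(groups)))
  for (i in seq_along(groups)) {
    for (j in seq_len(i - 1L)) {
      if (!sig[i, j]) next
      for (k in seq_along(cols)) {
        if (cols[[k]][i] && cols[[k]][j]) {
          new1 <- cols[[k]]; new1[i] <- FALSE
          new2 <- cols[[k]]; new2[j] <- FALSE
          cols[[k]] <- new1
          # absorb duplicates
          dup <- any(vapply(cols, function(cc) all(cc == new2), logical(1)))
          if (!dup) cols[[length(cols) + 1L]] <- new2
        }
      }
      # drop columns contained in another column
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && keep[a] && keep[b] &&
              all(cols[[a]] <= cols[[b]]) && any(cols[[a]] < cols[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- cols[keep]
    }
  }
  letters_out <- vapply(seq_along(groups), function(i) {
    paste(letters[which(vapply(cols, function(cc) cc[i], logical(1)))],
          collapse = "")
  }, character(1))
  setNames(letters_out, groups)
}

#' Group comparisons: ANOVA + Tukey HSD, or a two-group t test
#'
#' With three or more groups: one-way ANOVA, Tukey HSD pairwise
#' comparisons, and a compact letter display at `alpha` (insertion method
#' over the significance matrix; groups ordered by decreasing mean share a
#' letter when not significantly different). With exactly two groups: a
#' two-sided Welch t test. Degenerate (zero-variance overall) inputs are
#' flagged and produce no letters.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length.
#' @param alpha significance level (default 0.05).
#' @return Object of class `"group_test"`: list with `method`, `p_value`
#'   (ANOVA F test or t test), `pairwise` (Tukey adjusted p-values or the t
#'   test p), `letters` (named by group), `flagged`.
#' @export
group_tests <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with >= 2 replicates each", call. = FALSE)
  }
  means <- tapply(values, groups, mean)
  if (sd(values) == 0) {
    return(structure(list(method = "degenerate", p_value = NA_real_,
                          pairwise = NULL,
                          letters = setNames(rep("a", length(tab)),
                                             names(tab)),
                          flagged = TRUE),
                     class = "group_test"))
  }
  if (length(tab) == 2) {
    tt <- t.test(values ~ groups)
    gs <- names(tab)
    same <- tt$p.value >= alpha
    lets <- if (same) setNames(c("a", "a"), gs)
            else setNames(c("a", "b"), names(sort(-means)))
    return(structure(list(method = "t.test", p_value = tt$p.value,
                          pairwise = setNames(tt$p.value,
                                              paste(gs[2], gs[1], sep = "-")),
                          letters = lets, flagged = FALSE),
                     class = "group_test"))
  }
  d <- data.frame(y = values, g = factor(groups))
  fit <- aov(y ~ g, data = d)
  sm <- summary(fit)[[1]]
  p <- sm[["Pr(>F)"]][1]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  padj <- tk[, "p adj"]
  gs <- levels(d$g)
  sig <- matrix(FALSE, length(gs), length(gs), dimnames = list(gs, gs))
  for (nm in rownames(tk)) {
    pair <- strsplit(nm, "-", fixed = TRUE)[[1]]
    s <- padj[nm] < alpha
    sig[pair[1], pair[2]] <- s
    sig[pair[2], pair[1]] <- s
  }
  lets <- .compact_letters(sig, means[gs])
  structure(list(method = "anova_tukey", p_value = p, pairwise = padj,
                 letters = lets, flagged = FALSE),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Group test (%s): p = %s\n", x$method,
              format(x$p_value, digits = 4)))
  if (!is.null(x$letters)) {
    cat("  letters:", paste(names(x$letters), x$letters, sep = "=",
                            collapse = ", "), "\n")
  }
  invisible(x)
}
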