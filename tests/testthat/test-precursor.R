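cfg <- miraux_config()

test_that("mature miRNA location with U/T equivalence", {
  mir <- "ACGUACGUACGUACGUACGUA"
  tx <- paste0(strrep("C", 30), chartr("U", "T", mir), strrep("C", 30))
  hits <- locate_mature(tx, mir)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 30)
  expect_equal(hits$end, 51)

  expect_equal(nrow(locate_mature(strrep("C", 60), mir)), 0)

  twice <- paste0(tx, chartr("U", "T", mir), strrep("C", 10))
  expect_equal(nrow(locate_mature(twice, mir)), 2)

  near <- paste0(strrep("C", 30),
                 sub("A", "G", chartr("U", "T", mir)), strrep("C", 30))
  expect_equal(nrow(locate_mature(near, mir, max_mismatch = 0)), 0)
  expect_equal(nrow(locate_mature(near, mir, max_mismatch = 1)), 1)
})

test_that("maximum base pairing fold: designed cases", {
  expect_equal(fold_window("AAAA")$structure, "....")
  f <- fold_window("GGGAAACCC", min_loop = 3)
  expect_equal(f$n_pairs, 3)
  expect_equal(f$structure, "(((...)))")
  # hairpin loop constraint: pairs closer than min_loop are forbidden
  expect_equal(fold_window("GC", min_loop = 3)$n_pairs, 0)
  expect_error(fold_window(strrep("A", 500)), "max_window")
  expect_error(fold_window("GGXCC"), "non-RNA")
})

test_that("fold pair count equals exhaustive enumeration for short windows", {
  set.seed(202)
  for (rep in 1:60) {
    s <- rand_rna(sample(6:14, 1))
    expect_equal(fold_window(s)$n_pairs, nussinov_oracle(s),
                 label = s)
  }
})

test_that("fold invariants: nestedness, legal pairs, loop size", {
  set.seed(7)
  for (rep in 1:25) {
    s <- rand_rna(sample(20:60, 1))
    f <- fold_window(s)
    p <- f$pairs
    if (nrow(p) == 0) next
    chars <- strsplit(f$seq, "")[[1]]
    for (r in seq_len(nrow(p))) {
      i <- p[r, 1]; j <- p[r, 2]
      expect_true(paste0(chars[i], chars[j]) %in%
                    c("AU", "UA", "CG", "GC", "GU", "UG"))
      expect_gt(j - i, 3)
    }
    # no crossing pairs
    for (a in seq_len(nrow(p))) {
      for (b in seq_len(nrow(p))) {
        if (a >= b) next
        i1 <- p[a, 1]; j1 <- p[a, 2]; i2 <- p[b, 1]; j2 <- p[b, 2]
        crossing <- (i1 < i2 && i2 < j1 && j1 < j2) ||
                    (i2 < i1 && i1 < j2 && j2 < j1)
        expect_false(crossing)
      }
    }
  }
})

test_that("stem membership on designed hairpins", {
  # spec-style construct: arm (25 nt) + 8-nt loop + reverse complement
  arm <- "GAGGAAGGGAGAAGGAAGAGAGGAA"          # purine arm, no self pairs
  arm3 <- chartr("ACGT", "UGCA",
                 paste(rev(strsplit(arm, "")[[1]]), collapse = ""))
  hp <- paste0(arm, "CCCCCCCC", arm3)
  f <- fold_window(hp)
  cand <- assess_stem_membership(f, c(2, 23), cfg)
  expect_true(cand$in_stem)
  expect_equal(cand$arm, "5p")
  expect_equal(cand$paired_fraction, 1.0)

  # span wholly inside the loop: loop bases are unpaired
  loop_span <- assess_stem_membership(f, c(26, 32), cfg)
  expect_false(loop_span$in_stem)
  expect_equal(loop_span$paired_fraction, 0)

  # span across the arm/loop junction fails the paired-fraction rule
  junc <- assess_stem_membership(f, c(15, 33), cfg)
  expect_false(junc$in_stem)

  # reverse complement swaps arms but preserves stem membership
  hp_rc <- chartr("ACGU", "UGCA",
                  paste(rev(strsplit(f$seq, "")[[1]]), collapse = ""))
  f_rc <- fold_window(hp_rc)
  n <- nchar(hp)
  cand_rc <- assess_stem_membership(f_rc, c(n - 23, n - 2), cfg)
  expect_true(cand_rc$in_stem)
  expect_equal(cand_rc$arm, "3p")

  expect_error(assess_stem_membership(f, c(50, 80), cfg), "outside")
})

test_that("Spearman correlation filter uses average ranks and strict 0.5", {
  r1 <- correlate_expression(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(r1$rho, 1)
  expect_true(r1$passes)

  r2 <- correlate_expression(c(1, 2, 3, 4), c(40, 30, 20, 10))
  expect_equal(r2$rho, -1)
  expect_false(r2$passes)

  # ties: equals the average-rank formula
  set.seed(33)
  for (rep in 1:20) {
    x <- sample(1:4, 8, replace = TRUE)
    y <- sample(1:4, 8, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(correlate_expression(x, y)$rho, spearman_oracle(x, y))
  }

  # invariance under strictly monotone transforms
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(correlate_expression(x, y)$rho,
               correlate_expression(exp(x), y^3 + 5 * y)$rho)

  # zero variance: undefined, flagged, fails
  r3 <- correlate_expression(rep(2, 5), c(1, 2, 3, 4, 5))
  expect_true(r3$flagged)
  expect_false(r3$passes)
  expect_true(is.na(r3$rho))

  # the threshold is strictly greater-than: rho exactly 0.5 fails
  r4 <- correlate_expression(1:5, c(2, 1, 5, 4, 3))
  expect_equal(r4$rho, 0.5)
  expect_false(r4$passes)
})

test_that("planted precursors are recovered with correct arm calls", {
  g <- gen_precursors(list(n_5p = 6, n_3p = 6, n_outside = 8), seed = 14)
  res <- find_precursors(g$transcripts, g$mirnas, cfg)
  m <- merge(g$truth, res, by = c("transcript_id", "mirna_id"))
  expect_equal(nrow(m), nrow(g$truth))
  expect_equal(m$in_stem, m$in_stem_expected)
  planted <- m[m$in_stem_expected, ]
  expect_equal(planted$arm, planted$arm_expected)
  expect_true(all(planted$paired_fraction >= 0.9))
})
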