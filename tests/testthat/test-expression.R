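test_that("FPKM and RPM follow their definitions", {
  m <- matrix(c(10, 990990), 2, 1, dimnames = list(c("f1", "f2"), "s1"))
  got <- fpkm(m, lengths = c(2000, 1000))
  expect_equal(got["f1", "s1"], 10 / ((10 + 990990) / 1e6) / 2)

  # counts 10, length 2000 nt, library total 1e6 -> FPKM 5.0
  lib <- matrix(c(10, 1e6 - 10), 2, 1)
  expect_equal(unname(fpkm(lib, c(2000, 1000))[1, 1]), 5.0)

  r <- rpm(matrix(c(7, 1e6 - 7), 2, 1))
  expect_equal(unname(r[1, 1]), 7)
  expect_equal(unname(colSums(r)), 1e6)

  expect_error(fpkm(matrix(0, 2, 1), c(100, 100)), "zero library")
  expect_error(rpm(matrix(0, 1, 1)), "zero library")
  expect_error(fpkm(matrix(1, 1, 1), 0), "> 0")
})

test_that("FPKM/RPM agree with a direct spreadsheet-style recomputation", {
  set.seed(91)
  for (rep in 1:10) {
    nf <- sample(3:8, 1); ns <- sample(2:5, 1)
    counts <- matrix(rpois(nf * ns, 50) + 1, nf, ns)
    lens <- sample(200:3000, nf)
    got_f <- fpkm(counts, lens)
    got_r <- rpm(counts)
    for (i in seq_len(nf)) {
      for (j in seq_len(ns)) {
        expect_equal(got_f[i, j],
                     counts[i, j] / (sum(counts[, j]) / 1e6) /
                       (lens[i] / 1e3))
        expect_equal(got_r[i, j], counts[i, j] / (sum(counts[, j]) / 1e6))
      }
    }
    # scaling a sample's counts uniformly leaves its FPKM unchanged
    scaled <- counts
    scaled[, 1] <- scaled[, 1] * 3
    expect_equal(fpkm(scaled, lens)[, 1], got_f[, 1])
    # permutation of features permutes rows accordingly
    pidx <- sample(nf)
    expect_equal(fpkm(counts[pidx, , drop = FALSE], lens[pidx]),
                 got_f[pidx, , drop = FALSE])
  }
})

test_that("row Z-scores use the population sd and flag constant rows", {
  z <- zscore_rows(matrix(c(1, 2, 3), 1, 3))
  expect_equal(unname(z[1, ]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  zc <- zscore_rows(matrix(c(5, 5, 5, 1, 2, 3), 2, 3, byrow = TRUE))
  expect_equal(unname(zc[1, ]), c(0, 0, 0))
  expect_equal(attr(zc, "flagged_rows"), 1L)

  set.seed(92)
  x <- matrix(rnorm(60), 6, 10)
  z2 <- zscore_rows(x)
  expect_true(all(abs(rowMeans(z2)) < 1e-9))
  expect_true(all(abs(sqrt(rowMeans(z2^2)) - 1) < 1e-9))
})

test_that("2^-ddCt: worked example, calibrator identity, shift invariance", {
  # gene Ct 20 vs ref 18 (treated); gene 22 vs ref 18 (calibrator):
  # ddCt = (20-18) - (22-18) = -2 -> fold 4
  q <- data.frame(gene = rep(c("g", "ref"), each = 2),
                  group = rep(c("treated", "control"), 2),
                  bio_rep = 1, tech_rep = 1, ct = c(20, 22, 18, 18))
  r <- ddct(q, "ref", "control")
  expect_equal(r$fold_change[r$group == "treated"], 4.0)
  expect_equal(r$fold_change[r$group == "control"], 1.0)

  # technical replicates are averaged on the Ct scale first
  q2 <- rbind(q, within(q, ct <- ct + 0.4))
  q2$tech_rep <- rep(1:2, each = 4)
  r2 <- ddct(q2, "ref", "control")
  expect_equal(r2$fold_change[r2$group == "treated"], 4.0)

  # adding a constant to every Ct of a sample cancels out
  q3 <- q
  q3$ct[q3$group == "treated"] <- q3$ct[q3$group == "treated"] + 3
  r3 <- ddct(q3, "ref", "control")
  expect_equal(r3$fold_change[r3$group == "treated"], 4.0)

  # missing reference replicate excluded with warning
  q4 <- data.frame(gene = c("g", "g", "ref"),
                   group = c("control", "control", "control"),
                   bio_rep = c(1, 2, 1), tech_rep = 1, ct = c(22, 23, 18))
  expect_warning(r4 <- ddct(q4, "ref", "control"), "excluded")
  expect_equal(r4$n_reps, 1)

  expect_error(ddct(q, "ref", "nogroup"), "calibrator")
  expect_error(ddct(q, "nogene", "control"), "reference")
})

test_that("planted qPCR fold changes are recovered within the noise band", {
  set.seed(93)
  est <- replicate(50, {
    g <- gen_qpcr(list(ct_sd = 0.2), seed = sample.int(1e6, 1))
    r <- ddct(g$qpcr, "LlActin", "control")
    r$fold_change[r$gene == "gene_four" & r$group == "drought"]
  })
  expect_gte(mean(est >= 3.0 & est <= 5.3), 0.95)
})

test_that("group tests: t test fallback, Tukey letters, degenerate input", {
  # identical groups: same letter
  set.seed(94)
  v <- c(rnorm(3, 5, 0.1), rnorm(3, 5, 0.1))
  g <- rep(c("a", "b"), each = 3)
  gt <- group_tests(v, g)
  expect_equal(gt$method, "t.test")
  expect_true(gt$p_value > 0.05)
  expect_equal(unname(gt$letters), c("a", "a"))

  # well-separated groups get different letters
  v2 <- c(rnorm(3, 0, 0.01), rnorm(3, 10, 0.01))
  gt2 <- group_tests(v2, rep(c("a", "b"), each = 3))
  expect_equal(sort(unname(gt2$letters)), c("a", "b"))

  # three groups, one distinct: the distinct group gets its own letter
  v3 <- c(rnorm(4, 0, 0.05), rnorm(4, 0.02, 0.05), rnorm(4, 8, 0.05))
  g3 <- rep(c("g1", "g2", "g3"), each = 4)
  gt3 <- group_tests(v3, g3)
  expect_equal(gt3$method, "anova_tukey")
  expect_true(gt3$p_value < 0.05)
  expect_equal(gt3$letters[["g1"]], gt3$letters[["g2"]])
  expect_false(gt3$letters[["g3"]] %in%
                 c(gt3$letters[["g1"]], gt3$letters[["g2"]]))

  # compact letters are consistent with the Tukey significance matrix
  set.seed(95)
  v4 <- rnorm(24, rep(c(0, 0.2, 4, 8), each = 6), 0.5)
  g4 <- rep(paste0("g", 1:4), each = 6)
  gt4 <- group_tests(v4, g4)
  for (nm in names(gt4$pairwise)) {
    pair <- strsplit(nm, "-")[[1]]
    share <- any(strsplit(gt4$letters[[pair[1]]], "")[[1]] %in%
                   strsplit(gt4$letters[[pair[2]]], "")[[1]])
    expect_equal(share, gt4$pairwise[[nm]] >= 0.05,
                 label = paste("pair", nm))
  }

  degen <- group_tests(rep(1, 6), rep(c("a", "b"), each = 3))
  expect_true(degen$flagged)

  expect_error(group_tests(1:3, c("a", "a", "b")), ">= 2")
})
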