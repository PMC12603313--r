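cfg <- miraux_config()

test_that("site penalty: perfect complement, seed weighting, G:U wobble", {
  set.seed(51)
  mir <- rand_rna(21)
  perfect <- reverse_complement_rna(mir)
  s0 <- score_site(mir, perfect)
  expect_equal(s0$penalty, 0)
  expect_true(all(s0$alignment$state == "match"))

  # mismatch opposite position 15 costs 1; the same edit at position 5
  # (seed region) costs 2
  mm_at <- function(pos) {
    w <- strsplit(perfect, "")[[1]]
    q <- strsplit(mir, "")[[1]][pos]
    bad <- setdiff(c("A", "C", "G", "U"),
                   c(chartr("ACGU", "UGCA", q),
                     if (q == "G") "U", if (q == "U") "G"))[1]
    w[nchar(perfect) - pos + 1] <- bad
    paste(w, collapse = "")
  }
  expect_equal(score_site(mir, mm_at(15))$penalty, 1.0)
  expect_equal(score_site(mir, mm_at(5))$penalty, 2.0)

  # G:U wobble costs half a mismatch
  gpos <- which(strsplit(mir, "")[[1]] == "G" & seq_len(21) > 13)
  if (length(gpos) > 0) {
    w <- strsplit(perfect, "")[[1]]
    w[nchar(perfect) - gpos[1] + 1] <- "U"
    expect_equal(score_site(mir, paste(w, collapse = ""))$penalty, 0.5)
  }

  # cleavage is predicted opposite miRNA position 10
  expect_equal(s0$cleavage_window_pos, nchar(perfect) - 10 + 1)

  expect_error(score_site(mir, "ACGU"), "max_bulge")
  expect_error(score_site("ACXU", "ACGU"), "non-RNA")
})

test_that("penalty equals exhaustive alignment enumeration", {
  set.seed(52)
  for (rep in 1:60) {
    m <- sample(6:12, 1)
    mir <- rand_rna(m)
    win <- rand_rna(m + sample(-2:2, 1))
    expect_equal(score_site(mir, win)$penalty,
                 site_penalty_oracle(mir, win),
                 label = paste(mir, win))
  }
})

test_that("penalty is zero iff gap-free perfect complementarity", {
  set.seed(53)
  for (rep in 1:20) {
    mir <- rand_rna(21)
    s <- score_site(mir, reverse_complement_rna(mir))
    expect_equal(s$penalty, 0)
    w <- strsplit(reverse_complement_rna(mir), "")[[1]]
    q10 <- strsplit(mir, "")[[1]][10]
    w[12] <- setdiff(c("A", "C", "G", "U"),
                     c(chartr("ACGU", "UGCA", q10),
                       if (q10 == "G") "U", if (q10 == "U") "G"))[1]
    expect_gt(score_site(mir, paste(w, collapse = ""))$penalty, 0)
  }
})

test_that("worsening one position never decreases the penalty", {
  # match -> GU -> mismatch at a fixed position is monotone in cost
  mir <- "AAGGCUACGUACGUACGUACG"
  perfect <- reverse_complement_rna(mir)
  w <- strsplit(perfect, "")[[1]]
  pos <- 17                                  # miRNA position (weight 1)
  j <- nchar(perfect) - pos + 1
  stopifnot(strsplit(mir, "")[[1]][pos] == "G")
  p_match <- score_site(mir, perfect)$penalty
  w[j] <- "U"                                # G:U
  p_gu <- score_site(mir, paste(w, collapse = ""))$penalty
  w[j] <- "A"                                # mismatch
  p_mm <- score_site(mir, paste(w, collapse = ""))$penalty
  expect_true(p_match <= p_gu && p_gu <= p_mm)
})

test_that("target scan recovers planted sites at the penalty threshold", {
  g <- gen_targets(list(), seed = 61)
  sites <- scan_targets(g$mirnas, g$transcripts, cfg)
  expected <- g$truth[g$truth$penalty <= cfg$max_penalty, ]
  got <- merge(expected, sites, by = c("mirna_id", "transcript_id"),
               suffixes = c(".exp", ".got"))
  expect_equal(nrow(sites), nrow(expected))
  expect_equal(nrow(got), nrow(expected))
  expect_equal(got$penalty.got, got$penalty.exp)
  expect_equal(got$site_start.got, got$site_start.exp)
  expect_equal(got$cleavage_pos.got, got$cleavage_pos.exp)
})

test_that("degradome categories follow the ladder definitions", {
  prof <- data.frame(position = c(100, 200, 300), count = c(50, 3, 2))
  expect_equal(categorise_cleavage(prof, 100)$category, 0L)

  shared <- data.frame(position = c(100, 200), count = c(5, 5))
  expect_equal(categorise_cleavage(shared, 100)$category, 1L)

  single <- data.frame(position = c(100, 200), count = c(1, 7))
  expect_equal(categorise_cleavage(single, 100)$category, 4L)

  none <- categorise_cleavage(prof, 150)
  expect_true(is.na(none$category))
  expect_equal(none$reads_at_site, 0L)

  set.seed(62)
  for (rep in 1:100) {
    k <- sample(2:12, 1)
    pos <- sort(sample(1:500, k))
    cnt <- sample(1:40, k, replace = TRUE)
    prof <- data.frame(position = pos, count = cnt)
    cp <- if (rep %% 3 == 0) sample(1:500, 1) else sample(pos, 1)
    expect_equal(categorise_cleavage(prof, cp)$category,
                 category_oracle(pos, cnt, cp))
  }
})

test_that("category order statistics are scale-invariant and monotone", {
  set.seed(63)
  for (rep in 1:25) {
    k <- sample(3:10, 1)
    pos <- sort(sample(1:400, k))
    cnt <- sample(2:30, k, replace = TRUE)
    cp <- sample(pos, 1)
    base <- categorise_cleavage(data.frame(position = pos, count = cnt),
                                cp)$category
    scaled <- categorise_cleavage(data.frame(position = pos,
                                             count = cnt * 5), cp)$category
    expect_equal(scaled, base)       # categories 0-2 depend on order stats
    # adding reads at the cleavage position never worsens the category
    cnt2 <- cnt
    cnt2[pos == cp] <- cnt2[pos == cp] + 10
    better <- categorise_cleavage(data.frame(position = pos, count = cnt2),
                                  cp)$category
    expect_lte(better, base)
  }
})

test_that("T-plot export round-trips and flags the cleavage row", {
  prof <- data.frame(position = c(30, 10, 20), count = c(4, 2, 9))
  out <- withr::local_tempfile(fileext = ".tsv")
  tp <- export_tplot(prof, 20, out)
  expect_equal(tp$position, c(10, 20, 30))   # ordered by position
  expect_equal(tp$is_cleavage, c(FALSE, TRUE, FALSE))
  back <- read.delim(out)
  expect_equal(back$position, tp$position)
  expect_equal(back$count, tp$count)
  # profile reconstructable from the exported table
  expect_equal(back[order(back$position), "count"],
               prof[order(prof$position), "count"])

  empty <- export_tplot(data.frame(position = integer(), count = integer()),
                        5)
  expect_equal(nrow(empty), 0)
})

test_that("module table joins evidence with classifications", {
  ev <- data.frame(mirna_id = c("lup-miR393a", "lup-miR393a"),
                   transcript_id = c("t1", "t2"),
                   site_start = c(10, 20), site_end = c(31, 41),
                   penalty = c(0, 1.5), cleavage_pos = c(22, 32),
                   category = c(0L, 2L))
  ann <- data.frame(transcript_id = c("t1", "t2"),
                    annotation = c("receptor", "full_arf"))
  tab <- build_module_table(ev, ann, cfg)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$mirna_family, c("MIR393", "MIR393"))
  expect_equal(tab$annotation, c("receptor", "full_arf"))

  # dangling transcript: warning, annotated unclassified, not dropped
  expect_warning(tab2 <- build_module_table(ev, ann[1, , drop = FALSE], cfg),
                 "unclassified")
  expect_equal(nrow(tab2), 2)
  expect_equal(tab2$annotation[tab2$transcript_id == "t2"], "unclassified")

  # category filter
  strict <- build_module_table(ev, ann, miraux_config(max_category = 1))
  expect_equal(nrow(strict), 1)
})
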