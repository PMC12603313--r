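refs <- reference_set()
cfg <- miraux_config()

test_that("residue anchoring transfers reference numbering onto queries", {
  tir <- refs$tir
  checks <- anchor_residues(tir$seq, tir$seq, tir$pocket, cfg,
                            ref_name = tir$id)
  expect_equal(nrow(checks), 11)
  expect_true(all(checks$conserved))

  # single planted substitution K410 -> R flips exactly that check
  q <- tir$seq
  substr(q, 410, 410) <- "R"
  checks2 <- anchor_residues(q, tir$seq, tir$pocket, cfg)
  expect_equal(checks2$ref_pos[!checks2$conserved], 410)
  expect_equal(checks2$query_aa[!checks2$conserved], "R")

  # deletion spanning 438-441 reports gaps as non-conserved
  q3 <- paste0(substring(tir$seq, 1, 425), substring(tir$seq, 456))
  checks3 <- anchor_residues(q3, tir$seq, tir$pocket, cfg)
  gap_rows <- checks3[checks3$ref_pos %in% 438:441, ]
  expect_true(all(!gap_rows$conserved))
  expect_true(all(gap_rows$query_aa == "-"))

  # expected residues are validated against the reference itself
  bad <- data.frame(pos = 410, aa = "W", role = "orientation")
  expect_error(anchor_residues(tir$seq, tir$seq, bad, cfg),
               "reference/position mismatch")
})

test_that("anchoring is invariant to N-terminal padding of the query", {
  tir <- refs$tir
  padded <- paste0("GSGSGSGSGSGSGS", tir$seq)
  checks <- anchor_residues(padded, tir$seq, tir$pocket, cfg)
  expect_true(all(checks$conserved))
})

test_that("TIR1/AFB classification reproduces the curation funnel", {
  tir <- refs$tir
  r1 <- classify_tir_afb(tir$seq, refs, cfg)
  expect_equal(r1$verdict, "receptor")
  expect_equal(sum(r1$pocket_checks$conserved), 11)
  expect_equal(sum(r1$ac_checks$conserved), 3)

  # C-terminal truncation: the LRR ring cannot close
  trunc <- substring(tir$seq, 1, round(0.6 * nchar(tir$seq)))
  r2 <- classify_tir_afb(trunc, refs, cfg)
  expect_equal(r2$verdict, "incomplete")
  expect_true(r2$has_fbox)
  expect_lt(r2$lrr_coverage, cfg$lrr_min_coverage)

  # AC-domain Asn -> Asp in the first key position is reported but does not
  # revoke receptor status
  q <- tir$seq
  substr(q, tir$ac$pos[1], tir$ac$pos[1]) <- "D"
  r3 <- classify_tir_afb(q, refs, cfg)
  expect_equal(r3$verdict, "receptor")
  expect_false(r3$ac_checks$conserved[1])
  expect_equal(r3$ac_checks$query_aa[1], "D")
  expect_equal(r3$ac_checks$ref_aa[1], "N")   # first key position is Asn

  # randomised F-box span fails the F-box quality threshold
  set.seed(8)
  q4 <- tir$seq
  substr(q4, tir$fbox[1], tir$fbox[2]) <-
    paste(sample(c("A", "V", "T", "E"), tir$fbox[2] - tir$fbox[1] + 1,
                 replace = TRUE), collapse = "")
  r4 <- classify_tir_afb(q4, refs, cfg)
  expect_equal(r4$verdict, "rejected")

  # incomplete ORFs are rejected outright
  p <- data.frame(transcript_id = "x", aa_seq = tir$seq, complete = FALSE)
  expect_equal(classify_tir_afb(p, refs, cfg)$verdict, "rejected")
})

test_that("B3 motif scan finds SxxxxHGxxSxxR and reports substitutions", {
  hit <- scan_dbd_motif("AAASACDEHGKLSQWRAAA")
  expect_equal(hit$n_mismatch, 0)
  expect_equal(hit$window, "SACDEHGKLSQWR")
  expect_equal(length(hit$substitutions), 0)

  # the ARF17/18-type H -> G variant is detected and recorded
  var <- scan_dbd_motif("AAASACDEGGKLSQWRAAA")
  expect_equal(var$n_mismatch, 1)
  expect_equal(unname(var$substitutions["H"]), "G")

  # two mismatches exceed the default tolerance
  expect_null(scan_dbd_motif("AAASACDEGGKLSQWAAAA"))
})

test_that("B3 motif scan agrees with a brute-force window oracle", {
  set.seed(77)
  n_present <- 0
  for (rep in 1:60) {
    aa <- rand_protein(200)
    got <- scan_dbd_motif(aa)
    exp <- dbd_scan_oracle(aa)
    if (is.null(exp)) {
      expect_null(got)
    } else {
      n_present <- n_present + 1
      expect_equal(got$start, exp$start)
      expect_equal(got$n_mismatch, exp$n_mismatch)
    }
  }
  # planted motifs to make sure the positive path is exercised too
  for (rep in 1:10) {
    aa <- paste0(rand_protein(40), "SACDEHGKLSQWR", rand_protein(40))
    expect_equal(scan_dbd_motif(aa)$n_mismatch, 0)
  }
})

test_that("PB1 typing distinguishes the lysine and OPCA faces", {
  arf <- refs$arf
  pb1_region <- substring(arf$seq, arf$pb1[1], arf$pb1[2])
  full <- type_pb1(pb1_region, refs, cfg)
  expect_equal(full$type, "full")
  expect_true(full$motif_I && full$motif_II)

  # canonical K -> A leaves only the OPCA face (type I)
  k_rel <- arf$pb1_k - arf$pb1[1] + 1
  edited <- pb1_region
  substr(edited, k_rel, k_rel) <- "A"
  t1 <- type_pb1(edited, refs, cfg)
  expect_equal(t1$type, "typeI_OPCA_only")

  # OPCA first/last D removed leaves only the lysine face (type II)
  opca_rel <- arf$opca - arf$pb1[1] + 1
  edited2 <- pb1_region
  substr(edited2, opca_rel[1], opca_rel[1]) <- "K"
  substr(edited2, opca_rel[2], opca_rel[2]) <- "K"
  t2 <- type_pb1(edited2, refs, cfg)
  expect_equal(t2$type, "typeII_lysine_only")

  # unrelated sequence: no region reaches the identity threshold
  set.seed(5)
  expect_equal(type_pb1(rand_protein(200), refs, cfg)$type, "absent")
})

test_that("middle-domain composition rule separates the two families", {
  act <- classify_md(strrep("QQQSSSLLL", 5), 1, 45,
                     miraux_config(md_min_len = 20))
  expect_equal(act$md_call, "activator")
  expect_equal(sum(act$composition), 1, tolerance = 1e-9)

  rep_ <- classify_md(strrep("SSLLPPGG", 5), 1, 40,
                      miraux_config(md_min_len = 20))
  expect_equal(rep_$md_call, "repressor")
  expect_equal(unname(rep_$composition["Q"]), 0)

  # scale invariance: doubling the span leaves the call unchanged
  act2 <- classify_md(strrep("QQQSSSLLL", 10), 1, 90,
                      miraux_config(md_min_len = 20))
  expect_equal(act2$md_call, "activator")

  # spans shorter than md_min_len yield no call; inverted spans error
  expect_equal(classify_md("QQQSSSLLL", 1, 9, cfg)$md_call, "none")
  expect_error(classify_md("QQQSSSLLL", 5, 2, cfg), "invalid")

  set.seed(19)
  seqs_a <- gen_md_sequences(100, "activator")
  seqs_r <- gen_md_sequences(100, "repressor")
  calls_a <- vapply(seqs_a, function(s) {
    classify_md(s, 1, nchar(s), cfg)$md_call
  }, character(1))
  calls_r <- vapply(seqs_r, function(s) {
    classify_md(s, 1, nchar(s), cfg)$md_call
  }, character(1))
  expect_true(all(calls_a == "activator"))
  expect_true(all(calls_r == "repressor"))
})

test_that("architecture mapping is deterministic over domain flags", {
  expect_equal(assign_architecture(TRUE, TRUE, TRUE)$architecture,
               "full_arf")
  expect_equal(assign_architecture(TRUE, FALSE, FALSE)$architecture,
               "dbd_only")
  expect_equal(assign_architecture(FALSE, FALSE, TRUE)$architecture,
               "pb1_only")
  expect_equal(assign_architecture(TRUE, TRUE, FALSE)$architecture,
               "no_pb1")
  expect_equal(assign_architecture(FALSE, FALSE, FALSE)$architecture,
               "no_dbd")
})

test_that("planted architectures are recovered exactly on a small cohort", {
  g <- gen_transcriptome(list(arf_classes = c(full_arf = 4, dbd_only = 4,
                                              pb1_only = 4, no_pb1 = 4,
                                              no_dbd = 4),
                              arf_md_class = "mixed",
                              tir_classes = c(intact = 2, truncated = 2,
                                              ac_edit = 2, no_fbox = 2),
                              n_decoys = 0),
                         seed = 21, refs = refs)
  orfs <- longest_orfs(g$transcripts)
  cls <- classify_proteins(orfs, refs, cfg)
  tir <- merge(g$truth, data.frame(id = cls$tir$protein_id,
                                   got = cls$tir$verdict))
  expect_true(all(tir$got == tir$expected))
  arf <- merge(g$truth, data.frame(id = cls$arf$protein_id,
                                   got = cls$arf$architecture))
  expect_true(all(arf$got == arf$expected))
})
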