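test_that("a germline-identical read aligns gaplessly with zero mutations", {
  db <- annotate_repertoire(make_db(make_read()), test_ref)
  expect_true(db$v_aligned)
  expect_equal(db$v_identity, 1)
  expect_equal(db$v_coverage, 1)
  expect_equal(db$n_mutations, 0L)
  expect_false(grepl("-", db$aln_germ))
})

test_that("chosen substitutions are recovered exactly with codon context", {
  subs <- c("5" = "A", "98" = "T", "102" = "C", "200" = "G", "294" = "A")
  db <- annotate_repertoire(make_db(make_read(subs)), test_ref)
  mut <- db$mutations[[1]]
  expect_equal(mut$pos, c(5L, 98L, 102L, 200L, 294L))
  expect_identical(mut$to, unname(subs))
  expect_identical(mut$from, GERM[c(5, 98, 102, 200, 294)])
  expect_identical(mut$region, c("FR1", "CDR1", "FR2", "FR3", "FR3"))
  # W33L: codon 33 TGG -> TTG, i.e. tryptophan to leucine
  w33 <- mut[mut$pos == 98, ]
  expect_identical(w33$aa_from, "W")
  expect_identical(w33$aa_to, "L")
  expect_true(db$has_w33l)
  expect_true(db$has_pos102)
  # independent check: translate the read codon 33 from scratch
  expect_identical(clonmix:::translate_nt(substr(db$nt_seq, 97, 99)), "L")
  # involution: applying the called mutations to the germline reconstructs
  # the read's V region
  expect_identical(apply_mutations(test_ref, mut),
                   substr(db$nt_seq, 1, nchar(test_ref$nt_seq)))
})

test_that("unrelated sequences are flagged non-target below the identity floor", {
  set.seed(99)
  junk <- paste(sample(c("A", "C", "G", "T"), 294 + 63, replace = TRUE),
                collapse = "")
  db <- annotate_repertoire(make_db(junk), test_ref)
  expect_false(db$v_aligned)
  expect_identical(db$reject_reason, "not_vh186")
  # brute-force check on the forced gapless alignment: identity really is
  # below the 70% floor
  ham_id <- mean(strsplit(substr(junk, 1, 294), "")[[1]] == GERM)
  expect_lt(ham_id, 0.7)
})

test_that("short reads are rejected with a reason code, not an exception", {
  db <- annotate_repertoire(make_db(substr(make_read(), 1, 100)), test_ref)
  expect_false(db$v_aligned)
  expect_identical(db$reject_reason, "too_short")
  expect_identical(db$cdr3_reason, "not_aligned")
  expect_true(is.na(db$np_binding))
})

test_that("N bases are skipped, indel codons excluded from aa inference", {
  read <- make_read(c("50" = "A"))
  substr(read, 10, 10) <- "N"
  db <- annotate_repertoire(make_db(read), test_ref)
  expect_equal(db$n_skipped, 1L)
  expect_equal(db$mutations[[1]]$pos, 50L)
  # deletion of one base: indel tallied, overlapping codon aa set to NA
  read2 <- paste0(substr(make_read(c("31" = "A")), 1, 59),
                  substr(make_read(c("31" = "A")), 61, 1000))
  db2 <- annotate_repertoire(make_db(read2), test_ref)
  expect_true(db2$v_aligned)
  expect_gte(db2$n_indels, 1L)
  expect_equal(db2$mutations[[1]]$pos[1], 31L)
})

test_that("CDR3 extraction inverts the read construction", {
  for (aa in c("ARYYYGSSDY", "ARDYYYGSSV", "AKYYYGMD")) {
    db <- annotate_repertoire(make_db(make_read(cdr3_aa = aa)), test_ref)
    expect_identical(db$cdr3_aa, aa)
    expect_identical(db$cdr3_nt, clonmix:::encode_aa(aa))
    expect_true(db$productive)
  }
  # no junction appended: V ends at FR3, no J anchor downstream
  db <- annotate_repertoire(make_db(make_read(junction = FALSE)), test_ref)
  expect_true(is.na(db$cdr3_aa))
  expect_identical(db$cdr3_reason, "no_junction")
  # read truncated before the FR3 end
  db <- annotate_repertoire(make_db(substr(make_read(), 1, 250)), test_ref)
  expect_true(is.na(db$cdr3_aa))
  expect_identical(db$cdr3_reason, "fr3_end_uncovered")
})

test_that("NP classification implements the CDR3 rule exactly", {
  cfg <- annotate_config()
  # length outside 9-11
  expect_false(classify_np_binding("ARYYYGDY", cfg))          # 8 aa
  expect_false(classify_np_binding("ARYYYGSSGMDY", cfg))      # 12 aa
  # anchor residue (3rd by default) not tyrosine
  expect_false(classify_np_binding("ARFYYYGSDV", cfg))
  # anchor Y followed by Y,Y,G: satisfied
  expect_true(classify_np_binding("ARYYYGSSDV", cfg))
  # anchor Y but fewer than two tyrosines in the next three
  expect_false(classify_np_binding("ARYDGSYYDV", cfg))
  # stop codon: nonproductive, classified FALSE
  expect_false(classify_np_binding("ARY*YGSSDV", cfg))
  expect_true(is.na(classify_np_binding(NA_character_, cfg)))
  # the anchor offset is configurable
  cfg4 <- annotate_config(np_offset = 4)
  expect_true(classify_np_binding("ARFYYYGSDV", cfg4))
  expect_false(classify_np_binding("ARYYDGSSDV", cfg4))
})

test_that("mutation calling is an involution on simulated repertoires", {
  sim <- simulate_repertoire(
    simulation_config(seed = 13, n_mice = 2, clones_per_mouse = 8))
  db <- annotate_repertoire(sim$db, test_ref)
  glen <- nchar(test_ref$nt_seq)
  for (i in seq_len(nrow(db))) {
    expect_identical(apply_mutations(test_ref, db$mutations[[i]]),
                     substr(db$nt_seq[i], 1, glen))
  }
})

test_that("group summaries report loads, affinity fractions and MW tests", {
  db <- annotate_repertoire(
    make_db(c(make_read(c("5" = "A", "10" = "A", "15" = "A", "20" = "A",
                          "25" = "A")),
              make_read(c("98" = "T"))),
            subset = c("MEMORY", "LONGLIVED_PC")), test_ref)
  db$has_cdr3_yg <- c(FALSE, FALSE)
  s <- mutation_summary(db, group_by = "subset")
  expect_equal(s$mean_mut[s$subset == "MEMORY"], 5)
  expect_equal(s$frac_w33l[s$subset == "LONGLIVED_PC"], 1)
  # a requested group with no sequences yields n = 0, not an error
  s2 <- mutation_summary(db, group_by = "subset",
                         groups = data.frame(subset = c("MEMORY", "BOOST_PC")))
  expect_equal(s2$n[s2$subset == "BOOST_PC"], 0)
  expect_true(is.na(s2$mean_mut[s2$subset == "BOOST_PC"]))
  # spectrum counts each mutated position once per sequence
  sp <- position_spectrum(db, test_ref)
  expect_equal(sum(sp$count), 6)
  expect_equal(sp$count[sp$pos == 98], 1)
})

test_that("Mann-Whitney comparison of identical groups is well calibrated", {
  set.seed(1)
  n_ok <- 0L
  for (rep in 1:100) {
    x <- stats::rpois(30, 5)
    y <- stats::rpois(30, 5)
    db <- data.frame(v_aligned = TRUE, n_mutations = c(x, y),
                     grp = rep(c("a", "b"), each = 30))
    if (compare_groups(db, "grp", "a", "b")$p > 0.05) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 94)
})
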