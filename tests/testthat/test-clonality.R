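test_that("junction identity drives single-linkage clone grouping", {
  # identical junctions: one clone of two
  db <- annotate_repertoire(make_db(c(make_read(c("5" = "A")),
                                      make_read(c("10" = "A")))), test_ref)
  db <- group_clones(db)
  expect_identical(db$clone_id[1], db$clone_id[2])
  # same CDR3 length, junction identity ~0.5: two singleton clones
  db2 <- annotate_repertoire(
    make_db(c(make_read(cdr3_aa = "ARYYYGSSDV"),
              make_read(cdr3_aa = "TPYYYGKLMN"))), test_ref)
  id <- mean(strsplit(db2$cdr3_nt[1], "")[[1]] ==
               strsplit(db2$cdr3_nt[2], "")[[1]])
  expect_lt(id, 0.9)
  db2 <- group_clones(db2)
  expect_false(db2$clone_id[1] == db2$clone_id[2])
  # different CDR3 lengths never link
  db3 <- annotate_repertoire(
    make_db(c(make_read(cdr3_aa = "ARYYYGSSDV"),
              make_read(cdr3_aa = "ARYYYGSSDYV"))), test_ref)
  db3 <- group_clones(db3, threshold = 0)
  expect_false(db3$clone_id[1] == db3$clone_id[2])
})

test_that("grouping is a partition with an explicit unassigned pool", {
  sim <- simulate_repertoire(
    simulation_config(seed = 23, n_mice = 2, clones_per_mouse = 8))
  db <- annotate_repertoire(sim$db, test_ref)
  db$cdr3_nt[1] <- NA  # simulate an undefined CDR3
  db <- group_clones(db)
  expect_true(is.na(db$clone_id[1]))          # sentinel pool, never dropped
  expect_true(all(!is.na(db$clone_id[-1])))
  # deterministic: same input, same output
  expect_identical(db$clone_id, group_clones(db[, setdiff(
    names(db), "clone_id")])$clone_id)
  # clones never span mice
  ct <- clone_table(db)
  expect_true(all(table(ct$clone_id) == 1))
  expect_identical(ct$mouse_id, sub("_c\\d+$", "", ct$clone_id))
})

test_that("truth clones are recovered exactly under clear identity separation", {
  # no CDR3 Y->G events, so intra-clone junction identity is exactly 1
  sim <- simulate_repertoire(
    simulation_config(seed = 31, n_mice = 3, clones_per_mouse = 12,
                      w33l_share = 1))
  db <- annotate_repertoire(sim$db, test_ref)
  # brute-force separation check: intra-clone pairs >= 0.95 identity,
  # inter-clone pairs (same mouse, same CDR3 length) <= 0.7
  tr <- sim$truth$sequences
  for (mouse in unique(tr$mouse_id)) {
    idx <- which(tr$mouse_id == mouse)
    for (i in idx) for (j in idx) {
      if (i < j && nchar(db$cdr3_nt[i]) == nchar(db$cdr3_nt[j])) {
        id <- mean(strsplit(db$cdr3_nt[i], "")[[1]] ==
                     strsplit(db$cdr3_nt[j], "")[[1]])
        if (tr$clone[i] == tr$clone[j]) expect_gte(id, 0.95)
        else expect_lte(id, 0.7)
      }
    }
  }
  db <- group_clones(db, threshold = 0.90)
  expect_equal(mclust::adjustedRandIndex(db$clone_id, tr$clone), 1)
})

test_that("overlap report arithmetic matches hand-computed fractions", {
  # all singleton clones: zero mixed
  db <- annotate_repertoire(
    make_db(c(make_read(cdr3_aa = "ARYYYGSSDV"),
              make_read(cdr3_aa = "TPYYYGKLMN")),
            subset = c("MEMORY", "LONGLIVED_PC")), test_ref)
  db <- group_clones(db)
  ov0 <- overlap_table(db)
  expect_equal(ov0$per_mouse$n_mixed, 0)
  # one clone holding 5 of 6 BM and 1 of 4 LP sequences
  reads <- replicate(10, make_read(cdr3_aa = "ARYYYGSSDV"))
  db <- make_db(reads, subset = c(rep("LONGLIVED_PC", 6), rep("MEMORY", 4)))
  db <- annotate_repertoire(db, test_ref)
  # clone A: reads 1-5 (PC) + 7 (memory); clone B: read 6 (PC singleton);
  # clone C: reads 8-10 (memory)
  db$cdr3_nt[6] <- clonmix:::encode_aa("TPNNNGKLMN")
  db$cdr3_nt[8:10] <- clonmix:::encode_aa("GSHHHKLMNP")
  db <- group_clones(db)
  ov <- overlap_table(db, "subset", "LONGLIVED_PC", "MEMORY")
  expect_equal(ov$per_mouse$n_mixed, 1)
  expect_equal(ov$mixed_clones$frac_of_a, 5 / 6)
  expect_equal(ov$mixed_clones$frac_of_b, 1 / 4)
  # absent axis label: zeros plus warning, no exception
  expect_warning(ovz <- overlap_table(db, "subset", "LONGLIVED_PC",
                                      "BOOST_PC"), "BOOST_PC")
  expect_equal(ovz$per_mouse$n_mixed, 0)
})

test_that("clone-level mixing parameter controls compartment spanning", {
  sim0 <- simulate_repertoire(
    simulation_config(seed = 7, n_mice = 2, clones_per_mouse = 15,
                      mixing = 0))
  expect_true(all(sim0$truth$clones$n_subsets == 1))
  db0 <- annotate_repertoire(sim0$db, test_ref)
  db0 <- group_clones(db0)
  expect_equal(sum(overlap_table(db0)$per_mouse$n_mixed), 0)

  sim1 <- simulate_repertoire(
    simulation_config(seed = 7, n_mice = 2, clones_per_mouse = 15,
                      mixing = 1))
  cl <- sim1$truth$clones
  expect_true(all(cl$n_subsets[cl$size >= 2] == 2))
  db1 <- annotate_repertoire(sim1$db, test_ref)
  db1 <- group_clones(db1)
  expect_equal(sum(overlap_table(db1,
                                 a = "MEMORY",
                                 b = "LONGLIVED_PC")$per_mouse$n_mixed),
               sum(cl$size >= 2))
})

test_that("CDR3 Y->G is flagged against the clone consensus junction", {
  sim <- simulate_repertoire(
    simulation_config(seed = 57, n_mice = 2, clones_per_mouse = 12,
                      p_haff = 0.6, w33l_share = 0.5))
  db <- annotate_repertoire(sim$db, test_ref)
  db <- group_clones(db)
  db <- flag_high_affinity(db)
  tr <- sim$truth$sequences
  expect_gt(sum(tr$has_yg_true), 0)   # the regime actually produced events
  # the ancestral junction is only inferable within multi-member clones
  sz <- table(tr$clone)
  multi <- tr$clone %in% names(sz)[sz >= 2]
  expect_identical(db$has_cdr3_yg[multi], tr$has_yg_true[multi])
  expect_true(all(is.na(db$has_cdr3_yg[!multi])))
  expect_identical(db$high_affinity[multi],
                   (tr$has_w33l_true | tr$has_yg_true)[multi])
})
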