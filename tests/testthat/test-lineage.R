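ann_clone <- function(reads, cdr3 = "ARYYYGSSDV") {
  db <- annotate_repertoire(make_db(vapply(reads, function(s)
    make_read(s, cdr3_aa = cdr3), "")), test_ref)
  db$clone_id <- "c1"
  db
}

test_that("nested mutations give a chain, disjoint ones a star", {
  # germline+m1 and germline+m1+m2: chain with unit edges
  db <- ann_clone(list(c("10" = "A"), c("10" = "A", "20" = "C")))
  tree <- build_tree(db, "c1", test_ref)
  expect_equal(tree$total_mutations, 2)
  st <- tree_stats(tree)
  expect_equal(st$n_leaves, 1)
  expect_true(st$unbranched)
  expect_equal(st$pl_max, 2)
  expect_equal(sort(tree$edges$n_mut), c(1, 1))
  # germline+m1 and germline+m2: star from the root
  db2 <- ann_clone(list(c("10" = "A"), c("20" = "C")))
  tree2 <- build_tree(db2, "c1", test_ref)
  expect_equal(tree2$total_mutations, 2)
  st2 <- tree_stats(tree2)
  expect_equal(st2$trunk_length, 0)
  expect_equal(st2$n_leaves, 2)
  expect_equal(st2$max_out_degree, 2)
})

test_that("shared mutations are factored into inferred intermediates", {
  db <- ann_clone(list(c("10" = "A", "20" = "C", "30" = "G"),
                       c("10" = "A", "20" = "C", "40" = "T")))
  tree <- build_tree(db, "c1", test_ref)
  # optimal: root -> i1 {10,20} -> each leaf, total 2 + 1 + 1
  expect_equal(tree$total_mutations, 4)
  expect_equal(sum(tree$nodes$type == "inferred"), 1)
  st <- tree_stats(tree)
  expect_equal(st$trunk_length, 2)
  expect_equal(st$pl_min, 3)
})

test_that("trivial shape statistics match hand computation", {
  db <- ann_clone(list(c("10" = "A", "20" = "C", "30" = "G")))
  st <- tree_stats(build_tree(db, "c1", test_ref))
  expect_equal(st$pl_min, 3)
  expect_equal(st$pl_max, 3)
  expect_true(st$unbranched)
  db2 <- ann_clone(list(c("10" = "A"), c("20" = "C"), c("30" = "G")))
  st2 <- tree_stats(build_tree(db2, "c1", test_ref))
  expect_equal(st2$trunk_length, 0)
  expect_equal(st2$pl_min, 1)
  expect_equal(st2$max_out_degree, 3)
  # duplicate reads collapse into one node with multiplicity
  db3 <- ann_clone(list(c("10" = "A"), c("10" = "A")))
  tree3 <- build_tree(db3, "c1", test_ref)
  expect_equal(sum(tree3$nodes$type == "observed"), 1)
  expect_equal(tree3$nodes$multiplicity[tree3$nodes$type == "observed"], 2)
})

test_that("built trees reach the exhaustive parsimony minimum (small clones)", {
  set.seed(1234)
  for (rep in 1:40) {
    cl <- make_small_clone()
    tree <- build_tree(cl$db, "c1", test_ref)
    expect_equal(tree$total_mutations, oracle_parsimony(cl$sets))
    keys <- vapply(cl$sets, okey, "")
    star <- sum(vapply(cl$sets[!duplicated(keys)], length, 0L))
    expect_lte(tree$total_mutations, star)
  }
})

test_that("greedy fallback obeys the invariants and the star-tree bound", {
  sim <- simulate_repertoire(
    simulation_config(seed = 3, n_mice = 1, clones_per_mouse = 6,
                      clone_size_dist = list(dist = "fixed", k = 12),
                      target_mut_mean = 8))
  db <- annotate_repertoire(sim$db, test_ref)
  db <- group_clones(db)
  for (cid in unique(db$clone_id)) {
    tree <- build_tree(db, cid, test_ref, method = "greedy")
    obs <- tree$nodes[tree$nodes$type == "observed", ]
    expect_lte(tree$total_mutations, sum(obs$n_from_germline))
    # path sums equal germline distances (subset-respecting edges)
    st <- tree_stats(tree)
    expect_lte(st$trunk_length, st$pl_min)
    auto <- build_tree(db, cid, test_ref)
    expect_lte(auto$total_mutations, tree$total_mutations)
  }
})

test_that("shape-statistic invariants hold across thousands of genealogies", {
  sim <- simulate_repertoire(
    simulation_config(seed = 99, n_mice = 5, clones_per_mouse = 400,
                      target_mut_mean = 6, mixing = 0.2))
  tr <- sim$truth
  expect_gte(nrow(tr$clones), 2000)
  evv <- tr$events[tr$events$layer == "V", ]
  ev_by_clone <- split(evv, evv$clone)
  n_checked <- 0L
  for (ci in seq_len(nrow(tr$clones))) {
    cid <- tr$clones$clone[ci]
    parent <- tr$genealogies[[cid]]
    ev <- ev_by_clone[[cid]]
    if (is.null(ev)) ev <- evv[0, ]
    edges <- data.frame(
      parent = ifelse(parent == 0L, "germline", paste0("n", parent)),
      child = paste0("n", seq_along(parent)),
      n_mut = vapply(seq_along(parent), function(i) sum(ev$node == i), 0L),
      flagged = FALSE, stringsAsFactors = FALSE)
    edges$positions <- I(lapply(seq_along(parent), function(i)
      stats::setNames(ev$to[ev$node == i], ev$pos[ev$node == i])))
    tree <- structure(list(clone_id = cid,
                           nodes = data.frame(
                             node_id = c("germline", edges$child),
                             type = c("germline",
                                      rep("observed", nrow(edges))),
                             stringsAsFactors = FALSE),
                           edges = edges, total_mutations = sum(edges$n_mut),
                           germline_length = 294L),
                      class = "lineage_tree")
    st <- tree_stats(tree)
    expect_lte(st$pl_min, st$pl_mean + 1e-9)
    expect_lte(st$pl_mean, st$pl_max + 1e-9)
    expect_lte(st$trunk_length, st$pl_min)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 2000)
})

test_that("tree-statistic comparison handles degenerate and tiny inputs", {
  a <- data.frame(pl_min = c(2, 2, 2), trunk_length = c(1, 1, 1))
  expect_equal(compare_tree_stats(a, a, "pl_min")$p, 1)
  expect_error(compare_tree_stats(a, a, "banana"), "pl_min")
  b1 <- data.frame(pl_min = 2)
  expect_warning(out <- compare_tree_stats(b1, b1, "pl_min"), "single-tree")
  expect_true(out$p >= 0 && out$p <= 1)
})

test_that("mutation ordering distinguishes precedence, ties and absences", {
  # chain: edge 1 mutates 98, edge 2 mutates 102
  db <- ann_clone(list(c("98" = "T"), c("98" = "T", "102" = "C")))
  tree <- build_tree(db, "c1", test_ref)
  ord <- mutation_order_precedes(list(tree), 98, 102)
  expect_equal(ord$a_first, 1)
  expect_equal(ord$b_first, 0)
  rev <- mutation_order_precedes(list(tree), 102, 98)
  expect_equal(rev$a_first, 0)
  expect_true(rev$never_precedes)
  # same-edge co-mutation is a tie
  db2 <- ann_clone(list(c("98" = "T", "102" = "C")))
  ord2 <- mutation_order_precedes(list(build_tree(db2, "c1", test_ref)),
                                  98, 102)
  expect_equal(ord2$tie, 1)
  expect_equal(ord2$a_first, 0)
  # a tie is not a precedence: with zero preceding paths and one co-mutated
  # path the "never precedes" verdict holds
  expect_true(ord2$never_precedes)
  expect_error(mutation_order_precedes(list(tree), 0, 98), "V region")
  expect_error(mutation_order_precedes(list(tree), 98, 400), "V region")
})

test_that("selection mode never mutates 102 before 98 in NP clones", {
  sim <- simulate_repertoire(
    simulation_config(seed = 8, n_mice = 3, clones_per_mouse = 10,
                      np_fraction = 1, p_haff = 0.7))
  db <- annotate_repertoire(sim$db, test_ref)
  db <- group_clones(db)
  trees <- build_trees(db, test_ref, min_size = 2)
  ord <- mutation_order_precedes(trees, 102, 98)
  expect_equal(ord$a_first, 0)
  expect_gte(ord$n_both, 1)
  expect_true(ord$never_precedes)
})

test_that("newick export round-trips through a standard parser", {
  db <- ann_clone(list(c("10" = "A", "20" = "C", "30" = "G"),
                       c("10" = "A", "20" = "C", "40" = "T"),
                       c("10" = "A", "20" = "C")))
  tree <- build_tree(db, "c1", test_ref)
  nk <- as_newick(tree)
  ph <- ape::read.tree(text = nk)
  expect_equal(sum(ph$edge.length), tree$total_mutations)
  expect_true(any(grepl("^i\\d+$", c(ph$tip.label, ph$node.label))) ||
                sum(tree$nodes$type == "inferred") == 0)
  path <- tempfile(fileext = ".tsv")
  write_trees(list(c1 = tree), path)
  tab <- utils::read.delim(path)
  expect_identical(tab$clone_id, "c1")
})

test_that("indel-bearing members are attached on flagged edges only", {
  r1 <- make_read(c("10" = "A"))
  r2 <- make_read(c("10" = "A", "20" = "C"))
  r3 <- paste0(substr(r2, 1, 59), substr(r2, 61, nchar(r2)))  # deletion
  db <- annotate_repertoire(make_db(c(r1, r2, r3)), test_ref)
  db$clone_id <- "c1"
  tree <- build_tree(db, "c1", test_ref)
  expect_equal(sum(tree$edges$flagged), 1)
  st <- tree_stats(tree)            # flagged edge excluded from statistics
  expect_equal(st$pl_max, 2)
})
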