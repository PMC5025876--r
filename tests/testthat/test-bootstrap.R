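test_that("size-preserving null matches hand enumeration on the 2+2 case", {
  # 2 cells per compartment, 2 clones of size 2: the 6 equally likely label
  # arrangements give mixed-clone counts 0,2,2,2,2,0, hence mean 4/3
  cells <- data.frame(group = "g1", label = rep(c("A", "B"), each = 2))
  sizes <- list(g1 = c(2L, 2L))
  ex <- exact_mixed_null(cells, sizes)
  expect_equal(ex$mean, 4 / 3)
  expect_equal(ex$var, mean(c(0, 2, 2, 2, 2, 0)^2) - (4 / 3)^2)
  b <- bootstrap_mixed_clones(cells, sizes, observed_mixed = 0,
                              n_runs = 10000, seed = 2)
  se <- stats::sd(rep(c(0, 2, 2, 2, 2, 0))) / sqrt(10000)
  expect_lt(abs(b$null_mean - 4 / 3), 3 * se)
})

test_that("exact enumeration agrees with the independent oracle", {
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    k <- sample(2:(n - 1), 1)
    sizes <- tabulate(sample.int(k, n - k, replace = TRUE), k) + 1L
    labels <- sample(c("A", "B"), n, replace = TRUE)
    cells <- data.frame(group = "g", label = labels)
    ex <- exact_mixed_null(cells, list(g = sizes))
    or <- oracle_mixed_one_group(labels, sizes)
    expect_equal(ex$mean, or$mean)
    expect_equal(ex$var, or$var)
    b <- bootstrap_mixed_clones(cells, list(g = sizes), 0, n_runs = 4000,
                                seed = rep)
    expect_lt(abs(b$null_mean - or$mean),
              3 * sqrt(or$var / 4000) + 1e-12)
  }
})

test_that("multi-group nulls combine by summing means and variances", {
  cells <- data.frame(group = rep(c("m1", "m2"), each = 4),
                      label = rep(c("A", "A", "B", "B"), 2))
  sizes <- list(m1 = c(2L, 2L), m2 = c(3L, 1L))
  ex <- exact_mixed_null(cells, sizes)
  o1 <- oracle_mixed_one_group(rep(c("A", "B"), each = 2), c(2L, 2L))
  o2 <- oracle_mixed_one_group(rep(c("A", "B"), each = 2), c(3L, 1L))
  expect_equal(ex$mean, o1$mean + o2$mean)
  expect_equal(ex$var, o1$var + o2$var)
})

test_that("degenerate nulls are flagged, never silently tested", {
  # a single clone containing both compartments is mixed in every run
  cells <- data.frame(group = "g", label = c("A", "B", "B"))
  b <- bootstrap_mixed_clones(cells, list(g = 3L), observed_mixed = 1,
                              n_runs = 500, seed = 1)
  expect_true(b$degenerate)
  expect_equal(b$null_mean, 1)
  expect_true(is.na(b$p_two_sided))
  expect_warning(v <- relatedness_verdict(b), "degenerate")
  expect_identical(v, "CONSISTENT_WITH_NULL")
  # all-singleton clones can never mix
  b2 <- bootstrap_mixed_clones(
    data.frame(group = "g", label = c("A", "B")),
    list(g = c(1L, 1L)), observed_mixed = 0, n_runs = 500, seed = 1)
  expect_true(b2$degenerate)
  expect_equal(b2$null_mean, 0)
})

test_that("bootstrap is bit-identical under a fixed seed", {
  cells <- data.frame(group = rep("g", 10),
                      label = rep(c("A", "B"), 5))
  sizes <- list(g = c(4L, 3L, 2L, 1L))
  b1 <- bootstrap_mixed_clones(cells, sizes, 2, n_runs = 1000, seed = 77)
  b2 <- bootstrap_mixed_clones(cells, sizes, 2, n_runs = 1000, seed = 77)
  expect_identical(b1, b2)
  b3 <- bootstrap_mixed_clones(cells, sizes, 2, n_runs = 1000, seed = 78,
                               mode = "UNIFORM_PARTITION")
  expect_identical(
    b3, bootstrap_mixed_clones(cells, sizes, 2, n_runs = 1000, seed = 78,
                               mode = "UNIFORM_PARTITION"))
})

test_that("uniform-partition mode matches exhaustive surjection enumeration", {
  # n = 5 cells (3 A, 2 B) into k = 2 clones: enumerate all surjections
  labels <- c("A", "A", "A", "B", "B")
  n <- 5L
  k <- 2L
  grid <- expand.grid(rep(list(seq_len(k)), n))
  surj <- grid[apply(grid, 1, function(a) length(unique(a)) == k), ]
  mixed <- apply(surj, 1, function(a) {
    sum(vapply(seq_len(k), function(cl) {
      lab <- labels[a == cl]
      any(lab == "A") && any(lab == "B")
    }, NA))
  })
  b <- bootstrap_mixed_clones(
    data.frame(group = "g", label = labels), list(g = c(3L, 2L)),
    observed_mixed = 0, n_runs = 20000, seed = 5,
    mode = "UNIFORM_PARTITION")
  expect_lt(abs(b$null_mean - mean(mixed)),
            3 * stats::sd(mixed) / sqrt(20000))
  # clone count equal to cell count forces singletons: zero mixed always
  b2 <- bootstrap_mixed_clones(
    data.frame(group = "g", label = c("A", "B", "A")),
    list(g = c(1L, 1L, 1L)), 0, n_runs = 200, seed = 1,
    mode = "UNIFORM_PARTITION")
  expect_equal(b2$null_mean, 0)
})

test_that("input contract violations are errors", {
  cells <- data.frame(group = "g", label = c("A", "B"))
  expect_error(bootstrap_mixed_clones(cells, list(g = c(1L, 1L, 1L)), 0,
                                      n_runs = 10, seed = 1),
               "clone count exceeds")
  expect_error(bootstrap_mixed_clones(cells, list(g = 3L), 0,
                                      n_runs = 10, seed = 1), "sum")
  expect_error(bootstrap_mixed_clones(cells, list(), 0, n_runs = 10,
                                      seed = 1), "clone sizes")
})

test_that("verdicts follow the sign of z at the 0.05 level", {
  res <- structure(list(degenerate = FALSE, z = -5, p_two_sided = 1e-6),
                   class = "bootstrap_result")
  expect_identical(relatedness_verdict(res), "FEWER_MIXED_THAN_NULL")
  res$z <- 5
  expect_identical(relatedness_verdict(res), "MORE_MIXED_THAN_NULL")
  res$z <- 0.1
  res$p_two_sided <- 0.92
  expect_identical(relatedness_verdict(res), "CONSISTENT_WITH_NULL")
})
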