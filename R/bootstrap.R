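# Bootstrap null model for mixed-clone counts: cells of each mouse group are
# repeatedly re-partitioned at random into the observed number of clones, and
# the observed count of clones mixing two compartment/subset labels is
# compared with the null via a z-test (normal approximation), mirroring the
# random-assignment simulations used for clonal-relatedness claims.

# mixed-clone count for one group given permuted two-level labels:
# cl = clone index per cell, s = clone sizes, isa = logical label indicator
.count_mixed <- function(isa_perm, cl, s) {
  na <- tabulate(cl[isa_perm], nbins = length(s))
  sum(na > 0L & na < s)
}

# solve for the zero-truncated Poisson rate with mean m (= n/k)
.ztp_lambda <- function(m) {
  if (m <= 1 + 1e-12) return(1e-8)
  stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                 lower = 1e-8, upper = max(m * 2, 2))$root
}

# uniformly random surjective occupancy: n cells into k non-empty clones.
# Equivalent to iid zero-truncated Poisson counts conditioned on their sum,
# sampled by rejection.
.uniform_surjection_sizes <- function(n, k, lambda, max_tries = 100000L) {
  if (k == n) return(rep(1L, n))
  for (t in seq_len(max_tries)) {
    x <- stats::rpois(k, lambda)
    while (any(x == 0L)) x[x == 0L] <- stats::rpois(sum(x == 0L), lambda)
    if (sum(x) == n) return(x)
  }
  stop("uniform-partition sampler failed to hit the target cell count",
       call. = FALSE)
}

#' Bootstrap null for the number of mixed clones
#'
#' Each run randomly re-partitions the cells of every group into the observed
#' number of clones and counts clones containing both axis labels; the
#' observed mixed-clone count is compared with the null mean/sd by a
#' two-sided z-test. `PRESERVE_SIZES` permutes cell labels over the empirical
#' clone-size multiset (permutation-test flavour, the default);
#' `UNIFORM_PARTITION` draws a uniformly random surjective assignment of
#' cells to clones each run. Fully reproducible from `seed`.
#'
#' @param cells data.frame with columns `group` (e.g. mouse) and `label` (the
#'   compartment/subset axis; exactly the two labels under test).
#' @param clone_sizes named list, one integer vector of clone sizes per
#'   group; sizes must sum to the group's cell count (clone count is the
#'   vector length).
#' @param observed_mixed observed number of mixed clones (summed over groups).
#' @param n_runs number of bootstrap runs (the headline analyses use 10,000).
#' @param mode `"PRESERVE_SIZES"` or `"UNIFORM_PARTITION"`.
#' @param seed integer RNG seed.
#' @return object of class `bootstrap_result`: observed count, null mean/sd,
#'   `z`, normal two-sided `p_two_sided`, the empirical two-sided tail
#'   fraction, run count, seed, mode and a `degenerate` flag (`null_sd = 0`).
#' @export
bootstrap_mixed_clones <- function(cells, clone_sizes, observed_mixed,
                                   n_runs = 10000L,
                                   mode = c("PRESERVE_SIZES",
                                            "UNIFORM_PARTITION"),
                                   seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(c("group", "label") %in% names(cells)))
  groups <- sort(unique(as.character(cells$group)))
  labs <- sort(unique(as.character(cells$label)))
  if (length(labs) > 2L) {
    stop("cells$label must hold at most two labels", call. = FALSE)
  }
  prep <- lapply(groups, function(g) {
    lab <- as.character(cells$label[cells$group == g])
    s <- as.integer(clone_sizes[[g]])
    if (is.null(clone_sizes[[g]])) {
      stop(sprintf("no clone sizes for group '%s'", g), call. = FALSE)
    }
    if (any(s < 1L)) stop("clone sizes must be >= 1", call. = FALSE)
    if (length(s) > length(lab)) {
      stop(sprintf("group '%s': clone count exceeds cell count", g),
           call. = FALSE)
    }
    if (sum(s) != length(lab)) {
      stop(sprintf("group '%s': clone sizes must sum to the cell count", g),
           call. = FALSE)
    }
    list(n = length(lab), k = length(s), s = s,
         isa = lab == labs[1], cl = rep.int(seq_along(s), s),
         lambda = .ztp_lambda(length(lab) / length(s)))
  })
  names(prep) <- groups

  counts <- with_seed(seed, {
    vapply(seq_len(n_runs), function(run) {
      tot <- 0L
      for (p in prep) {
        if (mode == "PRESERVE_SIZES") {
          s <- p$s
          cl <- p$cl
        } else {
          s <- .uniform_surjection_sizes(p$n, p$k, p$lambda)
          cl <- rep.int(seq_along(s), s)
        }
        tot <- tot + .count_mixed(p$isa[sample.int(p$n)], cl, s)
      }
      tot
    }, integer(1))
  })

  null_mean <- mean(counts)
  null_sd <- stats::sd(counts)
  degenerate <- !is.finite(null_sd) || null_sd == 0
  z <- if (degenerate) NA_real_ else (observed_mixed - null_mean) / null_sd
  p <- if (degenerate) NA_real_ else 2 * stats::pnorm(-abs(z))
  emp <- min(1, 2 * min(mean(counts <= observed_mixed),
                        mean(counts >= observed_mixed)))
  structure(list(observed_mixed = as.integer(observed_mixed),
                 null_mean = null_mean, null_sd = null_sd, z = z,
                 p_two_sided = p, empirical_p = emp,
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 mode = mode, degenerate = degenerate,
                 null_table = table(counts)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "bootstrap_result (%s, %d runs, seed %d)\n  observed mixed clones: %d\n  null: mean %.3f, sd %.3f\n",
    x$mode, x$n_runs, x$seed, x$observed_mixed, x$null_mean, x$null_sd))
  if (x$degenerate) {
    cat("  degenerate null (sd = 0); z/p undefined\n")
  } else {
    cat(sprintf("  z = %.3f, two-sided p = %.3g (empirical %.3g)\n",
                x$z, x$p_two_sided, x$empirical_p))
  }
  invisible(x)
}

#' Exact null for the size-preserving random partition
#'
#' Enumerates, per group, every arrangement of the two-level label multiset
#' over the fixed clone-size partition (all position subsets of the minority
#' label) and returns the exact mean and standard deviation of the
#' mixed-clone count; groups combine by summing means and variances
#' (independence). Feasible for small groups only; the independent check for
#' the simulated null.
#'
#' @param cells,clone_sizes as in [bootstrap_mixed_clones()].
#' @param max_cells guard on per-group enumeration size.
#' @return list with `mean`, `sd`, `var` and the per-group distributions.
#' @export
exact_mixed_null <- function(cells, clone_sizes, max_cells = 15L) {
  groups <- sort(unique(as.character(cells$group)))
  labs <- sort(unique(as.character(cells$label)))
  tot_mean <- 0
  tot_var <- 0
  dists <- list()
  for (g in groups) {
    lab <- as.character(cells$label[cells$group == g])
    s <- as.integer(clone_sizes[[g]])
    n <- length(lab)
    if (n > max_cells) {
      stop(sprintf("group '%s' too large for exhaustive enumeration", g),
           call. = FALSE)
    }
    na <- sum(lab == labs[1])
    cl <- rep.int(seq_along(s), s)
    vals <- if (na == 0L || na == n) {
      0L  # single-label group can never form a mixed clone
    } else {
      sets <- utils::combn(n, na)
      apply(sets, 2, function(pos) {
        isa <- rep(FALSE, n)
        isa[pos] <- TRUE
        .count_mixed(isa, cl, s)
      })
    }
    tot_mean <- tot_mean + mean(vals)
    # population variance over the equally likely arrangements
    tot_var <- tot_var +
      (if (length(vals) > 1L) mean(vals^2) - mean(vals)^2 else 0)
    dists[[g]] <- vals
  }
  list(mean = tot_mean, var = tot_var, sd = sqrt(tot_var),
       per_group = dists)
}

#' Verdict on clonal relatedness from a bootstrap result
#'
#' @param result a `bootstrap_result`.
#' @param alpha significance level (default 0.05, two-sided z-test).
#' @return one of `"FEWER_MIXED_THAN_NULL"`, `"MORE_MIXED_THAN_NULL"`,
#'   `"CONSISTENT_WITH_NULL"`; a degenerate result yields
#'   `CONSISTENT_WITH_NULL` with a warning.
#' @export
relatedness_verdict <- function(result, alpha = 0.05) {
  if (isTRUE(result$degenerate)) {
    warning("degenerate bootstrap null (sd = 0); verdict defaults to CONSISTENT_WITH_NULL",
            call. = FALSE)
    return("CONSISTENT_WITH_NULL")
  }
  if (result$p_two_sided < alpha) {
    if (result$z < 0) "FEWER_MIXED_THAN_NULL" else "MORE_MIXED_THAN_NULL"
  } else "CONSISTENT_WITH_NULL"
}

#' Build bootstrap inputs from a clone-assigned repertoire
#'
#' Restricts to sequences carrying a clone id and one of the two axis labels,
#' treats each mouse as a group, takes the empirical clone-size multiset and
#' observed mixed-clone count, and runs [bootstrap_mixed_clones()].
#'
#' @param db clone-assigned repertoire data.frame.
#' @param axis_col,a,b the compartment/subset axis (see [overlap_table()]).
#' @param ... passed to [bootstrap_mixed_clones()].
#' @return a `bootstrap_result`.
#' @export
bootstrap_from_clones <- function(db, axis_col = "subset", a = "MEMORY",
                                  b = "LONGLIVED_PC", ...) {
  keep <- !is.na(db$clone_id) & db[[axis_col]] %in% c(a, b)
  dbc <- db[keep, , drop = FALSE]
  if (nrow(dbc) == 0L) stop("no clone-assigned cells on the requested axis",
                            call. = FALSE)
  cells <- data.frame(group = dbc$mouse_id, label = dbc[[axis_col]],
                      stringsAsFactors = FALSE)
  clone_sizes <- lapply(split(dbc$clone_id, dbc$mouse_id),
                        function(x) as.integer(unname(table(x))))
  ov <- suppressWarnings(overlap_table(dbc, axis_col, a, b))
  bootstrap_mixed_clones(cells, clone_sizes,
                         observed_mixed = sum(ov$per_mouse$n_mixed), ...)
}
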