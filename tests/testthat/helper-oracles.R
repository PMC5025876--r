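# Independent oracles used by the tests. These reimplement, by brute force
# and from scratch, the quantities the package computes with cleverer code.

# --- parsimony -------------------------------------------------------------

okey <- function(s) paste(names(s), s, sep = ">", collapse = ";")

osubset <- function(a, b) {
  length(a) <= length(b) && all(names(a) %in% names(b)) &&
    all(b[names(a)] == a)
}

# exhaustive minimum total edge mutations over germline-rooted trees whose
# every edge extends its parent's mutation set (observed sets plus any
# subset of intersection-closure intermediates may appear as nodes)
oracle_parsimony <- function(sets) {
  keys <- vapply(sets, okey, "")
  sets <- sets[!duplicated(keys)]
  pool <- sets
  keys <- unique(keys)
  repeat {
    added <- FALSE
    n <- length(pool)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
      common <- intersect(names(pool[[i]]), names(pool[[j]]))
      common <- common[pool[[i]][common] == pool[[j]][common]]
      m <- pool[[i]][common]
      k <- okey(m)
      if (!k %in% keys) {
        pool <- c(pool, list(m))
        keys <- c(keys, k)
        added <- TRUE
      }
    }
    if (!added) break
  }
  obs_keys <- vapply(sets, okey, "")
  cand <- pool[!(keys %in% c(obs_keys, okey(character(0))))]
  nc <- length(cand)
  stopifnot(nc <= 14)
  best <- Inf
  for (mask in 0:(2^nc - 1)) {
    sel <- if (nc > 0) which(bitwAnd(mask, 2^(seq_len(nc) - 1)) > 0) else
      integer(0)
    nodes <- c(sets, cand[sel])
    cost <- 0
    for (vi in seq_along(nodes)) {
      v <- nodes[[vi]]
      if (length(v) == 0L) next
      psz <- 0L
      for (ui in seq_along(nodes)) {
        if (ui != vi && length(nodes[[ui]]) < length(v) &&
            osubset(nodes[[ui]], v)) psz <- max(psz, length(nodes[[ui]]))
      }
      cost <- cost + length(v) - psz
    }
    best <- min(best, cost)
  }
  best
}

# random small clone: genealogy over a 6-position pool; returns the member
# mutation sets plus a minimal annotated data.frame for build_tree()
make_small_clone <- function(pool_size = 6L, max_k = 5L) {
  k <- sample(2:max_k, 1L)
  pool_pos <- sample(length(GERM), pool_size)
  parent <- c(0L, if (k > 1L) vapply(2:k, function(i) sample.int(i - 1L, 1L),
                                     0L))
  sets <- vector("list", k)
  for (i in seq_len(k)) {
    cur <- if (i == 1L) stats::setNames(character(0), character(0)) else
      sets[[parent[i]]]
    m <- stats::rpois(1L, 1.2)
    for (p in sample(pool_pos, min(m, pool_size))) {
      from <- if (as.character(p) %in% names(cur)) cur[[as.character(p)]]
      else GERM[p]
      cur[as.character(p)] <- sample(setdiff(c("A", "C", "G", "T"), from), 1L)
      cur <- cur[cur != GERM[as.integer(names(cur))]]
    }
    sets[[i]] <- cur[order(as.integer(names(cur)))]
  }
  db <- data.frame(seq_id = sprintf("s%02d", seq_len(k)), mouse_id = "m1",
                   stringsAsFactors = FALSE)
  db$v_aligned <- TRUE
  db$n_indels <- 0L
  db$mutations <- lapply(sets, function(s) {
    data.frame(pos = as.integer(names(s)),
               from = GERM[as.integer(names(s))], to = unname(s),
               stringsAsFactors = FALSE)
  })
  db$clone_id <- "c1"
  list(db = db, sets = sets)
}

# --- bootstrap -------------------------------------------------------------

# exact mean/sd of the mixed-clone count for ONE group by enumerating every
# arrangement of the two-level label multiset over fixed clone sizes
oracle_mixed_one_group <- function(labels, sizes) {
  n <- length(labels)
  stopifnot(sum(sizes) == n)
  lv <- sort(unique(labels))
  na <- sum(labels == lv[1])
  cl <- rep.int(seq_along(sizes), sizes)
  vals <- if (na == 0L || na == n) 0L else {
    apply(utils::combn(n, na), 2, function(posn) {
      cnt <- tabulate(cl[posn], nbins = length(sizes))
      sum(cnt > 0L & cnt < sizes)
    })
  }
  list(mean = mean(vals), var = mean(vals^2) - mean(vals)^2, vals = vals)
}
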