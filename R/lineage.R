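# Lineage trees: germline-rooted parsimony reconstruction of clonal
# genealogies with inferred intermediate ancestors, tree-shape statistics
# (minimum path length, trunk length) and mutation-ordering queries.
#
# A node is represented by its V-region mutation set relative to the
# germline: a named character vector (names = 1-based nucleotide positions,
# values = the observed base). Trees are grown greedily so that every
# parent's mutation set is a subset of its child's; edge mutation counts then
# equal Hamming distances and path sums from the root equal each node's
# distance from germline.

.mutset <- function(mut) {
  if (is.null(mut) || nrow(mut) == 0L) return(stats::setNames(character(0),
                                                              character(0)))
  stats::setNames(mut$to, as.character(mut$pos))[order(mut$pos)]
}

# non-empty even for the empty set: "" is not a usable list name in R
.mutset_key <- function(s) {
  paste0("|", paste(names(s), s, sep = ">", collapse = ";"))
}

# is a a subset of b (same position AND same base)?
.subset_of <- function(a, b) {
  length(a) <= length(b) && all(names(a) %in% names(b)) &&
    all(b[names(a)] == a)
}

.intersect_sets <- function(a, b) {
  common <- intersect(names(a), names(b))
  common <- common[a[common] == b[common]]
  a[common]
}

# Hamming distance between two mutation sets (over the implied sequences)
.mut_dist <- function(a, b) {
  pos <- union(names(a), names(b))
  if (length(pos) == 0L) return(0L)
  av <- ifelse(pos %in% names(a), a[pos], "")
  bv <- ifelse(pos %in% names(b), b[pos], "")
  sum(av != bv)
}

#' Build a germline-rooted parsimony lineage tree for one clone
#'
#' Identical V-region sequences are deduplicated into single nodes
#' (multiplicity recorded). Trees respect the lineage invariant that every
#' parent's mutation set is contained in its child's, so edge counts are
#' Hamming distances and root-to-node path sums equal each node's mutation
#' distance from germline. Small clones (intersection closure of at most
#' `max_exact` candidate intermediates) are solved exactly by enumerating
#' which shared-mutation intersections to materialise as inferred ancestors;
#' larger clones fall back to a greedy agglomeration that repeatedly attaches
#' the node with the cheapest available parent (an existing node, or a new
#' intermediate splitting an existing edge), ties broken by more shared
#' mutations then lexicographic node id. Members whose alignment carries
#' indels are attached by a flagged edge excluded from shape statistics.
#'
#' @param db annotated repertoire data.frame.
#' @param clone_id the clone to build (or `NULL` to use all rows of `db`).
#' @param ref a `germline_reference`.
#' @param method `"auto"` (exact when feasible), `"exact"` or `"greedy"`.
#' @param max_exact largest intermediate-closure size solved exactly.
#' @return object of class `lineage_tree`: node table (id, type, mutation
#'   distance from germline, multiplicity, member seq_ids), edge table
#'   (parent, child, mutation count, mutated positions, flag), and the total
#'   tree mutation count.
#' @export
build_tree <- function(db, clone_id = NULL, ref,
                       method = c("auto", "exact", "greedy"),
                       max_exact = 12L) {
  method <- match.arg(method)
  rows <- if (is.null(clone_id)) seq_len(nrow(db)) else
    which(!is.na(db$clone_id) & db$clone_id == clone_id)
  if (length(rows) == 0L) stop("clone has no member sequences", call. = FALSE)
  aligned <- rows[!is.na(db$v_aligned[rows]) & db$v_aligned[rows]]
  clean <- aligned[db$n_indels[aligned] == 0L]
  flagged_rows <- setdiff(aligned, clean)

  # deduplicate identical mutation sets
  sets <- list()
  members <- list()
  for (i in clean) {
    s <- .mutset(db$mutations[[i]])
    key <- .mutset_key(s)
    if (is.null(sets[[key]])) {
      sets[[key]] <- s
      members[[key]] <- db$seq_id[i]
    } else {
      members[[key]] <- c(members[[key]], db$seq_id[i])
    }
  }
  keys <- names(sets)
  node_id <- vapply(keys, function(k) min(sort(members[[k]])), "")
  ord <- order(node_id)
  keys <- keys[ord]
  node_id <- node_id[ord]

  # choose solver: exact enumeration when the intersection closure is small
  state <- NULL
  if (method != "greedy") {
    cand <- .intersection_closure(sets[keys], max_cand = max_exact)
    if (!is.null(cand) || method == "exact") {
      if (is.null(cand)) {
        stop("clone too large for the exact method; use method = 'greedy'",
             call. = FALSE)
      }
      state <- .exact_tree(sets[keys], node_id, cand)
    }
  }
  if (!is.null(state)) {
    ids <- state$ids
    nsets <- state$nsets
    parent <- state$parent
  } else {
    st <- .greedy_tree(sets, keys, node_id)
    ids <- st$ids
    nsets <- st$nsets
    parent <- st$parent
  }

  .materialise_tree(db, clone_id, ref, ids, nsets, parent, node_id, keys,
                    members, flagged_rows)
}

# Greedy agglomeration: repeatedly make the globally cheapest attachment of
# an unplaced node, either directly under an existing (subset) node or under
# a new intermediate obtained by splitting an existing edge at the
# shared-mutation intersection.
.greedy_tree <- function(sets, keys, node_id) {
  ids <- "germline"
  nsets <- list(germline = stats::setNames(character(0), character(0)))
  parent <- c(germline = NA_character_)
  n_inferred <- 0L

  unattached <- stats::setNames(keys, node_id)
  while (length(unattached) > 0L) {
    best <- NULL  # list(uid, cost, shared, mode, t, ...)
    for (ui in seq_along(unattached)) {
      uid <- names(unattached)[ui]
      u <- sets[[unattached[ui]]]
      for (tid in ids) {
        t <- nsets[[tid]]
        if (.subset_of(t, u)) {
          cand <- list(uid = uid, cost = length(u) - length(t),
                       shared = length(t), mode = "direct", t = tid)
          best <- .better_attach(best, cand)
        }
        p <- parent[[tid]]
        if (!is.na(p)) {
          m <- .intersect_sets(u, t)
          ps <- nsets[[p]]
          if (length(m) > length(ps) && length(m) < length(t) &&
              .subset_of(ps, m)) {
            cand <- list(uid = uid, cost = length(u) - length(m),
                         shared = length(m), mode = "insert", t = tid)
            best <- .better_attach(best, cand)
          }
        }
      }
    }
    u <- sets[[unattached[[best$uid]]]]
    if (best$mode == "direct") {
      ids <- c(ids, best$uid)
      nsets[[best$uid]] <- u
      parent[best$uid] <- best$t
    } else {
      t <- nsets[[best$t]]
      m <- .intersect_sets(u, t)
      mkey <- .mutset_key(m)
      if (identical(mkey, .mutset_key(u))) {
        # the new node itself lies on the edge: insert it, no intermediate
        ids <- c(ids, best$uid)
        nsets[[best$uid]] <- u
        parent[best$uid] <- parent[[best$t]]
        parent[best$t] <- best$uid
      } else {
        existing <- ids[vapply(ids, function(id)
          identical(.mutset_key(nsets[[id]]), mkey), NA)]
        if (length(existing) > 0L) {
          mid <- existing[1]
        } else {
          n_inferred <- n_inferred + 1L
          mid <- sprintf("i%d", n_inferred)
          ids <- c(ids, mid)
          nsets[[mid]] <- m
          parent[mid] <- parent[[best$t]]
          parent[best$t] <- mid
        }
        ids <- c(ids, best$uid)
        nsets[[best$uid]] <- u
        parent[best$uid] <- mid
      }
    }
    unattached <- unattached[names(unattached) != best$uid]
  }
  list(ids = ids, nsets = nsets, parent = parent)
}

# Intersection closure of the observed mutation sets (candidates for
# inferred ancestors), excluding the sets themselves and the empty set.
# Returns NULL when the closure exceeds max_cand.
.intersection_closure <- function(obs_sets, max_cand = 12L) {
  pool <- obs_sets
  keys <- vapply(pool, .mutset_key, "")
  repeat {
    added <- FALSE
    n <- length(pool)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i < j) {
          m <- .intersect_sets(pool[[i]], pool[[j]])
          k <- .mutset_key(m)
          if (!k %in% keys) {
            pool <- c(pool, list(m))
            keys <- c(keys, k)
            added <- TRUE
            if (length(pool) - length(obs_sets) > max_cand + 2L) return(NULL)
          }
        }
      }
    }
    if (!added) break
  }
  obs_keys <- vapply(obs_sets, .mutset_key, "")
  root_key <- .mutset_key(stats::setNames(character(0), character(0)))
  cand <- pool[!(keys %in% c(obs_keys, root_key))]
  if (length(cand) > max_cand) return(NULL)
  # deterministic candidate order: by size then key
  ck <- vapply(cand, .mutset_key, "")
  cand[order(vapply(cand, length, 0L), ck)]
}

# Exact small-instance solver: choose the subset of candidate intermediates
# minimising total edge mutations, where each node's parent is its largest
# proper-subset node (cost decomposes per node under the subset-respecting
# tree invariant). Ties prefer fewer intermediates, then the earliest
# candidate combination in deterministic order.
.exact_tree <- function(obs_sets, node_id, cand) {
  nobs <- length(obs_sets)
  nc <- length(cand)
  allsets <- c(obs_sets, cand)
  sizes <- vapply(allsets, length, 0L)
  ntot <- length(allsets)
  # strict-subset matrix: sub[u, v] = set u is a proper subset of set v
  sub <- matrix(FALSE, ntot, ntot)
  for (u in seq_len(ntot)) {
    for (v in seq_len(ntot)) {
      if (u != v && sizes[u] < sizes[v] &&
          .subset_of(allsets[[u]], allsets[[v]])) sub[u, v] <- TRUE
    }
  }
  masks <- 0:(2^nc - 1)
  if (nc > 0L) {
    pc <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(nc - 1))) > 0), 0)
    masks <- masks[order(pc, masks)]
  }
  best_cost <- Inf
  best_sel <- integer(0)
  for (mask in masks) {
    sel <- if (nc > 0L) which(bitwAnd(mask, 2^(seq_len(nc) - 1L)) > 0L) else
      integer(0)
    active <- c(seq_len(nobs), nobs + sel)
    cost <- 0
    for (v in active) {
      if (sizes[v] == 0L) next               # unmutated: free root edge
      par_sizes <- sizes[active][sub[active, v]]
      cost <- cost + sizes[v] - (if (length(par_sizes) > 0L)
        max(par_sizes) else 0L)
    }
    if (cost < best_cost) {
      best_cost <- cost
      best_sel <- sel
    }
  }

  active <- c(seq_len(nobs), nobs + best_sel)
  ids_of <- character(ntot)
  ids_of[seq_len(nobs)] <- node_id
  if (length(best_sel) > 0L) {
    ids_of[nobs + best_sel] <- sprintf("i%d", seq_along(best_sel))
  }
  # parent = largest proper subset among active nodes (root if none);
  # tie-break on node id for determinism
  parent <- c(germline = NA_character_)
  for (v in active) {
    cands <- active[sub[active, v]]
    pid <- if (length(cands) == 0L) "germline" else {
      mx <- max(sizes[cands])
      ids <- sort(ids_of[cands[sizes[cands] == mx]])
      ids[1]
    }
    parent[ids_of[v]] <- pid
  }
  # order ids so that parents precede children (by set size, then id)
  ord <- active[order(sizes[active], ids_of[active])]
  ids <- c("germline", ids_of[ord])
  nsets <- c(list(germline = stats::setNames(character(0), character(0))),
             stats::setNames(allsets[ord], ids_of[ord]))
  list(ids = ids, nsets = nsets, parent = parent)
}

.materialise_tree <- function(db, clone_id, ref, ids, nsets, parent,
                              node_id, keys, members, flagged_rows) {
  obs_ids <- node_id
  nodes <- data.frame(
    node_id = ids,
    type = ifelse(ids == "germline", "germline",
                  ifelse(ids %in% obs_ids, "observed", "inferred")),
    n_from_germline = vapply(ids, function(id) length(nsets[[id]]), 0L),
    multiplicity = vapply(ids, function(id) {
      if (id %in% obs_ids) length(members[[keys[match(id, node_id)]]]) else 0L
    }, 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  nodes$seq_ids <- lapply(ids, function(id) {
    if (id %in% obs_ids) sort(members[[keys[match(id, node_id)]]]) else
      character(0)
  })

  edges <- do.call(rbind, lapply(ids[-1], function(id) {
    p <- parent[[id]]
    positions <- setdiff(names(nsets[[id]]), names(nsets[[p]]))
    data.frame(parent = p, child = id,
               n_mut = length(nsets[[id]]) - length(nsets[[p]]),
               positions = I(list(stats::setNames(
                 nsets[[id]][positions], positions))),
               flagged = FALSE,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(parent = character(0), child = character(0),
                        n_mut = integer(0), positions = I(list()),
                        flagged = logical(0))
  }

  # indel-discordant members: flagged edges from the root, excluded from stats
  for (i in flagged_rows) {
    edges <- rbind(edges, data.frame(
      parent = "germline", child = db$seq_id[i], n_mut = NA_integer_,
      positions = I(list(character(0))), flagged = TRUE,
      stringsAsFactors = FALSE))
    nodes <- rbind(nodes, data.frame(
      node_id = db$seq_id[i], type = "indel_flagged",
      n_from_germline = NA_integer_, multiplicity = 1L,
      seq_ids = I(list(db$seq_id[i])), stringsAsFactors = FALSE))
  }

  structure(list(clone_id = clone_id %||% "clone",
                 nodes = nodes, edges = edges,
                 sets = nsets,
                 total_mutations = sum(edges$n_mut[!edges$flagged]),
                 germline_length = nchar(ref$nt_seq)),
            class = "lineage_tree")
}

.better_attach <- function(best, cand) {
  if (is.null(best)) return(cand)
  if (cand$cost != best$cost) {
    return(if (cand$cost < best$cost) cand else best)
  }
  if (cand$shared != best$shared) {
    return(if (cand$shared > best$shared) cand else best)
  }
  key_c <- paste(cand$uid, cand$t)
  key_b <- paste(best$uid, best$t)
  if (key_c < key_b) cand else best
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf(
    "lineage_tree '%s': %d nodes (%d observed, %d inferred), total %d mutations\n",
    x$clone_id, nrow(x$nodes), sum(x$nodes$type == "observed"),
    sum(x$nodes$type == "inferred"), x$total_mutations))
  invisible(x)
}

#' Build lineage trees for every clone in a repertoire
#' @param db clone-assigned, annotated repertoire data.frame.
#' @param ref a `germline_reference`.
#' @param min_size smallest clone to build (default 1).
#' @return named list of `lineage_tree` objects.
#' @export
build_trees <- function(db, ref, min_size = 1L) {
  cls <- sort(unique(stats::na.omit(db$clone_id)))
  out <- list()
  for (cid in cls) {
    if (sum(db$clone_id == cid, na.rm = TRUE) >= min_size) {
      out[[cid]] <- build_tree(db, cid, ref)
    }
  }
  out
}

.children_of <- function(tree) {
  e <- tree$edges[!tree$edges$flagged, , drop = FALSE]
  split(e$child, factor(e$parent, levels = tree$nodes$node_id))
}

#' Tree-shape statistics
#'
#' Path lengths are summed edge mutation counts from the germline root;
#' `pl_min`/`pl_max`/`pl_mean` are over leaves, `trunk_length` is the summed
#' mutations from the root to the first node with out-degree two or more. An
#' unbranched tree (chain) reports its whole root-to-leaf path as the trunk
#' with `unbranched = TRUE` so chains can be excluded from trunk analyses.
#' Node multiplicities (duplicate reads) do not affect the statistics;
#' flagged indel edges are ignored.
#'
#' @param tree a `lineage_tree`.
#' @return one-row data.frame with `n_nodes`, `n_leaves`, `n_inferred`,
#'   `pl_min`, `pl_max`, `pl_mean`, `trunk_length`, `max_out_degree`,
#'   `unbranched`.
#' @export
tree_stats <- function(tree) {
  kids <- .children_of(tree)
  e <- tree$edges[!tree$edges$flagged, , drop = FALSE]
  depth <- c(germline = 0L)
  queue <- "germline"
  while (length(queue) > 0L) {
    node <- queue[1]
    queue <- queue[-1]
    for (k in kids[[node]]) {
      depth[k] <- depth[[node]] + e$n_mut[e$child == k]
      queue <- c(queue, k)
    }
  }
  in_tree <- c("germline", e$child)
  nkids <- vapply(kids[in_tree], length, 0L)
  leaves <- in_tree[nkids == 0L & in_tree != "germline"]
  if (length(leaves) == 0L) leaves <- "germline"
  pl <- unname(depth[leaves])
  # trunk: follow the single-child chain from the root
  node <- "germline"
  trunk <- 0L
  unbranched <- FALSE
  repeat {
    k <- kids[[node]]
    if (length(k) >= 2L) break
    if (length(k) == 0L) {            # chain all the way to a leaf
      unbranched <- TRUE
      break
    }
    trunk <- trunk + e$n_mut[e$child == k]
    node <- k
  }
  data.frame(
    clone_id = tree$clone_id,
    n_nodes = length(in_tree),
    n_leaves = length(leaves),
    n_inferred = sum(tree$nodes$type == "inferred"),
    pl_min = min(pl), pl_max = max(pl), pl_mean = mean(pl),
    trunk_length = trunk,
    max_out_degree = max(nkids),
    unbranched = unbranched,
    total_mutations = tree$total_mutations,
    stringsAsFactors = FALSE)
}

#' Shape statistics for a list of trees
#' @param trees list of `lineage_tree` objects.
#' @return data.frame, one row per tree.
#' @export
tree_stats_table <- function(trees) {
  do.call(rbind, lapply(trees, tree_stats))
}

#' Mann-Whitney comparison of a tree-shape statistic between two tree sets
#'
#' @param stats_a,stats_b data.frames from [tree_stats_table()].
#' @param statistic column name to compare (e.g. `"pl_min"`,
#'   `"trunk_length"`).
#' @return list with medians, sample sizes and the two-sided p; when every
#'   pooled value is identical the comparison is fully tied and `p = 1`
#'   exactly. Single-tree lists are compared with a wide-uncertainty warning.
#' @export
compare_tree_stats <- function(stats_a, stats_b, statistic) {
  if (!statistic %in% names(stats_a)) {
    stop(sprintf("unknown statistic '%s'; available: %s", statistic,
                 paste(setdiff(names(stats_a),
                               c("clone_id", "unbranched")), collapse = ", ")),
         call. = FALSE)
  }
  xa <- stats_a[[statistic]]
  xb <- stats_b[[statistic]]
  if (length(xa) == 0L || length(xb) == 0L) {
    stop("both tree-statistic lists must be non-empty", call. = FALSE)
  }
  if (length(xa) == 1L && length(xb) == 1L) {
    warning("single-tree comparison: p has very wide uncertainty",
            call. = FALSE)
  }
  p <- if (length(unique(c(xa, xb))) == 1L) 1 else
    suppressWarnings(stats::wilcox.test(xa, xb,
                                        alternative = "two.sided")$p.value)
  list(statistic = statistic, n_a = length(xa), n_b = length(xb),
       median_a = stats::median(xa), median_b = stats::median(xb), p = p)
}

#' Mutation-ordering query over lineage trees
#'
#' Over all root-to-leaf paths of all trees, counts paths where the first
#' mutation at `pos_a` precedes the first at `pos_b`, follows it, falls on
#' the same edge (tie), or where only one/neither position mutates. The
#' `never_precedes` verdict is `TRUE` when no path mutates `pos_a` before
#' `pos_b` and at least one path mutates both.
#'
#' @param trees list of `lineage_tree` objects.
#' @param pos_a,pos_b 1-based germline nucleotide positions.
#' @return list of path counts plus the verdict.
#' @export
mutation_order_precedes <- function(trees, pos_a, pos_b) {
  glen <- trees[[1]]$germline_length
  if (pos_a < 1L || pos_a > glen || pos_b < 1L || pos_b > glen) {
    stop(sprintf("positions must lie in the V region (1..%d)", glen),
         call. = FALSE)
  }
  cnt <- c(a_first = 0L, b_first = 0L, tie = 0L, only_a = 0L, only_b = 0L,
           neither = 0L)
  for (tree in trees) {
    kids <- .children_of(tree)
    e <- tree$edges[!tree$edges$flagged, , drop = FALSE]
    in_tree <- c("germline", e$child)
    leaves <- in_tree[vapply(kids[in_tree], length, 0L) == 0L &
                        in_tree != "germline"]
    parent <- stats::setNames(e$parent, e$child)
    edge_pos <- stats::setNames(lapply(e$positions, names), e$child)
    for (leaf in leaves) {
      path <- character(0)
      node <- leaf
      while (node != "germline") {
        path <- c(node, path)
        node <- parent[[node]]
      }
      step_a <- NA_integer_
      step_b <- NA_integer_
      for (si in seq_along(path)) {
        pp <- edge_pos[[path[si]]]
        if (is.na(step_a) && as.character(pos_a) %in% pp) step_a <- si
        if (is.na(step_b) && as.character(pos_b) %in% pp) step_b <- si
      }
      lab <- if (is.na(step_a) && is.na(step_b)) "neither"
      else if (is.na(step_b)) "only_a"
      else if (is.na(step_a)) "only_b"
      else if (step_a < step_b) "a_first"
      else if (step_a > step_b) "b_first"
      else "tie"
      cnt[lab] <- cnt[lab] + 1L
    }
  }
  both <- cnt[["a_first"]] + cnt[["b_first"]] + cnt[["tie"]]
  c(as.list(cnt),
    list(pos_a = pos_a, pos_b = pos_b, n_both = both,
         never_precedes = cnt[["a_first"]] == 0L && both >= 1L))
}

#' Newick export of a lineage tree
#'
#' Edge lengths are mutation counts; inferred intermediates are labelled
#' `i#`, observed nodes by their representative sequence id. Flagged indel
#' edges are exported with zero length and a `_indel` suffix.
#'
#' @param tree a `lineage_tree`.
#' @return single-line Newick string.
#' @export
as_newick <- function(tree) {
  e <- tree$edges
  kids <- split(seq_len(nrow(e)), factor(e$parent,
                                         levels = tree$nodes$node_id))
  fmt <- function(node) {
    ki <- kids[[node]]
    lab <- gsub("[();,: ]", "_", node)
    if (length(ki) == 0L) return(lab)
    subs <- vapply(ki, function(i) {
      child <- e$child[i]
      len <- if (e$flagged[i]) 0L else e$n_mut[i]
      suff <- if (e$flagged[i]) "_indel" else ""
      sub <- fmt(child)
      sprintf("%s%s:%d", sub, suff, len)
    }, "")
    sprintf("(%s)%s", paste(subs, collapse = ","), lab)
  }
  paste0(fmt("germline"), ";")
}

#' Write lineage trees as a Newick table
#' @param trees named list of `lineage_tree` objects.
#' @param path output TSV path (clone_id, newick).
#' @return invisibly, `path`.
#' @export
write_trees <- function(trees, path) {
  out <- data.frame(clone_id = names(trees),
                    newick = vapply(trees, as_newick, ""),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
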