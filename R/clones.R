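#' Group annotated sequences into clones
#'
#' Clones are detected within a single mouse: sequences sharing CDR3
#' amino-acid length are single-linkage clustered, linking any pair whose
#' junction nucleotide identity is at least `threshold` (default 0.90;
#' `threshold = 1` gives the strict shared-rearrangement mode). Output is
#' deterministic given the input: members are sorted by `seq_id` and clone ids
#' are assigned by the sorted representative (lexicographically smallest
#' member). Sequences with an undefined CDR3 keep `clone_id = NA` (the
#' sentinel "unassigned" pool), never silently dropped.
#'
#' @param db annotated repertoire data.frame (needs `cdr3_nt`, `mouse_id`).
#' @param threshold junction nucleotide identity linking threshold.
#' @return `db` with a `clone_id` column.
#' @export
group_clones <- function(db, threshold = 0.90) {
  db$clone_id <- rep(NA_character_, nrow(db))
  ok_aligned <- if ("v_aligned" %in% names(db)) {
    !is.na(db$v_aligned) & db$v_aligned
  } else rep(TRUE, nrow(db))
  assignable <- which(!is.na(db$cdr3_nt) & ok_aligned)
  for (mouse in sort(unique(db$mouse_id[assignable]))) {
    for (len in sort(unique(nchar(db$cdr3_nt[assignable])[
      db$mouse_id[assignable] == mouse]))) {
      idx <- assignable[db$mouse_id[assignable] == mouse &
                          nchar(db$cdr3_nt[assignable]) == len]
      idx <- idx[order(db$seq_id[idx])]
      m <- length(idx)
      chars <- do.call(rbind, strsplit(db$cdr3_nt[idx], ""))
      g <- igraph::make_empty_graph(n = m, directed = FALSE)
      if (m > 1L) {
        edges <- integer(0)
        for (i in seq_len(m - 1L)) {
          for (j in seq((i + 1L), m)) {
            if (sum(chars[i, ] == chars[j, ]) / len >= threshold) {
              edges <- c(edges, i, j)
            }
          }
        }
        if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
      }
      memb <- igraph::components(g)$membership
      for (cc in unique(memb)) {
        members <- idx[memb == cc]
        rep_id <- min(db$seq_id[members])
        db$clone_id[members] <- paste0(mouse, "|", len, "|", rep_id)
      }
    }
  }
  # stable, human-readable ids: per mouse, number clones by representative
  cl <- unique(stats::na.omit(db$clone_id))
  if (length(cl) > 0L) {
    key <- sort(cl)
    mouse_of <- sub("\\|.*$", "", key)
    new_id <- character(length(key))
    for (mouse in unique(mouse_of)) {
      sel <- mouse_of == mouse
      new_id[sel] <- sprintf("%s_c%03d", mouse, seq_len(sum(sel)))
    }
    db$clone_id <- new_id[match(db$clone_id, key)]
  }
  db
}

#' Per-clone summary table
#' @param db clone-assigned repertoire data.frame.
#' @return data.frame with clone id, mouse, size, CDR3 length, representative
#'   junction and per-subset/compartment member counts.
#' @export
clone_table <- function(db) {
  keep <- !is.na(db$clone_id)
  dbc <- db[keep, , drop = FALSE]
  cls <- sort(unique(dbc$clone_id))
  rows <- lapply(cls, function(cid) {
    m <- dbc[dbc$clone_id == cid, , drop = FALSE]
    m <- m[order(m$seq_id), , drop = FALSE]
    subs <- table(factor(m$subset, levels = SUBSETS))
    comps <- table(factor(m$compartment, levels = COMPARTMENTS))
    data.frame(clone_id = cid, mouse_id = m$mouse_id[1], size = nrow(m),
               cdr3_len_aa = nchar(m$cdr3_aa[1]),
               junction_nt = m$cdr3_nt[1],
               members = paste(m$seq_id, collapse = ";"),
               t(as.matrix(subs)), t(as.matrix(comps)),
               row.names = NULL, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-compartment clone overlap report
#'
#' Quantifies, per mouse, how many clones mix sequences of two labels of a
#' metadata axis (e.g. memory B cells vs long-lived plasma cells), the label
#' composition of every mixed clone, and the count/fraction of each label's
#' sequences residing in mixed clones. An axis label absent from the data
#' yields a zero row with a warning, not an exception.
#'
#' @param db clone-assigned repertoire data.frame.
#' @param axis_col metadata column defining the axis (default `"subset"`).
#' @param a,b the two axis labels.
#' @return list with `per_mouse` and `mixed_clones` data.frames.
#' @export
overlap_table <- function(db, axis_col = "subset", a = "MEMORY",
                          b = "LONGLIVED_PC") {
  for (lab in c(a, b)) {
    if (!lab %in% db[[axis_col]]) {
      warning(sprintf("axis label '%s' absent from dataset", lab),
              call. = FALSE)
    }
  }
  keep <- !is.na(db$clone_id) & db[[axis_col]] %in% c(a, b)
  dbc <- db[keep, , drop = FALSE]
  mice <- sort(unique(db$mouse_id))
  per_mouse <- list()
  mixed <- list()
  for (mouse in mice) {
    m <- dbc[dbc$mouse_id == mouse, , drop = FALSE]
    na_tot <- sum(m[[axis_col]] == a)
    nb_tot <- sum(m[[axis_col]] == b)
    cls <- unique(m$clone_id)
    n_mixed <- 0L
    na_mixed <- 0L
    nb_mixed <- 0L
    for (cid in sort(cls)) {
      ca <- sum(m$clone_id == cid & m[[axis_col]] == a)
      cb <- sum(m$clone_id == cid & m[[axis_col]] == b)
      if (ca > 0L && cb > 0L) {
        n_mixed <- n_mixed + 1L
        na_mixed <- na_mixed + ca
        nb_mixed <- nb_mixed + cb
        mixed[[length(mixed) + 1L]] <- data.frame(
          mouse_id = mouse, clone_id = cid, n_a = ca, n_b = cb,
          frac_of_a = ca / na_tot, frac_of_b = cb / nb_tot,
          stringsAsFactors = FALSE)
      }
    }
    per_mouse[[length(per_mouse) + 1L]] <- data.frame(
      mouse_id = mouse, n_clones = length(cls), n_mixed = n_mixed,
      n_a_seqs = na_tot, n_b_seqs = nb_tot,
      n_a_in_mixed = na_mixed,
      frac_a_in_mixed = if (na_tot > 0L) na_mixed / na_tot else 0,
      n_b_in_mixed = nb_mixed,
      frac_b_in_mixed = if (nb_tot > 0L) nb_mixed / nb_tot else 0,
      stringsAsFactors = FALSE)
  }
  list(per_mouse = do.call(rbind, per_mouse),
       mixed_clones = if (length(mixed) > 0L) do.call(rbind, mixed) else
         data.frame(mouse_id = character(0), clone_id = character(0),
                    n_a = integer(0), n_b = integer(0),
                    frac_of_a = numeric(0), frac_of_b = numeric(0)),
       axis = c(a = a, b = b), axis_col = axis_col)
}

#' Flag CDR3 Y-to-G mutations and the combined high-affinity call
#'
#' The CDR3 junction has no germline template, so Y-to-G replacements are
#' detected against the clone's inferred unmutated junction: for each
#' sequence, the per-position majority amino acid over the clone's OTHER
#' members (leave-one-out, so a sequence's own replacement cannot mask the
#' ancestral state; ties favour tyrosine, the ancestral residue of the
#' canonical junction layout). Singleton clones carry no information about
#' the ancestral junction and keep `has_cdr3_yg = NA`. `high_affinity` is
#' W33L OR CDR3 Y-to-G (with unknown Y-to-G treated as absent).
#'
#' @param db clone-assigned repertoire data.frame.
#' @return `db` with columns `has_cdr3_yg`, `high_affinity`.
#' @export
flag_high_affinity <- function(db) {
  db$has_cdr3_yg <- rep(NA, nrow(db))
  for (cid in unique(stats::na.omit(db$clone_id))) {
    idx <- which(!is.na(db$clone_id) & db$clone_id == cid &
                   !is.na(db$cdr3_aa))
    if (length(idx) == 0L) next
    aas <- db$cdr3_aa[idx]
    len <- max(nchar(aas))
    idx <- idx[nchar(aas) == len]
    aas <- aas[nchar(aas) == len]
    if (length(idx) < 2L) next
    chars <- do.call(rbind, strsplit(aas, ""))
    for (j in seq_along(idx)) {
      others <- chars[-j, , drop = FALSE]
      anc <- apply(others, 2, function(col) {
        tab <- table(col)
        top <- names(tab)[tab == max(tab)]
        if ("Y" %in% top) "Y" else top[1]
      })
      db$has_cdr3_yg[idx[j]] <- any(anc == "Y" & chars[j, ] == "G")
    }
  }
  yg <- !is.na(db$has_cdr3_yg) & db$has_cdr3_yg
  db$high_affinity <- ifelse(is.na(db$has_w33l), NA, db$has_w33l | yg)
  db
}
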