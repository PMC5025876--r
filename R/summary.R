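#' Per-group mutation-load and affinity summary
#'
#' For every combination of the grouping keys: number of sequences, mean and
#' median V-region mutation count, the fraction of sequences carrying a
#' high-affinity mutation (CDR1 W33L or CDR3 Y-to-G; also reported
#' separately) and the fraction mutated at the counter-selected position 102.
#' Groups with no annotated sequences yield a row with `n = 0` and `NA`
#' statistics, never an exception.
#'
#' @param db annotated repertoire data.frame (ideally after
#'   [flag_high_affinity()]; without clone assignment the Y-to-G component is
#'   treated as unknown and only W33L feeds `frac_high_affinity`).
#' @param group_by character vector of metadata column names.
#' @param groups optional data.frame of group combinations to report (rows
#'   absent from the data are emitted with `n = 0`).
#' @return data.frame, one row per group.
#' @export
mutation_summary <- function(db, group_by = "subset", groups = NULL) {
  keep <- !is.na(db$v_aligned) & db$v_aligned
  dba <- db[keep, , drop = FALSE]
  yg <- if ("has_cdr3_yg" %in% names(dba)) dba$has_cdr3_yg else
    rep(NA, nrow(dba))
  haff <- dba$has_w33l | (!is.na(yg) & yg)
  key <- if (nrow(dba) > 0L) {
    interaction(dba[, group_by, drop = FALSE], drop = FALSE, sep = "\r")
  } else factor(character(0))
  if (is.null(groups)) {
    groups <- unique(dba[, group_by, drop = FALSE])
    groups <- groups[do.call(order, groups), , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(groups)), function(gi) {
    sel <- rep(TRUE, nrow(dba))
    for (cn in group_by) sel <- sel & dba[[cn]] == groups[[cn]][gi]
    x <- dba$n_mutations[sel]
    n <- sum(sel)
    data.frame(groups[gi, , drop = FALSE],
               n = n,
               mean_mut = if (n > 0L) mean(x) else NA_real_,
               median_mut = if (n > 0L) stats::median(x) else NA_real_,
               frac_high_affinity = if (n > 0L) mean(haff[sel]) else NA_real_,
               frac_w33l = if (n > 0L) mean(dba$has_w33l[sel]) else NA_real_,
               frac_cdr3_yg = if (n > 0L && !all(is.na(yg[sel])))
                 mean(yg[sel], na.rm = TRUE) else NA_real_,
               frac_pos102 = if (n > 0L) mean(dba$has_pos102[sel]) else
                 NA_real_,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-position mutation frequency spectrum over the V region
#' @param db annotated repertoire data.frame.
#' @param ref a `germline_reference`.
#' @return data.frame with `pos`, `region`, `count`, `frequency` (count over
#'   aligned sequences), one row per germline position.
#' @export
position_spectrum <- function(db, ref) {
  keep <- !is.na(db$v_aligned) & db$v_aligned
  glen <- nchar(ref$nt_seq)
  pos_all <- unlist(lapply(db$mutations[keep], function(m) m$pos))
  cnt <- tabulate(pos_all, nbins = glen)
  n <- sum(keep)
  data.frame(pos = seq_len(glen),
             region = region_at(ref, seq_len(glen)),
             count = cnt,
             frequency = if (n > 0L) cnt / n else rep(NA_real_, glen))
}

#' Mann-Whitney comparison of mutation counts between two groups
#'
#' Thin reporting convenience around [stats::wilcox.test()] (two-sided).
#'
#' @param db annotated repertoire data.frame.
#' @param group_col metadata column name.
#' @param a,b the two group labels to compare.
#' @param value column holding the compared quantity (default `n_mutations`).
#' @return list with `n_a`, `n_b`, `median_a`, `median_b`, `p`.
#' @export
compare_groups <- function(db, group_col, a, b, value = "n_mutations") {
  keep <- !is.na(db$v_aligned) & db$v_aligned
  xa <- db[[value]][keep & db[[group_col]] == a]
  xb <- db[[value]][keep & db[[group_col]] == b]
  if (length(xa) == 0L || length(xb) == 0L) {
    stop(sprintf("group '%s' or '%s' has no aligned sequences", a, b),
         call. = FALSE)
  }
  p <- suppressWarnings(
    stats::wilcox.test(xa, xb, alternative = "two.sided")$p.value)
  list(n_a = length(xa), n_b = length(xb),
       median_a = stats::median(xa), median_b = stats::median(xb), p = p)
}
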