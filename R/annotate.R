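#' Alignment / annotation configuration
#'
#' Scoring follows the package default for heavily mutated amplicons: match +1,
#' mismatch -2, gap open -4, gap extend -1; a read must cover at least
#' `min_coverage` of the germline V region and reach `min_identity` nucleotide
#' identity over the covered span, otherwise it is flagged non-V_H_186.2 and
#' excluded downstream (reason code, not an exception). The germline is always
#' fully aligned (global on the reference, local on the read) so terminal
#' V-region mutations are never clipped by end-free scoring.
#'
#' @param match,mismatch,gap_open,gap_ext alignment scores.
#' @param min_coverage minimum fraction of germline positions covered.
#' @param min_identity minimum identity over covered, non-N positions.
#' @param j_motif nucleotide motif whose first occurrence 3' of the V region
#'   marks the J-region tryptophan anchoring the CDR3 end (exclusive).
#' @param np_offset 1-based index into the CDR3 amino-acid string of the
#'   anchor tyrosine of the NP-binding rule ("position 99"; default third
#'   residue, matching the canonical B1-8 junction layout).
#' @param np_len CDR3 amino-acid length range accepted by the NP rule.
#' @return list of class `annotate_config`.
#' @export
annotate_config <- function(match = 1, mismatch = -2, gap_open = -4,
                            gap_ext = -1, min_coverage = 0.8,
                            min_identity = 0.7, j_motif = "TGGGG",
                            np_offset = 3L, np_len = c(9L, 11L)) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, min_coverage = min_coverage,
                 min_identity = min_identity, j_motif = j_motif,
                 np_offset = as.integer(np_offset),
                 np_len = as.integer(np_len)),
            class = "annotate_config")
}

# Substitution matrix over the observed alphabet. N scores 0 against
# everything: uninformative, neither rewarded nor penalised.
.sub_matrix <- function(match, mismatch) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Align reads to the germline V region
#'
#' Adds alignment columns to the repertoire table: gapped germline/read
#' strings over the V span, identity, coverage, the read coordinate where the
#' germline V region ends (CDR3 anchor), and a reject reason for reads that
#' fail the coverage or identity floors.
#'
#' @param db repertoire data.frame from [read_fasta()].
#' @param ref a `germline_reference`.
#' @param cfg an [annotate_config()].
#' @return `db` with columns `v_aligned`, `reject_reason`, `v_identity`,
#'   `v_coverage`, `aln_germ`, `aln_read`, `v_end_read`.
#' @export
align_to_germline <- function(db, ref, cfg = annotate_config()) {
  n <- nrow(db)
  glen <- nchar(ref$nt_seq)
  db$v_aligned <- rep(FALSE, n)
  db$reject_reason <- rep(NA_character_, n)
  db$v_identity <- rep(NA_real_, n)
  db$v_coverage <- rep(NA_real_, n)
  db$aln_germ <- rep(NA_character_, n)
  db$aln_read <- rep(NA_character_, n)
  db$v_germ_start <- rep(NA_integer_, n)
  db$v_end_read <- rep(NA_integer_, n)
  if (n == 0L) return(db)

  too_short <- nchar(db$nt_seq) < cfg$min_coverage * glen
  db$reject_reason[too_short] <- "too_short"
  idx <- which(!too_short)
  if (length(idx) == 0L) return(db)

  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(db$nt_seq[idx]),
    subject = Biostrings::DNAString(ref$nt_seq),
    type = "local-global",
    substitutionMatrix = .sub_matrix(cfg$match, cfg$mismatch),
    gapOpening = abs(cfg$gap_open), gapExtension = abs(cfg$gap_ext))

  # gapped strings over the aligned region (subject = germline is global, so
  # all germline positions appear; read flanks beyond the V region are clipped)
  gt <- as.character(Biostrings::subject(al))
  rt <- as.character(Biostrings::pattern(al))
  # read coordinate of the last aligned read base (original read coordinates)
  # and the first germline position present in the aligned strings (leading
  # or trailing germline positions may be clipped when the read is truncated)
  p_end <- Biostrings::end(Biostrings::pattern(al))
  g_start <- Biostrings::start(Biostrings::subject(al))

  for (j in seq_along(idx)) {
    i <- idx[j]
    g <- strsplit(gt[j], "")[[1]]
    r <- strsplit(rt[j], "")[[1]]
    gpos <- g != "-"
    rbase <- r != "-"
    covered <- gpos & rbase
    # leading/trailing germline positions opposite read gaps are uncovered,
    # not deletions; internal ones count as indels at mutation-calling time
    ncov <- sum(covered)
    cov <- ncov / glen
    informative <- covered & g %in% c("A", "C", "G", "T") &
      r %in% c("A", "C", "G", "T")
    ident <- if (sum(informative) > 0L) {
      sum(g[informative] == r[informative]) / sum(informative)
    } else 0
    db$v_coverage[i] <- cov
    db$v_identity[i] <- ident
    db$aln_germ[i] <- gt[j]
    db$aln_read[i] <- rt[j]
    db$v_germ_start[i] <- g_start[j]
    db$v_end_read[i] <- p_end[j]
    # the non-target call uses identity over the WHOLE germline (uncovered
    # positions count as mismatches, matching a forced gapless comparison),
    # so unrelated amplicons are labelled as such rather than "low coverage"
    ident_global <- if (sum(informative) > 0L)
      sum(g[informative] == r[informative]) / glen else 0
    if (ident_global < cfg$min_identity) {
      db$reject_reason[i] <- "not_vh186"
    } else if (cov < cfg$min_coverage) {
      db$reject_reason[i] <- "low_coverage"
    } else if (ident < cfg$min_identity) {
      db$reject_reason[i] <- "not_vh186"
    } else {
      db$v_aligned[i] <- TRUE
    }
  }
  db
}

# Annotate a bare substitution table (pos/from/to) with region, codon index
# and amino-acid change inferred from the germline alone (single-substitution
# codon translation; used when reconstituting TSVs).
describe_mutations <- function(mut, ref) {
  if (nrow(mut) == 0L) {
    mut$region <- character(0); mut$codon <- integer(0)
    mut$aa_from <- character(0); mut$aa_to <- character(0)
    mut$silent <- logical(0)
    return(mut)
  }
  mut$region <- region_at(ref, mut$pos)
  mut$codon <- ceiling((mut$pos - ref$frame_offset) / 3)
  gc <- vapply(mut$codon, function(k) germline_codon(ref, k), "")
  off <- (mut$pos - ref$frame_offset - 1L) %% 3L + 1L
  mc <- gc
  substr(mc, off, off) <- mut$to
  mut$aa_from <- vapply(gc, translate_nt, "")
  mut$aa_to <- vapply(mc, translate_nt, "")
  mut$silent <- mut$aa_from == mut$aa_to
  mut
}

#' Call somatic mutations from a germline alignment
#'
#' Walks every aligned read/germline column and records substitutions with
#' germline coordinates, region, codon index and amino-acid change. Positions
#' opposite N bases are skipped (tallied in `n_skipped`); codons touched by
#' indels are excluded from amino-acid inference and tallied in `n_indels`.
#' `n_mutations` counts V-region substitutions only (the CDR3 junction is
#' templated by the rearrangement, not the germline V, and is handled
#' separately). The amino-acid change of a mutation reflects the read's full
#' codon, so co-mutated codons report the observed replacement.
#'
#' @param db output of [align_to_germline()].
#' @param ref a `germline_reference`.
#' @return `db` with list-column `mutations` and columns `n_mutations`,
#'   `n_indels`, `n_skipped`, `has_w33l`, `has_pos102`.
#' @export
call_mutations <- function(db, ref) {
  n <- nrow(db)
  empty <- describe_mutations(
    data.frame(pos = integer(), from = character(), to = character(),
               stringsAsFactors = FALSE), ref)
  db$mutations <- rep(list(empty), n)
  db$n_mutations <- rep(NA_integer_, n)
  db$n_indels <- rep(NA_integer_, n)
  db$n_skipped <- rep(NA_integer_, n)
  db$has_w33l <- rep(NA, n)
  db$has_pos102 <- rep(NA, n)
  for (i in seq_len(n)) {
    if (!isTRUE(db$v_aligned[i])) next
    g <- strsplit(db$aln_germ[i], "")[[1]]
    r <- strsplit(db$aln_read[i], "")[[1]]
    # germline coordinate per column (offset when 5' positions are clipped)
    gpos_idx <- cumsum(g != "-") + db$v_germ_start[i] - 1L
    covered_cols <- which(g != "-" & r != "-")
    # trim leading/trailing read-gap runs: uncovered, not deletions
    span <- if (length(covered_cols) > 0L)
      seq(min(covered_cols), max(covered_cols)) else integer(0)
    indel_cols <- span[g[span] == "-" | r[span] == "-"]
    n_ins <- sum(g[indel_cols] == "-")
    del_cols <- indel_cols[g[indel_cols] != "-"]
    indel_codons <- unique(ceiling(
      (gpos_idx[del_cols] - ref$frame_offset) / 3))
    sub_cols <- span[g[span] != "-" & r[span] != "-"]
    is_n <- r[sub_cols] == "N" | g[sub_cols] == "N"
    n_skip <- sum(is_n)
    sub_cols <- sub_cols[!is_n]
    diff_cols <- sub_cols[g[sub_cols] != r[sub_cols]]
    mut <- data.frame(pos = gpos_idx[diff_cols], from = g[diff_cols],
                      to = r[diff_cols], stringsAsFactors = FALSE)
    mut <- describe_mutations(mut, ref)
    if (nrow(mut) > 0L) {
      # recompute aa_to from the read's actual codon; NA when the codon is
      # indel-affected or carries an N
      for (k in unique(mut$codon)) {
        cols_k <- span[gpos_idx[span] %in%
                         (ref$frame_offset + (3L * k - 2L):(3L * k)) &
                         g[span] != "-"]
        rc <- r[cols_k]
        if (k %in% indel_codons || length(cols_k) != 3L || any(rc == "-") ||
            any(rc == "N")) {
          mut$aa_to[mut$codon == k] <- NA_character_
          mut$silent[mut$codon == k] <- NA
        } else {
          aa <- translate_nt(paste(rc, collapse = ""))
          mut$aa_to[mut$codon == k] <- aa
          mut$silent[mut$codon == k] <- aa == mut$aa_from[mut$codon == k][1]
        }
      }
    }
    db$mutations[[i]] <- mut
    db$n_mutations[i] <- nrow(mut)
    db$n_indels[i] <- length(del_cols) + n_ins
    db$n_skipped[i] <- n_skip
    db$has_w33l[i] <- any(mut$pos == 98L & mut$aa_from == "W" &
                            !is.na(mut$aa_to) & mut$aa_to == "L")
    db$has_pos102[i] <- any(mut$pos == 102L)
  }
  db
}

#' Apply a mutation table to the germline (involution check helper)
#' @param ref a `germline_reference`.
#' @param mut data.frame with `pos`, `to` columns.
#' @return mutated V-region nucleotide string.
#' @export
apply_mutations <- function(ref, mut) {
  s <- strsplit(ref$nt_seq, "")[[1]]
  if (nrow(mut) > 0L) s[mut$pos] <- mut$to
  paste(s, collapse = "")
}

#' Extract the CDR3 amino-acid string
#'
#' Translates the junction between the conserved FR3 cysteine (the last
#' germline V codon, located via the alignment; exclusive) and the J-region
#' tryptophan motif (first `j_motif` occurrence 3' of the V region;
#' exclusive). Reads whose alignment does not reach the 3' end of FR3, or
#' where the anchor motif is absent or out of frame, get a reason code and are
#' excluded from NP classification.
#'
#' @param db output of [align_to_germline()].
#' @param ref a `germline_reference`.
#' @param cfg an [annotate_config()].
#' @return `db` with columns `cdr3_nt`, `cdr3_aa`, `cdr3_reason`, `productive`.
#' @export
extract_cdr3 <- function(db, ref, cfg = annotate_config()) {
  n <- nrow(db)
  glen <- nchar(ref$nt_seq)
  db$cdr3_nt <- rep(NA_character_, n)
  db$cdr3_aa <- rep(NA_character_, n)
  db$cdr3_reason <- rep(NA_character_, n)
  db$productive <- rep(NA, n)
  for (i in seq_len(n)) {
    if (!isTRUE(db$v_aligned[i])) {
      db$cdr3_reason[i] <- "not_aligned"
      next
    }
    g <- strsplit(db$aln_germ[i], "")[[1]]
    r <- strsplit(db$aln_read[i], "")[[1]]
    gpos <- cumsum(g != "-") + db$v_germ_start[i] - 1L
    hit_cols <- which(gpos == glen & g != "-")
    if (length(hit_cols) == 0L || r[max(hit_cols)] == "-") {
      db$cdr3_reason[i] <- "fr3_end_uncovered"  # alignment misses FR3 end
      next
    }
    tail_nt <- substr(db$nt_seq[i], db$v_end_read[i] + 1L,
                      nchar(db$nt_seq[i]))
    if (!nzchar(tail_nt)) {
      db$cdr3_reason[i] <- "no_junction"
      next
    }
    hit <- regexpr(cfg$j_motif, tail_nt, fixed = TRUE)
    if (hit < 0L) {
      db$cdr3_reason[i] <- "no_j_anchor"
      next
    }
    cdr3 <- substr(tail_nt, 1L, hit - 1L)
    if (!nzchar(cdr3)) {
      db$cdr3_reason[i] <- "empty_cdr3"
      next
    }
    if (nchar(cdr3) %% 3L != 0L) {
      db$cdr3_reason[i] <- "out_of_frame"
      next
    }
    aa <- translate_nt(cdr3)
    db$cdr3_nt[i] <- cdr3
    db$cdr3_aa[i] <- aa
    db$productive[i] <- !grepl("*", aa, fixed = TRUE)
  }
  db
}

#' Classify NP binding from CDR3 composition
#'
#' A sequence is called NP-binding when its CDR3 is 9-11 amino acids long, the
#' anchor residue ("position 99" in antibody numbering; by default
#' the third CDR3 residue) is tyrosine, and at least two of the following
#' three residues are tyrosines. Pure total function of the CDR3 string:
#' CDR3s containing a stop codon are classified `FALSE` (nonproductive), and
#' `NA` input yields `NA`.
#'
#' @param cdr3_aa character vector of CDR3 amino-acid strings.
#' @param cfg an [annotate_config()] (fields `np_offset`, `np_len`).
#' @return logical vector.
#' @export
classify_np_binding <- function(cdr3_aa, cfg = annotate_config()) {
  vapply(cdr3_aa, function(s) {
    if (is.na(s)) return(NA)
    if (grepl("*", s, fixed = TRUE)) return(FALSE)
    len <- nchar(s)
    if (len < cfg$np_len[1] || len > cfg$np_len[2]) return(FALSE)
    if (len < cfg$np_offset) return(FALSE)
    if (substr(s, cfg$np_offset, cfg$np_offset) != "Y") return(FALSE)
    tail3 <- substr(s, cfg$np_offset + 1L, min(len, cfg$np_offset + 3L))
    sum(strsplit(tail3, "")[[1]] == "Y") >= 2L
  }, NA)
}

#' Full annotation pipeline for a repertoire table
#'
#' Runs [align_to_germline()], [call_mutations()], [extract_cdr3()] and
#' [classify_np_binding()] in order.
#'
#' @param db repertoire data.frame from [read_fasta()].
#' @param ref a `germline_reference`.
#' @param cfg an [annotate_config()].
#' @return annotated repertoire data.frame (adds column `np_binding`).
#' @export
annotate_repertoire <- function(db, ref, cfg = annotate_config()) {
  db <- align_to_germline(db, ref, cfg)
  db <- call_mutations(db, ref)
  db <- extract_cdr3(db, ref, cfg)
  db$np_binding <- classify_np_binding(db$cdr3_aa, cfg)
  db
}
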