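#' Read a repertoire FASTA with its metadata manifest
#'
#' Pairs every FASTA entry with its row in a tab-separated manifest keyed by
#' `seq_id` with `mouse_id`, `compartment`, `subset` and `isotype` columns
#' (unknown extra columns are carried through untouched). FASTA order is
#' preserved and sequences are uppercased.
#'
#' @param fasta_path FASTA file of heavy-chain V-region reads.
#' @param manifest_path tab-separated metadata table.
#' @return data.frame with columns `seq_id`, `nt_seq`, `mouse_id`,
#'   `compartment`, `subset`, `isotype` plus any extra manifest columns.
#' @export
read_fasta <- function(fasta_path, manifest_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate seq_id in FASTA: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  man <- utils::read.delim(manifest_path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  req <- c("seq_id", "mouse_id", "compartment", "subset", "isotype")
  missing_cols <- setdiff(req, names(man))
  if (length(missing_cols) > 0L) {
    stop(sprintf("manifest lacks required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(man$seq_id)) {
    stop(sprintf("duplicate seq_id in manifest: %s",
                 paste(unique(man$seq_id[duplicated(man$seq_id)]),
                       collapse = ", ")), call. = FALSE)
  }
  orphan <- setdiff(ids, man$seq_id)
  if (length(orphan) > 0L) {
    stop(sprintf("FASTA seq_id(s) absent from manifest: %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  }
  check_enum(man$compartment, COMPARTMENTS, "compartment")
  check_enum(man$subset, SUBSETS, "subset")
  check_enum(man$isotype, ISOTYPES, "isotype")
  nt <- toupper(as.character(seqs))
  if (any(!nzchar(nt))) stop("empty sequence in FASTA", call. = FALSE)
  if (any(grepl("[^ACGTN]", nt))) {
    stop("sequences may contain only A/C/G/T/N", call. = FALSE)
  }
  man <- man[match(ids, man$seq_id), , drop = FALSE]
  out <- data.frame(seq_id = ids, nt_seq = unname(nt),
                    man[, setdiff(names(man), "seq_id"), drop = FALSE],
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out[, c(req[1], "nt_seq", req[-1],
          setdiff(names(out), c(req, "nt_seq"))), drop = FALSE]
}

#' Write a repertoire to FASTA + manifest
#' @param db repertoire data.frame (as from [read_fasta()]).
#' @param fasta_path,manifest_path output paths.
#' @return invisibly, the two paths.
#' @export
write_fasta <- function(db, fasta_path, manifest_path) {
  x <- Biostrings::DNAStringSet(db$nt_seq)
  names(x) <- db$seq_id
  Biostrings::writeXStringSet(x, fasta_path)
  man <- db[, setdiff(names(db), "nt_seq"), drop = FALSE]
  utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, manifest_path))
}

# Serialisation of a mutation table to the compact "pos:from>to;..." form used
# in the annotation TSV, and its inverse.
format_mutations <- function(mut) {
  if (is.null(mut) || nrow(mut) == 0L) return("")
  paste(sprintf("%d:%s>%s", mut$pos, mut$from, mut$to), collapse = ";")
}

parse_mutations <- function(s, ref = NULL) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(pos = integer(), from = character(),
                      to = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "[:>]")
  out <- data.frame(pos = as.integer(vapply(parts, `[`, "", 1L)),
                    from = vapply(parts, `[`, "", 2L),
                    to = vapply(parts, `[`, "", 3L),
                    stringsAsFactors = FALSE)
  if (!is.null(ref)) out <- describe_mutations(out, ref)
  out
}

ANNOT_COLS <- c("seq_id", "mouse_id", "compartment", "subset", "isotype",
                "v_aligned", "reject_reason", "v_identity", "v_coverage",
                "n_mutations", "n_indels", "n_skipped", "mutations",
                "cdr3_nt", "cdr3_aa", "cdr3_reason", "productive",
                "np_binding", "has_w33l", "has_pos102", "has_cdr3_yg",
                "high_affinity", "clone_id")

#' Write annotated sequences as an AIRR-style TSV
#'
#' One row per sequence: metadata, alignment summary, mutation count, the
#' mutation list (`pos:from>to`, semicolon-joined), CDR3, NP-binding flag and
#' clone id (if assigned). [read_annotations()] inverts it losslessly.
#'
#' @param db annotated repertoire data.frame.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_annotations <- function(db, path) {
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    seq_id = character(0))
  if (nrow(db) > 0L) {
    cols <- lapply(ANNOT_COLS, function(cn) {
      if (cn == "mutations") {
        vapply(db$mutations, format_mutations, "")
      } else if (cn %in% names(db)) db[[cn]] else rep(NA, nrow(db))
    })
    names(cols) <- ANNOT_COLS
    out <- as.data.frame(cols, stringsAsFactors = FALSE)
  } else {
    out <- as.data.frame(
      stats::setNames(replicate(length(ANNOT_COLS), character(0),
                                simplify = FALSE), ANNOT_COLS))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read an annotation TSV written by [write_annotations()]
#' @param path TSV path.
#' @param ref optional `germline_reference`; when given, per-mutation region,
#'   codon and amino-acid change columns are reconstituted.
#' @return annotated repertoire data.frame.
#' @export
read_annotations <- function(path, ref = NULL) {
  db <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = "")
  for (cn in c("v_aligned", "productive", "np_binding", "has_w33l",
               "has_pos102", "has_cdr3_yg", "high_affinity")) {
    db[[cn]] <- as.logical(db[[cn]])
  }
  for (cn in c("n_mutations", "n_indels", "n_skipped")) {
    db[[cn]] <- as.integer(db[[cn]])
  }
  for (cn in c("v_identity", "v_coverage")) db[[cn]] <- as.numeric(db[[cn]])
  mut_str <- db$mutations
  mut_str[is.na(mut_str)] <- ""
  db$mutations <- lapply(mut_str, parse_mutations, ref = ref)
  db
}
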