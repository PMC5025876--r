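# Shared fixtures: the bundled germline, tiny hand-built reads and an
# independent read constructor (germline + explicit substitutions + junction).

test_ref <- vh186_reference()
GERM <- strsplit(test_ref$nt_seq, "")[[1]]
JSEG <- "TGGGGTCAAGGAACCTCAGTCACCGTCTCCTCA"

# build a read from the germline with named substitutions (pos -> base) and
# an optional CDR3 amino-acid junction
make_read <- function(subs = c(), cdr3_aa = "ARYYYGSSDY", junction = TRUE) {
  v <- GERM
  if (length(subs) > 0L) v[as.integer(names(subs))] <- subs
  jnt <- if (junction && nzchar(cdr3_aa)) clonmix:::encode_aa(cdr3_aa) else ""
  paste0(paste(v, collapse = ""), jnt, if (junction) JSEG else "")
}

make_db <- function(seqs, mouse = "m1", compartment = "PP",
                    subset = "MEMORY", isotype = "IgA") {
  n <- length(seqs)
  data.frame(seq_id = sprintf("s%02d", seq_len(n)), nt_seq = unname(seqs),
             mouse_id = rep_len(mouse, n),
             compartment = rep_len(compartment, n),
             subset = rep_len(subset, n), isotype = rep_len(isotype, n),
             stringsAsFactors = FALSE)
}

write_tiny_fasta <- function(db, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("clonmix_fix")
    dir.create(dir)
  }
  fa <- file.path(dir, "reads.fasta")
  mf <- file.path(dir, "manifest.tsv")
  writeLines(paste0(">", db$seq_id, "\n", db$nt_seq), fa)
  utils::write.table(db[, setdiff(names(db), "nt_seq")], mf, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(fasta = fa, manifest = mf, dir = dir)
}
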