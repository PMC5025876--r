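# Internal helpers shared across modules.

# Permitted metadata vocabularies (SequenceRecord enums).
COMPARTMENTS <- c("PP", "MLN", "SPL", "SI_LP", "COLON", "BM")
SUBSETS      <- c("MEMORY", "LONGLIVED_PC", "RESPONDING_MEM", "BOOST_PC", "OTHER")
ISOTYPES     <- c("IgM", "IgG1", "IgG_other", "IgA", "UNKNOWN")

# Run `code` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

check_enum <- function(x, permitted, what) {
  bad <- setdiff(unique(x), permitted)
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s value(s): %s; permitted: %s", what,
                 paste(bad, collapse = ", "), paste(permitted, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

# Translate an in-frame nucleotide string via the standard genetic code
# (Biostrings::GENETIC_CODE); ambiguous codons yield X. Plain lookup rather
# than Biostrings::translate() because annotation translates one codon at a
# time and the S4 call overhead dominates otherwise.
translate_nt <- function(nt) {
  n <- nchar(nt)
  if (n == 0L) return("")
  codons <- substring(nt, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# 0-based <-> 1-based index conversion. The single place 0-based coordinates
# may appear in the code base (spec'd coordinate hygiene).
to0 <- function(i) i - 1L
to1 <- function(i) i + 1L

`%||%` <- function(a, b) if (is.null(a)) b else a
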