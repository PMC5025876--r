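#' Germline V-region reference
#'
#' A `germline_reference` bundles the nucleotide sequence of a heavy-chain V
#' gene with its framework/CDR region boundaries and reading frame. All
#' coordinates in the package are 1-based inclusive nucleotide positions on
#' this reference. The coordinate convention is anchored by codon 33: under the
#' declared frame it must translate to tryptophan (TGG), so that a G-to-T
#' substitution at nucleotide 98 (the middle base of codon 33) produces the
#' canonical affinity-enhancing W33L replacement of anti-NP antibodies.
#'
#' @param name identifier, e.g. `"VH186.2-synthetic"`.
#' @param nt_seq nucleotide string (A/C/G/T only), a whole number of codons
#'   after `frame_offset`.
#' @param region_map data.frame with columns `region` (one of FR1, CDR1, FR2,
#'   CDR2, FR3), `start`, `end`; must tile the V region without gaps/overlaps.
#' @param frame_offset integer; codon `k` spans nucleotides
#'   `frame_offset + (3k-2):(3k)`.
#' @return object of class `germline_reference`.
#' @export
germline_reference <- function(name, nt_seq, region_map, frame_offset = 0L) {
  nt_seq <- toupper(nt_seq)
  if (grepl("[^ACGT]", nt_seq)) {
    stop("germline nt_seq may contain only A/C/G/T", call. = FALSE)
  }
  frame_offset <- as.integer(frame_offset)
  n <- nchar(nt_seq)
  if ((n - frame_offset) %% 3L != 0L || frame_offset < 0L || frame_offset >= n) {
    stop("germline length is not a whole number of codons after frame offset",
         call. = FALSE)
  }
  region_map <- as.data.frame(region_map)[, c("region", "start", "end")]
  region_map$start <- as.integer(region_map$start)
  region_map$end <- as.integer(region_map$end)
  check_enum(region_map$region, c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
             "region label")
  rm_ord <- region_map[order(region_map$start), ]
  if (rm_ord$start[1] != frame_offset + 1L || rm_ord$end[nrow(rm_ord)] != n ||
      (nrow(rm_ord) > 1L &&
       any(rm_ord$start[-1] != rm_ord$end[-nrow(rm_ord)] + 1L))) {
    stop("region_map must tile the V region without gaps or overlaps",
         call. = FALSE)
  }
  ref <- structure(
    list(name = name, nt_seq = nt_seq, region_map = rm_ord,
         frame_offset = frame_offset),
    class = "germline_reference")
  w33 <- translate_nt(germline_codon(ref, 33L))
  if (!identical(w33, "W")) {
    stop(sprintf(
      "codon 33 translates to '%s', not W: coordinate convention broken", w33),
      call. = FALSE)
  }
  ref
}

#' @export
print.germline_reference <- function(x, ...) {
  cat(sprintf("germline_reference '%s': %d nt, frame offset %d\n",
              x$name, nchar(x$nt_seq), x$frame_offset))
  print(x$region_map, row.names = FALSE)
  invisible(x)
}

#' Nucleotides of germline codon `k`
#' @param ref a `germline_reference`.
#' @param k codon index (1-based).
#' @return three-letter nucleotide string.
#' @export
germline_codon <- function(ref, k) {
  substr(ref$nt_seq, ref$frame_offset + 3L * k - 2L, ref$frame_offset + 3L * k)
}

#' Region label at a germline nucleotide position
#' @param ref a `germline_reference`.
#' @param pos vector of 1-based nucleotide positions.
#' @return character vector of region labels.
#' @export
region_at <- function(ref, pos) {
  idx <- findInterval(pos, ref$region_map$start)
  out <- rep(NA_character_, length(pos))
  ok <- idx >= 1L & pos <= ref$region_map$end[pmax(idx, 1L)]
  out[ok] <- ref$region_map$region[idx[ok]]
  out
}

#' Load a germline reference from FASTA + JSON region map
#'
#' The JSON file holds `frame_offset` and a `regions` array of
#' `{region, start, end}` records. All `germline_reference` invariants,
#' including the codon-33 tryptophan check, are verified at load time.
#'
#' @param fasta_path FASTA file with a single entry.
#' @param regions_path JSON region map.
#' @return a `germline_reference`.
#' @export
load_germline <- function(fasta_path, regions_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) stop("germline FASTA must hold exactly one sequence",
                               call. = FALSE)
  meta <- jsonlite::fromJSON(regions_path)
  germline_reference(
    name = sub("\\s.*$", "", names(seqs)[1]),
    nt_seq = as.character(seqs[[1]]),
    region_map = as.data.frame(meta$regions),
    frame_offset = meta$frame_offset %||% 0L)
}

#' Write a germline reference as FASTA + JSON region map
#' @param ref a `germline_reference`.
#' @param fasta_path,regions_path output paths.
#' @return invisibly, the two paths.
#' @export
write_germline <- function(ref, fasta_path, regions_path) {
  x <- Biostrings::DNAStringSet(ref$nt_seq)
  names(x) <- ref$name
  Biostrings::writeXStringSet(x, fasta_path)
  jsonlite::write_json(
    list(frame_offset = ref$frame_offset,
         regions = ref$region_map),
    regions_path, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta_path, regions_path))
}

# Fixed codon choice per amino acid used by the synthetic reference and the
# simulator's junction encoder (deterministic; W = TGG by the genetic code).
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
              H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
              P = "CCT", Q = "CAG", R = "CGT", S = "AGC", T = "ACA", V = "GTT",
              W = "TGG", Y = "TAT")

encode_aa <- function(aa) {
  paste(CODON_OF[strsplit(aa, "")[[1]]], collapse = "")
}

#' Synthetic V_H_186.2-like germline reference
#'
#' The study's germline allele sequence is not bundled with this package; this
#' constructor builds a synthetic stand-in with the canonical V_H_186.2 layout:
#' 98 codons (294 nt, frame offset 0), FR1 (nt 1-75), CDR1 (76-99), FR2
#' (100-150), CDR2 (151-174) and FR3 (175-294); codon 33 (nt 97-99) is TGG so
#' that G98T yields W33L, and the final FR3 codon is the conserved cysteine
#' that anchors the CDR3 junction. It is deterministic and identical to the
#' copy shipped under `inst/extdata/vh186_synthetic.*`.
#'
#' @return a `germline_reference`.
#' @export
synthetic_vh186_germline <- function() {
  fr1  <- "EVQLQQSGPELVKPGASVKISCKAS"                  # codons 1-25
  cdr1 <- "GYTFTDYW"                                   # codons 26-33 (W33)
  fr2  <- "INWVKQRPGQGLEWIGR"                          # codons 34-50
  cdr2 <- "IYPGNGDT"                                   # codons 51-58
  fr3  <- "GRVYNQKFKGKATLTVDKSSSTAYMELRSLTSEDSAVYYC"   # codons 59-98 (C98)
  nt <- paste(vapply(c(fr1, cdr1, fr2, cdr2, fr3), encode_aa, ""),
              collapse = "")
  germline_reference(
    name = "VH186.2-synthetic",
    nt_seq = nt,
    region_map = data.frame(
      region = c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
      start  = c(1L, 76L, 100L, 151L, 175L),
      end    = c(75L, 99L, 150L, 174L, 294L)),
    frame_offset = 0L)
}

#' Bundled synthetic V_H_186.2 reference
#'
#' Loads the synthetic germline shipped under `inst/extdata/` (see
#' [synthetic_vh186_germline()] for its provenance and layout).
#' @return a `germline_reference`.
#' @export
vh186_reference <- function() {
  load_germline(
    system.file("extdata", "vh186_synthetic.fasta", package = "clonmix",
                mustWork = TRUE),
    system.file("extdata", "vh186_synthetic_regions.json", package = "clonmix",
                mustWork = TRUE))
}
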