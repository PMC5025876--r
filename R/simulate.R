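# Synthetic germinal-centre repertoire generator. Emits repertoires with the
# statistical structure the analysis assumes -- clonal genealogies under
# somatic hypermutation with hotspot/selection effects, NP / non-NP CDR3
# junctions, compartment assignment with a controllable clone-mixing
# probability -- together with a complete truth table, so every pipeline
# stage can be tested without external data.

# residues for free CDR3 slots: no Y (the NP rule counts tyrosines), no W
# (reserved for the J-anchor motif), no C
FREE_AA <- c("A", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
             "R", "S", "T", "V")
# synthetic J segment; opens with the conserved tryptophan (TGGGG... motif)
J_SEGMENT <- "TGGGGTCAAGGAACCTCAGTCACCGTCTCCTCA"

# Clone-level CDR3 amino-acid construction. NP-binding junctions satisfy the
# classifier rule exactly (length 9-11, Y at the anchor position, two of the
# three following residues Y); non-NP junctions violate it by a failed
# anchor, failed support tyrosines, or an out-of-range length. The final
# residue is always the tyrosine designated as the CDR3 Y->G target.
.random_cdr3 <- function(np, anchor = 3L) {
  if (np) {
    len <- sample(9:11, 1L)
    aa <- sample(FREE_AA, len, replace = TRUE)
    aa[anchor] <- "Y"
    aa[sample(anchor + (1:3), 2L)] <- "Y"
    aa[len] <- "Y"
  } else {
    mode <- sample(c("anchor", "support", "short", "long"), 1L)
    len <- switch(mode, short = 8L, long = 12L, sample(9:11, 1L))
    aa <- sample(FREE_AA, len, replace = TRUE)
    if (mode == "anchor") {
      # support tyrosines present, anchor residue not Y
      aa[sample(anchor + (1:3), 2L)] <- "Y"
    } else {
      aa[anchor] <- "Y"                  # support block stays tyrosine-free
    }
    aa[len] <- "Y"
  }
  paste(aa, collapse = "")
}

# synonymous codons per amino acid, excluding stops, TGG (tryptophan never
# appears in junctions) and GGG (a GGG codon could complete a spurious
# TGGGG J-anchor motif inside the junction)
JUNCTION_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[!names(gc) %in% c("TGG", "GGG", "TAA", "TAG", "TGA")]
  split(names(gc), unname(gc))
})

# clone-specific junction nucleotide encoding: random synonymous codon per
# residue, emulating junctional (N/P and D-segment) nucleotide diversity
# between independent rearrangements that happen to share CDR3 amino acids
.encode_junction <- function(aa) {
  paste(vapply(strsplit(aa, "")[[1]], function(a) {
    cods <- JUNCTION_CODONS[[a]]
    cods[sample.int(length(cods), 1L)]
  }, ""), collapse = "")
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: clones descend from a
#' single germline rearrangement; per-sequence mutation loads are
#' Poisson-like with a configurable target mean (the pre-boost regime centres
#' on 5 mutations per V region, the post-boost regime on 10); high-affinity
#' events (CDR1 W33L at nucleotide 98, with a minority share of CDR3 Y->G)
#' are injected per sequence; position 102 is counter-selected in NP binders
#' and, under `np_select`, can only mutate together with or after position
#' 98; clone sizes are skewed; and a clone-level mixing probability controls
#' how often clones span the two compartments of the axis under study.
#'
#' @param seed RNG seed (mandatory for reproducibility).
#' @param n_mice number of mice.
#' @param clones_per_mouse clones generated per mouse.
#' @param clone_size_dist one of `list(dist = "geometric", p = )`,
#'   `list(dist = "zipf", s = , max = )` or `list(dist = "fixed", k = )`.
#' @param target_mut_mean desired mean V-region mutations per sequence.
#' @param trunk_mut_mean Poisson mean of the germline-to-founder (trunk)
#'   edge; larger values model clones that expanded after a long shared
#'   maturation phase.
#' @param branch_mut_mean Poisson mean per genealogy edge; `NULL` (default)
#'   calibrates it per clone from the realized genealogy depths so the
#'   per-sequence mean hits `target_mut_mean` in expectation.
#' @param hotspot named numeric vector of per-position weight multipliers
#'   over a uniform base profile (names are 1-based V positions).
#' @param selection_mode `"none"`, `"np_select"` (enrich W33L via private
#'   per-sequence injection; forbid 102 before 98 in NP clones; elevate 102
#'   in non-NP clones) or `"counter_select_102"` (elevate 102 everywhere,
#'   no injection).
#' @param p_haff per-sequence probability of a high-affinity event in NP
#'   clones under `np_select`.
#' @param w33l_share fraction of high-affinity events realised as W33L (the
#'   rest are CDR3 Y->G).
#' @param p102_after_98 probability that a W33L sequence co-mutates position
#'   102 on the same (terminal) edge.
#' @param mixing probability that a clone spans both axis labels.
#' @param np_fraction fraction of clones given rule-satisfying CDR3s.
#' @param subsets length-2 character vector: the two subset labels of the
#'   mixing axis.
#' @param compartment_probs named list mapping each subset to a named
#'   probability vector over compartments.
#' @param isotype_probs named probability vector over isotypes.
#' @param error_rate uniform per-base substitution sequencing-error rate
#'   applied to emitted reads (recorded separately in the truth; default 0).
#' @param max_junction_identity cap on the junction nucleotide identity
#'   between distinct clones of the same mouse and CDR3 length (junctions
#'   are redrawn until they respect it); independent rearrangements do not
#'   share junctions, and this keeps truth clones separable by any
#'   clustering threshold above the cap.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_mice = 3L, clones_per_mouse = 8L,
                              clone_size_dist = list(dist = "geometric",
                                                     p = 0.25),
                              target_mut_mean = 5,
                              trunk_mut_mean = 1,
                              branch_mut_mean = NULL,
                              hotspot = NULL,
                              selection_mode = c("np_select", "none",
                                                 "counter_select_102"),
                              p_haff = 0.5,
                              w33l_share = 0.85,
                              p102_after_98 = 0.55,
                              mixing = 0.1,
                              np_fraction = 0.8,
                              subsets = c("MEMORY", "LONGLIVED_PC"),
                              compartment_probs = NULL,
                              isotype_probs = c(IgA = 0.9, IgM = 0.1),
                              error_rate = 0,
                              max_junction_identity = 0.7) {
  selection_mode <- match.arg(selection_mode)
  stopifnot(p_haff >= 0, p_haff <= 1, mixing >= 0, mixing <= 1,
            np_fraction >= 0, np_fraction <= 1, w33l_share >= 0,
            w33l_share <= 1, error_rate >= 0, error_rate < 1,
            length(subsets) == 2L, target_mut_mean >= 0,
            trunk_mut_mean >= 0)
  check_enum(subsets, SUBSETS, "subset")
  if (is.null(compartment_probs)) {
    compartment_probs <- stats::setNames(list(c(PP = 0.7, MLN = 0.3),
                                              c(SI_LP = 0.7, BM = 0.3)),
                                         subsets)
  }
  structure(list(seed = as.integer(seed), n_mice = as.integer(n_mice),
                 clones_per_mouse = as.integer(clones_per_mouse),
                 clone_size_dist = clone_size_dist,
                 target_mut_mean = target_mut_mean,
                 trunk_mut_mean = trunk_mut_mean,
                 branch_mut_mean = branch_mut_mean,
                 hotspot = hotspot, selection_mode = selection_mode,
                 p_haff = p_haff, w33l_share = w33l_share,
                 p102_after_98 = p102_after_98, mixing = mixing,
                 np_fraction = np_fraction, subsets = subsets,
                 compartment_probs = compartment_probs,
                 isotype_probs = isotype_probs, error_rate = error_rate,
                 max_junction_identity = max_junction_identity),
            class = "simulation_config")
}

#' Study-scale simulation presets
#'
#' Presets sized like a low-throughput (cloned-transcript Sanger) study:
#' 6 mice, 24 clones per mouse with geometric(0.25) size skew (roughly 50
#' sequences per subset per mouse, tens of clones per group). The `long`
#' regime models resting memory B cells vs long-lived plasma cells one year
#' after oral priming: mean 5 V-region mutations, ~50% of sequences carrying
#' a high-affinity mutation, short trunks, low clone mixing. The `boost`
#' regime models responding memory B cells vs post-boost plasma cells: mean
#' 10 mutations, ~75% high-affinity, an extended shared-trunk phase and high
#' mixing.
#'
#' @param regime `"long"` or `"boost"`.
#' @param seed RNG seed.
#' @return a `simulation_config`.
#' @export
study_scale_preset <- function(regime = c("long", "boost"), seed = 1L) {
  regime <- match.arg(regime)
  if (regime == "long") {
    simulation_config(seed = seed, n_mice = 6L, clones_per_mouse = 24L,
                      target_mut_mean = 5, trunk_mut_mean = 1,
                      p_haff = 0.5, p102_after_98 = 0.55, mixing = 0.05,
                      subsets = c("MEMORY", "LONGLIVED_PC"))
  } else {
    simulation_config(seed = seed, n_mice = 6L, clones_per_mouse = 24L,
                      target_mut_mean = 10, trunk_mut_mean = 5,
                      p_haff = 0.75, p102_after_98 = 0.3, mixing = 0.6,
                      subsets = c("RESPONDING_MEM", "BOOST_PC"))
  }
}

.draw_clone_size <- function(d) {
  switch(d$dist,
         geometric = 1L + stats::rgeom(1L, d$p),
         fixed = as.integer(d$k),
         zipf = {
           probs <- (seq_len(d$max %||% 50L))^(-d$s)
           sample.int(d$max %||% 50L, 1L, prob = probs)
         },
         stop(sprintf("unknown clone size distribution '%s'", d$dist),
              call. = FALSE))
}

# positional weight profile for SHM draws (uniform base x hotspot multipliers)
.position_weights <- function(glen, hotspot) {
  w <- rep(1, glen)
  if (!is.null(hotspot)) w[as.integer(names(hotspot))] <- hotspot
  w
}

#' Simulate a germinal-centre repertoire with complete ground truth
#'
#' For each clone: a Yule-type random genealogy is grown (each new cell picks
#' a uniformly random existing cell as parent), Poisson mutation loads are
#' drawn per edge at positions sampled from the hotspot-weighted profile
#' (without replacement within an edge), selection constraints are applied,
#' a CDR3 junction is appended (rule-satisfying iff the clone is NP-labelled)
#' and cells are assigned to compartments according to the clone-level mixing
#' probability. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @param dir optional output directory; when given, `reads.fasta`,
#'   `manifest.tsv`, `truth.json` and the germline reference files are
#'   written there.
#' @param ref germline reference (default the bundled synthetic V_H_186.2).
#' @return list with `db` (a repertoire data.frame as returned by
#'   [read_fasta()]) and `truth` (per-sequence/per-clone truth tables, all
#'   mutation events, genealogies and realized summary statistics).
#' @export
simulate_repertoire <- function(cfg, dir = NULL,
                                ref = synthetic_vh186_germline()) {
  glen <- nchar(ref$nt_seq)
  germ <- strsplit(ref$nt_seq, "")[[1]]
  base_w <- .position_weights(glen, cfg$hotspot)
  bases <- c("A", "C", "G", "T")

  # expected count of private (per-sequence) V-region injections, used when
  # calibrating the per-branch rate to the target mean
  e_priv_np <- if (cfg$selection_mode == "np_select") {
    cfg$p_haff * cfg$w33l_share * (1 + cfg$p102_after_98)
  } else 0

  res <- with_seed(cfg$seed, {
    seq_rows <- list()
    clone_rows <- list()
    event_rows <- list()
    genealogies <- list()
    reads <- character(0)
    seq_counter <- 0L

    for (mi in seq_len(cfg$n_mice)) {
      mouse <- sprintf("m%d", mi)
      mouse_junctions <- list()   # per CDR3 length, for the identity cap
      for (ci in seq_len(cfg$clones_per_mouse)) {
        clone_id_true <- sprintf("%s_t%03d", mouse, ci)
        k <- .draw_clone_size(cfg$clone_size_dist)
        np <- stats::runif(1) < cfg$np_fraction

        # genealogy topology: random recursive (Yule-type) tree
        parent <- c(0L, if (k > 1L)
          vapply(2:k, function(i) sample.int(i - 1L, 1L), 0L))
        depth <- integer(k)
        for (i in seq_len(k)[-1]) depth[i] <- depth[parent[i]] + 1L

        # per-clone rate calibration
        e_priv <- if (np) e_priv_np else 0
        trunk_lambda <- cfg$trunk_mut_mean
        if (k == 1L) {
          trunk_lambda <- max(0, cfg$target_mut_mean - e_priv)
        }
        branch_lambda <- if (!is.null(cfg$branch_mut_mean)) {
          cfg$branch_mut_mean
        } else if (mean(depth) > 0) {
          max(0, (cfg$target_mut_mean - trunk_lambda - e_priv) / mean(depth))
        } else 0

        # positional weights under the clone's selection regime
        w <- base_w
        if (cfg$selection_mode == "np_select") {
          w[98L] <- 0                    # reserved for private injection
          if (np) {
            # NP binding depends on an intact codon 33: destructive W33
            # replacements are purged by selection, and 102 never mutates
            # before 98 (it can only ride along with a W33L event)
            w[c(97L, 99L, 102L)] <- 0
          } else {
            # counter-selected in NP binders only: non-NP sequences mutate
            # 102 at the elevated background rate (roughly 4 in 10 sequences
            # at a mean load of five mutations)
            w[102L] <- base_w[102L] * 35
          }
        } else if (cfg$selection_mode == "counter_select_102") {
          w[102L] <- base_w[102L] * 35
        }

        # junction: clone-level CDR3 template instance, fixed codon encoding
        for (try in 1:100) {
          cdr3_aa_clone <- .random_cdr3(np)
          junction_nt <- .encode_junction(cdr3_aa_clone)
          prev <- mouse_junctions[[as.character(nchar(junction_nt))]]
          ok <- TRUE
          for (pj in prev) {
            id <- mean(strsplit(junction_nt, "")[[1]] ==
                         strsplit(pj, "")[[1]])
            if (id > cfg$max_junction_identity) {
              ok <- FALSE
              break
            }
          }
          if (ok) break
        }
        jlen <- as.character(nchar(junction_nt))
        mouse_junctions[[jlen]] <- c(mouse_junctions[[jlen]], junction_nt)

        # draw edge mutations; genomes accumulate along the genealogy
        genome <- matrix(rep(germ, k), nrow = k, byrow = TRUE)
        for (i in seq_len(k)) {
          lam <- if (i == 1L) trunk_lambda else branch_lambda
          cur <- if (i == 1L) germ else genome[parent[i], ]
          m <- stats::rpois(1L, lam)
          m <- min(m, sum(w > 0))
          pos <- if (m > 0L) sample.int(glen, m, prob = w) else integer(0)
          for (p in pos) {
            from <- cur[p]
            to <- sample(setdiff(bases, from), 1L)
            cur[p] <- to
            event_rows[[length(event_rows) + 1L]] <- data.frame(
              mouse_id = mouse, clone = clone_id_true, node = i,
              layer = "V", pos = p, from = from, to = to,
              stringsAsFactors = FALSE)
          }
          genome[i, ] <- cur
        }

        # private per-sequence events (not inherited): W33L / 102 / CDR3 Y->G
        priv_w33l <- rep(FALSE, k)
        priv_102 <- rep(FALSE, k)
        priv_yg <- rep(FALSE, k)
        if (np && cfg$selection_mode == "np_select") {
          hit <- stats::runif(k) < cfg$p_haff
          kind_w <- stats::runif(k) < cfg$w33l_share
          priv_w33l <- hit & kind_w
          priv_yg <- hit & !kind_w
          priv_102 <- priv_w33l & (stats::runif(k) < cfg$p102_after_98)
        }

        emitted <- character(k)
        cdr3_nt_emitted <- character(k)
        cdr3_aa_emitted <- character(k)
        for (i in seq_len(k)) {
          v <- genome[i, ]
          if (priv_w33l[i]) {
            event_rows[[length(event_rows) + 1L]] <- data.frame(
              mouse_id = mouse, clone = clone_id_true, node = i,
              layer = "V_private", pos = 98L, from = v[98L], to = "T",
              stringsAsFactors = FALSE)
            v[98L] <- "T"
          }
          if (priv_102[i]) {
            from <- v[102L]
            to <- sample(setdiff(bases, from), 1L)
            event_rows[[length(event_rows) + 1L]] <- data.frame(
              mouse_id = mouse, clone = clone_id_true, node = i,
              layer = "V_private", pos = 102L, from = from, to = to,
              stringsAsFactors = FALSE)
            v[102L] <- to
          }
          jaa <- cdr3_aa_clone
          jnt <- junction_nt
          if (priv_yg[i]) {
            # mutate the designated terminal tyrosine codon to glycine
            ypos <- nchar(jaa)
            substr(jaa, ypos, ypos) <- "G"
            gcodon <- CODON_OF[["G"]]
            substr(jnt, 3L * ypos - 2L, 3L * ypos) <- gcodon
            event_rows[[length(event_rows) + 1L]] <- data.frame(
              mouse_id = mouse, clone = clone_id_true, node = i,
              layer = "junction", pos = ypos, from = "Y", to = "G",
              stringsAsFactors = FALSE)
          }
          emitted[i] <- paste0(paste(v, collapse = ""), jnt, J_SEGMENT)
          cdr3_nt_emitted[i] <- jnt
          cdr3_aa_emitted[i] <- jaa
        }

        # sequencing errors (uniform substitutions on the emitted read)
        if (cfg$error_rate > 0) {
          for (i in seq_len(k)) {
            ch <- strsplit(emitted[i], "")[[1]]
            err <- which(stats::runif(length(ch)) < cfg$error_rate)
            for (p in err) {
              from <- ch[p]
              to <- sample(setdiff(bases, from), 1L)
              ch[p] <- to
              event_rows[[length(event_rows) + 1L]] <- data.frame(
                mouse_id = mouse, clone = clone_id_true, node = i,
                layer = "seq_error", pos = p, from = from, to = to,
                stringsAsFactors = FALSE)
            }
            emitted[i] <- paste(ch, collapse = "")
          }
        }

        # compartment assignment: clone-level mixing, binomial member split
        mixed <- k >= 2L && stats::runif(1) < cfg$mixing
        if (mixed) {
          side <- stats::rbinom(k, 1L, 0.5)
          if (all(side == 0L)) side[sample.int(k, 1L)] <- 1L
          if (all(side == 1L)) side[sample.int(k, 1L)] <- 0L
        } else {
          side <- rep((ci - 1L) %% 2L, k)  # alternate clones across subsets
        }
        subset <- cfg$subsets[side + 1L]
        compartment <- vapply(subset, function(su) {
          pr <- cfg$compartment_probs[[su]]
          sample(names(pr), 1L, prob = pr)
        }, "")
        isotype <- sample(names(cfg$isotype_probs), k, replace = TRUE,
                          prob = cfg$isotype_probs)

        seq_ids <- sprintf("%s_s%05d", mouse, seq_counter + seq_len(k))
        seq_counter <- seq_counter + k
        n_mut_true <- vapply(seq_len(k), function(i) {
          v <- substr(emitted[i], 1L, glen)
          sum(strsplit(v, "")[[1]] != germ)
        }, 0L)
        seq_rows[[length(seq_rows) + 1L]] <- data.frame(
          seq_id = seq_ids, mouse_id = mouse, clone = clone_id_true,
          node = seq_len(k), parent_node = parent, depth = depth,
          subset = unname(subset), compartment = unname(compartment),
          isotype = isotype, np_label = np,
          n_mut_true = n_mut_true,
          has_w33l_true = priv_w33l, has_102_true = vapply(
            seq_len(k), function(i)
              substr(emitted[i], 102L, 102L) != germ[102L], NA),
          has_yg_true = priv_yg,
          cdr3_aa_true = cdr3_aa_emitted, cdr3_nt_true = cdr3_nt_emitted,
          stringsAsFactors = FALSE)
        clone_rows[[length(clone_rows) + 1L]] <- data.frame(
          clone = clone_id_true, mouse_id = mouse, size = k,
          np_label = np, mixed_true = mixed,
          junction_nt = junction_nt, cdr3_aa = cdr3_aa_clone,
          n_subsets = length(unique(subset)),
          stringsAsFactors = FALSE)
        genealogies[[clone_id_true]] <- parent
        reads <- c(reads, stats::setNames(emitted, seq_ids))
      }
    }

    seqs <- do.call(rbind, seq_rows)
    list(seqs = seqs,
         clones = do.call(rbind, clone_rows),
         events = if (length(event_rows) > 0L) do.call(rbind, event_rows)
         else data.frame(mouse_id = character(0), clone = character(0),
                         node = integer(0), layer = character(0),
                         pos = integer(0), from = character(0),
                         to = character(0)),
         genealogies = genealogies, reads = reads)
  })

  db <- data.frame(seq_id = res$seqs$seq_id,
                   nt_seq = unname(res$reads[res$seqs$seq_id]),
                   mouse_id = res$seqs$mouse_id,
                   compartment = res$seqs$compartment,
                   subset = res$seqs$subset,
                   isotype = res$seqs$isotype,
                   stringsAsFactors = FALSE)
  truth <- list(config = cfg,
                sequences = res$seqs,
                clones = res$clones,
                events = res$events,
                genealogies = res$genealogies,
                germline = ref,
                realized = list(
                  mean_mut = mean(res$seqs$n_mut_true),
                  frac_haff = mean(res$seqs$has_w33l_true |
                                     res$seqs$has_yg_true),
                  n_sequences = nrow(res$seqs)))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(db, file.path(dir, "reads.fasta"),
                file.path(dir, "manifest.tsv"))
    write_germline(ref, file.path(dir, "germline.fasta"),
                   file.path(dir, "germline_regions.json"))
    tr <- truth
    tr$germline <- list(name = ref$name)
    tr$config <- unclass(cfg)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(db = db, truth = truth)
}

#' Replay truth events to reconstruct every emitted read
#'
#' Applies the recorded genealogy edge events, private events, junction
#' events and sequencing errors to the germline and returns the rebuilt
#' reads; byte-for-byte equality with the emitted FASTA is the generator's
#' core integrity property.
#'
#' @param truth the `truth` element of [simulate_repertoire()] output.
#' @return named character vector of rebuilt reads (by `seq_id`).
#' @export
replay_truth <- function(truth) {
  ref <- truth$germline
  germ <- strsplit(ref$nt_seq, "")[[1]]
  out <- character(nrow(truth$sequences))
  names(out) <- truth$sequences$seq_id
  ev <- truth$events
  for (r in seq_len(nrow(truth$sequences))) {
    row <- truth$sequences[r, ]
    parent <- truth$genealogies[[row$clone]]
    # genealogy path from founder to this node
    path <- integer(0)
    node <- row$node
    while (node != 0L) {
      path <- c(node, path)
      node <- parent[node]
    }
    v <- germ
    for (nd in path) {
      e <- ev[ev$clone == row$clone & ev$node == nd & ev$layer == "V", ,
              drop = FALSE]
      if (nrow(e) > 0L) v[e$pos] <- e$to
    }
    e <- ev[ev$clone == row$clone & ev$node == row$node &
              ev$layer == "V_private", , drop = FALSE]
    if (nrow(e) > 0L) v[e$pos] <- e$to
    clone_row <- truth$clones[truth$clones$clone == row$clone, ]
    jnt <- clone_row$junction_nt
    e <- ev[ev$clone == row$clone & ev$node == row$node &
              ev$layer == "junction", , drop = FALSE]
    if (nrow(e) > 0L) {
      for (i in seq_len(nrow(e))) {
        substr(jnt, 3L * e$pos[i] - 2L, 3L * e$pos[i]) <- CODON_OF[[e$to[i]]]
      }
    }
    read <- paste0(paste(v, collapse = ""), jnt, J_SEGMENT)
    e <- ev[ev$clone == row$clone & ev$node == row$node &
              ev$layer == "seq_error", , drop = FALSE]
    if (nrow(e) > 0L) {
      ch <- strsplit(read, "")[[1]]
      ch[e$pos] <- e$to
      read <- paste(ch, collapse = "")
    }
    out[row$seq_id] <- read
  }
  out
}
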