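---
title: "Methods: germline-anchored clonal relatedness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline-anchored clonal relatedness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

clonmix asks a single biological question of a heavy-chain amplicon
repertoire: how clonally related are two B-cell compartments — typically gut
memory B cells and long-lived IgA plasma cells — when every analysed sequence
is a rearrangement of one V gene, V_H_186.2, the segment that dominates the
anti-NP response of C57BL/6 mice? This vignette documents the model behind
each stage, the parameters that matter, and the choices made where the design
was genuinely open.

## Coordinate model and the germline reference

All coordinates are 1-based nucleotide positions on the germline V region.
The reference carries a region map (FR1, CDR1, FR2, CDR2, FR3) and a reading
frame; codon *k* spans nucleotides 3k−2 … 3k after the frame offset. The
convention is anchored at codon 33: it must read TGG (tryptophan), so that a
G→T substitution at nucleotide 98 — the middle base of codon 33 — produces
the canonical affinity-enhancing W33→L replacement. Nucleotide 102, three
positions downstream, is the counter-selected site: commonly mutated in
non-NP-binding sequences but disfavoured in NP binders. Reading 98 and 102 as
nucleotide positions is the only interpretation under which "CDR1 W33→L" and
"position 98" describe the same event, and `load_germline()` enforces the
codon-33 invariant at load time.

The bundled reference (`inst/extdata/vh186_synthetic.*`) is a **synthetic**
V_H_186.2-like gene built by `synthetic_vh186_germline()`: 98 codons laid out
as FR1 (nt 1–75), CDR1 (76–99), FR2 (100–150), CDR2 (151–174), FR3 (175–294),
ending in the conserved FR3 cysteine that anchors the CDR3. It reproduces the
layout and the coordinate conventions of the real allele, not its exact
sequence; any analysis of real data should substitute a database allele via
`load_germline()`. All packaged analyses are synthetic-to-synthetic, so no
conclusion depends on the stand-in's residues.

## Alignment and mutation calling

Reads are aligned with `Biostrings::pairwiseAlignment` under match +1,
mismatch −2, gap open −4, gap extend −1. The germline side is anchored
(global on the reference, free on the read) rather than plain ends-free:
under ends-free scoring a terminal V-region mismatch is worth −2 and is
silently clipped, which would systematically lose mutations in the last
codons; anchoring the reference forces those columns to be scored. Reads
shorter than 80% of the V region are rejected up front (`too_short`); reads
whose whole-germline identity (uncovered positions counted as mismatches,
i.e. a forced gapless comparison) falls below 70% are flagged `not_vh186`
and excluded downstream — at ten mutations a genuine read still shows ≈97%
identity, so the floor only removes off-target amplicons. Both floors are
configurable in `annotate_config()`.

Mutations are substitutions relative to the germline, reported with region,
codon and amino-acid change; the replacement amino acid reflects the read's
whole codon, so co-mutated codons report what is actually encoded. Positions
opposite N bases are skipped and tallied; codons touched by indels are
excluded from amino-acid inference and tallied separately. `n_mutations`
counts V-region (FR1–FR3) substitutions only: the CDR3 junction is templated
by the rearrangement, not the germline V, so junction differences are not
germline mutations. The calling is involutive — applying the called mutation
set to the germline reconstructs the aligned read — and that property is
tested on every simulated repertoire.

## CDR3 extraction and the NP-binding rule

The CDR3 is translated from the conserved FR3 cysteine (exclusive) to the
J-region tryptophan (exclusive). The cysteine is located through the
alignment — it is by construction the last germline V codon — because a motif
search for it would be confused by somatic mutation of nearby codons; the J
tryptophan is found by motif search (default `TGGGG`, configurable). A
sequence is NP-binding when its CDR3 is 9–11 amino acids long, the anchor
tyrosine is present, and at least two of the following three residues are
tyrosines. The anchor ("position 99" in antibody numbering) is a configurable
offset into the CDR3 string, defaulting to the third residue to match the
canonical B1-8 junction layout; the numbering scheme behind the rule is not
fixed by any published convention we could adopt, which is why the offset is
exposed and the classifier is tested under alternative offsets. CDR3s with
stop codons are nonproductive and classified negative.

"High-affinity" means W33L **or** a CDR3 Y→G replacement; both components are
also reported separately. Y→G has no germline template, so it is called
against the clone's inferred ancestral junction: the per-position majority
amino acid over the clone's *other* members (leave-one-out, ties resolved
toward tyrosine, the ancestral residue of the canonical junction). A
singleton clone carries no information about its ancestral junction, so its
Y→G status is `NA`; because sequence-weighted singleton mass is small in
skewed clone-size distributions, this biases the high-affinity fraction by
well under one percentage point.

## Clonal grouping and the mixed-clone bootstrap

Clones are built within a mouse by single-linkage clustering of sequences
sharing CDR3 amino-acid length, linking pairs at ≥90% junction nucleotide
identity (threshold configurable; 1.0 reproduces the strict
shared-rearrangement definition). There is no single canonical junction
threshold for clone definition in NGS repertoires, so 0.90 is a
reconstruction of common AIRR practice, and conclusions that depend on it
should be read with that caveat. Sequences without an extractable CDR3 go to
an explicit unassigned pool.

A clone is *mixed* when it contains members of both labels of a chosen axis
(default: memory vs long-lived plasma-cell subsets). The significance of an
observed mixed-clone count is assessed against a random-partition null: each
run re-partitions every mouse's cells into the observed number of clones and
counts mixed clones; over 10,000 runs the observed count is compared with the
null mean by a two-sided z-test (normal approximation), with the empirical
tail fraction reported alongside. The null's partition law is not uniquely
determined by its verbal description, so both readings are implemented:
`PRESERVE_SIZES` permutes cell labels over the empirical clone-size multiset
(a permutation test conditioned on the observed size spectrum — the default,
being the more conservative and conventional choice), and
`UNIFORM_PARTITION` draws a uniformly random surjective assignment of cells
to clones each run, sampled exactly via zero-truncated-Poisson occupancy
conditioned on the total. Degenerate nulls (zero variance, e.g. a single
clone) are flagged rather than tested. The PRESERVE_SIZES mean is checked
against exhaustive enumeration on all instances small enough to enumerate,
and the z-test's type-I error is verified to sit at 5% ± 2% under its own
null; the normal approximation deteriorates for very few clones, which the
degeneracy flag and empirical tail are there to expose.

## Lineage trees

Trees are rooted at the germline; nodes are observed sequences (deduplicated,
with multiplicities) plus inferred intermediates; every edge extends its
parent's mutation set, so edge lengths are Hamming distances and the path sum
from the root to any node equals that node's mutation distance from germline.
Within that family the builder minimises total edge mutations. Because the
cost of a node decomposes as its set size minus its parent's, the optimum
over which shared-mutation intersections to materialise as ancestors can be
found exactly by enumerating subsets of the intersection closure; `build_tree`
does that whenever the closure is small (≤12 candidates, covering the clone
sizes this analysis meets) and otherwise falls back to a documented greedy
agglomeration that repeatedly makes the cheapest attachment, splitting an
existing edge when an intersection pays for itself. A pure greedy was
measured to miss the optimum on a few percent of random small genealogies,
which is why small instances are solved exactly; the exhaustive oracle in the
test suite certifies equality on random clones with ≤5 distinct sequences
and ≤6 mutated positions. Parallel mutations on sibling branches are paid for
twice rather than explained by homoplasy — a known limitation shared with
simple parsimony reconstructions. Members whose alignment contains indels
attach by flagged edges excluded from statistics.

Shape statistics: `pl_min`/`pl_max`/`pl_mean` are root-to-leaf path lengths
in mutations; `trunk_length` is the path to the first node with out-degree
≥2. The reference definition of the trunk for unbranched trees is not
available to us, so a chain reports its full path length with
`unbranched = TRUE`, letting analyses exclude chains explicitly — the packaged regime
comparisons do exclude them, because a chain's "trunk" is its whole path
length and belongs to the path-length distribution, not the trunk one. Mutation
ordering queries (does position 102 ever mutate before 98?) walk every
root-to-leaf path and classify first-mutation order, with same-edge
co-mutation counted as a tie; the "never precedes" verdict requires zero
preceding paths and at least one co-mutated path.

## The synthetic repertoire generator

The generator is the package's test bed: it emits repertoires with the
statistical structure the analysis assumes, plus a complete truth table
(clone assignments, genealogies, every mutation event, junction events,
sequencing errors) from which every emitted read can be replayed
byte-for-byte.

Per clone: a Yule-type random genealogy (each new cell attaches to a
uniformly chosen existing cell) of geometric(0.25)-distributed size; Poisson
mutation loads per edge at positions drawn from a hotspot-weighted profile
without within-edge replacement; a clone-level CDR3 built to satisfy or
violate the NP rule exactly, encoded with clone-specific synonymous codons
(emulating junctional nucleotide diversity) and capped at 70% nucleotide
identity to any same-length junction of the same mouse, since independent
rearrangements do not share junctions; and clone-level compartment mixing —
a clone spans both axis labels with probability π, its members then split
binomially. A Yule genealogy rather than an explicit dark/light-zone
germinal-centre model is sufficient to produce the tree-shape and
mutation-load structure the analysis consumes, and no more.

Two calibrations deserve explanation. First, the per-branch Poisson rate is
set per clone from the realized genealogy depths so that the per-sequence
mutation mean hits the regime target in expectation, with a separate trunk
(germline→founder) rate modelling the shared maturation phase. Mutation-count
dispersion is Poisson-like by assumption — group means are known but
dispersions are not, so Poisson is the minimal choice, stated here because
nothing in the data constrains it. Second, high-affinity events are injected
per emitted cell as *private* terminal events (not inherited by genealogy
descendants): W33L with 85% share, CDR3 Y→G otherwise. This makes the
realized high-affinity fraction an independent Bernoulli per sequence, which
is what lets the preset fractions be recovered tightly; the cost is that
W33L never defines a subclone, a simplification relative to real germinal
centres where selection amplifies W33L lineages. In NP clones the codon-33
neighbourhood (nt 97–99) and position 102 are excluded from background
mutation — destructive W33 replacements are purged by selection, and 102 can
only ride along with a W33L event (probability 0.55 in the long regime,
giving ≈27.5% of NP sequences 102-mutated) — so "102 never mutates before
98" holds in the truth genealogies by construction. Non-NP clones instead
mutate 102 at a ×35-weighted rate, landing near 42% of sequences at a mean
load of five.

The presets encode the two immunization regimes at low-throughput
(cloned-transcript) sequencing scale — 6 mice, 24 clones per mouse, roughly
50 sequences per subset per mouse: `long` (target mean 5 mutations, trunk mean 1,
high-affinity probability 0.5, mixing 0.05) and `boost` (mean 10, trunk 5,
0.75, mixing 0.6). What the generator does **not** emulate: indel
hypermutation, Ion Torrent homopolymer errors (only a uniform substitution
error is available), affinity-dependent fitness, and cross-mouse public
clones. Tests passing on synthetic data therefore certify the pipeline's
bookkeeping and statistics, not the biology of any particular real dataset.

## Problem sizes and numerical choices

The shipped analyses and tests run at fixed sizes chosen to exercise the
statistics meaningfully: annotation exactness and classifier recovery on
1,000 sequences; clone recovery on 3 mice × 15 clones; the parsimony oracle
on 200 random clones of ≤5 distinct sequences over 6 positions; bootstrap
calibration on 1,000 replicates of a 3-group, 60-cell, 20-clone layout with
400-run nulls; power and tree-shape discrimination on 100 replicates each at
3-mouse scale with 1,000-run nulls. Headline analyses use 10,000 bootstrap
runs. Ties in clone ids, attachment order and consensus calls are broken
lexicographically so that every pipeline stage is bit-reproducible from its
seed; the bootstrap restores the caller's RNG state.

## Known limitations

The clone-definition threshold and the trunk convention are reconstructions
(see above). The z-test inherits the normal approximation; for very small
clone counts the empirical tail fraction is the safer number. The parsimony
builder ignores homoplasy beyond shared-intersection ancestors. Y→G calls
are undefined for singleton clones. The bundled germline is a synthetic
stand-in, adequate for coordinate-anchored synthetic analyses but not a
substitute for a database allele on real reads.
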