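# clonmix

Clonal-relatedness analysis of immunoglobulin heavy-chain repertoires from
gut B-cell compartments.

## The scientific problem

After oral immunization with a hapten–carrier antigen, mice maintain both
long-lived IgA plasma cells (in the small-intestinal lamina propria and bone
marrow) and memory B cells (in Peyer's patches, mesenteric lymph nodes and
spleen). Whether these two compartments descend from the same germinal-centre
clones is a central question for mucosal vaccine design. Because the anti-NP
(4-hydroxy-3-nitrophenyl)acetyl response of C57BL/6 mice is dominated by a
single heavy-chain V gene, V_H_186.2, every sequenced transcript can be
anchored to one germline and the question becomes quantitative:

- **Mutation profiling.** Somatic hypermutations are called against the
  V_H_186.2 germline in 1-based nucleotide coordinates. Codon 33 (nt 97–99,
  TGG) anchors the conventions: the affinity-enhancing mutation is G→T at
  nt 98 (W33→L); nt 102 is the counter-selected neighbour. "High-affinity"
  sequences carry W33L or a CDR3 Y→G replacement.
- **NP-binding classification.** A sequence is NP-binding when its CDR3 is
  9–11 amino acids long with a tyrosine at the anchor position and at least
  two more tyrosines in the following three residues.
- **Clones and mixed clones.** Sequences of one mouse sharing CDR3 length
  are single-linkage clustered at ≥90% junction nucleotide identity. A
  *mixed clone* contains members of both compartments under study — the unit
  of the relatedness analysis.
- **Bootstrap null.** The observed mixed-clone count is compared with a
  random-partition null: each of 10,000 runs re-partitions each mouse's
  cells into the observed number of clones (preserving the clone-size
  multiset by default) and counts mixed clones; a two-sided z-test
  `z = (observed − null mean) / null sd` gives the verdict
  (`FEWER_MIXED_THAN_NULL` / `MORE_MIXED_THAN_NULL` / consistent).
- **Lineage trees.** Per-clone germline-rooted parsimony trees with inferred
  intermediates; edge lengths are mutation counts. Shape statistics include
  PL_min (minimum root-to-leaf path length) and trunk length (mutations to
  the first branching node), plus mutation-ordering queries such as "does
  nt 102 ever mutate before nt 98?".
- **Synthetic repertoires.** A germinal-centre simulator (Yule genealogies,
  hotspot-weighted Poisson hypermutation, rule-exact CDR3s, clone-level
  compartment mixing π) emits FASTA + metadata + complete ground truth, so
  every stage is validated end to end without external data.

The bundled germline is a **synthetic** V_H_186.2-like reference (layout and
coordinate conventions of the real allele, not its sequence); real data
require a database allele via `load_germline()`.

## Worked example

```r
library(clonmix)

ref <- vh186_reference()
sim <- simulate_repertoire(study_scale_preset("long", seed = 1))
db  <- annotate_repertoire(sim$db, ref)
db  <- group_clones(db, threshold = 0.90)
db  <- flag_high_affinity(db)

mutation_summary(db, group_by = "subset")[, 1:5]
#>         subset   n mean_mut median_mut frac_high_affinity
#> 1 LONGLIVED_PC 236 5.186441          5          0.3559322
#> 2       MEMORY 311 4.826367          5          0.4276527

npb <- !is.na(db$np_binding) & db$np_binding
mean(db$high_affinity[npb])
#> [1] 0.4943052

boot <- bootstrap_from_clones(db, "subset", "MEMORY", "LONGLIVED_PC",
                              n_runs = 10000, seed = 17)
boot
#> bootstrap_result (PRESERVE_SIZES, 10000 runs, seed 17)
#>   observed mixed clones: 7
#>   null: mean 82.340, sd 3.613
#>   z = -20.853, two-sided p = 1.43e-96 (empirical 0)
relatedness_verdict(boot)
#> [1] "FEWER_MIXED_THAN_NULL"
```

The summary shows the pre-boost regime: about five V-region mutations per
sequence, and 49% of NP-binding sequences carry a high-affinity mutation
(the per-subset fractions are lower because they average over non-NP
sequences, which never acquire W33L). The bootstrap compares the 7 observed
memory/plasma-cell mixed clones with the ~82 expected under random
assignment of the same cells to the same clone structure: far fewer mixed
clones than chance, i.e. the two compartments are poorly clonally related
in this regime.

The `analysis/` directory holds the numbered drivers that reproduce the full
workflow on synthetic data (simulate → annotate → clonality/bootstrap →
lineage trees); each writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_annotate.R
Rscript analysis/03_clonality.R
Rscript analysis/04_lineage.R
```

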