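#!/usr/bin/env Rscript
# Stage 1: generate the two study-scale synthetic repertoires.
#
# The `long` regime emulates resting memory B cells vs long-lived plasma
# cells one year after oral priming (mean 5 V-region mutations, ~50%
# high-affinity, low clone mixing); the `boost` regime emulates responding
# memory B cells vs post-boost plasma cells (mean 10 mutations, ~75%
# high-affinity, extended trunks, high mixing). Both are written with full
# ground truth under results/data/.

suppressPackageStartupMessages(library(clonmix))
seed <- 20251001L

for (regime in c("long", "boost")) {
  dir <- file.path("results", "data", regime)
  sim <- simulate_repertoire(study_scale_preset(regime, seed = seed), dir = dir)
  tr <- sim$truth
  message(sprintf(
    "[%s] %d sequences in %d clones across %d mice; realized mutation mean %.2f, high-affinity fraction %.2f",
    regime, nrow(tr$sequences), nrow(tr$clones),
    length(unique(tr$sequences$mouse_id)),
    tr$realized$mean_mut, tr$realized$frac_haff))
}
message("wrote FASTA/manifest/truth bundles under results/data/")
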