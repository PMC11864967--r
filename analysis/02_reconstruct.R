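#!/usr/bin/env Rscript
# Stage 2 — reconstruct the pedigree from the observed tables.
#
# Runs the stepwise assembly (sibships first, then oriented
# parent-offspring links, latent parents, scored second-degree
# placements) on the tables written by 01_simulate.R, then measures how
# much of the true pedigree the observations allowed us to recover.

suppressMessages(library(kinweave))

seed <- 3L
out_dir <- "results"

man <- run_pipeline(config = list(observe = list(degree_noise = 0.05)),
                    stages = "reconstruct", seed = seed, out_dir = out_dir)
rec <- attr(man, "results")$reconstruct

truth <- read_pedigree_graphml(file.path(out_dir, "truth_pedigree.graphml"))
pe <- compare_parent_edges(truth, rec$pedigree)

cat(sprintf("Reconstructed pedigree: %d individuals (%d latent), consistency score %g.\n",
            nrow(rec$pedigree$ind), sum(!rec$pedigree$ind$sampled), rec$score))
cat(sprintf("Subpedigree units: %d; unplaced related: %d; unrelated: %d.\n",
            length(unique(rec$subpedigrees$unit)),
            length(rec$unplaced_related), length(rec$unrelated)))
cat(sprintf("Against truth: %d/%d sampled parent-child edges recovered (recall %.1f%%, precision %.1f%%).\n",
            pe$n_recovered, pe$n_true, 100 * pe$recall, 100 * pe$precision))
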