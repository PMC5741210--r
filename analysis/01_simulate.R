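#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs.
#
# Generates the synthetic comparative-genomics panel at the reference study
# conditions (2,000 baseline peptides, 7 phagocyte vs 6 nonphagocyte
# genomes, planted phagotrophy / biosynthesis / core / noise classes) and
# writes every downstream input under results/inputs/.

suppressPackageStartupMessages(library(phagoprofile))

seed <- 1L
out <- "results/inputs"
cfg <- generator_config(seed = seed)
sim <- generate_panel(cfg)
write_panel_inputs(sim, out)

cat(sprintf("panel: %d peptides x %d organisms; %d hit records emitted\n",
            cfg$n_peptides, nrow(sim$panel), nrow(sim$hits)))
cat(sprintf("planted classes: %s\n",
            paste(sprintf("%s=%d", names(table(sim$truth$class)),
                          table(sim$truth$class)), collapse = ", ")))
cat(sprintf("planted phagosome homologs: %d of %d peptides\n",
            sum(sim$truth$phagosome), cfg$n_peptides))
cat("inputs written to", out, "\n")
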