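#!/usr/bin/env Rscript
# Stage 2: homology filtering.
#
# Applies the dual retention criteria (e-value <= 1e-4 for whole-genome
# comparison, HSSP distance strictly > 5) to the simulated hit table and
# writes the retained hits. The generator plants decoy hits on either side
# of both thresholds, so the retention rate here reflects the filter, not
# just the presence structure.

suppressPackageStartupMessages(library(phagoprofile))

panel <- read_panel("results/inputs/panel.tsv")
hits <- read_blast_hits("results/inputs/hits.tsv", panel)
crit <- filter_criteria("comparison")
keep <- passes_dual_criteria(hits, crit)
retained <- hits[keep]
write_blast_hits(retained, "results/retained_hits.tsv")

cat(sprintf("dual criteria (e <= %g, DIST > %g): retained %d of %d hits (%.1f%%)\n",
            crit$evalue_max, crit$dist_min, nrow(retained), nrow(hits),
            100 * mean(keep)))
cat("retained hits written to results/retained_hits.tsv\n")
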