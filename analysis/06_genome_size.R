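#!/usr/bin/env Rscript
# Stage 6: genome size from the k-mer spectrum.
#
# Two simulated spectra: a repeat-free 1 Mb genome and a repeat-rich one in
# the regime of the study organism (77% of the k-mer mass in repeats). The
# estimator reports total genome size (mass above the error cutoff divided
# by peak coverage) and the unique portion (distinct k-mers around the
# peak).

suppressPackageStartupMessages({
  library(phagoprofile)
  library(data.table)
})

for (rf in c(0, 0.77)) {
  sp <- generate_kmer_spectrum(genome_size = 1e6, repeat_fraction = rf,
                               coverage = 20, seed = 4)
  write_kmer_histogram(sp, sprintf("results/kmer_rf%02.0f.histo", 100 * rf))
  est <- estimate_genome_size(sp, error_cutoff = 3)
  cat(sprintf("repeat fraction %.2f: genome %.3f Mb, peak %.1fx, unique %.3f Mb (%.0f%% of genome)\n",
              rf, est$genome_size / 1e6, est$peak_coverage,
              est$unique_size / 1e6,
              100 * est$unique_size / est$genome_size))
}
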