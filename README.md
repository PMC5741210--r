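# phagoprofile

Comparative genomic presence/absence profiling for inferring
phagotrophy-associated gene sets in mixotrophic eukaryotes.

## The problem

Phago-mixotrophic algae feed both by photosynthesis and by engulfing
particles (phagocytosis). Which genes support the feeding mode? A direct
way to ask is comparative: screen every predicted peptide of a baseline
proteome against a panel of genomes from organisms that demonstrably
phagocytose and genomes from organisms that do not, and look for peptides
systematically present in the first group and absent from the second. The
mirror-image comparison (present in nonphagocytes, absent from phagocytes)
recovers genes that obligate phagotrophs tend to lose — dominated by
small-molecule biosynthesis.

`phagoprofile` implements that inference as a tested pipeline, together
with the supporting analyses such a study needs: metabolic pathway
completeness from EC annotations, GO-term over-representation with
redundancy elimination, and genome-size estimation from k-mer spectra. A
first-class simulation module generates every input with planted gene
classes, so the whole chain is validated end to end against known truth.

## The method

**Homology filtering.** A hit from baseline peptide to panel organism is
retained iff

1. e-value ≤ 1e-4 (whole-genome comparison profile; 1e-5 for functional
   annotation), and
2. HSSP distance DIST = PIDE − t(L) > 5 (strictly), where the
   twilight-zone threshold is t(L) = 480·L^(−0.32·(1+e^(−L/1000))) for
   L ≤ 450 and 19.5 beyond.

**Presence scores.** Entry (p, o) of the binary presence matrix is 1 iff
peptide p has a retained hit in organism o. Group presence scores are the
row sums over the P phagocyte and N nonphagocyte columns.

**Criterion optimization.** A grouping criterion (k_min, m_min) selects
peptides present in ≥ k_min focal-group genomes and absent from ≥ m_min
contrast-group genomes. Each candidate set of size s with k_ph members in
the phagosome-homolog reference (B peptides with retained hits to known
phagosome components) is scored by

    wps = 100·k_ph/s − penalty(s)·(1 − k_ph/B)
    ds  = wps_focal · (wps_focal − wps_contrast) / 100

where the penalty grows with |log_B(s/B)|, is anchored to a minimum set
size of 30, and is clamped to [0, 100]. Every (k_min, m_min) pair is
enumerated in both directions and the argmax-ds criterion selected per
direction.

## Worked example

The numbered scripts under `analysis/` run the whole study on simulated
inputs (`Rscript analysis/01_simulate.R`, then 02…06). Stage 3 prints, at
the default study conditions (seed 1):

```
phagosome reference: 2037 unique components, B = 510 flagged peptides
phagocyte direction: k_min=6 m_min=3  s=428 k_ph=271 (63.3%)  wps=60.42 ds=36.50
nonphagocyte direction: k_min=3 m_min=1  s=343 k_ph=44 (12.8%)  wps=0.03 ds=-0.01
phagocyte-enriched set: 428 peptides, 63% phagosome homologs, contains 96% of planted phagotrophy class
nonphagocyte-enriched set: 343 peptides, 13% phagosome homologs, contains 100% of planted biosynthesis class
```

Reading: the optimizer lands on "present in at least 6 of 7 phagocytes,
absent from at least 3 of 6 nonphagocytes" — the planted regime — and the
selected set is strongly enriched in phagosome homologs (63%) relative to
the mirrored control direction (13%), recovering 96% of the planted
phagotrophy-associated peptides. The same run can be executed in one call
via

```r
library(phagoprofile)
run_pipeline(pipeline_config(synthetic = generator_config(seed = 1),
                             out_dir = "results/pipeline"))
```

Stage 6 prints the k-mer analysis; for a simulated 1 Mb genome with 77% of
its k-mer mass in repeats:

```
repeat fraction 0.77: genome 1.008 Mb, peak 19.8x, unique 0.229 Mb (23% of genome)
```

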