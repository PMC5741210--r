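Package: phagoprofile
Title: Comparative Genomic Presence/Absence Profiling for Phagotrophy Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers gene sets associated with phagotrophic feeding from
    all-vs-all protein homology searches against panels of phagocyte and
    nonphagocyte genomes. Homology hits are retained by a dual criterion
    (e-value cutoff plus an HSSP twilight-zone distance above the
    length-dependent identity threshold), converted to a binary peptide-by-
    organism presence matrix, and candidate grouping criteria (minimum
    presence among phagocytes, minimum absences among nonphagocytes) are
    scored by a weighted proportion score against a phagosome-proteome
    reference with a set-size penalty and a signal-to-noise distance score.
    Companion modules score metabolic pathway completeness from EC
    annotations, test GO-term over-representation with redundancy
    elimination and group-presence ranking, estimate genome size from k-mer
    spectra, and simulate every input with planted gene classes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
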