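peptide_classes <- c("phagotrophy", "biosynthesis", "core", "noise")

default_presence_probs <- function() {
  matrix(c(0.95, 0.20,   # phagotrophy-associated
           0.20, 0.95,   # biosynthesis-associated
           0.97, 0.94,   # core
           0.35, 0.12),  # noise / patchy
         ncol = 2, byrow = TRUE,
         dimnames = list(peptide_classes, c("phagocyte", "nonphagocyte")))
}

default_panel_organisms <- function(P = 7, N = 6) {
  ph <- c("Ddiscoideum", "Ehistolytica", "Dmelanogaster", "Mmusculus",
          "Tthermophila", "Ttrahens", "Bnatans")
  np <- c("Athaliana", "Osativa", "Creinhardtii", "Cmerolae",
          "Scerevisiae", "Bdendrobatidis")
  if (P > 7) ph <- c(ph, sprintf("phagocyte%02d", 8:P))
  if (N > 6) np <- c(np, sprintf("nonphagocyte%02d", 7:N))
  organism_panel(c(ph[seq_len(P)], np[seq_len(N)]),
                 rep(c("phagocyte", "nonphagocyte"), c(P, N)))
}

#' Configuration for the synthetic panel generator
#'
#' Defines the statistical structure of a simulated comparative-genomics
#' study: a baseline proteome of `n_peptides` peptides drawn from four
#' latent classes, screened against `n_phagocytes` phagocyte and
#' `n_nonphagocytes` nonphagocyte genomes with class-by-group Bernoulli
#' presence probabilities, phagosome-homology labels per class, and
#' alignment statistics that straddle the dual retention criteria.
#'
#' The defaults define the reference study conditions used throughout the
#' package's validation: a 7-vs-6 panel, 2,000 peptides, phagotrophy-class
#' presence 0.95 in phagocytes vs 0.20 in nonphagocytes, and phagosome
#' label probability 0.6 for the phagotrophy class vs 0.15 for the rest.
#'
#' @param n_peptides Number of baseline peptides.
#' @param n_phagocytes,n_nonphagocytes Panel group sizes.
#' @param class_mix Proportions over the classes phagotrophy, biosynthesis,
#'   core, noise; must sum to 1.
#' @param presence_probs 4 x 2 matrix of Bernoulli presence probabilities
#'   (rows: classes; columns: phagocyte, nonphagocyte).
#' @param phagosome_label_probs Per-class probability that a peptide is a
#'   phagosome-component homolog.
#' @param alignment_noise List controlling simulated hit statistics:
#'   `evalue_range` (log-uniform support of e-values), `boundary_fraction`
#'   (share of retained hits drawn within 5 identity points above the HSSP
#'   threshold), `decoy_fraction` (share of absent peptide-organism cells
#'   that still emit a failing hit), `length_range` (aligned length
#'   support).
#' @param n_phagosome_sources Number of phagocyte organisms contributing
#'   phagosome proteome lists (first organisms of the phagocyte group).
#' @param multi_hit If TRUE, a random half of present cells emit an extra,
#'   weaker redundant hit (exercises best-hit idempotence).
#' @param seed Integer seed; all generator draws are reproducible under it.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_peptides = 2000,
                             n_phagocytes = 7,
                             n_nonphagocytes = 6,
                             class_mix = c(phagotrophy = 0.22,
                                           biosynthesis = 0.10,
                                           core = 0.28,
                                           noise = 0.40),
                             presence_probs = default_presence_probs(),
                             phagosome_label_probs = c(phagotrophy = 0.60,
                                                       biosynthesis = 0.15,
                                                       core = 0.15,
                                                       noise = 0.15),
                             alignment_noise = list(
                               evalue_range = c(1e-30, 1e-2),
                               boundary_fraction = 0.30,
                               decoy_fraction = 0.08,
                               length_range = c(120L, 800L)),
                             n_phagosome_sources = 5,
                             multi_hit = FALSE,
                             seed = 1L) {
  stopifnot(n_peptides >= 1, n_phagocytes >= 1, n_nonphagocytes >= 1)
  class_mix <- unlist(class_mix)
  if (length(class_mix) != 4 || abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must be 4 proportions summing to 1")
  if (any(class_mix < 0)) stop("class_mix proportions must be >= 0")
  presence_probs <- as.matrix(presence_probs)
  if (!identical(dim(presence_probs), c(4L, 2L)))
    stop("presence_probs must be a 4 x 2 matrix (class x group)")
  if (any(presence_probs < 0 | presence_probs > 1))
    stop("presence probabilities must lie in [0, 1]")
  phagosome_label_probs <- unlist(phagosome_label_probs)
  if (length(phagosome_label_probs) != 4 ||
      any(phagosome_label_probs < 0 | phagosome_label_probs > 1))
    stop("phagosome_label_probs must be 4 probabilities in [0, 1]")
  an <- alignment_noise
  if (an$boundary_fraction < 0 || an$boundary_fraction > 1 ||
      an$decoy_fraction < 0 || an$decoy_fraction > 1)
    stop("alignment_noise fractions must lie in [0, 1]")
  n_phagosome_sources <- min(n_phagosome_sources, n_phagocytes)
  structure(list(n_peptides = as.integer(n_peptides),
                 n_phagocytes = as.integer(n_phagocytes),
                 n_nonphagocytes = as.integer(n_nonphagocytes),
                 class_mix = stats::setNames(class_mix, peptide_classes),
                 presence_probs = presence_probs,
                 phagosome_label_probs = stats::setNames(phagosome_label_probs,
                                                         peptide_classes),
                 alignment_noise = an,
                 n_phagosome_sources = as.integer(n_phagosome_sources),
                 multi_hit = isTRUE(multi_hit),
                 seed = as.integer(seed)),
            class = "generator_config")
}

r_log_uniform <- function(n, lo, hi) 10^stats::runif(n, log10(lo), log10(hi))

# Alignment stats for hits meant to pass (e-value below emax, DIST > 5) or
# fail (half by e-value above emax, half by DIST within (-5, 5]).
draw_hit_stats <- function(n, pass, an, emax = 1e-4) {
  len <- sample(seq(an$length_range[1], an$length_range[2]), n, replace = TRUE)
  dist <- numeric(n); ev <- numeric(n)
  if (any(pass)) {
    np <- sum(pass)
    near <- stats::runif(np) < an$boundary_fraction
    dist[pass] <- ifelse(near, stats::runif(np, 5 + 1e-3, 10),
                         stats::runif(np, 10, 45))
    ev[pass] <- r_log_uniform(np, an$evalue_range[1], emax)
  }
  if (any(!pass)) {
    nf <- sum(!pass)
    by_evalue <- stats::runif(nf) < 0.5
    dist[!pass] <- ifelse(by_evalue, stats::runif(nf, 10, 45),
                          stats::runif(nf, -5, 5))
    ev[!pass] <- ifelse(by_evalue,
                        r_log_uniform(nf, emax * 1.01, an$evalue_range[2]),
                        r_log_uniform(nf, an$evalue_range[1], emax))
  }
  pident <- pmin(100, hssp_curve(len) + dist)
  data.table::data.table(pident = round(pident, 2), length = len,
                         evalue = signif(ev, 3))
}

finish_hit_table <- function(dt) {
  dt$mismatch <- as.integer(round(dt$length * (1 - dt$pident / 100)))
  dt$gapopen <- 0L
  dt$qstart <- 1L; dt$qend <- dt$length
  dt$sstart <- 1L; dt$send <- dt$length
  dt$bitscore <- round(dt$length * dt$pident / 100 * 1.9, 1)
  data.table::setcolorder(dt, c(blast6_cols, "organism"))
  dt
}

#' Generate a synthetic comparative-genomics panel
#'
#' Draws latent peptide classes, class-by-group presence indicators, and
#' phagosome-homology labels; emits a BLAST-tabular-style hit table in
#' which every present peptide-organism cell carries one retained-quality
#' hit and a configurable fraction of absent cells carry a decoy hit that
#' fails the dual criteria (by e-value or by an HSSP distance within the
#' twilight band). Per-organism phagosome source lists contain the subject
#' proteins of labelled peptides in the first `n_phagosome_sources`
#' phagocytes, so the reference built downstream recovers the planted
#' labels up to filter-induced loss.
#'
#' @param config A [generator_config()].
#' @return A list with `hits` (12 BLAST columns + organism), `panel`,
#'   `phagosome_sources` (organism, protein_id), and `truth` (peptide,
#'   class, phagosome flag).
#' @export
generate_panel <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_peptides
  panel <- default_panel_organisms(config$n_phagocytes, config$n_nonphagocytes)
  peptides <- sprintf("pep%05d", seq_len(n))
  cls <- sample(peptide_classes, n, replace = TRUE, prob = config$class_mix)
  truth <- data.table::data.table(
    peptide = peptides, class = cls,
    phagosome = stats::rbinom(n, 1, config$phagosome_label_probs[cls]) == 1)

  cells <- data.table::CJ(peptide = peptides, organism = panel$organism,
                          sorted = FALSE)
  cells$class <- cls[match(cells$peptide, peptides)]
  cells$group <- panel$group[match(cells$organism, panel$organism)]
  p <- config$presence_probs[cbind(cells$class, cells$group)]
  cells$present <- stats::rbinom(nrow(cells), 1, p) == 1

  an <- config$alignment_noise
  emit <- cells$present | (stats::runif(nrow(cells)) < an$decoy_fraction)
  hits <- cells[emit, c("peptide", "organism", "present")]
  stats_dt <- draw_hit_stats(nrow(hits), hits$present, an)
  hits <- cbind(hits, stats_dt)
  hits$qseqid <- hits$peptide
  hits$sseqid <- paste0(hits$organism, "|g",
                        sprintf("%05d", match(hits$peptide, peptides)))
  if (config$multi_hit && any(hits$present)) {
    idx <- which(hits$present)
    extra <- hits[idx[stats::runif(length(idx)) < 0.5], ]
    if (nrow(extra) > 0) {
      st <- draw_hit_stats(nrow(extra), rep(TRUE, nrow(extra)), an)
      extra$pident <- st$pident
      extra$length <- st$length
      extra$evalue <- st$evalue
      extra$sseqid <- paste0(extra$sseqid, "b")
      hits <- rbind(hits, extra)
    }
  }
  hits <- finish_hit_table(hits[, !"peptide"])
  hits$present <- NULL

  src_orgs <- panel$organism[panel$group == "phagocyte"][
    seq_len(config$n_phagosome_sources)]
  flagged_idx <- which(truth$phagosome)
  src <- cells[cells$present & cells$organism %in% src_orgs &
               cells$peptide %in% peptides[flagged_idx],
               c("peptide", "organism")]
  phagosome_sources <- data.table::data.table(
    organism = src$organism,
    protein_id = paste0(src$organism, "|g",
                        sprintf("%05d", match(src$peptide, peptides))))

  list(hits = hits, panel = panel,
       phagosome_sources = phagosome_sources[order(organism, protein_id)],
       truth = truth)
}

#' Write all panel inputs to a directory
#'
#' Emits `hits.tsv` (BLAST outfmt-6), `panel.tsv`, `phagosome_sources.tsv`
#' and `truth.tsv`. Byte-identical on re-run under the same config.
#'
#' @param sim A [generate_panel()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_panel_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_blast_hits(sim$hits, file.path(dir, "hits.tsv"))
  write_panel(sim$panel, file.path(dir, "panel.tsv"))
  data.table::fwrite(sim$phagosome_sources,
                     file.path(dir, "phagosome_sources.tsv"), sep = "\t")
  data.table::fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t")
  invisible(dir)
}
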