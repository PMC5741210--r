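#' Genome size and unique fraction from a k-mer spectrum
#'
#' The spectrum is a histogram of distinct k-mer counts by multiplicity
#' (fold coverage). The peak is the modal bin above `error_cutoff`; genome
#' size is the total k-mer mass above the cutoff divided by the peak
#' coverage, and the unique (non-repetitive) portion is the distinct-k-mer
#' count summed over a window around the peak (default
#' \[peak/2, 2*peak\]).
#'
#' @param spectrum data.frame/data.table with columns `multiplicity`
#'   (positive integers) and `count` (>= 0), or a 2-column matrix.
#' @param error_cutoff Multiplicities at or below this are treated as
#'   sequencing-error k-mers (default 3).
#' @param peak_window Numeric length-2 multipliers of the peak bounding the
#'   unique-portion window (default `c(0.5, 2)`).
#' @return List with `genome_size`, `peak_coverage`, `unique_size` (bases).
#' @export
estimate_genome_size <- function(spectrum, error_cutoff = 3,
                                 peak_window = c(0.5, 2)) {
  sp <- data.table::as.data.table(spectrum)
  if (ncol(sp) < 2) stop("spectrum needs multiplicity and count columns")
  data.table::setnames(sp, 1:2, c("multiplicity", "count"))
  if (any(sp$count < 0) || any(sp$multiplicity < 1))
    stop("invalid spectrum: negative counts or multiplicities < 1")
  use <- sp[sp$multiplicity > error_cutoff & sp$count > 0]
  if (nrow(use) == 0) stop("no k-mer peak above the error cutoff")
  mode_bin <- use$multiplicity[which.max(use$count)]
  # refine the peak as the count-weighted mean multiplicity of the main
  # peak bulk (a symmetric fractional window around the mode): the raw mode
  # alternates between adjacent bins when coverage is near-integer, and a
  # narrow centroid is biased by the peak's skew
  nb <- use[use$multiplicity >= 0.6 * mode_bin &
            use$multiplicity <= 1.4 * mode_bin]
  peak <- sum(nb$multiplicity * nb$count) / sum(nb$count)
  genome <- sum(use$multiplicity * use$count) / peak
  win <- sp$multiplicity >= peak_window[1] * peak &
         sp$multiplicity <= peak_window[2] * peak
  unique_size <- sum(sp$count[win])
  list(genome_size = genome, peak_coverage = peak, unique_size = unique_size)
}

#' Simulate a k-mer spectrum
#'
#' A genome of `genome_size` bases in which a `repeat_fraction` share of
#' the k-mer mass comes from repetitive families. Unique k-mers occur at
#' copy number 1; repeat k-mers draw copy numbers >= 4 (shifted geometric),
#' so their multiplicities land well beyond twice the main peak. Each
#' distinct k-mer's observed multiplicity is Poisson with mean
#' `copy_number * coverage`. A light error spike at multiplicity ~1 is
#' added below the default error cutoff.
#'
#' @param genome_size Total bases (k-mer mass at coverage 1).
#' @param repeat_fraction Share of k-mer mass in repeats, in \[0, 1).
#' @param coverage Mean sequencing fold coverage of single-copy k-mers.
#' @param seed Integer seed.
#' @param error_kmer_fraction Distinct error k-mers as a fraction of
#'   genome_size (default 0.2).
#' @return `data.table` with columns `multiplicity`, `count`.
#' @export
generate_kmer_spectrum <- function(genome_size = 1e6, repeat_fraction = 0,
                                   coverage = 20, seed = 1L,
                                   error_kmer_fraction = 0.2) {
  stopifnot(repeat_fraction >= 0, repeat_fraction < 1,
            genome_size >= 1000, coverage >= 4)
  set.seed(seed)
  n_unique <- round((1 - repeat_fraction) * genome_size)
  mult <- stats::rpois(n_unique, coverage)
  if (repeat_fraction > 0) {
    copies_mean <- 4 + (1 - 0.25) / 0.25     # shifted geometric, mean 7
    n_rep <- round(repeat_fraction * genome_size / copies_mean)
    copies <- 4 + stats::rgeom(n_rep, 0.25)
    # rescale so the repeat mass matches the requested fraction exactly
    target <- repeat_fraction * genome_size
    copies <- copies * target / sum(copies)
    mult <- c(mult, stats::rpois(n_rep, copies * coverage))
  }
  n_err <- round(error_kmer_fraction * genome_size)
  if (n_err > 0) mult <- c(mult, 1 + stats::rpois(n_err, 0.3))
  mult <- mult[mult > 0]
  tab <- tabulate(mult)
  data.table::data.table(multiplicity = seq_along(tab),
                         count = tab)[count > 0]
}

#' Read / write a k-mer histogram TSV (multiplicity, count)
#' @export
read_kmer_histogram <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  data.table::setnames(dt, 1:2, c("multiplicity", "count"))
  dt
}

#' @rdname read_kmer_histogram
#' @export
write_kmer_histogram <- function(spectrum, path) {
  data.table::fwrite(spectrum, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
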