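#' Twilight-zone percent-identity threshold (HSSP curve)
#'
#' Length-dependent percent-identity threshold separating confident homology
#' from the "twilight zone". For alignments longer than 450 residues the
#' threshold is the constant plateau 19.5; below that it follows the
#' canonical curve `480 * L^(-0.32 * (1 + exp(-L/1000)))`, capped at 100 for
#' very short alignments. The offset is zero: distances are measured from
#' this curve itself.
#'
#' @param length Aligned residue count (numeric vector, all >= 1).
#' @return Percent-identity threshold in (0, 100], same length as `length`.
#' @examples
#' hssp_curve(c(100, 1000))
#' @export
hssp_curve <- function(length) {
  if (!is.numeric(length) || any(is.na(length)) || any(length < 1))
    stop("alignment length must be numeric and >= 1")
  thr <- ifelse(length > 450,
                19.5,
                pmin(100, 480 * length^(-0.32 * (1 + exp(-length / 1000)))))
  thr
}

#' HSSP distance (DIST relation)
#'
#' Percent identity minus the twilight-zone threshold at the alignment
#' length. Positive values lie above the curve; the retention rule used
#' throughout this package requires a distance strictly greater than 5.
#'
#' @param pide Percent identity in \[0, 100\].
#' @param length Aligned residue count (>= 1).
#' @return Numeric vector of distances.
#' @examples
#' hssp_dist(30, 1000) # 10.5 above the long-alignment plateau
#' @export
hssp_dist <- function(pide, length) {
  if (!is.numeric(pide) || any(is.na(pide)) || any(pide < 0 | pide > 100))
    stop("percent identity must lie in [0, 100]")
  pide - hssp_curve(length)
}

#' Retention criteria for homology hits
#'
#' Two named profiles are shipped: `"annotation"` (e-value <= 1e-5, used for
#' functional annotation against a large database) and `"comparison"`
#' (e-value <= 1e-4, the more permissive cutoff appropriate for searches
#' against single proteomes). Both require an HSSP distance strictly
#' greater than `dist_min`.
#'
#' @param profile `"comparison"` or `"annotation"`, ignored when
#'   `evalue_max` is given explicitly.
#' @param evalue_max Optional explicit e-value ceiling (> 0).
#' @param dist_min HSSP distance threshold; hits must exceed it strictly.
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(profile = c("comparison", "annotation"),
                            evalue_max = NULL, dist_min = 5) {
  if (is.null(evalue_max)) {
    profile <- match.arg(profile)
    evalue_max <- switch(profile, annotation = 1e-5, comparison = 1e-4)
  } else {
    profile <- "custom"
  }
  if (!is.numeric(evalue_max) || evalue_max <= 0)
    stop("evalue_max must be > 0")
  structure(list(profile = profile, evalue_max = evalue_max,
                 dist_min = dist_min),
            class = "filter_criteria")
}

#' Dual retention decision for homology hits
#'
#' A hit is retained iff its e-value is at or below the ceiling AND its HSSP
#' distance exceeds `dist_min` strictly. A hit sitting exactly on the
#' distance threshold is rejected; a hit exactly at the e-value ceiling is
#' accepted.
#'
#' @param hits A data.frame/data.table with columns `pident`, `length`,
#'   `evalue` (e.g. from [read_blast_hits()]).
#' @param criteria A [filter_criteria()] object.
#' @return Logical vector, one decision per hit.
#' @export
passes_dual_criteria <- function(hits, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  req <- c("pident", "length", "evalue")
  if (!all(req %in% names(hits)))
    stop("hits must carry columns: ", paste(req, collapse = ", "))
  if (nrow(hits) == 0) return(logical(0))
  if (any(hits$evalue < 0)) stop("negative e-values in hit table")
  hits$evalue <= criteria$evalue_max &
    hssp_dist(hits$pident, hits$length) > criteria$dist_min
}

blast6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a homology search table (BLAST tabular, outfmt 6)
#'
#' Reads the 12-column tab-separated format without header. The subject
#' organism is resolved from the `sseqid` prefix before the first `|`
#' (e.g. `Mmusculus|g00017`), and every organism must be a member of the
#' panel. Malformed rows (wrong field count, identity outside \[0,100\],
#' length < 1, negative e-value) abort with their line numbers.
#'
#' @param path Tabular file path.
#' @param panel An [organism_panel()].
#' @return A `data.table` with the 12 standard columns plus `organism`.
#' @export
read_blast_hits <- function(path, panel) {
  panel <- as_organism_panel(panel)
  dt <- suppressWarnings(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = c(1, 2))))
  if (nrow(dt) == 0) {
    warning("empty hit table: ", path)
    empty <- data.table::as.data.table(
      stats::setNames(rep(list(character(0)), 12), blast6_cols))
    empty$organism <- character(0)
    return(empty)
  }
  if (ncol(dt) != 12)
    stop("expected 12 tab-separated columns, found ", ncol(dt))
  data.table::setnames(dt, blast6_cols)
  for (col in blast6_cols[3:12]) dt[[col]] <- suppressWarnings(as.numeric(dt[[col]]))
  bad <- which(is.na(dt$pident) | dt$pident < 0 | dt$pident > 100 |
               is.na(dt$length) | dt$length < 1 |
               is.na(dt$evalue) | dt$evalue < 0)
  if (length(bad))
    stop("malformed hit rows at line(s): ",
         paste(utils::head(bad, 20), collapse = ", "))
  dt$organism <- sub("\\|.*$", "", dt$sseqid)
  unknown <- setdiff(unique(dt$organism), panel$organism)
  if (length(unknown))
    stop("hit subjects from organisms not in panel: ",
         paste(unknown, collapse = ", "))
  dt[]
}

#' Write hits in BLAST tabular format
#'
#' @param hits Hit table carrying the 12 standard columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_hits <- function(hits, path) {
  data.table::fwrite(hits[, blast6_cols, with = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}
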