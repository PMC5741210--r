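#' Binary presence matrix from retained hits
#'
#' Entry (p, o) is 1 iff at least one retained hit links baseline peptide p
#' to organism o; repeated hits to the same organism are idempotent.
#' Peptides listed in `peptides` but absent from the hit table appear as
#' all-zero rows, so the peptide universe is preserved through filtering.
#'
#' @param hits Retained hit table with columns `qseqid`, `organism`
#'   (pre-filtered with [passes_dual_criteria()]).
#' @param panel An [organism_panel()].
#' @param peptides Optional character vector fixing the row universe;
#'   defaults to the peptides seen in `hits`.
#' @return An object of class `presence_matrix`: a list with the binary
#'   `mat` (peptides x organisms), the `panel`, and per-peptide group
#'   presence scores `s_phag`, `s_nonphag`.
#' @export
build_presence_matrix <- function(hits, panel, peptides = NULL) {
  panel <- as_organism_panel(panel)
  if (nrow(hits) > 0) {
    unknown <- setdiff(unique(hits$organism), panel$organism)
    if (length(unknown))
      stop("hits reference organisms outside the panel: ",
           paste(unknown, collapse = ", "))
  }
  if (is.null(peptides)) peptides <- sort(unique(hits$qseqid))
  peptides <- as.character(peptides)
  mat <- matrix(0L, nrow = length(peptides), ncol = nrow(panel),
                dimnames = list(peptides, panel$organism))
  if (nrow(hits) > 0) {
    ij <- unique(data.frame(i = match(hits$qseqid, peptides),
                            j = match(hits$organism, panel$organism)))
    ij <- ij[!is.na(ij$i) & !is.na(ij$j), ]
    mat[cbind(ij$i, ij$j)] <- 1L
  }
  ph <- panel$organism[panel$group == "phagocyte"]
  np <- panel$organism[panel$group == "nonphagocyte"]
  structure(list(mat = mat, panel = panel,
                 s_phag = rowSums(mat[, ph, drop = FALSE]),
                 s_nonphag = rowSums(mat[, np, drop = FALSE])),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence matrix: %d peptides x %d organisms (%d phagocytes, %d nonphagocytes)\n",
              nrow(x$mat), ncol(x$mat),
              sum(x$panel$group == "phagocyte"),
              sum(x$panel$group == "nonphagocyte")))
  invisible(x)
}

#' Write / read a presence matrix as TSV (peptide + one 0/1 column per organism)
#' @export
write_presence_matrix <- function(pm, path) {
  dt <- data.table::data.table(peptide = rownames(pm$mat))
  for (org in colnames(pm$mat)) dt[[org]] <- pm$mat[, org]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path, panel) {
  panel <- as_organism_panel(panel)
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  mat <- as.matrix(dt[, panel$organism, with = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- dt$peptide
  ph <- panel$organism[panel$group == "phagocyte"]
  np <- panel$organism[panel$group == "nonphagocyte"]
  structure(list(mat = mat, panel = panel,
                 s_phag = rowSums(mat[, ph, drop = FALSE]),
                 s_nonphag = rowSums(mat[, np, drop = FALSE])),
            class = "presence_matrix")
}

#' Select peptides under a grouping criterion
#'
#' Returns the peptides whose presence score in the focal group is at least
#' `k_min` and whose number of absences in the contrast group is at least
#' `m_min`.
#'
#' @param pm A [build_presence_matrix()] result.
#' @param k_min Minimum focal-group presence score (0..focal group size).
#' @param m_min Minimum contrast-group absences (0..contrast group size).
#' @param focal `"phagocyte"` (default) or `"nonphagocyte"`.
#' @return Character vector of peptide ids.
#' @export
select_set <- function(pm, k_min, m_min, focal = c("phagocyte", "nonphagocyte")) {
  focal <- match.arg(focal)
  P <- sum(pm$panel$group == "phagocyte")
  N <- sum(pm$panel$group == "nonphagocyte")
  if (focal == "phagocyte") {
    fs <- pm$s_phag; cs <- pm$s_nonphag; FS <- P; CS <- N
  } else {
    fs <- pm$s_nonphag; cs <- pm$s_phag; FS <- N; CS <- P
  }
  if (k_min < 0 || k_min > FS) stop("k_min outside 0..", FS)
  if (m_min < 0 || m_min > CS) stop("m_min outside 0..", CS)
  rownames(pm$mat)[fs >= k_min & (CS - cs) >= m_min]
}

#' Build the phagosome-homolog reference
#'
#' Combines per-organism phagosome proteome lists into a unique component
#' set, then flags every baseline peptide with at least one retained hit to
#' any component. The reference count B is always computed from the data.
#'
#' @param sources A data.frame/data.table with columns `organism`,
#'   `protein_id`: proteins observed in purified phagosomes per source
#'   organism.
#' @param hits Retained hit table (columns `qseqid`, `sseqid`).
#' @return A list of class `phagosome_reference`: `components` (the unique
#'   union, size `U`), `flagged` (baseline peptide ids), and `B =
#'   length(flagged)`.
#' @export
build_phagosome_reference <- function(sources, hits) {
  if (NROW(sources) == 0) stop("empty phagosome source lists")
  if (!all(c("organism", "protein_id") %in% names(sources)))
    stop("sources must carry columns organism, protein_id")
  components <- unique(as.character(sources$protein_id))
  flagged <- sort(unique(hits$qseqid[hits$sseqid %in% components]))
  structure(list(components = components, U = length(components),
                 flagged = flagged, B = length(flagged)),
            class = "phagosome_reference")
}

#' @export
print.phagosome_reference <- function(x, ...) {
  cat(sprintf("phagosome reference: %d unique components; %d baseline peptides flagged (B)\n",
              x$U, x$B))
  invisible(x)
}
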