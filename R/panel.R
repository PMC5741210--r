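#' Organism panel
#'
#' An ordered table of panel organisms, each labelled `"phagocyte"` or
#' `"nonphagocyte"`. The baseline proteome (the organism whose peptides form
#' the rows of the presence matrix) is never itself a panel member.
#'
#' @param organism Character vector of organism identifiers (unique).
#' @param group Character vector of group labels, one per organism.
#' @return A `data.table` of class `organism_panel` with columns
#'   `organism`, `group`.
#' @export
organism_panel <- function(organism, group) {
  if (anyDuplicated(organism)) stop("duplicate organism identifiers")
  if (!all(group %in% c("phagocyte", "nonphagocyte")))
    stop("group labels must be 'phagocyte' or 'nonphagocyte'")
  if (length(organism) != length(group))
    stop("organism and group lengths differ")
  if (!any(group == "phagocyte") || !any(group == "nonphagocyte"))
    stop("panel needs at least one organism in each group")
  dt <- data.table::data.table(organism = as.character(organism),
                               group = group)
  data.table::setattr(dt, "class", c("organism_panel", class(dt)))
  dt
}

#' @export
as_organism_panel <- function(x) {
  if (inherits(x, "organism_panel")) return(x)
  if (!all(c("organism", "group") %in% names(x)))
    stop("cannot interpret object as organism panel")
  organism_panel(x$organism, x$group)
}

#' @export
print.organism_panel <- function(x, ...) {
  cat(sprintf("organism panel: %d phagocytes, %d nonphagocytes\n",
              sum(x$group == "phagocyte"), sum(x$group == "nonphagocyte")))
  NextMethod()
}

#' Read / write a panel table (TSV: organism, group)
#' @param path File path.
#' @return An [organism_panel()].
#' @export
read_panel <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  as_organism_panel(dt)
}

#' @rdname read_panel
#' @param panel Panel to write.
#' @export
write_panel <- function(panel, path) {
  data.table::fwrite(as_organism_panel(panel), path, sep = "\t")
  invisible(path)
}
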