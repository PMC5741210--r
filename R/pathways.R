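ec4_pattern <- "^(EC-)?[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$"

normalize_ec <- function(ec) sub("^EC-", "", ec)

#' Retain only fully specified EC annotations
#'
#' Keeps annotations whose EC number enumerates all four classification
#' levels (e.g. `EC-3.1.4.13`); partially specified numbers such as
#' `EC-3.1.4.-` are removed. The `EC-` prefix is tolerated and stripped.
#'
#' @param annotations data.frame/data.table with columns `organism`,
#'   `peptide`, `ec`.
#' @return A `data.table` of retained rows (`ec` normalized, prefix-free),
#'   with the number of removed rows reported in attribute `n_removed`.
#' @export
filter_complete_ec <- function(annotations) {
  ann <- data.table::as.data.table(annotations)
  if (nrow(ann) == 0) {
    out <- ann
    data.table::setattr(out, "n_removed", 0L)
    return(out)
  }
  keep <- grepl(ec4_pattern, ann$ec)
  out <- ann[keep]
  out$ec <- normalize_ec(out$ec)
  data.table::setattr(out, "n_removed", sum(!keep))
  out
}

#' Pathway definition
#'
#' @param pathway_id Identifier.
#' @param ec Character vector of member EC numbers, all four-level.
#' @param weights Optional positive per-enzyme weights (default uniform).
#' @return A list of class `pathway_definition`.
#' @export
pathway_definition <- function(pathway_id, ec, weights = NULL) {
  if (length(ec) < 1) stop("a pathway needs at least one member enzyme")
  if (!all(grepl(ec4_pattern, ec)))
    stop("all member EC numbers must be fully specified (four levels)")
  if (is.null(weights)) weights <- rep(1, length(ec))
  if (length(weights) != length(ec) || any(weights <= 0))
    stop("weights must be positive, one per enzyme")
  structure(list(pathway_id = pathway_id, ec = normalize_ec(ec),
                 weights = weights),
            class = "pathway_definition")
}

#' Weighted pathway completeness score
#'
#' The weighted fraction of a pathway's member enzymes annotated present in
#' an organism: `score = sum(w_e * present_e) / sum(w_e)`, where an enzyme
#' is present iff at least one retained peptide carries its EC number.
#' A complete pathway scores 1 and an unrepresented one 0 under any
#' positive weights.
#'
#' @param pathway A [pathway_definition()].
#' @param annotations EC annotation table for one organism (columns
#'   `peptide`, `ec`; run through [filter_complete_ec()] first).
#' @return Score in \[0, 1\].
#' @export
pathway_score <- function(pathway, annotations) {
  stopifnot(inherits(pathway, "pathway_definition"))
  present_ec <- unique(normalize_ec(annotations$ec))
  present <- pathway$ec %in% present_ec
  sum(pathway$weights * present) / sum(pathway$weights)
}

#' Score all pathways across organisms
#'
#' @param pathways List of [pathway_definition()] objects.
#' @param annotations EC annotation table with columns `organism`,
#'   `peptide`, `ec` (filtered to complete EC numbers).
#' @return `data.table` with one row per pathway x organism: `pathway_id`,
#'   `organism`, `n_enzymes`, `n_present`, `score`.
#' @export
score_pathways <- function(pathways, annotations) {
  ann <- data.table::as.data.table(annotations)
  orgs <- unique(ann$organism)
  rows <- list()
  for (pw in pathways) {
    for (org in orgs) {
      sub <- ann[ann$organism == org]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        pathway_id = pw$pathway_id, organism = org,
        n_enzymes = length(pw$ec),
        n_present = sum(pw$ec %in% unique(normalize_ec(sub$ec))),
        score = pathway_score(pw, sub))
    }
  }
  data.table::rbindlist(rows)
}

#' Presence/absence pathway calls against a focal organism
#'
#' A pathway is called focal-only when its score in the focal organism is
#' at least `present_threshold` while every other organism scores below
#' `absent_threshold`; conversely it is called focal-absent when the focal
#' score is below `absent_threshold` and at least one other organism
#' reaches `present_threshold`. Borderline pathways fall in neither list.
#'
#' @param score_table Output of [score_pathways()].
#' @param focal Focal organism id (must appear in the table).
#' @param present_threshold,absent_threshold Call thresholds in \[0, 1\]
#'   with `present_threshold > absent_threshold` (defaults 0.4 / 0.25).
#' @return List with `focal_only`, `focal_absent` (pathway ids) and the
#'   wide `scores` audit table (pathway x organism).
#' @export
compare_pathways <- function(score_table, focal,
                             present_threshold = 0.4,
                             absent_threshold = 0.25) {
  stopifnot(present_threshold > absent_threshold,
            present_threshold <= 1, absent_threshold >= 0)
  if (!focal %in% score_table$organism)
    stop("focal organism not in score table: ", focal)
  wide <- data.table::dcast(data.table::as.data.table(score_table),
                            pathway_id ~ organism, value.var = "score")
  others <- setdiff(names(wide), c("pathway_id", focal))
  omax <- apply(wide[, others, with = FALSE], 1, max)
  focal_sc <- wide[[focal]]
  list(
    focal_only = wide$pathway_id[focal_sc >= present_threshold &
                                 omax < absent_threshold],
    focal_absent = wide$pathway_id[focal_sc < absent_threshold &
                                   omax >= present_threshold],
    scores = wide)
}

#' Synthetic pathway and EC-annotation fixtures
#'
#' Generates `n_pathways` pathways over a universe of `ec_universe`
#' four-level EC numbers and per-organism annotation tables. By
#' construction the first pathway is fully annotated in the focal (first)
#' organism and unannotated in the second, and the annotation table of the
#' focal organism contains one partially specified EC string
#' (`EC-3.1.4.-`) so the completeness filter is exercised.
#'
#' @param n_pathways,ec_universe Positive counts.
#' @param seed Integer seed.
#' @param organisms Organism ids (>= 2; first is the focal organism).
#' @return List with `pathways` (list of [pathway_definition()]) and
#'   `annotations` (organism, peptide, ec; unfiltered).
#' @export
generate_pathway_fixtures <- function(n_pathways = 8, ec_universe = 40,
                                      seed = 1L,
                                      organisms = c("Ctetramitiformis",
                                                    "Creinhardtii",
                                                    "Otauri", "Mpusilla")) {
  stopifnot(n_pathways >= 1, ec_universe >= 3, length(organisms) >= 2)
  set.seed(seed)
  ecs <- unique(sprintf("%d.%d.%d.%d",
                        sample(1:6, ec_universe, TRUE),
                        sample(1:9, ec_universe, TRUE),
                        sample(1:9, ec_universe, TRUE),
                        sample(1:99, ec_universe, TRUE)))
  pathways <- lapply(seq_len(n_pathways), function(i) {
    k <- sample(3:min(8, length(ecs)), 1)
    pathway_definition(sprintf("PWY%03d", i), sample(ecs, k))
  })
  rows <- list()
  for (org in organisms) {
    # each organism carries a random ~60% of the EC universe
    carried <- sample(ecs, round(0.6 * length(ecs)))
    # plant pathway 1 complete in the focal organism, absent elsewhere
    if (org == organisms[1]) carried <- union(carried, pathways[[1]]$ec)
    else carried <- setdiff(carried, pathways[[1]]$ec)
    rows[[org]] <- data.table::data.table(
      organism = org,
      peptide = sprintf("%s_p%04d", org, seq_along(carried)),
      ec = paste0("EC-", carried))
  }
  ann <- data.table::rbindlist(rows)
  partial <- data.table::data.table(organism = organisms[1],
                                    peptide = "partial_pep", ec = "EC-3.1.4.-")
  list(pathways = pathways, annotations = rbind(ann, partial))
}
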