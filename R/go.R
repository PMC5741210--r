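#' Build a GO-style ontology object
#'
#' A rooted acyclic ontology over `is_a` edges. Internally an igraph with
#' edges child -> parent is kept alongside the term table.
#'
#' @param terms data.frame/data.table with columns `id`, `name`,
#'   `namespace`.
#' @param edges data.frame/data.table with columns `child`, `parent`
#'   (is_a relations).
#' @return A list of class `ontology` with `terms`, `edges`, `graph`.
#' @export
ontology <- function(terms, edges) {
  terms <- data.table::as.data.table(terms)
  edges <- data.table::as.data.table(edges)
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("child", "parent") %in% names(edges)))
  missing <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(missing))
    stop("edges reference unknown terms: ", paste(missing, collapse = ", "))
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     vertices = terms$id)
  if (!igraph::is_dag(g)) stop("ontology contains a cycle")
  structure(list(terms = terms, edges = edges, graph = g),
            class = "ontology")
}

#' Ancestors of each term (transitive is_a closure, term itself excluded)
#' @param onto An [ontology()].
#' @return Named list: term id -> character vector of ancestor ids.
#' @export
term_ancestors <- function(onto) {
  ids <- onto$terms$id
  out <- lapply(ids, function(id) {
    anc <- igraph::subcomponent(onto$graph, id, mode = "out")
    setdiff(names(anc), id)
  })
  stats::setNames(out, ids)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Every peptide annotated to a term becomes annotated to all of the
#' term's ancestors. Idempotent.
#'
#' @param annotations data.frame/data.table with columns `peptide`, `term`.
#' @param onto An [ontology()].
#' @return De-duplicated `data.table` (peptide, term) including ancestors.
#' @export
propagate_annotations <- function(annotations, onto) {
  ann <- data.table::as.data.table(annotations)
  if (nrow(ann) == 0) return(ann)
  unknown <- setdiff(unique(ann$term), onto$terms$id)
  if (length(unknown))
    stop("annotations reference unknown terms: ",
         paste(unknown, collapse = ", "))
  anc <- term_ancestors(onto)
  anc_dt <- data.table::rbindlist(lapply(names(anc), function(t) {
    if (length(anc[[t]]) == 0) return(NULL)
    data.table::data.table(term = t, ancestor = anc[[t]])
  }))
  direct <- unique(ann[, c("peptide", "term")])
  if (is.null(anc_dt) || nrow(anc_dt) == 0) return(direct)
  extra <- merge(direct, anc_dt, by = "term", allow.cartesian = TRUE)
  extra <- data.table::data.table(peptide = extra$peptide,
                                  term = extra$ancestor)
  unique(rbind(direct, extra))
}

#' One-sided Fisher over-representation test per term
#'
#' For every annotated term, tests over-representation of the term in the
#' study set against the reference via the hypergeometric upper tail of the
#' 2x2 table (study-with-term, study-without, rest-with, rest-without).
#' With `mode = "elim"`, terms are processed leaves-first and the study and
#' reference members of any term reaching `elim_cutoff` are removed from
#' its ancestors before those are tested (a decorrelation of nested terms).
#'
#' @param study Character vector of study peptides (must be a subset of
#'   `reference`).
#' @param reference Character vector of reference (background) peptides.
#' @param annotations Propagated annotation table (peptide, term).
#' @param onto Optional [ontology()]; required for `mode = "elim"` and for
#'   namespace filtering.
#' @param mode `"classic"` (default) or `"elim"`.
#' @param elim_cutoff Significance threshold used by the elim pass.
#' @param namespace Optional namespace filter (e.g.
#'   `"biological_process"`); requires `onto`.
#' @return `data.table` with `term`, `study_count`, `ref_count`, `p_value`
#'   and a list-column `members` (study peptides carrying the term),
#'   ordered by increasing p.
#' @export
fisher_enrichment <- function(study, reference, annotations, onto = NULL,
                              mode = c("classic", "elim"),
                              elim_cutoff = 0.01, namespace = NULL) {
  mode <- match.arg(mode)
  study <- unique(as.character(study))
  reference <- unique(as.character(reference))
  if (length(study) == 0) stop("empty study set")
  if (!all(study %in% reference))
    stop("study set must be a subset of the reference set")
  ann <- data.table::as.data.table(annotations)
  ann <- ann[ann$peptide %in% reference]
  if (!is.null(namespace)) {
    if (is.null(onto)) stop("namespace filtering requires an ontology")
    keep <- onto$terms$id[onto$terms$namespace == namespace]
    ann <- ann[ann$term %in% keep]
  }
  terms <- unique(ann$term)
  members_of <- split(ann$peptide, ann$term)
  n_ref <- length(reference)
  n_study <- length(study)

  test_term <- function(ref_members, study_members) {
    fisher_overrep_p(length(study_members), length(ref_members),
                     n_study, n_ref)
  }

  if (mode == "classic") {
    res <- lapply(terms, function(t) {
      rm_ <- unique(members_of[[t]])
      sm <- intersect(rm_, study)
      data.table::data.table(term = t, study_count = length(sm),
                             ref_count = length(rm_),
                             p_value = test_term(rm_, sm),
                             members = list(sort(sm)))
    })
  } else {
    if (is.null(onto)) stop("elim mode requires an ontology")
    anc <- term_ancestors(onto)
    depth <- vapply(terms, function(t) length(anc[[t]]), integer(1))
    removed <- stats::setNames(vector("list", length(terms)), terms)
    res <- list()
    for (t in terms[order(-depth)]) {
      rm_ <- setdiff(unique(members_of[[t]]), removed[[t]])
      sm <- intersect(rm_, study)
      p <- test_term(rm_, sm)
      res[[t]] <- data.table::data.table(term = t, study_count = length(sm),
                                         ref_count = length(rm_),
                                         p_value = p, members = list(sort(sm)))
      if (p < elim_cutoff) {
        for (a in intersect(anc[[t]], terms))
          removed[[a]] <- union(removed[[a]], unique(members_of[[t]]))
      }
    }
  }
  out <- data.table::rbindlist(res)
  out[order(out$p_value, out$term)]
}

#' One-sided over-representation p-value for a single 2x2 table
#'
#' Upper hypergeometric tail P(X >= a) for a study set of size `n` drawn
#' from a reference of size `N` in which `K` members carry the term and
#' `a` of the study members do. This is the per-term statistic used by
#' [fisher_enrichment()].
#'
#' @param a Study members carrying the term.
#' @param K Reference members carrying the term.
#' @param n Study-set size.
#' @param N Reference-set size.
#' @return p-value in (0, 1], vectorized.
#' @export
fisher_overrep_p <- function(a, K, n, N) {
  if (any(a > pmin(K, n)) || any(K > N) || any(n > N))
    stop("inconsistent 2x2 table margins")
  stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

#' Remove redundant terms with identical peptide lists
#'
#' Among terms annotating exactly the same study peptides, only the term
#' with the lowest p-value is kept (ties: lexicographically smallest term
#' id). Terms with distinct member lists pass through in stable order.
#'
#' @param results A [fisher_enrichment()] table (with `members`).
#' @return Filtered `data.table`.
#' @export
deduplicate_terms <- function(results) {
  if (nrow(results) == 0) return(results)
  key <- vapply(results$members,
                function(m) paste(sort(m), collapse = "\r"), character(1))
  keep <- logical(nrow(results))
  for (k in unique(key)) {
    idx <- which(key == k)
    best <- idx[order(results$p_value[idx], results$term[idx])][1]
    keep[best] <- TRUE
  }
  results[keep]
}

#' Rank enriched terms by contrast-group presence for heat-map display
#'
#' For each term, averages the binary presence of its member peptides per
#' organism, then per group; terms are sorted ascending by the
#' contrast-group average (terms whose members are most absent from the
#' contrast group come first) and the top `top_n` are returned.
#'
#' @param results A [fisher_enrichment()] (possibly deduplicated) table.
#' @param pm A [build_presence_matrix()] result covering all member
#'   peptides.
#' @param top_n Rows to return (default 25).
#' @param contrast_group Group whose average drives the sort (default
#'   `"nonphagocyte"`, the ordering used for phagocyte-enriched sets).
#' @return `data.table` with term, p_value, per-organism mean presence
#'   columns, and `phagocyte_mean` / `nonphagocyte_mean`.
#' @export
rank_terms_by_group_presence <- function(results, pm, top_n = 25,
                                         contrast_group = c("nonphagocyte",
                                                            "phagocyte")) {
  contrast_group <- match.arg(contrast_group)
  missing <- setdiff(unique(unlist(results$members)), rownames(pm$mat))
  if (length(missing))
    stop("member peptides absent from presence matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  orgs <- colnames(pm$mat)
  ph <- pm$panel$organism[pm$panel$group == "phagocyte"]
  np <- pm$panel$organism[pm$panel$group == "nonphagocyte"]
  rows <- lapply(seq_len(nrow(results)), function(i) {
    m <- results$members[[i]]
    means <- colMeans(pm$mat[m, , drop = FALSE])
    dt <- data.table::as.data.table(as.list(means))
    dt <- cbind(data.table::data.table(term = results$term[i],
                                       p_value = results$p_value[i]), dt)
    dt$phagocyte_mean <- mean(means[ph])
    dt$nonphagocyte_mean <- mean(means[np])
    dt
  })
  tab <- data.table::rbindlist(rows)
  sortcol <- paste0(contrast_group, "_mean")
  tab <- tab[order(tab[[sortcol]], tab$p_value)]
  utils::head(tab, top_n)
}

#' Synthetic ontology and annotation fixtures
#'
#' Builds a rooted is_a DAG of the requested depth, annotates peptides to
#' terms, plants one enriched term covering `planted_coverage` of the study
#' set but only `background_rate` of the rest of the reference, and plants
#' one exact duplicate term (identical annotated peptides) to exercise
#' redundancy elimination.
#'
#' @param n_terms Number of terms excluding root and the planted duplicate.
#' @param dag_depth Maximum is_a depth (>= 1).
#' @param seed Integer seed.
#' @param n_peptides Reference-set size (ignored when `peptides` is given).
#' @param study_fraction Fraction of peptides forming the study set
#'   (ignored when `study` is given).
#' @param planted_coverage,background_rate Annotation rates of the planted
#'   term inside / outside the study set.
#' @param peptides Optional explicit reference peptide ids.
#' @param study Optional explicit study subset of `peptides`.
#' @return List with `ontology`, `annotations` (direct, unpropagated),
#'   `study`, `reference`, and `truth` (planted and duplicate term ids).
#' @export
generate_go_fixtures <- function(n_terms = 30, dag_depth = 3, seed = 1L,
                                 n_peptides = 500, study_fraction = 0.1,
                                 planted_coverage = 0.8,
                                 background_rate = 0.1,
                                 peptides = NULL, study = NULL) {
  stopifnot(dag_depth >= 1, n_terms >= 3)
  set.seed(seed)
  if (is.null(peptides)) peptides <- sprintf("pep%05d", seq_len(n_peptides))
  if (is.null(study)) {
    study <- sample(peptides, max(2, round(study_fraction * length(peptides))))
  } else {
    stopifnot(all(study %in% peptides))
  }

  ids <- c("GO:0000001", sprintf("GO:%07d", seq_len(n_terms) + 1))
  level <- c(0, sample(seq_len(dag_depth), n_terms, replace = TRUE))
  terms <- data.table::data.table(
    id = ids, name = c("root", sprintf("term %d", seq_len(n_terms) + 1)),
    namespace = "biological_process")
  edges <- data.table::rbindlist(lapply(2:length(ids), function(i) {
    shallower <- which(level < level[i])
    parents <- ids[sample(shallower, min(length(shallower),
                                         sample(1:2, 1)))]
    data.table::data.table(child = ids[i], parent = parents)
  }))

  planted <- ids[which(level == max(level))[1]]
  in_study <- sample(study, round(planted_coverage * length(study)))
  outside <- setdiff(peptides, study)
  in_bg <- sample(outside, round(background_rate * length(outside)))
  rows <- list(data.table::data.table(peptide = c(in_study, in_bg),
                                      term = planted))
  for (t in setdiff(ids[-1], planted)) {
    n_ann <- sample(5:30, 1)
    rows[[t]] <- data.table::data.table(peptide = sample(peptides, n_ann),
                                        term = t)
  }
  ann <- unique(data.table::rbindlist(rows))

  # duplicate term: same parents and identical annotated peptides as planted
  dup <- "GO:0999999"
  terms <- rbind(terms, data.table::data.table(
    id = dup, name = "planted duplicate", namespace = "biological_process"))
  edges <- rbind(edges, data.table::data.table(
    child = dup, parent = edges$parent[edges$child == planted]))
  ann <- rbind(ann, data.table::data.table(
    peptide = ann$peptide[ann$term == planted], term = dup))

  list(ontology = ontology(terms, edges), annotations = ann,
       study = sort(study), reference = peptides,
       truth = list(planted_term = planted, duplicate_term = dup))
}

#' Write / read an OBO-lite ontology (id, name, namespace, is_a only)
#' @param onto An [ontology()].
#' @param path File path.
#' @export
write_obo_lite <- function(onto, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(onto$terms))) {
    id <- onto$terms$id[i]
    writeLines(c("", "[Term]",
                 paste0("id: ", id),
                 paste0("name: ", onto$terms$name[i]),
                 paste0("namespace: ", onto$terms$namespace[i]),
                 paste0("is_a: ", onto$edges$parent[onto$edges$child == id],
                        recycle0 = TRUE)),
               con)
  }
  invisible(path)
}

#' @rdname write_obo_lite
#' @export
read_obo_lite <- function(path) {
  lines <- readLines(path)
  blocks <- split(lines, cumsum(lines == "[Term]"))
  blocks <- blocks[names(blocks) != "0"]
  field <- function(b, key) sub(paste0("^", key, ": "), "",
                                grep(paste0("^", key, ": "), b, value = TRUE))
  terms <- data.table::rbindlist(lapply(blocks, function(b)
    data.table::data.table(id = field(b, "id"), name = field(b, "name"),
                           namespace = field(b, "namespace"))))
  edges <- data.table::rbindlist(lapply(blocks, function(b) {
    parents <- field(b, "is_a")
    if (length(parents) == 0) return(NULL)
    data.table::data.table(child = field(b, "id"), parent = parents)
  }))
  ontology(terms, edges)
}
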