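chain_ontology <- function() {
  # root <- t1 <- t2 <- t3 plus a side leaf
  ontology(
    terms = data.frame(id = c("GO:1", "GO:2", "GO:3", "GO:4", "GO:5"),
                       name = paste("t", 1:5),
                       namespace = "biological_process"),
    edges = data.frame(child = c("GO:2", "GO:3", "GO:4", "GO:5"),
                       parent = c("GO:1", "GO:2", "GO:3", "GO:1")))
}

test_that("ontology construction rejects cycles and unknown terms", {
  expect_error(ontology(
    data.frame(id = c("a", "b"), name = c("a", "b"), namespace = "bp"),
    data.frame(child = c("a", "b"), parent = c("b", "a"))), "cycle")
  expect_error(ontology(
    data.frame(id = "a", name = "a", namespace = "bp"),
    data.frame(child = "a", parent = "zzz")), "unknown")
})

test_that("propagation climbs the full parent chain and is idempotent", {
  onto <- chain_ontology()
  ann <- data.frame(peptide = "p1", term = "GO:4")
  prop <- propagate_annotations(ann, onto)
  expect_setequal(prop$term, c("GO:4", "GO:3", "GO:2", "GO:1"))
  expect_equal(nrow(propagate_annotations(prop, onto)), nrow(prop))
})

test_that("propagation equals a naive transitive-closure oracle on random DAGs", {
  for (seed in c(2, 5)) {
    fx <- generate_go_fixtures(n_terms = 20, dag_depth = 4, seed = seed,
                               n_peptides = 60)
    prop <- propagate_annotations(fx$annotations, fx$ontology)
    oracle <- naive_propagate(as.data.frame(fx$annotations),
                              as.data.frame(fx$ontology$edges))
    key <- function(d) sort(paste(d$peptide, d$term))
    expect_identical(key(as.data.frame(prop)), key(oracle))
  }
})

test_that("over-representation p-values match closed-form and fisher.test", {
  # frozen worked case: study 10 with 5 hits, reference 100 with 10 hits
  expect_equal(fisher_overrep_p(5, 10, 10, 100), 6.716277e-4,
               tolerance = 1e-6)
  expect_equal(fisher_overrep_p(5, 10, 10, 100),
               naive_overrep_p(5, 10, 10, 100), tolerance = 1e-12)
  expect_equal(fisher_overrep_p(5, 10, 10, 100),
               fisher.test(matrix(c(5, 5, 5, 85), 2),
                           alternative = "greater")$p.value,
               tolerance = 1e-9)
  set.seed(8)
  for (i in 1:50) {
    N <- sample(5:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    a <- sample(max(0, K + n - N):min(K, n), 1)
    expect_equal(fisher_overrep_p(a, K, n, N), naive_overrep_p(a, K, n, N),
                 tolerance = 1e-12, label = sprintf("a=%d K=%d n=%d N=%d", a, K, n, N))
  }
  expect_error(fisher_overrep_p(5, 3, 4, 100), "margins")
})

test_that("fisher_enrichment handles degenerate and invalid inputs", {
  onto <- chain_ontology()
  reference <- sprintf("p%02d", 1:20)
  ann <- data.frame(peptide = reference, term = "GO:1")  # annotates everything
  res <- fisher_enrichment(reference[1:5], reference, ann, onto)
  expect_equal(res$p_value, 1)                   # no enrichment possible
  expect_error(fisher_enrichment(character(0), reference, ann), "empty")
  expect_error(fisher_enrichment(c("zz"), reference, ann), "subset")
})

test_that("elim mode removes significant descendants' genes from ancestors", {
  onto <- chain_ontology()
  reference <- sprintf("p%02d", 1:40)
  study <- reference[1:10]
  # leaf GO:4 strongly enriched; its genes also annotate ancestors
  ann <- rbind(data.frame(peptide = reference[1:9], term = "GO:4"),
               data.frame(peptide = reference[c(1:9, 30:35)], term = "GO:3"))
  prop <- propagate_annotations(ann, onto)
  classic <- fisher_enrichment(study, reference, prop, onto, mode = "classic")
  elim <- fisher_enrichment(study, reference, prop, onto, mode = "elim")
  p3c <- classic$p_value[classic$term == "GO:3"]
  p3e <- elim$p_value[elim$term == "GO:3"]
  expect_lt(classic$p_value[classic$term == "GO:4"], 0.01)
  expect_gt(p3e, p3c)    # ancestor de-correlated once the leaf absorbed its genes
})

test_that("identical-member terms collapse onto the lowest-p representative", {
  res <- data.table::data.table(
    term = c("GO:b", "GO:a", "GO:c", "GO:d"),
    study_count = c(3, 3, 3, 2), ref_count = c(5, 5, 5, 9),
    p_value = c(0.01, 0.04, 0.01, 0.2),
    members = list(c("p1", "p2", "p3"), c("p3", "p2", "p1"),
                   c("p2", "p1", "p3"), c("p1", "p9")))
  out <- deduplicate_terms(res)
  expect_setequal(out$term, c("GO:b", "GO:d"))   # tie 0.01: lexicographic GO:b
  distinct <- res[4]
  expect_identical(deduplicate_terms(distinct)$term, "GO:d")
})

test_that("dedup never removes the minimum-p member of an identical-list class", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    members <- replicate(n, sort(sample(letters, sample(2:5, 1))),
                         simplify = FALSE)
    dup_idx <- sample(n, 2)
    members[[dup_idx[2]]] <- members[[dup_idx[1]]]
    res <- data.table::data.table(term = sprintf("GO:%03d", sample(1:999, n)),
                                  study_count = 1, ref_count = 2,
                                  p_value = runif(n), members = members)
    out <- deduplicate_terms(res)
    key <- vapply(res$members, paste, character(1), collapse = "|")
    for (k in unique(key)) {
      grp <- res[key == k]
      best <- grp$term[order(grp$p_value, grp$term)][1]
      expect_true(best %in% out$term)
    }
  }
})

test_that("group-presence ranking matches hand arithmetic and sort order", {
  panel <- organism_panel(c("PH1", "PH2", "NP1", "NP2"),
                          c("phagocyte", "phagocyte",
                            "nonphagocyte", "nonphagocyte"))
  mat <- matrix(c(1, 1, 0, 0,
                  1, 0, 1, 0,
                  1, 1, 1, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("p1", "p2", "p3"),
                                c("PH1", "PH2", "NP1", "NP2")))
  pm <- structure(list(mat = mat, panel = panel,
                       s_phag = rowSums(mat[, 1:2]),
                       s_nonphag = rowSums(mat[, 3:4])),
                  class = "presence_matrix")
  res <- data.table::data.table(
    term = c("GO:x", "GO:y"), study_count = c(2, 1), ref_count = c(2, 1),
    p_value = c(0.02, 0.01),
    members = list(c("p1", "p2"), "p3"))
  ranked <- rank_terms_by_group_presence(res, pm, top_n = 25)
  # GO:x members p1,p2: nonphag means (0.5, 0) -> group mean 0.25; GO:y -> 1
  expect_identical(ranked$term, c("GO:x", "GO:y"))
  expect_equal(ranked$nonphagocyte_mean, c(0.25, 1))
  expect_equal(ranked$phagocyte_mean, c(0.75, 1))
  expect_equal(unname(unlist(ranked[1, c("PH1", "PH2", "NP1", "NP2")])),
               c(1, 0.5, 0.5, 0))
  # a term absent everywhere in the contrast group ranks first
  expect_error(rank_terms_by_group_presence(
    data.table::data.table(term = "GO:z", study_count = 1, ref_count = 1,
                           p_value = 0.5, members = list("nope")), pm),
    "absent from presence matrix")
})

test_that("go fixtures plant an enriched term, a duplicate pair, and reproduce", {
  fx <- generate_go_fixtures(seed = 17)
  expect_true(fx$truth$planted_term %in% fx$ontology$terms$id)
  m1 <- sort(fx$annotations$peptide[fx$annotations$term == fx$truth$planted_term])
  m2 <- sort(fx$annotations$peptide[fx$annotations$term == fx$truth$duplicate_term])
  expect_identical(m1, m2)
  fx2 <- generate_go_fixtures(seed = 17)
  expect_identical(as.data.frame(fx$annotations), as.data.frame(fx2$annotations))
  # depth-1 ontology is a star: propagation only adds the root
  star <- generate_go_fixtures(n_terms = 10, dag_depth = 1, seed = 3,
                               n_peptides = 50)
  prop <- propagate_annotations(star$annotations, star$ontology)
  added <- setdiff(paste(prop$peptide, prop$term),
                   paste(star$annotations$peptide, star$annotations$term))
  expect_true(all(grepl("GO:0000001$", added)))
})

test_that("OBO-lite round-trips terms, namespaces and is_a edges", {
  fx <- generate_go_fixtures(n_terms = 12, dag_depth = 3, seed = 23,
                             n_peptides = 30)
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo_lite(fx$ontology, path)
  back <- read_obo_lite(path)
  expect_setequal(back$terms$id, fx$ontology$terms$id)
  key <- function(e) sort(paste(e$child, e$parent))
  expect_identical(key(as.data.frame(back$edges)),
                   key(as.data.frame(fx$ontology$edges)))
})
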