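mini_panel <- function() {
  organism_panel(c(sprintf("PH%d", 1:7), sprintf("NP%d", 1:6)),
                 rep(c("phagocyte", "nonphagocyte"), c(7, 6)))
}

test_that("presence matrix entries are idempotent and keep all-zero rows", {
  panel <- mini_panel()
  hits <- data.frame(qseqid = c("p1", "p1", "p1", "p2"),
                     organism = c("PH1", "PH1", "NP2", "PH3"),
                     sseqid = c("PH1|a", "PH1|b", "NP2|c", "PH3|d"))
  pm <- build_presence_matrix(hits, panel, peptides = c("p1", "p2", "p3"))
  expect_equal(pm$mat["p1", "PH1"], 1L)       # two hits, still 1
  expect_equal(sum(pm$mat["p3", ]), 0)        # no hits -> zero row
  expect_equal(unname(pm$s_phag), c(1, 1, 0))
  expect_equal(unname(pm$s_nonphag), c(1, 0, 0))
  expect_error(build_presence_matrix(
    data.frame(qseqid = "p1", organism = "XX", sseqid = "XX|a"), panel),
    "outside the panel")
})

test_that("peptides present in all seven phagocytes score 7", {
  panel <- mini_panel()
  hits <- data.frame(qseqid = "p1", organism = panel$organism,
                     sseqid = paste0(panel$organism, "|g1"))
  pm <- build_presence_matrix(hits, panel)
  expect_equal(unname(pm$s_phag), 7)
  expect_equal(unname(pm$s_nonphag), 6)
})

test_that("select_set honors both criterion bounds", {
  panel <- mini_panel()
  hits <- data.frame(qseqid = rep("p1", 13), organism = panel$organism,
                     sseqid = paste0(panel$organism, "|x"))
  pm <- build_presence_matrix(hits, panel, peptides = c("p1", "p2"))
  expect_identical(select_set(pm, 7, 6), character(0))  # all-ones row fails m
  expect_setequal(select_set(pm, 0, 0), c("p1", "p2"))
  expect_identical(select_set(pm, 7, 0), "p1")
  expect_error(select_set(pm, 8, 0), "k_min")
})

test_that("set size is monotone in criterion stringency", {
  inst <- random_instance(101)
  for (k in 0:6) {
    a <- length(select_set(inst$pm, k, 2))
    b <- length(select_set(inst$pm, k + 1, 2))
    expect_lte(b, a)
  }
  for (m in 0:5) {
    a <- length(select_set(inst$pm, 3, m))
    b <- length(select_set(inst$pm, 3, m + 1))
    expect_lte(b, a)
  }
})

test_that("penalty satisfies its anchor, growth and clamp properties", {
  for (form in c("linear", "exp")) {
    expect_equal(penalty(4305, 4305, 30, form), 0)
    expect_equal(penalty(1, 4305, 30, form), 100)
    s <- c(4305, 2000, 1000, 300, 100, 30)
    expect_true(all(diff(penalty(s, 4305, 30, form)) >= 0))
    up <- c(4305, 6000, 10000, 40000)
    expect_true(all(diff(penalty(up, 4305, 30, form)) >= 0))
  }
  expect_equal(penalty(30, 4305, 30, form = "exp"), 99)
  expect_equal(penalty(30, 4305, 30, form = "linear"), 100)
  expect_error(penalty(0, 4305), ">= 1")
  expect_error(penalty(100, 1), "B")
})

test_that("wps matches its formula and is bounded by 100", {
  B <- 4305
  expect_equal(wps(B, B, B, form = "exp"), 100)
  expect_equal(wps(B, B, B, form = "linear"), 100)
  expect_equal(wps(B, 0, B, form = "exp"), 0)
  expect_equal(wps(400, 200, B, 30, form = "exp"), 42.31959,
               tolerance = 1e-6)
  expect_equal(wps(1, 1, B, form = "exp"), 0.0232288, tolerance = 1e-6)
  set.seed(1)
  s <- sample(1:8000, 500, TRUE)
  k <- floor(runif(500) * pmin(s, B))
  for (form in c("linear", "exp"))
    expect_true(all(wps(s, k, B, 30, form) <= 100 + 1e-12))
  expect_error(wps(10, 11, B), "k_ph")
})

test_that("ds follows its formula and sign convention", {
  expect_equal(ds(50, 50), 0)
  expect_equal(ds(100, 0), 100)
  expect_equal(ds(50, 80), -15)
  expect_error(ds(Inf, 0), "finite")
})

test_that("criterion mirroring applies equal relaxation across group sizes", {
  expect_equal(unname(mirror_criterion(6, 3, 7, 6)), c(5, 3))
  expect_equal(unname(mirror_criterion(7, 3, 7, 6)), c(6, 3))
  expect_equal(unname(mirror_criterion(0, 6, 7, 6)), c(0, 6))
  expect_equal(unname(mirror_criterion(5, 3, 6, 7)), c(6, 3))
})

test_that("optimizer equals exhaustive naive recomputation on a small instance", {
  inst <- random_instance(7)
  for (form in c("linear", "exp")) {
    opt <- optimize_grouping(inst$pm, inst$reference, form = form)
    oracle <- naive_score_surface(inst$pm$mat, inst$groups, inst$flagged,
                                  inst$reference$B, form = form)
    for (dir in c("phagocyte", "nonphagocyte")) {
      sub <- opt$surface[opt$surface$direction == dir, ]
      for (i in seq_len(nrow(sub))) {
        o <- oracle[[dir]][[paste(sub$k_min[i], sub$m_min[i])]]
        expect_equal(sub$s[i], o$s)
        if (o$s > 0) {
          expect_equal(sub$wps[i], o$wps, tolerance = 1e-10)
          expect_equal(sub$ds[i], o$ds, tolerance = 1e-10)
        } else {
          expect_true(is.na(sub$ds[i]))
        }
      }
    }
  }
})

test_that("swapping group labels swaps the two directions' score tables", {
  inst <- random_instance(19)
  swapped_groups <- ifelse(inst$groups == "phagocyte",
                           "nonphagocyte", "phagocyte")
  panel2 <- organism_panel(inst$pm$panel$organism, swapped_groups)
  pm2 <- list(mat = inst$pm$mat, panel = panel2,
              s_phag = inst$pm$s_nonphag, s_nonphag = inst$pm$s_phag)
  class(pm2) <- "presence_matrix"
  o1 <- optimize_grouping(inst$pm, inst$reference)
  o2 <- optimize_grouping(pm2, inst$reference)
  a <- o1$surface[o1$surface$direction == "phagocyte",
                  c("k_min", "m_min", "s", "k_ph", "wps", "ds")]
  b <- o2$surface[o2$surface$direction == "nonphagocyte",
                  c("k_min", "m_min", "s", "k_ph", "wps", "ds")]
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("single-peptide reference set scores as the formulas dictate", {
  panel <- mini_panel()
  hits <- data.frame(qseqid = "p1", organism = panel$organism,
                     sseqid = paste0(panel$organism, "|g1"))
  pm <- build_presence_matrix(hits, panel)
  # B must exceed 1 for the log-scale penalty; use a 2-member reference
  ref <- structure(list(flagged = c("p1", "pX"), B = 2),
                   class = "phagosome_reference")
  opt <- optimize_grouping(pm, ref, min_size = 1, form = "exp")
  cell <- opt$surface[opt$surface$direction == "phagocyte" &
                      opt$surface$k_min == 7 & opt$surface$m_min == 0, ]
  expect_equal(cell$s, 1L)
  expect_equal(cell$wps, wps(1, 1, 2, 1, form = "exp"))
})

test_that("phagosome reference union and flagging follow the hits", {
  src <- data.frame(organism = c("A", "A", "A", "B", "B", "B"),
                    protein_id = c("A|1", "A|2", "A|3", "B|4", "B|5", "B|6"))
  hits <- data.frame(qseqid = c("p1", "p2"), sseqid = c("A|1", "C|9"),
                     organism = c("A", "C"))
  ref <- build_phagosome_reference(src, hits)
  expect_equal(ref$U, 6)                      # disjoint lists union
  expect_identical(ref$flagged, "p1")
  expect_equal(ref$B, 1)
  dup <- data.frame(organism = c("A", "B"), protein_id = c("A|1", "A|1"))
  expect_equal(build_phagosome_reference(dup, hits)$U, 1)  # identical lists
  expect_error(build_phagosome_reference(src[0, ], hits), "empty")
})
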