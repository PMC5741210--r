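# Independent, deliberately naive re-implementations used as oracles.
# These transcribe the formulas directly and never share code with the
# package internals they check.

naive_penalty <- function(s, B, min_size = 30, form = "linear") {
  x <- abs(log(s / B) / log(B))          # |log_B(s/B)|
  d <- abs(log(min_size / B) / log(B))   # |log_B(min/B)|
  p <- if (form == "exp") 100^(x / d) - 1 else 100 * x / d
  min(max(p, 0), 100)
}

naive_wps <- function(s, k_ph, B, min_size = 30, form = "linear") {
  100 * k_ph / s - naive_penalty(s, B, min_size, form) * (1 - k_ph / B)
}

naive_ds <- function(wf, wc) wf * (wf - wc) / 100

# Cell-by-cell recomputation of the full two-direction score surface with
# explicit loops, following the documented conventions: empty focal cell
# unscored; contrast wps taken at the relaxation-mirrored cell, floored at 0.
naive_score_surface <- function(mat, groups, flagged, B, min_size = 30,
                                form = "linear") {
  ph <- which(groups == "phagocyte")
  np <- which(groups == "nonphagocyte")
  P <- length(ph); N <- length(np)
  cell <- function(k, m, focal_cols, contrast_cols) {
    CS <- length(contrast_cols)
    sel <- character(0)
    for (pep in rownames(mat)) {
      fsc <- sum(mat[pep, focal_cols])
      csc <- sum(mat[pep, contrast_cols])
      if (fsc >= k && (CS - csc) >= m) sel <- c(sel, pep)
    }
    s <- length(sel)
    if (s == 0) return(list(s = 0, wps = NA_real_))
    k_ph <- sum(sel %in% flagged)
    list(s = s, k_ph = k_ph,
         wps = naive_wps(s, k_ph, B, min_size, form))
  }
  dir_tab <- function(focal_cols, contrast_cols) {
    FS <- length(focal_cols); CS <- length(contrast_cols)
    out <- list()
    for (k in 0:FS) for (m in 0:CS)
      out[[paste(k, m)]] <- c(list(k_min = k, m_min = m),
                              cell(k, m, focal_cols, contrast_cols))
    out
  }
  tab_ph <- dir_tab(ph, np)
  tab_np <- dir_tab(np, ph)
  add_ds <- function(tab, other, FS, CS) {
    for (nm in names(tab)) {
      k <- tab[[nm]]$k_min; m <- tab[[nm]]$m_min
      km <- min(max(k - (FS - CS), 0), CS)
      mm <- min(max(m, 0), FS)
      wc <- other[[paste(km, mm)]]$wps
      if (is.null(wc) || is.na(wc) || wc < 0) wc <- 0
      wf <- tab[[nm]]$wps
      tab[[nm]]$ds <- if (is.na(wf)) NA_real_ else naive_ds(wf, wc)
    }
    tab
  }
  list(phagocyte = add_ds(tab_ph, tab_np, P, N),
       nonphagocyte = add_ds(tab_np, tab_ph, N, P))
}

# Closed-form hypergeometric upper tail by direct summation.
naive_overrep_p <- function(a, K, n, N) {
  hi <- min(K, n)
  if (a > hi) return(0)
  sum(choose(K, a:hi) * choose(N - K, n - (a:hi))) / choose(N, n)
}

# Transitive-closure propagation by iterated parent expansion.
naive_propagate <- function(ann, edges) {
  res <- unique(ann[, c("peptide", "term")])
  repeat {
    step <- merge(res, edges, by.x = "term", by.y = "child")
    step <- unique(data.frame(peptide = step$peptide, term = step$parent))
    new <- rbind(res, step)
    new <- unique(new)
    if (nrow(new) == nrow(res)) return(res)
    res <- new
  }
}

# Small random presence-matrix instance for optimizer checks.
random_instance <- function(seed, n_pep = 100, P = 7, N = 6) {
  set.seed(seed)
  peptides <- sprintf("p%03d", seq_len(n_pep))
  orgs <- c(sprintf("PH%d", seq_len(P)), sprintf("NP%d", seq_len(N)))
  groups <- rep(c("phagocyte", "nonphagocyte"), c(P, N))
  mat <- matrix(rbinom(n_pep * (P + N), 1, runif(1, 0.3, 0.7)),
                nrow = n_pep, dimnames = list(peptides, orgs))
  flagged <- sample(peptides, round(n_pep * runif(1, 0.4, 0.6)))
  panel <- organism_panel(orgs, groups)
  pm <- list(mat = mat, panel = panel,
             s_phag = rowSums(mat[, groups == "phagocyte", drop = FALSE]),
             s_nonphag = rowSums(mat[, groups == "nonphagocyte", drop = FALSE]))
  class(pm) <- "presence_matrix"
  list(pm = pm, groups = groups, flagged = flagged,
       reference = structure(list(flagged = flagged, B = length(flagged)),
                             class = "phagosome_reference"))
}

# 20-hit boundary fixture with hand-derived retention labels under the
# comparison profile (e-value <= 1e-4, HSSP distance strictly > 5).
# Identity thresholds used for the labels: 19.5 at the long plateau,
# 28.98313 at L=100, 41.72685 at L=50 (frozen independent evaluations).
boundary_fixture <- function() {
  data.frame(
    pident = c(25.5, 24.5, 24.51, 24.49, 60, 60, 60, 16, 100, 24.6,
               24.4, 35, 33.9, 34.0, 29, 45, 47, 90, 50, 70),
    length = c(1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000, 451, 451,
               451, 100, 100, 100, 100, 50, 50, 30, 30, 2000),
    evalue = c(1e-5, 1e-20, 1e-6, 1e-6, 1e-4, 1.01e-4, 1e-3, 1e-30, 1e-10,
               1e-10, 1e-10, 1e-8, 1e-8, 1e-8, 1e-8, 1e-6, 1e-6, 1e-5,
               1e-5, 5e-5),
    expected = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE,
                 TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE,
                 FALSE, TRUE))
}
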