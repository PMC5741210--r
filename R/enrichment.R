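#' Set-size penalty
#'
#' Penalizes candidate sets whose size s deviates from the phagosome-homolog
#' reference count B, on a log scale anchored so that a set of size
#' `min_size` is maximally penalized. Two readings of the penalty are
#' implemented, both 0 at s = B, growing with |log_B(s/B)| and clamped to
#' \[0, 100\]:
#'
#' * `"linear"` (default): `100 * |log_B(s/B)| / |log_B(min_size/B)|` — a
#'   uniform restoring gradient in log-size space on both sides of B.
#' * `"exp"`: `100^(|log_B(s/B)| / |log_B(min_size/B)|) - 1` — flat near B
#'   and steep far from it; at s = min_size it evaluates to 99.
#'
#' @param s Set size(s), all >= 1.
#' @param B Reference count (> 1).
#' @param min_size Penalty anchor (1 <= min_size < B), default 30.
#' @param form `"linear"` or `"exp"`.
#' @return Penalty in \[0, 100\], vectorized over `s`.
#' @export
penalty <- function(s, B, min_size = 30, form = c("linear", "exp")) {
  form <- match.arg(form)
  if (any(s < 1)) stop("set size must be >= 1")
  if (B <= 1) stop("reference count B must be > 1")
  if (min_size < 1 || min_size >= B) stop("need 1 <= min_size < B")
  num <- abs(log(s / B))
  den <- abs(log(min_size / B))
  p <- switch(form,
              linear = 100 * num / den,
              exp = 100^(num / den) - 1)
  pmin(pmax(p, 0), 100)
}

#' Weighted proportion score (wps)
#'
#' The percentage of a candidate set found in the phagosome reference,
#' discounted by the set-size [penalty()] weighted by the share of the
#' reference the set fails to recover:
#' `wps = 100 * k_ph / s - penalty(s) * (1 - k_ph / B)`.
#' The score never exceeds 100, attained only by a full-proportion set with
#' a vanishing penalty term.
#'
#' @param s Set size(s) (>= 1).
#' @param k_ph Number of set members in the reference (0 <= k_ph <= min(s, B)).
#' @param B Reference count.
#' @param min_size Penalty anchor, default 30.
#' @param form Penalty form, see [penalty()].
#' @return Numeric vector of scores, each <= 100.
#' @export
wps <- function(s, k_ph, B, min_size = 30, form = c("linear", "exp")) {
  if (any(k_ph < 0) || any(k_ph > pmin(s, B)))
    stop("need 0 <= k_ph <= min(s, B)")
  100 * k_ph / s - penalty(s, B, min_size, form) * (1 - k_ph / B)
}

#' Distance score (ds)
#'
#' Signal-to-noise of a grouping criterion: the focal-direction wps scaled
#' by its margin over the contrast direction,
#' `ds = wps_focal * (wps_focal - wps_contrast) / 100`.
#' Its sign follows the margin only when `wps_focal > 0`; the optimizer
#' therefore never selects criteria with a non-positive focal score.
#'
#' @param wps_focal,wps_contrast Finite weighted proportion scores.
#' @return Numeric vector.
#' @export
ds <- function(wps_focal, wps_contrast) {
  if (any(!is.finite(wps_focal)) || any(!is.finite(wps_contrast)))
    stop("wps inputs must be finite")
  wps_focal * (wps_focal - wps_contrast) / 100
}

#' Mirror a grouping criterion into the contrast direction
#'
#' The control analysis applies the same relaxation in the opposite
#' direction: a focal criterion "present in at least (FS - a) of FS focal
#' genomes, absent from at least m contrast genomes" maps to "present in at
#' least (CS - a) of CS contrast genomes, absent from at least m focal
#' genomes". With groups of 7 and 6 this pairs (k=6, m=3) with (k=5, m=3).
#'
#' @param k_min,m_min Focal criterion.
#' @param focal_size,contrast_size Group sizes.
#' @return `c(k_min, m_min)` for the mirrored direction.
#' @export
mirror_criterion <- function(k_min, m_min, focal_size, contrast_size) {
  k <- min(max(k_min - (focal_size - contrast_size), 0), contrast_size)
  m <- min(max(m_min, 0), focal_size)
  c(k_min = k, m_min = m)
}

score_one_direction <- function(pm, reference, focal, min_size, form) {
  P <- sum(pm$panel$group == "phagocyte")
  N <- sum(pm$panel$group == "nonphagocyte")
  FS <- if (focal == "phagocyte") P else N
  CS <- if (focal == "phagocyte") N else P
  flagged <- rownames(pm$mat) %in% reference$flagged
  fs <- if (focal == "phagocyte") pm$s_phag else pm$s_nonphag
  cs <- if (focal == "phagocyte") pm$s_nonphag else pm$s_phag
  grid <- expand.grid(k_min = 0:FS, m_min = 0:CS)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- fs >= grid$k_min[i] & (CS - cs) >= grid$m_min[i]
    s <- sum(sel)
    if (s == 0)
      return(list(s = 0L, k_ph = 0L, proportion = NA_real_,
                  penalty = NA_real_, wps = NA_real_))
    k_ph <- sum(flagged & sel)
    list(s = s, k_ph = k_ph, proportion = 100 * k_ph / s,
         penalty = penalty(s, reference$B, min_size, form),
         wps = wps(s, k_ph, reference$B, min_size, form))
  })
  out <- data.table::data.table(direction = focal, grid,
                                data.table::rbindlist(res))
  out
}

#' Enumerate and optimize grouping criteria
#'
#' Scores every grouping criterion (k_min in 0..focal size, m_min in
#' 0..contrast size) in both directions against the phagosome reference,
#' computes ds for each cell against its mirrored contrast cell, and
#' returns the argmax-ds criterion per direction.
#'
#' Conventions: cells selecting an empty set are unscored (NA) and never
#' selectable; the contrast wps is floored at 0 inside ds (a contrast
#' direction with no enrichment signal contributes no noise term); only
#' cells with a strictly positive focal wps compete for the argmax; ties
#' break toward the most stringent criterion (highest k_min, then m_min).
#'
#' @param pm A [build_presence_matrix()] result.
#' @param reference A [build_phagosome_reference()] result (or any list with
#'   elements `flagged` and `B`).
#' @param min_size Penalty anchor, default 30.
#' @param form Penalty form, see [penalty()].
#' @return A list of class `grouping_optimization`: `surface` (one row per
#'   direction x criterion with s, k_ph, proportion, penalty, wps,
#'   wps_contrast, ds), `best` (named list with the winning row per
#'   direction) and `B`.
#' @export
optimize_grouping <- function(pm, reference, min_size = 30,
                              form = c("linear", "exp")) {
  form <- match.arg(form)
  if (nrow(pm$mat) == 0) stop("empty presence matrix")
  if (reference$B <= 1)
    stop("phagosome reference too small to score against (B <= 1)")
  P <- sum(pm$panel$group == "phagocyte")
  N <- sum(pm$panel$group == "nonphagocyte")
  tab_ph <- score_one_direction(pm, reference, "phagocyte", min_size, form)
  tab_np <- score_one_direction(pm, reference, "nonphagocyte", min_size, form)
  add_ds <- function(tab, other, FS, CS) {
    wc <- vapply(seq_len(nrow(tab)), function(i) {
      mi <- mirror_criterion(tab$k_min[i], tab$m_min[i], FS, CS)
      w <- other$wps[other$k_min == mi[1] & other$m_min == mi[2]]
      if (length(w) == 0 || is.na(w)) 0 else w
    }, numeric(1))
    tab$wps_contrast <- wc
    tab$ds <- ifelse(is.na(tab$wps), NA_real_, ds_cell(tab$wps, wc))
    tab
  }
  ds_cell <- function(wf, wc) wf * (wf - pmax(wc, 0)) / 100
  tab_ph <- add_ds(tab_ph, tab_np, P, N)
  tab_np <- add_ds(tab_np, tab_ph, N, P)
  pick <- function(tab) {
    ok <- !is.na(tab$ds) & tab$wps > 0
    if (!any(ok)) return(NULL)
    cand <- tab[ok & tab$ds >= max(tab$ds[ok]) - 1e-12, ]
    cand[order(-cand$k_min, -cand$m_min), ][1, ]
  }
  surface <- data.table::rbindlist(list(tab_ph, tab_np))
  structure(list(surface = surface,
                 best = list(phagocyte = pick(tab_ph),
                             nonphagocyte = pick(tab_np)),
                 B = reference$B, min_size = min_size, form = form),
            class = "grouping_optimization")
}

#' @export
print.grouping_optimization <- function(x, ...) {
  for (dir in names(x$best)) {
    b <- x$best[[dir]]
    if (is.null(b)) { cat(dir, ": no selectable criterion\n"); next }
    cat(sprintf("%s direction: k_min=%d m_min=%d  s=%d k_ph=%d (%.1f%%)  wps=%.2f ds=%.2f\n",
                dir, b$k_min, b$m_min, b$s, b$k_ph, b$proportion, b$wps, b$ds))
  }
  invisible(x)
}
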