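#' Pipeline configuration
#'
#' Exactly one of `synthetic` (a [generator_config()]) or `inputs` (paths to
#' `hits`, `panel`, `phagosome_sources` files) must be supplied. All
#' analysis thresholds carry the study defaults: comparison e-value 1e-4,
#' HSSP distance > 5, penalty anchor min_size = 30, top 25 GO terms.
#'
#' @param synthetic Optional [generator_config()].
#' @param inputs Optional named list of file paths: `hits`, `panel`,
#'   `phagosome_sources`.
#' @param profile Filter profile, `"comparison"` or `"annotation"`.
#' @param penalty_form `"linear"` or `"exp"`.
#' @param min_size Penalty anchor.
#' @param top_n GO terms to rank.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the manifest.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, inputs = NULL,
                            profile = "comparison",
                            penalty_form = "linear",
                            min_size = 30, top_n = 25,
                            out_dir = tempfile("phagoprofile_"),
                            seed = 1L) {
  if (is.null(synthetic) == is.null(inputs))
    stop("supply exactly one of 'synthetic' or 'inputs'")
  if (!is.null(synthetic) && !inherits(synthetic, "generator_config"))
    stop("'synthetic' must be a generator_config()")
  if (!is.null(inputs)) {
    need <- c("hits", "panel", "phagosome_sources")
    if (!all(need %in% names(inputs)))
      stop("'inputs' must name files: ", paste(need, collapse = ", "))
  }
  structure(list(synthetic = synthetic, inputs = inputs, profile = profile,
                 penalty_form = penalty_form, min_size = min_size,
                 top_n = top_n, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the inference pipeline end to end
#'
#' Stages: (1) generate or read the homology inputs; (2) retain hits by the
#' dual e-value + HSSP criteria; (3) build the presence matrix and the
#' phagosome reference; (4) enumerate and optimize grouping criteria in
#' both directions; (5) write the enriched peptide sets, the full score
#' surface, and a JSON manifest of parameters and per-stage record counts.
#' Re-running with the same configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly; all outputs under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$synthetic)) {
    sim <- stage("synthetic_data", generate_panel(config$synthetic))
    hits <- sim$hits; panel <- sim$panel; sources <- sim$phagosome_sources
    peptides <- sim$truth$peptide
    write_panel_inputs(sim, file.path(config$out_dir, "inputs"))
  } else {
    panel <- stage("read_panel", read_panel(config$inputs$panel))
    hits <- stage("read_hits", read_blast_hits(config$inputs$hits, panel))
    sources <- stage("read_sources",
                     data.table::fread(config$inputs$phagosome_sources,
                                       header = TRUE, sep = "\t"))
    peptides <- sort(unique(hits$qseqid))
  }

  crit <- filter_criteria(config$profile)
  retained <- stage("homology_filter", hits[passes_dual_criteria(hits, crit)])
  pm <- stage("presence_matrix",
              build_presence_matrix(retained, panel, peptides = peptides))
  reference <- stage("phagosome_reference",
                     build_phagosome_reference(sources, retained))
  opt <- stage("optimize_grouping",
               optimize_grouping(pm, reference, min_size = config$min_size,
                                 form = config$penalty_form))

  write_presence_matrix(pm, file.path(config$out_dir, "presence_matrix.tsv"))
  data.table::fwrite(opt$surface,
                     file.path(config$out_dir, "score_surface.tsv"),
                     sep = "\t")
  sets <- list()
  for (dir in c("phagocyte", "nonphagocyte")) {
    b <- opt$best[[dir]]
    if (is.null(b)) next
    set <- select_set(pm, b$k_min, b$m_min, focal = dir)
    sets[[dir]] <- set
    writeLines(set, file.path(config$out_dir,
                              paste0("enriched_", dir, ".txt")))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phagoprofile")),
    seed = config$seed,
    parameters = list(profile = config$profile,
                      evalue_max = crit$evalue_max,
                      dist_min = crit$dist_min,
                      penalty_form = config$penalty_form,
                      min_size = config$min_size, top_n = config$top_n),
    counts = list(hits_in = nrow(hits), hits_retained = nrow(retained),
                  peptides = nrow(pm$mat),
                  organisms = ncol(pm$mat),
                  phagosome_components = reference$U,
                  phagosome_flagged_B = reference$B,
                  enriched_phagocyte = length(sets$phagocyte),
                  enriched_nonphagocyte = length(sets$nonphagocyte)),
    best = lapply(opt$best, function(b)
      if (is.null(b)) NULL else
        list(k_min = b$k_min, m_min = b$m_min, s = b$s, k_ph = b$k_ph,
             proportion = b$proportion, wps = b$wps, ds = b$ds)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
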