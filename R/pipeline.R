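#' Analysis configuration
#'
#' The single source of every threshold the pipeline uses; validated here
#' and echoed verbatim into the run manifest.
#'
#' @param gate a \code{\link{gate_config}}.
#' @param reference_group reference group label (default \code{"WT"}).
#' @param disease_group disease group label (default \code{"APP/PS1"}).
#' @param marker_fold_threshold astrocyte-marker fold cutoff (default 100).
#' @param positive_fraction_threshold AEG endfoot-positive fraction cutoff
#'   (default 0.60).
#' @param ratio_change_threshold AD-related AEG ratio-change cutoff
#'   (default 0.15).
#' @param de_fc_threshold,de_alpha differential-expression filter (default
#'   |FC| > 1.5, adjusted p < 0.05).
#' @param score_bins,score_ctrl,score_threshold module-score parameters
#'   (default 24 bins, 100 controls, retain score > 0.8).
#' @param if_percent,if_coated_threshold,if_regions,if_region_um
#'   immunofluorescence parameters (top 1 percent, quarter rule, six
#'   0.2 mm regions).
#' @param seed integer master seed.
#' @return An \code{analysis_config} list.
#' @export
analysis_config <- function(gate = gate_config(),
                            reference_group = "WT",
                            disease_group = "APP/PS1",
                            marker_fold_threshold = 100,
                            positive_fraction_threshold = 0.60,
                            ratio_change_threshold = 0.15,
                            de_fc_threshold = 1.5, de_alpha = 0.05,
                            score_bins = 24, score_ctrl = 100,
                            score_threshold = 0.8,
                            if_percent = 1.0, if_coated_threshold = 0.25,
                            if_regions = 6, if_region_um = 200,
                            seed = 1L) {
  stopifnot(inherits(gate, "gate_config"),
            marker_fold_threshold > 0,
            positive_fraction_threshold >= 0, positive_fraction_threshold <= 1,
            ratio_change_threshold >= 0,
            de_fc_threshold >= 1, de_alpha > 0, de_alpha <= 1,
            score_bins >= 1, score_ctrl >= 1,
            if_percent > 0, if_percent <= 100,
            if_coated_threshold >= 0, if_coated_threshold <= 1)
  structure(list(gate = gate, reference_group = reference_group,
                 disease_group = disease_group,
                 marker_fold_threshold = marker_fold_threshold,
                 positive_fraction_threshold = positive_fraction_threshold,
                 ratio_change_threshold = ratio_change_threshold,
                 de_fc_threshold = de_fc_threshold, de_alpha = de_alpha,
                 score_bins = score_bins, score_ctrl = score_ctrl,
                 score_threshold = score_threshold,
                 if_percent = if_percent,
                 if_coated_threshold = if_coated_threshold,
                 if_regions = if_regions, if_region_um = if_region_um,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

config_manifest <- function(config) {
  out <- unclass(config)
  out$gate <- unclass(out$gate)
  out
}

#' Run the full polarization pipeline
#'
#' Orchestrates gate -> adjacency -> ratio table -> group summaries ->
#' AEG screen -> gene-set scores -> differential expression, and writes
#' every stage table plus a manifest (config, seed, per-stage row counts)
#' to \code{out_dir}. Reruns with the same inputs are byte-identical.
#'
#' @param bundle a \code{\link{spot_bundle}} (e.g. loaded with
#'   \code{\link{load_bundle}} or generated by
#'   \code{\link{generate_tissue}}).
#' @param config an \code{\link{analysis_config}}.
#' @param celltype_ref cell-type reference table for the marker screen
#'   (optional; the screen stage is skipped when absent).
#' @param gene_sets named list of \code{gene_set} objects (e.g. from
#'   \code{\link{read_gmt}}) to score (optional).
#' @param ratio_genes genes to compute ratios for; defaults to the whole
#'   panel.
#' @param out_dir output directory for the stage TSVs and manifest
#'   (optional; results are always returned).
#' @return A list with \code{classification}, \code{adjacency},
#'   \code{ratio_table}, \code{summary}, \code{summary_by_region},
#'   \code{screen}, \code{scores}, \code{score_comparisons}, \code{de}
#'   and \code{config}.
#' @export
run_pipeline <- function(bundle, config = analysis_config(),
                         celltype_ref = NULL, gene_sets = NULL,
                         ratio_genes = NULL, out_dir = NULL) {
  stopifnot(inherits(bundle, "spot_bundle"),
            inherits(config, "analysis_config"))
  cls <- gate_spots(bundle, config$gate)
  adj <- find_adjacent_pairs(cls, bundle, max_steps = config$gate$max_steps)
  if (is.null(ratio_genes)) ratio_genes <- bundle$gene_ids
  ratio_tab <- build_ratio_table(bundle, adj, ratio_genes)
  summary <- summarize_ratios(ratio_tab, config$reference_group)
  summary_region <- summarize_ratios(ratio_tab, config$reference_group,
                                     by_region = TRUE)
  screen <- NULL
  if (!is.null(celltype_ref))
    screen <- screen_aegs(celltype_ref, ratio_tab, summary,
                          fold_threshold = config$marker_fold_threshold,
                          positive_fraction_threshold =
                            config$positive_fraction_threshold,
                          change_threshold = config$ratio_change_threshold,
                          population_group = config$reference_group,
                          disease_group = config$disease_group)
  scores <- list(); score_cmp <- list()
  if (!is.null(gene_sets)) {
    for (nm in names(gene_sets)) {
      sc <- module_score(bundle, gene_sets[[nm]],
                         n_bins = config$score_bins,
                         n_ctrl = config$score_ctrl, seed = config$seed)
      scores[[nm]] <- sc
      score_cmp[[nm]] <- compare_scores(sc, threshold = config$score_threshold,
                                        reference_group = config$reference_group)
    }
  }
  ac_bc <- cls$barcode[cls$label == "AC"]
  de <- tryCatch(
    de_screen(bundle, ac_bc, config$disease_group, config$reference_group,
              fc_threshold = config$de_fc_threshold,
              alpha = config$de_alpha),
    error = function(e) NULL)
  result <- list(classification = cls, adjacency = adj,
                 ratio_table = ratio_tab, summary = summary,
                 summary_by_region = summary_region, screen = screen,
                 scores = scores, score_comparisons = score_cmp,
                 de = de, config = config)
  if (!is.null(out_dir)) {
    tables <- list(classification = cls,
                   ratio_table = ratio_tab,
                   ratio_summary = summary,
                   ratio_summary_by_region = summary_region)
    if (!is.null(screen)) {
      tables$marker_screen <- screen$marker_stats
      tables$aeg_screen <- screen$aeg_stats
      tables$ad_aeg_screen <- screen$ad_stats
    }
    for (nm in names(scores))
      tables[[paste0("score_", gsub("[^A-Za-z0-9]", "_", nm))]] <- scores[[nm]]
    if (!is.null(de)) tables$de_screen <- de
    save_results(tables, out_dir, config = config_manifest(config),
                 seed = config$seed)
  }
  result
}

#' Reproducible end-to-end demonstration
#'
#' Generates a synthetic tissue under the default study conditions (WT
#' Aqp4 endfoot share 0.7, disease effect 0.66, treatment effect 0.9),
#' a matching synthetic cell-type reference, and runs the full pipeline
#' including gene-set scoring of the packaged synthetic stand-in sets
#' (GMT in \code{inst/extdata}).
#'
#' @param seed integer seed.
#' @param out_dir optional output directory (see
#'   \code{\link{run_pipeline}}).
#' @param params optional \code{\link{synth_params}} override.
#' @return The \code{\link{run_pipeline}} result, plus \code{truth} and
#'   \code{bundle}.
#' @export
run_demo <- function(seed = 1L, out_dir = NULL, params = NULL) {
  if (is.null(params)) params <- synth_params(seed = seed)
  tissue <- generate_tissue(params)
  ref <- generate_celltype_reference(
    marker_genes = params$candidate_genes,
    other_genes = params$background_genes, seed = params$seed + 1L)
  config <- analysis_config(seed = params$seed)
  gmt <- system.file("extdata", "synthetic_gene_sets.gmt",
                     package = "aqpolar")
  gene_sets <- if (nzchar(gmt)) read_gmt(gmt) else NULL
  gene_sets <- Filter(function(s) any(s$genes %in% tissue$bundle$gene_ids),
                      gene_sets)
  res <- run_pipeline(tissue$bundle, config, celltype_ref = ref,
                      ratio_genes = params$candidate_genes,
                      gene_sets = gene_sets, out_dir = out_dir)
  res$truth <- tissue$truth
  res$bundle <- tissue$bundle
  res
}
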