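#' Depth-normalize and log-transform counts
#'
#' Standard library-size normalization: each spot is scaled to
#' \code{scale_factor} total counts and log1p-transformed. Zero-depth
#' spots stay all-zero.
#'
#' @param counts genes x spots count matrix (dense or sparse).
#' @param scale_factor target total per spot (default 1e4).
#' @param log apply log1p (default TRUE).
#' @return A dense genes x spots numeric matrix.
#' @export
normalize_log1p <- function(counts, scale_factor = 1e4, log = TRUE) {
  m <- as.matrix(counts)
  depth <- colSums(m)
  depth[depth == 0] <- 1
  m <- t(t(m) / depth * scale_factor)
  if (log) m <- log1p(m)
  m
}

#' Binned-control gene-set score per spot
#'
#' Reimplementation of the standard module-score algorithm: spots are
#' scored as the mean (log-normalized) expression of the set genes minus
#' the mean expression of expression-matched control genes. Genes are
#' ranked by their average expression over all in-tissue spots and split
#' into \code{n_bins} equal-frequency bins; for each set gene,
#' \code{n_ctrl} control genes are drawn (seeded, without replacement,
#' capped at the bin size so small bins contribute the whole bin) from its
#' bin, and the pooled control draws form the control average.
#'
#' @param bundle a \code{\link{spot_bundle}}.
#' @param gene_set a \code{gene_set} (from \code{\link{read_gmt}}) or a
#'   character vector of gene ids; genes absent from the panel are
#'   ignored, but at least one must be present.
#' @param n_bins number of average-expression bins (default 24, reduced if
#'   the panel is smaller).
#' @param n_ctrl control genes drawn per set gene (default 100).
#' @param seed integer seed for the control draws.
#' @param scale_factor depth-normalization target (default 1e4).
#' @return Data frame \code{barcode}, \code{score}, \code{sample},
#'   \code{group}, \code{region} over the in-tissue spots; attribute
#'   \code{controls} lists the control genes drawn per set gene.
#' @export
module_score <- function(bundle, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L, scale_factor = 1e4) {
  genes <- if (inherits(gene_set, "gene_set")) gene_set$genes
           else as.character(gene_set)
  genes <- sort(intersect(unique(genes), bundle$gene_ids))
  if (!length(genes))
    stop("module_score: no gene of the set is present in the panel")
  keep <- which(bundle$in_tissue)
  norm <- normalize_log1p(bundle$counts[, keep, drop = FALSE],
                          scale_factor = scale_factor)
  avg <- rowMeans(norm)
  n_genes <- length(avg)
  n_bins <- max(1L, min(n_bins, n_genes))
  # equal-frequency bins; ties and ordering resolved by gene id so the
  # binning is independent of panel order
  ord <- order(avg, bundle$gene_ids)
  rank_id <- integer(n_genes)
  rank_id[ord] <- seq_len(n_genes)
  bin <- ceiling(rank_id * n_bins / n_genes)
  names(bin) <- bundle$gene_ids
  ctrl <- vector("list", length(genes))
  names(ctrl) <- genes
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  for (g in genes) {
    pool <- bundle$gene_ids[bin == bin[[g]]]
    take <- min(n_ctrl, length(pool))
    ctrl[[g]] <- sort(sample(pool, take, replace = FALSE))
  }
  ctrl_genes <- unlist(ctrl, use.names = FALSE)  # multiset, duplicates kept
  set_mean <- colMeans(norm[genes, , drop = FALSE])
  ctrl_mean <- colMeans(norm[ctrl_genes, , drop = FALSE])
  out <- data.frame(barcode = bundle$barcodes[keep],
                    score = as.numeric(set_mean - ctrl_mean),
                    sample = bundle$sample_id[keep],
                    group = bundle$group[keep],
                    region = if (is.null(bundle$region)) NA_character_
                             else bundle$region[keep],
                    stringsAsFactors = FALSE)
  attr(out, "controls") <- ctrl
  out
}

#' Thresholded group comparison of module scores
#'
#' Retains the spots with score strictly above \code{threshold} and
#' compares groups on the retained scores: per-group n and mean, one-way
#' ANOVA and LSD pairwise p against the reference. If any group retains
#' fewer than 2 spots the comparison is undefined and flagged.
#'
#' @param scores output of \code{\link{module_score}}.
#' @param threshold score cutoff (default 0.8); use \code{-Inf} for the
#'   unfiltered comparison.
#' @param reference_group reference group label.
#' @return A list with \code{table} (group, n, mean_score, lsd_p_vs_ref),
#'   \code{anova_p}, and \code{defined} (FALSE when a group retained
#'   fewer than 2 spots).
#' @export
compare_scores <- function(scores, threshold = 0.8, reference_group) {
  groups <- sort(unique(scores$group))
  if (length(groups) < 2) stop("compare_scores: need >= 2 groups")
  if (!reference_group %in% groups)
    stop("compare_scores: reference group '", reference_group,
         "' not present")
  kept <- scores[scores$score > threshold, , drop = FALSE]
  n <- vapply(groups, function(g) sum(kept$group == g), 0L)
  mean_score <- vapply(groups, function(g) {
    v <- kept$score[kept$group == g]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  defined <- all(n >= 2)
  anova_p <- NA_real_
  lsd <- stats::setNames(rep(NA_real_, length(groups)), groups)
  if (defined) {
    fit <- anova_lsd(split(kept$score, kept$group))
    anova_p <- fit$p
    for (g in setdiff(groups, reference_group))
      lsd[[g]] <- fit$lsd_p[pair_key(g, reference_group)]
  }
  list(table = data.frame(group = groups, n = n, mean_score = mean_score,
                          lsd_p_vs_ref = as.numeric(lsd),
                          stringsAsFactors = FALSE, row.names = NULL),
       anova_p = anova_p, defined = defined, threshold = threshold)
}

# Seeded RNG scope: sets the seed and returns a restorer for the previous
# RNG state, so library calls are reproducible without clobbering the
# caller's stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
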