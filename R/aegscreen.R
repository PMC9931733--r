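#' Screen astrocyte marker genes from a cell-type reference
#'
#' Stage 1 of the endfoot-gene cascade. From a gene-by-cell-type table of
#' mean expression (astrocytes plus the other vascular cell types of the
#' BBB, e.g. endothelial cells, pericytes, smooth muscle), keeps the genes
#' whose astrocyte mean exceeds \code{fold_threshold}-fold the largest
#' mean among the other cell types (strict inequality). A zero denominator
#' is replaced by a small pseudo-mean so perfectly astrocyte-specific
#' genes pass rather than divide by zero.
#'
#' @param ref data frame or matrix, rownames (or first column \code{gene})
#'   giving gene ids, one column per cell type; must contain an
#'   \code{astrocyte} column.
#' @param fold_threshold fold-change cutoff (default 100).
#' @param astro_col name of the astrocyte column.
#' @param eps_frac pseudo-mean for zero denominators, as a fraction of the
#'   largest value in the table (default 1e-6).
#' @return Data frame \code{gene}, \code{astro_mean}, \code{max_other},
#'   \code{fold_change}, \code{is_marker}, ordered by decreasing fold
#'   change.
#' @export
screen_markers <- function(ref, fold_threshold = 100,
                           astro_col = "astrocyte", eps_frac = 1e-6) {
  if (is.data.frame(ref) && "gene" %in% names(ref)) {
    rn <- ref$gene
    ref <- as.matrix(ref[setdiff(names(ref), "gene")])
    rownames(ref) <- rn
  } else {
    ref <- as.matrix(ref)
  }
  if (!astro_col %in% colnames(ref))
    stop("screen_markers: reference lacks an '", astro_col, "' column")
  if (ncol(ref) < 2)
    stop("screen_markers: need >= 2 cell types")
  if (any(ref < 0)) stop("screen_markers: reference means must be >= 0")
  astro <- ref[, astro_col]
  other <- ref[, setdiff(colnames(ref), astro_col), drop = FALSE]
  max_other <- apply(other, 1, max)
  eps <- eps_frac * max(ref)
  denom <- ifelse(max_other > 0, max_other, eps)
  fc <- astro / denom
  out <- data.frame(gene = rownames(ref), astro_mean = astro,
                    max_other = max_other, fold_change = fc,
                    is_marker = fc > fold_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fold_change, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Call astrocyte endfoot genes (AEGs)
#'
#' Stage 2: among candidate (marker) genes, keeps those whose gene ratio
#' is positive in strictly more than \code{positive_fraction_threshold} of
#' the perivascular AC population. The denominator is the total number of
#' perivascular AC spots in the population (astrocytes where the gene is
#' detected in neither compartment count as endfoot-negative); by default
#' the population is the reference (WT) group.
#'
#' @param ratio_table output of \code{\link{build_ratio_table}}.
#' @param genes candidate genes (e.g. the markers from
#'   \code{\link{screen_markers}}); defaults to all genes in the table.
#' @param positive_fraction_threshold strict fraction cutoff (default
#'   0.60).
#' @param population_group group whose AC define the population (default
#'   \code{"WT"}; \code{NULL} pools all groups).
#' @return Data frame \code{gene}, \code{n_positive}, \code{n_ac},
#'   \code{positive_fraction}, \code{is_aeg}, \code{flagged} (no defined
#'   record at all; excluded).
#' @export
call_aegs <- function(ratio_table, genes = NULL,
                      positive_fraction_threshold = 0.60,
                      population_group = "WT") {
  tb <- ratio_table
  if (!is.null(population_group)) {
    tb <- tb[tb$group == population_group, , drop = FALSE]
    if (!nrow(tb))
      stop("call_aegs: no records for population group '",
           population_group, "'")
  }
  if (is.null(genes)) genes <- sort(unique(ratio_table$gene))
  n_ac <- length(unique(tb$barcode))
  res <- lapply(genes, function(g) {
    rec <- tb[tb$gene == g, , drop = FALSE]
    npos <- sum(rec$ratio > 0)
    frac <- if (n_ac > 0) npos / n_ac else NA_real_
    data.frame(gene = g, n_positive = npos, n_ac = n_ac,
               positive_fraction = frac,
               is_aeg = !is.na(frac) && nrow(rec) > 0 &&
                 frac > positive_fraction_threshold,
               flagged = nrow(rec) == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Call AD-related AEGs
#'
#' Stage 3: among AEGs, keeps the genes whose mean-ratio fold change in
#' the disease group deviates from 1 by strictly more than
#' \code{change_threshold} (default 0.15-fold). The deviation is unsigned
#' by default (a 0.15-fold rise also qualifies); set
#' \code{direction = "down"} to require a reduction.
#'
#' @param summary a \code{\link{summarize_ratios}} table (not
#'   region-stratified) whose fold changes are relative to the reference
#'   group.
#' @param genes candidate genes (e.g. the AEGs); defaults to all genes in
#'   the summary.
#' @param disease_group group whose fold change is tested (default
#'   \code{"APP/PS1"}).
#' @param change_threshold strict deviation cutoff (default 0.15).
#' @param direction \code{"both"} (unsigned, default) or \code{"down"}.
#' @return Data frame \code{gene}, \code{fold_change}, \code{ratio_change}
#'   (fold change minus 1), \code{is_ad_aeg}, \code{flagged} (undefined
#'   fold change; excluded).
#' @export
call_ad_aegs <- function(summary, genes = NULL, disease_group = "APP/PS1",
                         change_threshold = 0.15,
                         direction = c("both", "down")) {
  direction <- match.arg(direction)
  sm <- summary[summary$group == disease_group, , drop = FALSE]
  if (!nrow(sm))
    stop("call_ad_aegs: no summary rows for group '", disease_group, "'")
  if (is.null(genes)) genes <- sort(unique(sm$gene))
  res <- lapply(genes, function(g) {
    row <- sm[sm$gene == g, , drop = FALSE]
    fc <- if (nrow(row)) row$fold_change[[1]] else NA_real_
    flagged <- is.na(fc) || !is.finite(fc)
    dev <- fc - 1
    hit <- !flagged &&
      (if (direction == "both") abs(dev) > change_threshold
       else -dev > change_threshold)
    data.frame(gene = g, fold_change = fc, ratio_change = dev,
               is_ad_aeg = hit, flagged = flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Run the full three-stage AEG screening cascade
#'
#' Marker genes (reference fold change > \code{fold_threshold}) to AEGs
#' (endfoot-positive fraction > \code{positive_fraction_threshold}) to
#' AD-related AEGs (ratio fold-change deviation > \code{change_threshold}).
#' The subset chain ad_related \code{<=} aegs \code{<=} markers holds by
#' construction.
#'
#' @param ref cell-type reference for \code{\link{screen_markers}}.
#' @param ratio_table per-AC ratio table covering the marker genes.
#' @param summary group summary from \code{\link{summarize_ratios}}.
#' @param fold_threshold,positive_fraction_threshold,change_threshold
#'   stage thresholds (defaults 100, 0.60, 0.15).
#' @param ... passed to \code{\link{call_aegs}} / \code{\link{call_ad_aegs}}
#'   (e.g. \code{population_group}, \code{disease_group},
#'   \code{direction}).
#' @return A list of class \code{aeg_screen_result}: \code{markers},
#'   \code{aegs}, \code{ad_aegs} (character vectors) and the three stage
#'   tables \code{marker_stats}, \code{aeg_stats}, \code{ad_stats}.
#' @export
screen_aegs <- function(ref, ratio_table, summary,
                        fold_threshold = 100,
                        positive_fraction_threshold = 0.60,
                        change_threshold = 0.15, ...) {
  dots <- list(...)
  mk <- screen_markers(ref, fold_threshold = fold_threshold)
  markers <- mk$gene[mk$is_marker]
  cand <- intersect(markers, unique(ratio_table$gene))
  aeg_args <- c(list(ratio_table = ratio_table, genes = cand,
                     positive_fraction_threshold = positive_fraction_threshold),
                dots[names(dots) %in% "population_group"])
  at <- do.call(call_aegs, aeg_args)
  aegs <- at$gene[at$is_aeg]
  ad_args <- c(list(summary = summary, genes = aegs,
                    change_threshold = change_threshold),
               dots[names(dots) %in% c("disease_group", "direction")])
  ad <- do.call(call_ad_aegs, ad_args)
  ad_aegs <- ad$gene[ad$is_ad_aeg]
  structure(list(markers = markers, aegs = aegs, ad_aegs = ad_aegs,
                 marker_stats = mk, aeg_stats = at, ad_stats = ad),
            class = "aeg_screen_result")
}

#' @exportS3Method base::print
print.aeg_screen_result <- function(x, ...) {
  cat("AEG screening cascade:\n")
  cat("  markers:       ", length(x$markers), "\n")
  cat("  AEGs:          ", length(x$aegs), "\n")
  cat("  AD-related AEGs:", length(x$ad_aegs), "\n")
  invisible(x)
}
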