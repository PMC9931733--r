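#' Per-gene endfoot gene ratio
#'
#' The polarization statistic: for one astrocyte (AC) spot and the counts
#' of the same gene in its adjacent BBB spots, the gene ratio is the BBB
#' count divided by the sum of the AC and BBB counts, maximized over the
#' adjacent BBB spots. It estimates the fraction of the astrocyte's
#' transcripts sitting in the perivascular endfoot compartment and lies in
#' [0, 1].
#'
#' @param ac_expr non-negative count of the gene in the AC spot.
#' @param bbb_exprs non-empty vector of non-negative counts in the adjacent
#'   BBB spots.
#' @return A list with \code{ratio} and \code{which} (index of the
#'   maximizing neighbor; ties resolved to the first). If \code{ac_expr}
#'   and all \code{bbb_exprs} are zero the ratio is undefined and
#'   \code{NA_real_} is returned (callers drop such records).
#' @export
gene_ratio <- function(ac_expr, bbb_exprs) {
  if (length(bbb_exprs) < 1L) stop("gene_ratio: 'bbb_exprs' must be non-empty")
  if (ac_expr < 0 || any(bbb_exprs < 0))
    stop("gene_ratio: counts must be >= 0")
  if (ac_expr == 0 && all(bbb_exprs == 0))
    return(list(ratio = NA_real_, which = NA_integer_))
  r <- bbb_exprs / (ac_expr + bbb_exprs)
  r[ac_expr + bbb_exprs == 0] <- 0  # unreachable given the guard; defensive
  k <- which.max(r)
  list(ratio = r[[k]], which = k)
}

#' Build the per-AC, per-gene ratio table
#'
#' One record per (perivascular AC spot, gene) with a defined ratio.
#' Records where the gene is detected in neither the AC spot nor any
#' adjacent BBB spot (0/0) are omitted, not imputed, and counted in the
#' \code{"qc"} attribute.
#'
#' @param bundle a \code{\link{spot_bundle}}.
#' @param adjacency an \code{adjacency_map} from
#'   \code{\link{find_adjacent_pairs}}.
#' @param genes character vector of genes to score (must be in the panel).
#' @return Data frame with columns \code{barcode}, \code{gene},
#'   \code{ac_expr}, \code{bbb_expr}, \code{ratio}, \code{bbb_barcode},
#'   \code{sample}, \code{group}, \code{region}; attribute \code{qc} holds
#'   the per-gene count of dropped undefined records.
#' @export
build_ratio_table <- function(bundle, adjacency, genes) {
  stopifnot(inherits(bundle, "spot_bundle"), inherits(adjacency, "adjacency_map"))
  miss <- setdiff(genes, bundle$gene_ids)
  if (length(miss))
    stop("build_ratio_table: gene(s) absent from the panel: ",
         paste(miss, collapse = ", "))
  if (!length(adjacency)) {
    out <- data.frame(barcode = character(0), gene = character(0),
                      ac_expr = numeric(0), bbb_expr = numeric(0),
                      ratio = numeric(0), bbb_barcode = character(0),
                      sample = character(0), group = character(0),
                      region = character(0))
    attr(out, "qc") <- stats::setNames(integer(length(genes)), genes)
    return(out)
  }
  ac_bc <- names(adjacency)
  nn <- lengths(adjacency)
  pair_ac <- rep(ac_bc, nn)
  pair_bbb <- unlist(adjacency, use.names = FALSE)
  ai <- match(pair_ac, bundle$barcodes)
  bi <- match(pair_bbb, bundle$barcodes)
  if (anyNA(ai) || anyNA(bi))
    stop("build_ratio_table: adjacency references barcodes absent from bundle")
  grp_idx <- match(ac_bc, bundle$barcodes)
  pieces <- vector("list", length(genes))
  qc <- stats::setNames(integer(length(genes)), genes)
  pair_group <- rep(seq_along(ac_bc), nn)   # group pairs by AC spot
  for (k in seq_along(genes)) {
    g <- genes[[k]]
    row <- as.numeric(bundle$counts[g, ])
    a <- row[ai]; b <- row[bi]
    tot <- a + b
    r <- ifelse(tot > 0, b / tot, -Inf)   # -Inf marks undefined pairs
    # max over neighbors per AC spot; ties -> first neighbor in
    # ascending-barcode order (the stored order)
    ord <- order(pair_group, -r, rank(pair_bbb, ties.method = "first"))
    first <- !duplicated(pair_group[ord])
    sel <- ord[first]
    def <- is.finite(r[sel])
    qc[[k]] <- sum(!def)
    sel <- sel[def]
    if (!length(sel)) next
    pieces[[k]] <- data.frame(
      barcode = pair_ac[sel], gene = g,
      ac_expr = a[sel], bbb_expr = b[sel], ratio = r[sel],
      bbb_barcode = pair_bbb[sel],
      sample = bundle$sample_id[ai[sel]],
      group = bundle$group[ai[sel]],
      region = if (is.null(bundle$region)) NA_character_
               else bundle$region[ai[sel]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(barcode = character(0), gene = character(0),
                      ac_expr = numeric(0), bbb_expr = numeric(0),
                      ratio = numeric(0), bbb_barcode = character(0),
                      sample = character(0), group = character(0),
                      region = character(0))
  rownames(out) <- NULL
  attr(out, "qc") <- qc
  out
}

#' Group summaries of gene ratios
#'
#' Per gene (optionally stratified by region): per-group number of
#' perivascular AC records, mean ratio, fold change of the group mean over
#' the reference-group mean, one-way ANOVA p-value across groups, and the
#' LSD pairwise p-value of each group against the reference. Records are
#' pooled across samples by default; set \code{per_sample = TRUE} to
#' average per sample first and run the statistics on sample means.
#'
#' @param table ratio table from \code{\link{build_ratio_table}}.
#' @param reference_group reference group label (e.g. \code{"WT"}).
#' @param by_region stratify by the \code{region} column.
#' @param per_sample average records within each sample before testing.
#' @return Data frame with one row per gene x group (x region); groups with
#'   fewer than 2 records in a stratum get \code{NA} statistics and are
#'   flagged in \code{underpowered}.
#' @export
summarize_ratios <- function(table, reference_group, by_region = FALSE,
                             per_sample = FALSE) {
  groups <- unique(table$group)
  if (length(groups) < 2)
    stop("summarize_ratios: need >= 2 groups")
  if (!reference_group %in% groups)
    stop("summarize_ratios: reference group '", reference_group,
         "' not present")
  strata <- if (by_region) split(table, list(table$gene, table$region),
                                 drop = TRUE)
            else split(table, table$gene)
  out <- lapply(strata, function(tb) {
    gene <- tb$gene[[1]]
    region <- if (by_region) tb$region[[1]] else NA_character_
    vals <- tb$ratio; grp <- tb$group
    if (per_sample) {
      agg <- stats::aggregate(ratio ~ sample + group, data = tb, FUN = mean)
      vals <- agg$ratio; grp <- agg$group
    }
    n <- tapply(vals, grp, length)
    mns <- tapply(vals, grp, mean)
    present <- names(mns)
    underpowered <- any(!groups %in% present) ||
      any(n[groups[groups %in% present]] < 2)
    anova_p <- NA_real_
    lsd <- stats::setNames(rep(NA_real_, length(present)), present)
    if (!underpowered) {
      fit <- anova_lsd(split(vals, grp))
      anova_p <- fit$p
      for (g in setdiff(present, reference_group))
        lsd[[g]] <- fit$lsd_p[pair_key(g, reference_group)]
    }
    ref_mean <- if (reference_group %in% present) mns[[reference_group]]
                else NA_real_
    data.frame(gene = gene, region = region, group = present,
               n = as.integer(n[present]), mean_ratio = as.numeric(mns[present]),
               fold_change = as.numeric(mns[present]) / ref_mean,
               anova_p = anova_p, lsd_p_vs_ref = as.numeric(lsd[present]),
               underpowered = underpowered, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correlate two per-AC ratio tables
#'
#' Pairs the ratios of two genes on their common AC spots and fits a
#' Pearson correlation with a least-squares line (used for e.g. the
#' Aqp4-ratio vs Gfap-ratio relationship).
#'
#' @param table_a,table_b single-gene ratio tables (rows of the output of
#'   \code{\link{build_ratio_table}}).
#' @return A list with \code{r}, \code{p}, \code{slope}, \code{intercept}
#'   and \code{n}. With fewer than 3 common spots or zero variance in
#'   either gene the correlation is undefined and all values are NA with
#'   \code{defined = FALSE}.
#' @export
ratio_vs_ratio_fit <- function(table_a, table_b) {
  common <- intersect(table_a$barcode, table_b$barcode)
  x <- table_a$ratio[match(common, table_a$barcode)]
  y <- table_b$ratio[match(common, table_b$barcode)]
  n <- length(common)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = n, defined = FALSE))
  fit <- pearson_fit(x, y)
  c(fit, list(n = n, defined = TRUE))
}
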