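#' Gate configuration for AC/BBB spot selection
#'
#' Perivascular astrocyte (AC) spots are selected as the intersection of
#' spots detecting every AC marker (default Gfap > 0 and Aqp4 > 0, raw
#' counts) outside the CSF-facing exclusion regions; blood-brain-barrier
#' (BBB) spots analogously on the endothelial markers (default Pecam1 > 0
#' and Flt1 > 0).
#'
#' @param ac_markers named numeric vector: AC marker genes and the minimum
#'   count each must strictly exceed.
#' @param bbb_markers named numeric vector for the BBB gate.
#' @param ac_excluded_regions region labels never called AC.
#' @param bbb_excluded_regions region labels never called BBB.
#' @param overlap_policy what to do with spots passing both gates:
#'   \code{"bbb"} (default; such a spot is the barrier compartment and is
#'   removed from AC so astrocyte bodies inside a BBB spot are not counted
#'   twice), \code{"ac"}, or \code{"drop"} (label \code{other}).
#' @param max_steps lattice adjacency radius in hex steps for
#'   \code{\link{find_adjacent_pairs}} (default 1, the six immediate
#'   neighbors).
#' @return A \code{gate_config} list.
#' @export
gate_config <- function(ac_markers = c(Gfap = 0, Aqp4 = 0),
                        bbb_markers = c(Pecam1 = 0, Flt1 = 0),
                        ac_excluded_regions = c("glia limitans", "ependyma",
                                                "choroid plexus"),
                        bbb_excluded_regions = "choroid plexus",
                        overlap_policy = c("bbb", "ac", "drop"),
                        max_steps = 1L) {
  overlap_policy <- match.arg(overlap_policy)
  if (is.null(names(ac_markers)) || is.null(names(bbb_markers)))
    stop("gate_config: marker vectors must be named by gene id")
  if (any(ac_markers < 0) || any(bbb_markers < 0))
    stop("gate_config: marker thresholds must be >= 0")
  if (max_steps < 1L) stop("gate_config: max_steps must be >= 1")
  structure(list(ac_markers = ac_markers, bbb_markers = bbb_markers,
                 ac_excluded_regions = as.character(ac_excluded_regions),
                 bbb_excluded_regions = as.character(bbb_excluded_regions),
                 overlap_policy = overlap_policy,
                 max_steps = as.integer(max_steps)),
            class = "gate_config")
}

pass_gate <- function(bundle, markers) {
  ok <- rep(TRUE, ncol(bundle$counts))
  for (g in names(markers)) {
    ok <- ok & (as.numeric(bundle$counts[g, ]) > markers[[g]])
  }
  ok
}

#' Classify spots as perivascular-astrocyte, BBB, or other
#'
#' Labels are exhaustive and mutually exclusive. A spot is AC iff every AC
#' marker strictly exceeds its threshold, its region is not AC-excluded,
#' and the overlap policy does not reassign it; BBB analogously. Spots
#' outside the tissue are always \code{other}.
#'
#' @param bundle a \code{\link{spot_bundle}}.
#' @param config a \code{\link{gate_config}}.
#' @return A \code{spot_classification}: data frame with columns
#'   \code{barcode} and \code{label} (factor AC/BBB/other), aligned with
#'   the bundle's spots.
#' @export
gate_spots <- function(bundle, config = gate_config()) {
  stopifnot(inherits(bundle, "spot_bundle"), inherits(config, "gate_config"))
  need <- unique(c(names(config$ac_markers), names(config$bbb_markers)))
  miss <- setdiff(need, bundle$gene_ids)
  if (length(miss))
    stop("gate_spots: marker gene(s) absent from the panel: ",
         paste(miss, collapse = ", "))
  ac <- pass_gate(bundle, config$ac_markers)
  bbb <- pass_gate(bundle, config$bbb_markers)
  if (!is.null(bundle$region)) {
    ac <- ac & !(bundle$region %in% config$ac_excluded_regions)
    bbb <- bbb & !(bundle$region %in% config$bbb_excluded_regions)
  }
  ac <- ac & bundle$in_tissue
  bbb <- bbb & bundle$in_tissue
  both <- ac & bbb
  if (any(both)) {
    switch(config$overlap_policy,
           bbb = { ac[both] <- FALSE },
           ac = { bbb[both] <- FALSE },
           drop = { ac[both] <- FALSE; bbb[both] <- FALSE })
  }
  label <- rep("other", length(ac))
  label[ac] <- "AC"
  label[bbb] <- "BBB"
  structure(data.frame(barcode = bundle$barcodes,
                       label = factor(label, levels = c("AC", "BBB", "other")),
                       stringsAsFactors = FALSE),
            class = c("spot_classification", "data.frame"))
}

# Hex-lattice neighbor offsets in Space Ranger array coordinates:
# (r, c +- 2) and (r +- 1, c +- 1).
hex_offsets <- cbind(dr = c(0L, 0L, -1L, -1L, 1L, 1L),
                     dc = c(-2L, 2L, -1L, 1L, -1L, 1L))

# Offsets reachable within max_steps hex steps on the full lattice
# (excluding the origin). Steps are counted on the ideal lattice, so a
# missing intermediate spot does not break two-step adjacency.
hex_offsets_k <- function(max_steps) {
  pts <- matrix(0L, 1, 2)
  for (s in seq_len(max_steps)) {
    grown <- do.call(rbind, lapply(seq_len(nrow(hex_offsets)), function(o)
      cbind(pts[, 1] + hex_offsets[o, "dr"],
            pts[, 2] + hex_offsets[o, "dc"])))
    pts <- rbind(pts, grown)
    pts <- pts[!duplicated(paste(pts[, 1], pts[, 2])), , drop = FALSE]
  }
  pts[!(pts[, 1] == 0L & pts[, 2] == 0L), , drop = FALSE]
}

# Neighbor pairs within max_steps hex steps, per sample.
# Returns an integer matrix of (spot index, neighbor index) pairs.
lattice_edges <- function(bundle, max_steps = 1L) {
  offs <- hex_offsets_k(max_steps)
  res <- vector("list", 0L)
  for (s in unique(bundle$sample_id)) {
    idx <- which(bundle$sample_id == s)
    key <- paste(bundle$array_row[idx], bundle$array_col[idx])
    for (o in seq_len(nrow(offs))) {
      hit <- match(paste(bundle$array_row[idx] + offs[o, 1],
                         bundle$array_col[idx] + offs[o, 2]), key)
      keep <- !is.na(hit)
      if (any(keep))
        res[[length(res) + 1L]] <- cbind(i = idx[keep], j = idx[hit[keep]])
    }
  }
  if (!length(res)) return(cbind(i = integer(0), j = integer(0)))
  do.call(rbind, res)
}

#' Pair perivascular AC spots with adjacent BBB spots
#'
#' For every AC-labelled spot, finds the BBB-labelled spots among its hex
#' lattice neighbors (up to \code{config$max_steps} steps; default the six
#' immediate neighbors). AC spots with no BBB neighbor are dropped: the
#' retained keys are exactly the perivascular AC. Neighbor lists are
#' ordered by ascending barcode for determinism.
#'
#' @param cls a \code{spot_classification} from \code{\link{gate_spots}}.
#' @param bundle the matching \code{\link{spot_bundle}}.
#' @param max_steps adjacency radius in hex steps; defaults to 1.
#' @return An \code{adjacency_map}: named list mapping each perivascular AC
#'   barcode to a character vector of adjacent BBB barcodes.
#' @export
find_adjacent_pairs <- function(cls, bundle, max_steps = 1L) {
  stopifnot(inherits(cls, "spot_classification"),
            inherits(bundle, "spot_bundle"))
  if (!identical(cls$barcode, bundle$barcodes))
    stop("find_adjacent_pairs: classification is not aligned with bundle")
  edges <- lattice_edges(bundle, max_steps = max_steps)
  if (!nrow(edges)) return(structure(list(), class = "adjacency_map"))
  lab <- as.character(cls$label)
  keep <- lab[edges[, "i"]] == "AC" & lab[edges[, "j"]] == "BBB"
  edges <- edges[keep, , drop = FALSE]
  if (!nrow(edges)) return(structure(list(), class = "adjacency_map"))
  ac_bc <- bundle$barcodes[edges[, "i"]]
  bbb_bc <- bundle$barcodes[edges[, "j"]]
  out <- split(bbb_bc, ac_bc)
  out <- lapply(out, function(v) sort(unique(v)))
  out <- out[sort(names(out))]
  structure(out, class = "adjacency_map")
}
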