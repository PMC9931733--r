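#' Parameters for the synthetic Visium-like tissue generator
#'
#' The generator emulates the structure the analysis needs, with known
#' ground truth: a Space Ranger-style hexagonal spot lattice, vessel
#' (BBB) spots expressing endothelial markers, perivascular astrocyte
#' spots expressing the astrocyte markers, and candidate endfoot genes
#' whose transcripts are split between each astrocyte-vessel pair with a
#' per-gene, per-group endfoot allocation fraction \code{pi}. Counts are
#' negative binomial on the allocated means (Poisson in the
#' infinite-dispersion limit), so the expected observed gene ratio of a
#' generated pair equals \code{pi}.
#'
#' @param lattice_rows,lattice_cols lattice dimensions; spots occupy the
#'   positions with even \code{array_row + array_col}.
#' @param regions character vector of region labels assigned as contiguous
#'   equal-width column bands (at least one label; no more labels than
#'   columns).
#' @param vessel_density target fraction of spots designated vessel sites,
#'   in (0, 1). Each accepted vessel is paired with exactly one fresh
#'   neighboring astrocyte spot, and placement forbids a second vessel
#'   next to an existing astrocyte spot, so each generated astrocyte has
#'   exactly one vessel neighbor and the expected ratio stays analytic; at
#'   high densities the lattice saturates below the target.
#' @param candidate_genes endfoot candidate gene ids; must include
#'   \code{"Aqp4"}.
#' @param n_background number of background genes expressed everywhere.
#' @param baseline_mean named overrides of the per-gene expected counts.
#'   Defaults: candidate pair total 10; background genes log-spaced over
#'   0.5 to 20 (a realistic dynamic range, so expression-bin matching in
#'   \code{\link{module_score}} is meaningful); Gfap 8 at astrocyte
#'   spots and 0.5 at vessels, Pecam1 12 and Flt1 8 at vessels, Aqp4 3 at
#'   non-perivascular astrocytes.
#' @param nb_dispersion negative-binomial size parameter (variance =
#'   mu + mu^2/size); \code{Inf} gives Poisson counts.
#' @param pi per-candidate-gene endfoot allocation fraction in [0, 1]:
#'   either a named vector of baseline (WT) values to which the group
#'   effects are applied, or a genes x groups matrix of final values.
#' @param group_effects named multiplicative factors on \code{pi} per
#'   group; defaults WT 1, APP/PS1 0.66 (the disease reduction),
#'   APP/PS1+MOX 0.9 (the partial restoration).
#' @param astro_bg_fraction fraction of spots given astrocyte markers
#'   without an adjacent vessel (non-perivascular astrocytes).
#' @param pair_excluded_regions regions where no vessel-astrocyte pair is
#'   placed (the CSF-facing regions excluded from gating).
#' @param seed integer seed; identical parameters give byte-identical
#'   output.
#' @return A validated \code{synth_params} list.
#' @export
synth_params <- function(lattice_rows = 60, lattice_cols = 100,
                         regions = c("cortex", "hippocampus", "thalamus",
                                     "hypothalamus", "white matter",
                                     "choroid plexus"),
                         vessel_density = 0.08,
                         candidate_genes = c("Aqp4", "Slc4a4", "Slc6a11",
                                             "Gabrb1", "Gabrb3", "Kcnd2",
                                             "Kcnk1", "Dpp6", "Rgs7",
                                             "Slc25a18", "Cldn10", "Nkain4"),
                         n_background = 30,
                         baseline_mean = NULL,
                         nb_dispersion = 10,
                         pi = 0.7,
                         group_effects = c("WT" = 1, "APP/PS1" = 0.66,
                                           "APP/PS1+MOX" = 0.9),
                         astro_bg_fraction = 0.05,
                         pair_excluded_regions = c("glia limitans",
                                                   "ependyma",
                                                   "choroid plexus"),
                         seed = 1L) {
  if (lattice_rows < 2 || lattice_cols < 2)
    stop("synth_params: lattice dimensions must be positive (>= 2)")
  if (!length(regions))
    stop("synth_params: need at least one region label")
  if (length(regions) > lattice_cols)
    stop("synth_params: more region blocks than lattice columns")
  if (vessel_density <= 0 || vessel_density >= 1)
    stop("synth_params: vessel_density must lie in (0, 1)")
  if (!"Aqp4" %in% candidate_genes)
    stop("synth_params: candidate_genes must include 'Aqp4'")
  if (is.null(names(group_effects)) || !"WT" %in% names(group_effects))
    stop("synth_params: group_effects must be named and include 'WT'")
  if (any(group_effects <= 0 | group_effects > 1))
    stop("synth_params: group effects must lie in (0, 1]")
  groups <- names(group_effects)
  if (is.matrix(pi)) {
    if (is.null(rownames(pi)) || !setequal(rownames(pi), candidate_genes) ||
        !setequal(colnames(pi), groups))
      stop("synth_params: pi matrix must be candidate_genes x groups")
    pi_mat <- pi[candidate_genes, groups, drop = FALSE]
  } else {
    pw <- if (length(pi) == 1L && is.null(names(pi)))
      stats::setNames(rep(pi, length(candidate_genes)), candidate_genes)
    else pi
    if (!setequal(names(pw), candidate_genes))
      stop("synth_params: pi must be named by candidate gene")
    if (any(pw < 0 | pw > 1))
      stop("synth_params: pi must lie in [0, 1] for every gene and group")
    pi_mat <- outer(pw[candidate_genes], group_effects[groups])
    pi_mat <- pmin(pi_mat, 1)
    dimnames(pi_mat) <- list(candidate_genes, groups)
  }
  if (any(pi_mat < 0 | pi_mat > 1))
    stop("synth_params: pi must lie in [0, 1] for every gene and group")
  if (nb_dispersion <= 0)
    stop("synth_params: nb_dispersion must be > 0 (Inf for Poisson)")
  bg_genes <- sprintf("Bg%02d", seq_len(n_background))
  panel <- unique(c("Gfap", "Pecam1", "Flt1", candidate_genes, bg_genes))
  bg_means <- if (n_background > 1)
    exp(seq(log(0.5), log(20), length.out = n_background)) else rep(2, n_background)
  means <- c(stats::setNames(rep(10, length(candidate_genes)), candidate_genes),
             stats::setNames(bg_means, bg_genes),
             Gfap = 8, Gfap_bbb = 0.5, Pecam1 = 12, Flt1 = 8, Aqp4_bg = 3)
  if (!is.null(baseline_mean)) {
    if (is.null(names(baseline_mean)))
      stop("synth_params: baseline_mean overrides must be named")
    means[names(baseline_mean)] <- baseline_mean
  }
  structure(list(lattice_rows = as.integer(lattice_rows),
                 lattice_cols = as.integer(lattice_cols),
                 regions = regions, vessel_density = vessel_density,
                 candidate_genes = candidate_genes,
                 background_genes = bg_genes, gene_panel = panel,
                 baseline_mean = means, nb_dispersion = nb_dispersion,
                 pi = pi_mat, groups = groups,
                 group_effects = group_effects,
                 astro_bg_fraction = astro_bg_fraction,
                 pair_excluded_regions = pair_excluded_regions,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# Draw counts with mean mu and the configured dispersion.
draw_counts <- function(mu, size) {
  if (is.infinite(size)) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), size = size, mu = mu)
}

#' Generate a synthetic tissue with known ground truth
#'
#' Produces one sample per group on the configured lattice and returns the
#' combined \code{\link{spot_bundle}} together with a truth table of the
#' endfoot allocation fraction per gene and group. Generated vessel spots
#' always pass the BBB gate and generated perivascular astrocyte spots
#' always pass the AC gate (marker counts are floored at 1 wherever their
#' allocated mean is positive).
#'
#' @param params a \code{\link{synth_params}} object.
#' @param return_means also return the pre-noise mean matrix (genes x
#'   spots, aligned with the bundle).
#' @return A list with \code{bundle} (which carries per-spot generator
#'   roles in \code{bundle$role}: vessel / ac / astro / bg), \code{truth}
#'   (data frame gene, group, true_pi, expected_ratio), \code{pairs}
#'   (data frame of generated vessel-astrocyte barcode pairs) and, when
#'   requested, \code{means}.
#' @export
generate_tissue <- function(params, return_means = FALSE) {
  stopifnot(inherits(params, "synth_params"))
  restore <- local_rng(params$seed)
  on.exit(restore(), add = TRUE)
  bundles <- list(); means_l <- list(); pairs_l <- list()
  for (k in seq_along(params$groups)) {
    g <- params$groups[[k]]
    sm <- generate_sample(params, sample_id = sprintf("s%d", k), group = g,
                          k = k)
    bundles[[k]] <- sm$bundle
    means_l[[k]] <- sm$means
    pairs_l[[k]] <- sm$pairs
  }
  bundle <- bind_bundles(bundles)
  bundle$role <- unlist(lapply(bundles, function(b) b$role))
  truth <- do.call(rbind, lapply(params$groups, function(g)
    data.frame(gene = params$candidate_genes, group = g,
               true_pi = params$pi[, g],
               expected_ratio = params$pi[, g],
               stringsAsFactors = FALSE)))
  rownames(truth) <- NULL
  out <- list(bundle = bundle, truth = truth,
              pairs = do.call(rbind, pairs_l))
  if (return_means) out$means <- do.call(cbind, means_l)
  out
}

# One lattice sample for one group. Geometry and counts use separate
# derived seeds so the placement is invariant to count-model parameters
# (pre-noise pair totals must not depend on pi).
generate_sample <- function(params, sample_id, group, k = 1L) {
  set.seed((abs(params$seed) + 104729L * k) %% 2147483629L)
  rows <- params$lattice_rows; cols <- params$lattice_cols
  grid <- expand.grid(c = 0:(cols - 1L), r = 0:(rows - 1L))
  keep <- (grid$r + grid$c) %% 2L == 0L
  r <- grid$r[keep]; c <- grid$c[keep]
  n <- length(r)
  band <- findInterval(c, seq(0, cols, length.out = length(params$regions) + 1L),
                       rightmost.closed = TRUE)
  region <- params$regions[pmin(band, length(params$regions))]
  key <- paste(r, c)
  nbr <- matrix(NA_integer_, n, nrow(hex_offsets))
  for (o in seq_len(nrow(hex_offsets)))
    nbr[, o] <- match(paste(r + hex_offsets[o, "dr"],
                            c + hex_offsets[o, "dc"]), key)
  eligible <- !(region %in% params$pair_excluded_regions)
  role <- rep("bg", n)
  target <- round(params$vessel_density * n)
  order_v <- sample.int(n)
  pair_v <- integer(0); pair_a <- integer(0)
  for (v in order_v) {
    if (length(pair_v) >= target) break
    if (role[v] != "bg" || !eligible[v]) next
    nb <- nbr[v, ]; nb <- nb[!is.na(nb)]
    if (any(role[nb] == "ac")) next  # an existing astrocyte would gain a 2nd vessel
    cand <- nb[role[nb] == "bg" & eligible[nb]]
    if (length(cand) > 1) {
      ok <- vapply(cand, function(a) {
        an <- nbr[a, ]; an <- an[!is.na(an)]
        !any(role[an] == "vessel")
      }, TRUE)
      cand <- cand[ok]
    } else if (length(cand) == 1) {
      an <- nbr[cand, ]; an <- an[!is.na(an)]
      if (any(role[an] == "vessel")) cand <- integer(0)
    }
    if (!length(cand)) next
    a <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
    role[v] <- "vessel"; role[a] <- "ac"
    pair_v <- c(pair_v, v); pair_a <- c(pair_a, a)
  }
  # non-perivascular astrocytes, never adjacent to a vessel
  no_vessel_nb <- vapply(seq_len(n), function(i) {
    nb <- nbr[i, ]; nb <- nb[!is.na(nb)]
    !any(role[nb] == "vessel")
  }, TRUE)
  astro_pool <- which(role == "bg" & no_vessel_nb)
  n_astro <- min(length(astro_pool),
                 floor(params$astro_bg_fraction * n))
  if (n_astro > 0) {
    astro <- if (length(astro_pool) == 1) astro_pool
             else sample(astro_pool, n_astro)
    role[astro] <- "astro"
  }
  set.seed((abs(params$seed) + 15485863L + 104729L * k) %% 2147483629L)
  panel <- params$gene_panel
  mu <- matrix(0, length(panel), n, dimnames = list(panel, NULL))
  bm <- params$baseline_mean
  is_v <- role == "vessel"; is_a <- role == "ac"; is_s <- role == "astro"
  for (bg in params$background_genes) mu[bg, ] <- bm[[bg]]
  mu["Gfap", is_a | is_s] <- bm[["Gfap"]]
  mu["Gfap", is_v] <- bm[["Gfap_bbb"]]
  mu["Pecam1", is_v] <- bm[["Pecam1"]]
  mu["Flt1", is_v] <- bm[["Flt1"]]
  mu["Aqp4", is_s] <- mu["Aqp4", is_s] + bm[["Aqp4_bg"]]
  for (g in params$candidate_genes) {
    p <- params$pi[g, group]; m <- bm[[g]]
    mu[g, pair_a] <- mu[g, pair_a] + (1 - p) * m
    mu[g, pair_v] <- mu[g, pair_v] + p * m
  }
  counts <- matrix(0, length(panel), n, dimnames = list(panel, NULL))
  for (i in seq_len(nrow(mu)))
    if (any(mu[i, ] > 0)) counts[i, ] <- draw_counts(mu[i, ],
                                                     params$nb_dispersion)
  # marker noise floor: gated markers stay detectable wherever their
  # allocated mean is positive
  floor1 <- function(gene, sel) {
    s <- sel & mu[gene, ] > 0
    counts[gene, s] <<- pmax(counts[gene, s], 1)
  }
  floor1("Gfap", is_a | is_s)
  floor1("Pecam1", is_v); floor1("Flt1", is_v)
  floor1("Aqp4", is_a | is_s)
  barcodes <- sprintf("%s-r%03d-c%03d", sample_id, r, c)
  bundle <- spot_bundle(counts = counts, gene_ids = panel,
                        barcodes = barcodes, array_row = r, array_col = c,
                        region = region, sample_id = sample_id,
                        group = group)
  bundle$role <- role
  list(bundle = bundle, means = mu,
       pairs = data.frame(vessel = barcodes[pair_v],
                          ac = barcodes[pair_a],
                          sample = sample_id, group = group,
                          stringsAsFactors = FALSE))
}

#' Ground-truth ratio fold change between two groups
#'
#' @param truth truth table from \code{\link{generate_tissue}}.
#' @param group_a,group_b group labels; fold change is a over b.
#' @return Data frame \code{gene}, \code{fold_change} =
#'   expected_ratio(a) / expected_ratio(b).
#' @export
truth_summary <- function(truth, group_a, group_b) {
  for (g in c(group_a, group_b))
    if (!g %in% truth$group)
      stop("truth_summary: group '", g, "' not present in truth table")
  ta <- truth[truth$group == group_a, ]
  tb <- truth[truth$group == group_b, ]
  tb <- tb[match(ta$gene, tb$gene), ]
  data.frame(gene = ta$gene,
             fold_change = ta$expected_ratio / tb$expected_ratio,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cell-type reference expression table
#'
#' A stand-in for a vascular single-cell mean-expression resource, used to
#' drive the marker-screening stage on synthetic data. Designated marker
#' genes are strongly astrocyte-enriched (fold change well above the
#' default 100 cutoff); the remaining genes are expressed comparably
#' across cell types.
#'
#' @param marker_genes genes to make astrocyte-specific.
#' @param other_genes genes expressed across cell types.
#' @param cell_types non-astrocyte cell-type column names.
#' @param marker_fold range of true astrocyte fold enrichment for markers.
#' @param seed integer seed.
#' @return Data frame with a \code{gene} column, an \code{astrocyte}
#'   column and one column per other cell type.
#' @export
generate_celltype_reference <- function(marker_genes, other_genes = character(0),
                                        cell_types = c("endothelial",
                                                       "pericyte",
                                                       "smooth_muscle"),
                                        marker_fold = c(150, 500),
                                        seed = 1L) {
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  genes <- c(marker_genes, other_genes)
  n <- length(genes)
  astro <- numeric(n)
  other <- matrix(0, n, length(cell_types),
                  dimnames = list(genes, cell_types))
  nm <- length(marker_genes)
  astro[seq_len(nm)] <- stats::runif(nm, 200, 1000)
  fold <- stats::runif(nm, marker_fold[1], marker_fold[2])
  for (j in seq_along(cell_types))
    other[seq_len(nm), j] <- astro[seq_len(nm)] / fold *
      stats::runif(nm, 0.2, 1)
  if (length(other_genes)) {
    i <- nm + seq_along(other_genes)
    astro[i] <- stats::runif(length(other_genes), 5, 50)
    for (j in seq_along(cell_types))
      other[i, j] <- astro[i] * stats::runif(length(other_genes), 0.5, 2)
  }
  out <- data.frame(gene = genes, astrocyte = astro, other,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
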