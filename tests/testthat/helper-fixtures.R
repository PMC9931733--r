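# Hand-built fixtures used across the suite. All fixtures are generated
# in code; nothing is read from disk except through the package's own
# writers.

# A bundle from a named list of spots: each spot is list(r, c, counts =
# named vector, region). Genes absent from a spot get 0.
make_bundle <- function(spots, genes = NULL, sample_id = "s1",
                        group = "WT") {
  if (is.null(genes))
    genes <- unique(unlist(lapply(spots, function(s) names(s$counts))))
  counts <- sapply(spots, function(s) {
    v <- stats::setNames(numeric(length(genes)), genes)
    v[names(s$counts)] <- s$counts
    v
  })
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(genes))
  region <- vapply(spots, function(s)
    if (is.null(s$region)) "cortex" else s$region, "")
  spot_bundle(counts = counts, gene_ids = genes,
              barcodes = names(spots),
              array_row = vapply(spots, function(s) s$r, 0),
              array_col = vapply(spots, function(s) s$c, 0),
              region = region, sample_id = sample_id, group = group)
}

# Tiny default synthetic tissue used where scale does not matter.
small_tissue <- function(seed = 1, ...) {
  generate_tissue(synth_params(lattice_rows = 20, lattice_cols = 40,
                               seed = seed, ...))
}

# Brute-force gene-ratio enumerator: loop over neighbors, track the max.
oracle_gene_ratio <- function(ac, bbbs) {
  best <- -Inf
  for (b in bbbs) {
    if (ac + b == 0) next
    r <- b / (ac + b)
    if (r > best) best <- r
  }
  if (is.infinite(best)) NA_real_ else best
}

# From-scratch one-way ANOVA + LSD oracle via explicit sums of squares.
oracle_anova_lsd <- function(groups) {
  vals <- unlist(groups)
  n <- lengths(groups)
  k <- length(groups); N <- length(vals)
  means <- vapply(groups, mean, 0)
  ssb <- sum(n * (means - mean(vals))^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  df1 <- k - 1; df2 <- N - k
  msb <- ssb / df1; msw <- ssw / df2
  F <- msb / msw
  p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  pairs <- utils::combn(names(groups), 2)
  lsd <- stats::setNames(numeric(ncol(pairs)),
                         apply(pairs, 2, function(ab) pair_key(ab[1], ab[2])))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    tstat <- (means[[a]] - means[[b]]) / sqrt(msw * (1 / n[[a]] + 1 / n[[b]]))
    lsd[[j]] <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
  }
  list(F = F, p = p, lsd_p = lsd)
}

# Step-up BH oracle: p * n / rank, then running minimum from the largest.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * n / (n:1)))[ro]
}

# Closed-form Pearson sums.
oracle_pearson <- function(x, y) {
  sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sxx * syy)
  tstat <- r * sqrt((length(x) - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(tstat), length(x) - 2, lower.tail = FALSE),
       slope = sxy / sxx, intercept = mean(y) - sxy / sxx * mean(x))
}

# A square annular vessel whose outer perimeter (44 px) is divisible by 4.
square_ring_mask <- function(dim = c(80, 80)) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[30:41, 30:41] <- TRUE
  m[33:38, 33:38] <- FALSE
  m
}
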