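#' One-way ANOVA with LSD post hoc tests
#'
#' Fisher's omnibus F test across groups followed by least-significant-
#' difference pairwise comparisons: unadjusted t tests using the pooled
#' within-group mean square error and its degrees of freedom.
#'
#' @param data named list of numeric vectors, one per group (each n >= 2),
#'   or a two-column data frame \code{value}, \code{group}.
#' @return A list with \code{F}, \code{p}, \code{df} (between, within) and
#'   \code{lsd_p}, a named vector of pairwise p-values keyed
#'   \code{"a|b"} with the two group labels in sorted order (see
#'   \code{\link{pair_key}}).
#' @export
anova_lsd <- function(data) {
  if (is.data.frame(data)) data <- split(data$value, data$group)
  if (length(data) < 2) stop("anova_lsd: need >= 2 groups")
  n <- lengths(data)
  if (any(n < 2)) stop("anova_lsd: every group needs n >= 2")
  vals <- unlist(data, use.names = FALSE)
  if (any(!is.finite(vals))) stop("anova_lsd: values must be finite")
  grp <- factor(rep(names(data), n), levels = names(data))
  k <- length(data); N <- length(vals)
  gm <- mean(vals)
  means <- vapply(data, mean, 0)
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(data, function(v) sum((v - mean(v))^2), 0))
  df1 <- k - 1L; df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0) { F <- 0; p <- 1 } else { F <- Inf; p <- 0 }
    mse <- 0
  } else if (ssb == 0) {
    # groups exactly identical: avoid floating-point fuzz from the fit
    F <- 0; p <- 1; mse <- ssw / df2
  } else {
    # delegate the fit to the standard linear-model machinery and keep the
    # closed-form sums above only for the degenerate zero-variance guards
    fit <- stats::anova(stats::lm(vals ~ grp))
    F <- fit[["F value"]][1]; p <- fit[["Pr(>F)"]][1]
    mse <- ssw / df2
  }
  labs <- names(data)
  pairs <- utils::combn(labs, 2)
  lsd_p <- stats::setNames(numeric(ncol(pairs)),
                           apply(pairs, 2, function(ab) pair_key(ab[1], ab[2])))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (mse == 0) {
      lsd_p[[j]] <- if (means[[a]] == means[[b]]) 1 else 0
    } else {
      tstat <- (means[[a]] - means[[b]]) /
        sqrt(mse * (1 / n[[a]] + 1 / n[[b]]))
      lsd_p[[j]] <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
    }
  }
  list(F = F, p = p, df = c(between = df1, within = df2), mse = mse,
       lsd_p = lsd_p)
}

#' Canonical key for an unordered group pair
#' @param a,b group labels.
#' @return \code{"a|b"} with the labels sorted.
#' @export
pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, capped at 1 and monotone in
#' rank.
#'
#' @param pvalues numeric vector in [0, 1].
#' @param method \code{"BH"} (default) or \code{"bonferroni"}.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = method)
}

#' Pearson correlation with least-squares line
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with positive
#'   variance.
#' @return A list with \code{r}, \code{p} (two-sided t-based),
#'   \code{slope} and \code{intercept}.
#' @export
pearson_fit <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_fit: x and y lengths differ")
  if (length(x) < 3) stop("pearson_fit: need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_fit: zero variance; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Rank-sum differential expression screen
#'
#' Per-gene comparison of two groups within a spot subset (typically the
#' perivascular AC spots): fold change of depth-normalized group means, a
#' two-sided Wilcoxon rank-sum p-value, Benjamini-Hochberg adjustment, and
#' the filter flag |fold change| > \code{fc_threshold} (two-sided on the
#' log scale) with adjusted p < \code{alpha}.
#'
#' @param bundle a \code{\link{spot_bundle}}.
#' @param barcodes spot subset to compare within.
#' @param group_a,group_b group labels; fold change is a over b.
#' @param fc_threshold fold-change magnitude threshold (default 1.5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param scale_factor depth-normalization target per spot (default 1e4).
#' @param method multiple-testing adjustment passed to
#'   \code{\link{bh_adjust}}.
#' @return Data frame: gene, mean_a, mean_b, fold_change, log2_fc, p,
#'   adj_p, passes_filter.
#' @export
de_screen <- function(bundle, barcodes, group_a, group_b,
                      fc_threshold = 1.5, alpha = 0.05,
                      scale_factor = 1e4, method = "BH") {
  idx <- match(barcodes, bundle$barcodes)
  if (anyNA(idx)) stop("de_screen: unknown barcodes in subset")
  grp <- bundle$group[idx]
  ia <- idx[grp == group_a]; ib <- idx[grp == group_b]
  if (length(ia) < 3 || length(ib) < 3)
    stop("de_screen: each group needs >= 3 spots in the subset")
  m <- bundle$counts[, c(ia, ib), drop = FALSE]
  depth <- Matrix::colSums(m)
  depth[depth == 0] <- 1
  norm <- t(t(as.matrix(m)) / depth * scale_factor)
  na <- length(ia)
  res <- lapply(seq_len(nrow(norm)), function(i) {
    va <- norm[i, seq_len(na)]; vb <- norm[i, -seq_len(na)]
    ma <- mean(va); mb <- mean(vb)
    if (ma == 0 && mb == 0)
      return(data.frame(gene = bundle$gene_ids[i], mean_a = 0, mean_b = 0,
                        fold_change = NA_real_, log2_fc = NA_real_,
                        p = NA_real_))
    fc <- ma / mb
    p <- suppressWarnings(stats::wilcox.test(va, vb)$p.value)
    data.frame(gene = bundle$gene_ids[i], mean_a = ma, mean_b = mb,
               fold_change = fc, log2_fc = log2(fc), p = p)
  })
  res <- do.call(rbind, res)
  res$adj_p <- NA_real_
  def <- !is.na(res$p)
  res$adj_p[def] <- bh_adjust(res$p[def], method = method)
  # a complete knockout (fold change 0 or Inf) passes the magnitude rule
  res$passes_filter <- def & !is.na(res$log2_fc) &
    abs(res$log2_fc) > log2(fc_threshold) & res$adj_p < alpha
  rownames(res) <- NULL
  res
}

#' qPCR relative fold change (the -2dCT rule)
#'
#' Relative quantification against a housekeeping control:
#' fold change = 2^(-ddCT).
#'
#' @param delta_delta_ct finite numeric ddCT value(s).
#' @return 2^(-ddCT).
#' @export
ddct_fold_change <- function(delta_delta_ct) {
  if (any(!is.finite(delta_delta_ct)))
    stop("ddct_fold_change: input must be finite")
  2^(-delta_delta_ct)
}
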