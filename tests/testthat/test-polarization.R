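test_that("gene_ratio matches the per-neighbor maximum rule", {
  expect_equal(gene_ratio(0, 3)$ratio, 1.0)
  expect_equal(gene_ratio(5, 0)$ratio, 0.0)
  g <- gene_ratio(2, c(2, 6))
  expect_equal(g$ratio, 0.75)     # max(2/4, 6/8)
  expect_equal(g$which, 2L)
  expect_true(is.na(gene_ratio(0, c(0, 0))$ratio))
  expect_error(gene_ratio(1, numeric(0)), "non-empty")
  expect_error(gene_ratio(-1, 2), ">= 0")
})

test_that("ratio obeys bounds, monotonicity, scale and max-rule properties", {
  set.seed(11)
  for (i in 1:200) {
    ac <- rpois(1, 3)
    bb <- rpois(sample(1:6, 1), 4)
    if (ac == 0 && all(bb == 0)) next
    r <- gene_ratio(ac, bb)$ratio
    expect_identical(r, oracle_gene_ratio(ac, bb))
    expect_gte(r, 0); expect_lte(r, 1)
    # non-decreasing in any bbb count
    j <- sample(seq_along(bb), 1)
    bb2 <- bb; bb2[j] <- bb2[j] + 1
    expect_gte(gene_ratio(ac, bb2)$ratio, r)
    # non-increasing in the ac count
    expect_lte(gene_ratio(ac + 1, bb)$ratio, r)
    # adding a neighbor never decreases the ratio
    expect_gte(gene_ratio(ac, c(bb, rpois(1, 4)))$ratio, r)
    # common positive scaling leaves the ratio unchanged
    k <- sample(2:5, 1)
    expect_equal(gene_ratio(k * ac, k * bb)$ratio, r)
  }
})

ratio_fixture <- function() {
  genes <- c("Gfap", "Aqp4", "Pecam1", "Flt1", "Gja1")
  b <- make_bundle(list(
    a1 = list(r = 0, c = 0, counts = c(Gfap = 1, Aqp4 = 1)),
    v1 = list(r = 0, c = 2, counts = c(Pecam1 = 1, Flt1 = 1, Aqp4 = 1)),
    a2 = list(r = 4, c = 0, counts = c(Gfap = 1, Aqp4 = 2)),
    v2 = list(r = 4, c = 2, counts = c(Pecam1 = 1, Flt1 = 1, Aqp4 = 2)),
    v3 = list(r = 5, c = 1, counts = c(Pecam1 = 1, Flt1 = 1, Aqp4 = 6))),
    genes = genes)
  cls <- gate_spots(b)
  list(bundle = b, adj = find_adjacent_pairs(cls, b))
}

test_that("ratio table records ratios and argmax neighbors", {
  fx <- ratio_fixture()
  tab <- build_ratio_table(fx$bundle, fx$adj, "Aqp4")
  one <- tab[tab$barcode == "a1", ]
  expect_equal(one$ratio, 0.5)
  expect_identical(one$bbb_barcode, "v1")
  two <- tab[tab$barcode == "a2", ]
  expect_equal(two$ratio, 0.75)           # max(2/4, 6/8)
  expect_identical(two$bbb_barcode, "v3") # the argmax neighbor is stored
  expect_error(build_ratio_table(fx$bundle, fx$adj, "NotAGene"), "NotAGene")
})

test_that("undefined 0/0 records are dropped and QC-counted", {
  fx <- ratio_fixture()
  tab <- build_ratio_table(fx$bundle, fx$adj, c("Aqp4", "Gfap"))
  # Gfap is absent from every vessel spot and positive in AC: ratio 0
  expect_true(all(tab$ratio[tab$gene == "Gfap"] == 0))
  qc <- attr(tab, "qc")
  expect_identical(qc[["Aqp4"]], 0L)
  # a gene detected nowhere is entirely undefined: no records, all dropped
  tab2 <- build_ratio_table(fx$bundle, fx$adj, "Gja1")
  expect_equal(nrow(tab2), 0L)
  expect_identical(attr(tab2, "qc")[["Gja1"]], 2L)
})

test_that("pi = 1 sends every transcript to the endfoot", {
  cand <- c("Aqp4", "Slc4a4")
  pim <- matrix(c(0.7, 0.7, 0.7, 1, 1, 1), nrow = 2, byrow = TRUE,
                dimnames = list(cand, c("WT", "APP/PS1", "APP/PS1+MOX")))
  tis <- generate_tissue(synth_params(lattice_rows = 20, lattice_cols = 40,
                                      candidate_genes = cand, pi = pim,
                                      seed = 6))
  b <- tis$bundle
  # pre-noise allocation: the gene is absent from every astrocyte spot
  expect_true(all(as.matrix(b$counts)["Slc4a4", b$role == "ac"] == 0))
  cls <- gate_spots(b)
  adj <- find_adjacent_pairs(cls, b)
  tab <- build_ratio_table(b, adj, "Slc4a4")
  expect_true(nrow(tab) > 0)
  expect_true(all(tab$ratio == 1))
})

test_that("group summaries compute means, fold changes and tests", {
  tab <- data.frame(
    barcode = sprintf("b%d", 1:6), gene = "Aqp4",
    ac_expr = 1, bbb_expr = 1,
    ratio = c(0.8, 0.6, 0.7, 0.4, 0.5, 0.3),
    bbb_barcode = "v", sample = "s1",
    group = rep(c("WT", "APP/PS1"), each = 3), region = "cortex")
  sm <- summarize_ratios(tab, "WT")
  ad <- sm[sm$group == "APP/PS1", ]
  expect_equal(ad$mean_ratio, 0.4)
  expect_equal(ad$fold_change, 0.4 / 0.7, tolerance = 1e-12)
  expect_equal(sm$fold_change[sm$group == "WT"], 1.0)
  # identical groups: fold change 1, F = 0, p = 1
  tab2 <- tab; tab2$ratio <- rep(c(0.8, 0.6, 0.7), 2)
  sm2 <- summarize_ratios(tab2, "WT")
  expect_true(all(sm2$fold_change == 1))
  expect_true(all(sm2$anova_p == 1))
  expect_error(summarize_ratios(tab, "nope"), "reference")
  # a group with n < 2 in a stratum is flagged with NA statistics
  tab3 <- tab[-(4:5), ]
  sm3 <- summarize_ratios(tab3, "WT")
  expect_true(all(sm3$underpowered))
  expect_true(all(is.na(sm3$anova_p)))
})

test_that("per-sample averaging reduces records to sample means", {
  tab <- data.frame(
    barcode = sprintf("b%d", 1:8), gene = "Aqp4", ac_expr = 1, bbb_expr = 1,
    ratio = c(0.9, 0.7, 0.5, 0.3, 0.8, 0.6, 0.4, 0.2),
    bbb_barcode = "v",
    sample = rep(c("s1", "s2", "s3", "s4"), each = 2),
    group = rep(c("WT", "APP/PS1"), each = 4), region = "cortex")
  sm <- summarize_ratios(tab, "WT", per_sample = TRUE)
  expect_equal(sm$n[sm$group == "WT"], 2L)   # two samples, not four records
  expect_equal(sm$mean_ratio[sm$group == "WT"], mean(c(0.8, 0.4)))
})

test_that("ratio-vs-ratio correlation matches closed-form sums", {
  ta <- data.frame(barcode = c("a", "b", "c"), ratio = c(0, 1, 2))
  tb <- data.frame(barcode = c("a", "b", "c"), ratio = c(0, 2, 2))
  fit <- ratio_vs_ratio_fit(ta, tb)
  expect_equal(fit$r, sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  ident <- ratio_vs_ratio_fit(ta, ta)
  expect_equal(ident$r, 1); expect_equal(ident$slope, 1)
  # zero variance is an undefined-correlation signal, not an answer
  tc <- data.frame(barcode = c("a", "b", "c"), ratio = c(1, 1, 1))
  expect_false(ratio_vs_ratio_fit(ta, tc)$defined)
  # independent ratios are uncorrelated
  set.seed(31)
  big_a <- data.frame(barcode = sprintf("b%d", 1:5000),
                      ratio = runif(5000))
  big_b <- data.frame(barcode = sprintf("b%d", 1:5000),
                      ratio = runif(5000))
  expect_lt(abs(ratio_vs_ratio_fit(big_a, big_b)$r), 0.05)
})
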