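test_that("marker screen applies the strict fold rule with safe denominators", {
  ref <- data.frame(gene = c("X", "Y", "Z", "S"),
                    astrocyte = c(500, 500, 500, 42),
                    endothelial = c(4, 10, 5, 0),
                    pericyte = c(3, 2, 4, 0))
  mk <- screen_markers(ref, fold_threshold = 100)
  called <- mk$gene[mk$is_marker]
  expect_true("X" %in% called)        # 500/4 = 125 > 100
  expect_false("Y" %in% called)       # 500/10 = 50
  expect_false("Z" %in% called)       # exactly 100: strict ">"
  expect_true("S" %in% called)        # zero denominator -> pseudo-mean
  expect_error(screen_markers(ref[, c("gene", "endothelial")]), "astrocyte")
  expect_error(screen_markers(data.frame(gene = "a", astrocyte = 1)),
               "2 cell types")
})

test_that("AEG call uses a strict fraction over the AC population", {
  tab <- data.frame(
    barcode = rep(sprintf("b%d", 1:10), 2),
    gene = rep(c("g7", "g6"), each = 10),
    ac_expr = 1, bbb_expr = 1,
    ratio = c(c(rep(0.5, 7), rep(0, 3)),    # positive in 7 of 10
              c(rep(0.5, 6), rep(0, 4))),   # positive in 6 of 10
    bbb_barcode = "v", sample = "s1", group = "WT", region = "cortex")
  out <- call_aegs(tab, positive_fraction_threshold = 0.60)
  expect_true(out$is_aeg[out$gene == "g7"])    # 0.70 > 0.60
  expect_false(out$is_aeg[out$gene == "g6"])   # exactly 0.60: strict
  expect_equal(out$n_ac, c(10L, 10L))
  # a gene with no defined record is flagged and excluded
  out2 <- call_aegs(tab, genes = c("g7", "ghost"))
  expect_true(out2$flagged[out2$gene == "ghost"])
  expect_false(out2$is_aeg[out2$gene == "ghost"])
  expect_error(call_aegs(tab, population_group = "APP/PS1"), "population")
})

test_that("a gene with zero endfoot allocation is never an AEG", {
  cand <- c("Aqp4", "Slc4a4")
  pim <- matrix(c(0.7, 0.7, 0.7, 0, 0, 0), nrow = 2, byrow = TRUE,
                dimnames = list(cand, c("WT", "APP/PS1", "APP/PS1+MOX")))
  tis <- generate_tissue(synth_params(lattice_rows = 20, lattice_cols = 40,
                                      candidate_genes = cand, pi = pim,
                                      seed = 13))
  cls <- gate_spots(tis$bundle)
  adj <- find_adjacent_pairs(cls, tis$bundle)
  tab <- build_ratio_table(tis$bundle, adj, cand)
  out <- call_aegs(tab)
  expect_false(out$is_aeg[out$gene == "Slc4a4"])
  expect_true(out$is_aeg[out$gene == "Aqp4"])
})

test_that("AD-related call tests unsigned deviation of the fold change", {
  sm <- data.frame(gene = c("down", "small", "up"),
                   region = NA, group = "APP/PS1", n = 10,
                   mean_ratio = c(0.4, 0.45, 0.6),
                   fold_change = c(0.8, 0.9, 1.2),
                   anova_p = 0.01, lsd_p_vs_ref = 0.01,
                   underpowered = FALSE)
  out <- call_ad_aegs(sm, change_threshold = 0.15)
  expect_true(out$is_ad_aeg[out$gene == "down"])    # |0.8 - 1| = 0.2
  expect_false(out$is_ad_aeg[out$gene == "small"])  # 0.1
  expect_true(out$is_ad_aeg[out$gene == "up"])      # unsigned
  down_only <- call_ad_aegs(sm, change_threshold = 0.15,
                            direction = "down")
  expect_false(down_only$is_ad_aeg[down_only$gene == "up"])
  # undefined fold changes are flagged, not called
  sm$fold_change[1] <- NA
  out2 <- call_ad_aegs(sm)
  expect_true(out2$flagged[out2$gene == "down"])
  expect_false(out2$is_ad_aeg[out2$gene == "down"])
})

test_that("the cascade keeps the subset chain and is threshold-monotone", {
  tis <- small_tissue(seed = 17)
  cls <- gate_spots(tis$bundle)
  adj <- find_adjacent_pairs(cls, tis$bundle)
  p <- synth_params(lattice_rows = 20, lattice_cols = 40, seed = 17)
  tab <- build_ratio_table(tis$bundle, adj, p$candidate_genes)
  sm <- summarize_ratios(tab, "WT")
  ref <- generate_celltype_reference(p$candidate_genes,
                                     other_genes = p$background_genes,
                                     seed = 18)
  scr <- screen_aegs(ref, tab, sm)
  expect_true(all(scr$ad_aegs %in% scr$aegs))
  expect_true(all(scr$aegs %in% scr$markers))
  for (fold in c(100, 300, 1000)) {
    for (frac in c(0.6, 0.8, 0.95)) {
      tight <- screen_aegs(ref, tab, sm, fold_threshold = fold,
                           positive_fraction_threshold = frac)
      expect_true(all(tight$markers %in% scr$markers))
      expect_true(all(tight$aegs %in%
                        screen_aegs(ref, tab, sm,
                                    fold_threshold = fold)$aegs))
      expect_true(all(tight$ad_aegs %in% tight$aegs))
    }
  }
  # raising the change threshold never grows the AD-related set
  loose <- call_ad_aegs(sm, change_threshold = 0.05)
  tight <- call_ad_aegs(sm, change_threshold = 0.25)
  expect_true(all(tight$gene[tight$is_ad_aeg] %in%
                    loose$gene[loose$is_ad_aeg]))
})
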