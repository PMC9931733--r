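five_spot_bundle <- function() {
  make_bundle(list(
    A = list(r = 0, c = 0, counts = c(Gfap = 1, Aqp4 = 2), region = "cortex"),
    B = list(r = 0, c = 2, counts = c(Aqp4 = 3), region = "cortex"),
    C = list(r = 0, c = 4, counts = c(Gfap = 1, Aqp4 = 1),
             region = "choroid plexus"),
    D = list(r = 1, c = 1, counts = c(Pecam1 = 2, Flt1 = 1),
             region = "cortex"),
    E = list(r = 1, c = 3, counts = c(Gfap = 1, Aqp4 = 1, Pecam1 = 1,
                                      Flt1 = 2), region = "cortex")),
    genes = c("Gfap", "Aqp4", "Pecam1", "Flt1"))
}

test_that("marker gates and region exclusions label spots as specified", {
  b <- five_spot_bundle()
  cls <- gate_spots(b, gate_config())
  expect_identical(as.character(cls$label),
                   c("AC", "other", "other", "BBB", "BBB"))
  # a double-positive spot follows the overlap policy
  cls_drop <- gate_spots(b, gate_config(overlap_policy = "drop"))
  expect_identical(as.character(cls_drop$label[cls$barcode == "E"]), "other")
  cls_ac <- gate_spots(b, gate_config(overlap_policy = "ac"))
  expect_identical(as.character(cls_ac$label[cls$barcode == "E"]), "AC")
})

test_that("detection requires every marker strictly positive", {
  b <- make_bundle(list(
    x = list(r = 0, c = 0, counts = c(Gfap = 1, Aqp4 = 0)),
    z = list(r = 1, c = 1, counts = c(Gfap = 0, Aqp4 = 0))),
    genes = c("Gfap", "Aqp4", "Pecam1", "Flt1"))
  cls <- gate_spots(b)
  expect_identical(as.character(cls$label), c("other", "other"))
  expect_error(gate_spots(b, gate_config(ac_markers = c(Nope = 0))), "Nope")
})

test_that("gating is exhaustive, exclusive and idempotent", {
  tis <- small_tissue(seed = 2)
  cls1 <- gate_spots(tis$bundle)
  cls2 <- gate_spots(tis$bundle)
  expect_identical(cls1, cls2)
  expect_equal(sum(table(cls1$label)), length(tis$bundle$barcodes))
  # excluded regions never yield AC/BBB regardless of markers
  excl <- tis$bundle$region %in% c("glia limitans", "ependyma",
                                   "choroid plexus")
  expect_true(all(cls1$label[excl] != "AC"))
  excl_bbb <- tis$bundle$region %in% "choroid plexus"
  expect_true(all(cls1$label[excl_bbb] != "BBB"))
})

test_that("hex adjacency finds the six neighbors and drops lone AC", {
  genes <- c("Gfap", "Aqp4", "Pecam1", "Flt1")
  ac <- c(Gfap = 1, Aqp4 = 1); bb <- c(Pecam1 = 1, Flt1 = 1)
  b <- make_bundle(list(
    a = list(r = 2, c = 4, counts = ac),
    n1 = list(r = 2, c = 6, counts = bb),
    n2 = list(r = 3, c = 5, counts = bb),
    far = list(r = 8, c = 8, counts = bb)), genes = genes)
  cls <- gate_spots(b)
  adj <- find_adjacent_pairs(cls, b)
  expect_identical(names(adj), "a")
  expect_identical(adj$a, c("n1", "n2"))
  # a lone AC with no BBB anywhere gives an empty map
  b2 <- make_bundle(list(a = list(r = 2, c = 4, counts = ac)), genes = genes)
  adj2 <- find_adjacent_pairs(gate_spots(b2), b2)
  expect_length(adj2, 0)
})

test_that("hex neighbors equal pixel-distance-minimal pairs on a 6x6 lattice", {
  grid <- expand.grid(r = 0:5, c = 0:5)
  grid <- grid[(grid$r + grid$c) %% 2 == 0, ]
  genes <- c("Gfap", "Aqp4", "Pecam1", "Flt1")
  spots <- lapply(seq_len(nrow(grid)), function(i)
    list(r = grid$r[i], c = grid$c[i], counts = c(Gfap = 1, Aqp4 = 1)))
  names(spots) <- sprintf("s%02d", seq_along(spots))
  b <- make_bundle(spots, genes = genes)
  edges <- aqpolar:::lattice_edges(b, max_steps = 1L)
  # Euclidean oracle on the default pixel coordinates (100 um pitch)
  d <- as.matrix(dist(cbind(b$pxl_row, b$pxl_col)))
  dmin <- min(d[d > 0])
  oracle <- which(abs(d - dmin) < 1e-9, arr.ind = TRUE)
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_identical(key(edges), key(oracle))
  # symmetry: b in neighbors(a) <=> a in neighbors(b)
  expect_setequal(paste(edges[, 1], edges[, 2]),
                  paste(edges[, 2], edges[, 1]))
})

test_that("adjacency radius is configurable in lattice steps", {
  genes <- c("Gfap", "Aqp4", "Pecam1", "Flt1")
  b <- make_bundle(list(
    a = list(r = 0, c = 0, counts = c(Gfap = 1, Aqp4 = 1)),
    two = list(r = 0, c = 4, counts = c(Pecam1 = 1, Flt1 = 1))),
    genes = genes)
  cls <- gate_spots(b)
  expect_length(find_adjacent_pairs(cls, b, max_steps = 1), 0)
  adj2 <- find_adjacent_pairs(cls, b, max_steps = 2)
  expect_identical(adj2$a, "two")
})

test_that("adjacency never crosses samples", {
  genes <- c("Gfap", "Aqp4", "Pecam1", "Flt1")
  b1 <- make_bundle(list(a = list(r = 0, c = 0,
                                  counts = c(Gfap = 1, Aqp4 = 1))),
                    genes = genes, sample_id = "s1")
  b2 <- make_bundle(list(v = list(r = 0, c = 2,
                                  counts = c(Pecam1 = 1, Flt1 = 1))),
                    genes = genes, sample_id = "s2")
  b <- bind_bundles(b1, b2)
  expect_length(find_adjacent_pairs(gate_spots(b), b), 0)
})
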