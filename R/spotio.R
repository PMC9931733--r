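#' Construct a spot bundle
#'
#' A spot bundle is the package's container for one or more Visium-style
#' samples: a genes-by-spots count matrix plus the per-spot lattice
#' coordinates, pixel coordinates, tissue flag, and optional region, sample
#' and experimental-group labels.
#'
#' @param counts genes x spots matrix of non-negative integer counts
#'   (dense or \code{Matrix} sparse).
#' @param gene_ids character vector of gene identifiers (rows of
#'   \code{counts}).
#' @param barcodes character vector of unique spot barcodes (columns).
#' @param array_row,array_col 0-based integer lattice coordinates
#'   (Space Ranger convention: \code{array_row + array_col} is even on the
#'   hexagonal lattice).
#' @param pxl_row,pxl_col numeric pixel coordinates of the spot centers.
#' @param in_tissue logical or 0/1 vector; spots outside tissue are kept in
#'   the files but ignored by analysis.
#' @param region optional character vector of anatomical region labels.
#' @param sample_id character vector (or scalar) identifying the sample each
#'   spot belongs to; lattice adjacency is only defined within a sample.
#' @param group character vector (or scalar) of experimental group labels,
#'   e.g. \code{"WT"}, \code{"APP/PS1"}, \code{"APP/PS1+MOX"}.
#'
#' @return An object of class \code{spot_bundle}.
#' @export
spot_bundle <- function(counts, gene_ids, barcodes,
                        array_row, array_col,
                        pxl_row = NULL, pxl_col = NULL,
                        in_tissue = NULL, region = NULL,
                        sample_id = "sample1", group = NA_character_) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  n_genes <- nrow(counts)
  n_spots <- ncol(counts)
  gene_ids <- as.character(gene_ids)
  barcodes <- as.character(barcodes)
  if (length(gene_ids) != n_genes)
    stop("spot_bundle: length of 'gene_ids' (", length(gene_ids),
         ") does not match nrow(counts) (", n_genes, ")")
  if (length(barcodes) != n_spots)
    stop("spot_bundle: length of 'barcodes' (", length(barcodes),
         ") does not match ncol(counts) (", n_spots, ")")
  if (anyDuplicated(barcodes))
    stop("spot_bundle: duplicate barcodes: ",
         paste(utils::head(barcodes[duplicated(barcodes)], 3), collapse = ", "))
  if (any(counts@x < 0))
    stop("spot_bundle: negative entries in count matrix")
  array_row <- as.integer(array_row)
  array_col <- as.integer(array_col)
  if (length(array_row) != n_spots || length(array_col) != n_spots)
    stop("spot_bundle: array coordinates do not match the number of spots")
  if (is.null(pxl_row)) pxl_row <- array_row * sqrt(3) * 50
  if (is.null(pxl_col)) pxl_col <- array_col * 50
  if (is.null(in_tissue)) in_tissue <- rep(TRUE, n_spots)
  in_tissue <- as.logical(as.integer(in_tissue))
  sample_id <- rep_len(as.character(sample_id), n_spots)
  group <- rep_len(as.character(group), n_spots)
  if (!is.null(region)) region <- rep_len(as.character(region), n_spots)
  dimnames(counts) <- list(gene_ids, barcodes)
  structure(list(counts = counts, gene_ids = gene_ids, barcodes = barcodes,
                 array_row = array_row, array_col = array_col,
                 pxl_row = as.numeric(pxl_row), pxl_col = as.numeric(pxl_col),
                 in_tissue = in_tissue, region = region,
                 sample_id = sample_id, group = group),
            class = "spot_bundle")
}

#' @exportS3Method base::print
print.spot_bundle <- function(x, ...) {
  cat("spot_bundle:", nrow(x$counts), "genes x", ncol(x$counts), "spots\n")
  cat("  samples:", paste(unique(x$sample_id), collapse = ", "), "\n")
  grp <- unique(x$group)
  if (!all(is.na(grp))) cat("  groups: ", paste(grp, collapse = ", "), "\n")
  if (!is.null(x$region))
    cat("  regions:", paste(unique(x$region), collapse = ", "), "\n")
  invisible(x)
}

#' Combine spot bundles (e.g. one per sample) into one
#'
#' Gene panels must be identical; barcodes must remain unique.
#' @param ... \code{spot_bundle} objects.
#' @return A single \code{spot_bundle}.
#' @export
bind_bundles <- function(...) {
  bs <- list(...)
  if (length(bs) == 1L && is.list(bs[[1]]) && !inherits(bs[[1]], "spot_bundle"))
    bs <- bs[[1]]
  stopifnot(length(bs) >= 1L)
  g0 <- bs[[1]]$gene_ids
  for (b in bs)
    if (!identical(b$gene_ids, g0))
      stop("bind_bundles: gene panels differ between bundles")
  spot_bundle(
    counts = do.call(cbind, lapply(bs, `[[`, "counts")),
    gene_ids = g0,
    barcodes = unlist(lapply(bs, `[[`, "barcodes")),
    array_row = unlist(lapply(bs, `[[`, "array_row")),
    array_col = unlist(lapply(bs, `[[`, "array_col")),
    pxl_row = unlist(lapply(bs, `[[`, "pxl_row")),
    pxl_col = unlist(lapply(bs, `[[`, "pxl_col")),
    in_tissue = unlist(lapply(bs, `[[`, "in_tissue")),
    region = if (all(vapply(bs, function(b) !is.null(b$region), TRUE)))
      unlist(lapply(bs, `[[`, "region")) else NULL,
    sample_id = unlist(lapply(bs, `[[`, "sample_id")),
    group = unlist(lapply(bs, `[[`, "group")))
}

#' Write a spot bundle as a standard 10x-style file set
#'
#' Writes \code{matrix.mtx} (MatrixMarket, 1-based indices),
#' \code{features.tsv}, \code{barcodes.tsv},
#' \code{tissue_positions.csv} (barcode,in_tissue,array_row,array_col,
#' pxl_row_in_fullres,pxl_col_in_fullres), and, when present,
#' \code{regions.tsv} (barcode, region) and \code{groups.tsv}
#' (barcode, sample, group).
#'
#' @param bundle a \code{spot_bundle}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "spot_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- bundle$counts
  dimnames(m) <- NULL
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(id = bundle$gene_ids, name = bundle$gene_ids,
                                type = "Gene Expression"),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(bundle$barcodes, file.path(dir, "barcodes.tsv"))
  pos <- data.frame(barcode = bundle$barcodes,
                    in_tissue = as.integer(bundle$in_tissue),
                    array_row = bundle$array_row,
                    array_col = bundle$array_col,
                    pxl_row_in_fullres = bundle$pxl_row,
                    pxl_col_in_fullres = bundle$pxl_col)
  utils::write.table(pos, file.path(dir, "tissue_positions.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$region))
    utils::write.table(data.frame(barcode = bundle$barcodes,
                                  region = bundle$region),
                       file.path(dir, "regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(barcode = bundle$barcodes,
                                sample = bundle$sample_id,
                                group = bundle$group),
                     file.path(dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a spot bundle from a 10x-style file set
#'
#' Reads the files written by \code{\link{write_bundle}}. MatrixMarket
#' 1-based indices are converted to the internal 0-based/1-based R
#' convention by the reader. Loaders validate rather than repair: dimension
#' mismatches, duplicate barcodes, barcodes present in the positions file
#' but absent from the matrix, and negative counts are format errors that
#' name the offending file.
#'
#' @param dir directory containing \code{matrix.mtx}, \code{features.tsv},
#'   \code{barcodes.tsv} and \code{tissue_positions.csv} (plus optional
#'   \code{regions.tsv} and \code{groups.tsv}).
#' @return A \code{spot_bundle}.
#' @export
load_bundle <- function(dir) {
  need <- c("matrix.mtx", "features.tsv", "barcodes.tsv",
            "tissue_positions.csv")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("load_bundle: missing file '", f, "' in ", dir)
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             header = FALSE, colClasses = "character")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(feats) != nrow(m))
    stop("load_bundle: features.tsv has ", nrow(feats),
         " rows but matrix.mtx has ", nrow(m), " rows")
  if (length(barcodes) != ncol(m))
    stop("load_bundle: barcodes.tsv has ", length(barcodes),
         " entries but matrix.mtx has ", ncol(m), " columns")
  if (anyDuplicated(barcodes))
    stop("load_bundle: duplicate barcodes in barcodes.tsv")
  if (any(m@x < 0))
    stop("load_bundle: negative entries in matrix.mtx")
  pos <- utils::read.csv(file.path(dir, "tissue_positions.csv"),
                         colClasses = c(barcode = "character"))
  missing_bc <- setdiff(pos$barcode, barcodes)
  if (length(missing_bc))
    stop("load_bundle: tissue_positions.csv lists barcodes absent from ",
         "the matrix: ", paste(utils::head(missing_bc, 3), collapse = ", "))
  if (!setequal(pos$barcode, barcodes) || nrow(pos) != length(barcodes))
    stop("load_bundle: tissue_positions.csv does not cover every barcode")
  pos <- pos[match(barcodes, pos$barcode), ]
  region <- NULL
  sample_id <- "sample1"; group <- NA_character_
  rf <- file.path(dir, "regions.tsv")
  if (file.exists(rf)) {
    reg <- utils::read.table(rf, sep = "\t", header = TRUE,
                             colClasses = "character")
    region <- reg$region[match(barcodes, reg$barcode)]
    if (anyNA(region))
      stop("load_bundle: regions.tsv does not cover every barcode")
  }
  gf <- file.path(dir, "groups.tsv")
  if (file.exists(gf)) {
    grp <- utils::read.table(gf, sep = "\t", header = TRUE,
                             colClasses = "character")
    i <- match(barcodes, grp$barcode)
    if (anyNA(i)) stop("load_bundle: groups.tsv does not cover every barcode")
    sample_id <- grp$sample[i]; group <- grp$group[i]
  }
  spot_bundle(counts = m, gene_ids = feats[[1]], barcodes = barcodes,
              array_row = pos$array_row, array_col = pos$array_col,
              pxl_row = pos$pxl_row_in_fullres,
              pxl_col = pos$pxl_col_in_fullres,
              in_tissue = pos$in_tissue, region = region,
              sample_id = sample_id, group = group)
}

#' Read gene sets from a GMT file
#'
#' One set per tab-separated line: name, description, then gene ids.
#' Duplicate gene ids within a line are removed (first occurrence kept).
#'
#' @param path path to a GMT file.
#' @return A named list of \code{gene_set} objects, each a list with
#'   elements \code{name}, \code{source} (the description field, typically a
#'   GO accession) and \code{genes}.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("read_gmt: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("read_gmt: line ", i, " has fewer than 3 tab-separated fields")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("read_gmt: line ", i, " (set '", f[1], "') has no genes")
    sets[[i]] <- structure(list(name = f[1], source = f[2], genes = genes),
                           class = "gene_set")
  }
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Save result tables with a reproducible run manifest
#'
#' Writes each table as a TSV with a stable column order (the data frame's
#' own order) and a \code{manifest.json} recording the configuration,
#' seed, package version and per-table row counts. The manifest carries no
#' timestamps so that a rerun with the same inputs is byte-identical.
#'
#' @param tables non-empty named list of data frames.
#' @param dir output directory.
#' @param config optional list of configuration values echoed verbatim into
#'   the manifest.
#' @param seed optional integer seed echoed into the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
save_results <- function(tables, dir, config = NULL, seed = NULL) {
  if (!length(tables) || is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("save_results: 'tables' must be a non-empty named list")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- file.access(dir, mode = 2) == 0
  if (!ok) stop("save_results: directory not writable: ", dir)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    stopifnot(is.data.frame(tab))
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], function(x)
      ifelse(is.na(x), NA, formatC(x, digits = 12, format = "g")))
    utils::write.table(tab, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "aqpolar",
    version = as.character(utils::packageVersion("aqpolar")),
    seed = seed,
    config = config,
    tables = lapply(tables, nrow))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
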