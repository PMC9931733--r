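#' Top-percent intensity mask
#'
#' Thresholds a fluorescence channel at the top \code{percent} of its
#' intensity distribution: pixels strictly above the
#' (100 - percent)-th percentile are positive. On a uniform image the mask
#' is empty (the strict inequality).
#'
#' @param channel numeric intensity matrix.
#' @param percent percentage of the intensity distribution to keep
#'   (default 1, the top 1 percent).
#' @return Logical matrix of the same dimensions.
#' @export
top_percent_mask <- function(channel, percent = 1.0) {
  if (!length(channel)) stop("top_percent_mask: empty raster")
  thr <- stats::quantile(channel, probs = 1 - percent / 100, names = FALSE)
  channel > thr
}

# 4-neighbor shift helper: logical matrix shifted by (dr, dc), padded FALSE.
shift_mask <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  rfrom <- rs - dr; cfrom <- cs - dc
  rok <- rfrom >= 1 & rfrom <= nrow(m)
  cok <- cfrom >= 1 & cfrom <= ncol(m)
  out[rs[rok], cs[cok]] <- m[rfrom[rok], cfrom[cok], drop = FALSE]
  out
}

#' Detect vessels as CD31 rings enclosing a lumen
#'
#' Vessels are the vacuole-like structures in the CD31 channel: connected
#' CD31-positive components that enclose an interior hole (the lumen) of
#' at least \code{min_lumen_px} pixels. Filled blobs without a lumen are
#' rejected. The returned perimeter is the outer boundary of each
#' component (pixels 4-adjacent to the exterior).
#'
#' @param cd31 either a numeric CD31 intensity matrix or a logical mask.
#'   A numeric channel is thresholded at \code{threshold} (default half
#'   the channel maximum; vessels are simply "the structures with CD31
#'   expression", so no top-percent rule applies here), or at the top
#'   \code{percent} of intensities when \code{percent} is given.
#' @param min_lumen_px minimum lumen size in pixels (default 4).
#' @param threshold absolute intensity cutoff (pixels strictly above are
#'   CD31-positive); ignored for logical input.
#' @param percent optional top-percent threshold overriding
#'   \code{threshold}.
#' @return A \code{vessel_set}: list of vessels, each with \code{pixels},
#'   \code{perimeter} (n x 2 matrices of row/col coordinates),
#'   \code{centroid} and \code{lumen_px}; attribute \code{field_dim} holds the
#'   raster dimensions.
#' @export
detect_vessels <- function(cd31, min_lumen_px = 4, threshold = NULL,
                           percent = NULL) {
  mask <- if (is.logical(cd31)) cd31
          else if (!is.null(percent)) top_percent_mask(cd31, percent)
          else cd31 > (if (is.null(threshold)) max(cd31) / 2 else threshold)
  if (!any(mask))
    return(structure(list(), class = "vessel_set", field_dim = dim(mask)))
  lbl <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lbl <- EBImage::imageData(lbl)
  vessels <- list()
  for (id in seq_len(max(lbl))) {
    comp <- lbl == id
    filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp * 1))) > 0
    lumen <- filled & !comp
    if (sum(lumen) < min_lumen_px) next
    outside <- !filled
    ext_adj <- shift_mask(outside, 1, 0) | shift_mask(outside, -1, 0) |
      shift_mask(outside, 0, 1) | shift_mask(outside, 0, -1) |
      border_mask(dim(comp))
    perim <- comp & ext_adj
    pix <- which(comp, arr.ind = TRUE)
    vessels[[length(vessels) + 1L]] <- list(
      pixels = pix,
      perimeter = which(perim, arr.ind = TRUE),
      centroid = colMeans(pix),
      lumen_px = sum(lumen))
  }
  structure(vessels, class = "vessel_set", field_dim = dim(mask))
}

border_mask <- function(d) {
  m <- matrix(FALSE, d[1], d[2])
  m[1, ] <- TRUE; m[d[1], ] <- TRUE; m[, 1] <- TRUE; m[, d[2]] <- TRUE
  m
}

# Coated indicator per perimeter pixel of one vessel.
# radial mode: an AQP4 pixel q supports perimeter pixel p when
# |q - p| <= radius AND the component of (q - p) perpendicular to the
# outward radial direction at p is <= tangential_tol. This keeps the
# probe from bleeding tangentially around the ends of a coated arc.
coated_pixels <- function(vessel, aqp4_idx, pairing_radius_px,
                          pairing_mode, tangential_tol) {
  per <- vessel$perimeter
  m <- nrow(per)
  if (!m) return(logical(0))
  if (!nrow(aqp4_idx)) return(rep(FALSE, m))
  keep <- aqp4_idx[, 1] >= min(per[, 1]) - pairing_radius_px &
    aqp4_idx[, 1] <= max(per[, 1]) + pairing_radius_px &
    aqp4_idx[, 2] >= min(per[, 2]) - pairing_radius_px &
    aqp4_idx[, 2] <= max(per[, 2]) + pairing_radius_px
  q <- aqp4_idx[keep, , drop = FALSE]
  if (!nrow(q)) return(rep(FALSE, m))
  dx <- outer(per[, 1], q[, 1], `-`)
  dy <- outer(per[, 2], q[, 2], `-`)
  dist_ok <- dx * dx + dy * dy <= pairing_radius_px^2
  if (pairing_mode == "disk") return(rowSums(dist_ok) > 0)
  ux <- per[, 1] - vessel$centroid[1]
  uy <- per[, 2] - vessel$centroid[2]
  nrm <- sqrt(ux^2 + uy^2)
  nrm[nrm == 0] <- 1
  ux <- ux / nrm; uy <- uy / nrm
  # tangential component of (q - p): cross product with the radial unit
  tang <- abs((-dx) * uy - (-dy) * ux)
  rowSums(dist_ok & tang <= tangential_tol) > 0
}

#' Quantify the proportion of AQP4-coated vessels
#'
#' For each detected vessel, computes the fraction of outer-perimeter
#' pixels supported by a nearby AQP4-positive pixel and calls the vessel
#' coated when that fraction strictly exceeds \code{coated_threshold}
#' (the quarter rule). The field proportion is the coated fraction of all
#' vessels; optionally, square regions are sampled (seeded, without
#' overlap) and the proportion is also reported per region with its mean.
#'
#' @param vessels a \code{vessel_set} from \code{\link{detect_vessels}}.
#' @param aqp4_mask logical AQP4-positive mask (e.g.
#'   \code{\link{top_percent_mask}} of the AQP4 channel).
#' @param pairing_radius_px maximum pixel distance between a perimeter
#'   pixel and a supporting AQP4 pixel (default 3, must be >= 1).
#' @param coated_threshold strict perimeter-fraction cutoff (default
#'   0.25).
#' @param pairing_mode \code{"radial"} (default; a radial-sector probe
#'   that does not bleed around arc endpoints) or \code{"disk"}
#'   (isotropic distance only).
#' @param tangential_tol tangential tolerance in pixels for the radial
#'   probe (default 0.75).
#' @param n_regions number of randomly placed square regions (0 = whole
#'   field only; default 6 in the field protocol).
#' @param region_size_um region side length in micrometers (default 200).
#' @param um_per_px raster scale (default 1).
#' @param seed seed for region placement.
#' @return A \code{vessel_coating_result}: \code{per_vessel} data frame
#'   (perimeter_px, coated_px, coated_fraction, coated),
#'   \code{proportion_coated}, \code{n_vessels}, and when regions are
#'   sampled, \code{regions} (per-region counts and proportion) and
#'   \code{region_mean}.
#' @export
quantify_coating <- function(vessels, aqp4_mask, pairing_radius_px = 3,
                             coated_threshold = 0.25,
                             pairing_mode = c("radial", "disk"),
                             tangential_tol = 0.75,
                             n_regions = 0, region_size_um = 200,
                             um_per_px = 1, seed = 1L) {
  pairing_mode <- match.arg(pairing_mode)
  if (pairing_radius_px < 1) stop("quantify_coating: pairing radius must be >= 1 px")
  d <- attr(vessels, "field_dim")
  if (!is.null(d) && !identical(as.integer(d), as.integer(dim(aqp4_mask))))
    stop("quantify_coating: AQP4 mask dimensions do not match the vessel field")
  aqp4_idx <- which(aqp4_mask, arr.ind = TRUE)
  per_vessel <- lapply(seq_along(vessels), function(i) {
    v <- vessels[[i]]
    cp <- coated_pixels(v, aqp4_idx, pairing_radius_px, pairing_mode,
                        tangential_tol)
    data.frame(vessel = i,
               centroid_row = v$centroid[1], centroid_col = v$centroid[2],
               perimeter_px = length(cp), coated_px = sum(cp),
               coated_fraction = if (length(cp)) mean(cp) else NA_real_)
  })
  pv <- if (length(per_vessel)) do.call(rbind, per_vessel)
        else data.frame(vessel = integer(0), centroid_row = numeric(0),
                        centroid_col = numeric(0), perimeter_px = integer(0),
                        coated_px = integer(0), coated_fraction = numeric(0))
  pv$coated <- !is.na(pv$coated_fraction) &
    pv$coated_fraction > coated_threshold
  out <- list(per_vessel = pv,
              n_vessels = nrow(pv),
              proportion_coated = if (nrow(pv)) mean(pv$coated) else NA_real_,
              coated_threshold = coated_threshold,
              pairing_radius_px = pairing_radius_px,
              pairing_mode = pairing_mode)
  if (n_regions > 0) {
    side <- round(region_size_um / um_per_px)
    if (is.null(d)) d <- dim(aqp4_mask)
    if (side > min(d))
      stop("quantify_coating: field (", d[1], "x", d[2],
           ") is smaller than the region size (", side, " px)")
    restore <- local_rng(seed)
    on.exit(restore(), add = TRUE)
    corners <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(corners) < n_regions && tries < 1000L) {
      tries <- tries + 1L
      cand <- c(sample.int(d[1] - side + 1L, 1), sample.int(d[2] - side + 1L, 1))
      if (nrow(corners) &&
          any(abs(corners[, 1] - cand[1]) < side &
              abs(corners[, 2] - cand[2]) < side)) next
      corners <- rbind(corners, cand)
    }
    if (nrow(corners) < n_regions)
      stop("quantify_coating: could not place ", n_regions,
           " non-overlapping regions")
    regions <- lapply(seq_len(nrow(corners)), function(j) {
      r0 <- corners[j, 1]; c0 <- corners[j, 2]
      inreg <- pv$centroid_row >= r0 & pv$centroid_row < r0 + side &
        pv$centroid_col >= c0 & pv$centroid_col < c0 + side
      data.frame(region = j, row0 = r0, col0 = c0, side = side,
                 n_vessels = sum(inreg), n_coated = sum(pv$coated[inreg]),
                 proportion = if (any(inreg)) mean(pv$coated[inreg])
                              else NA_real_)
    })
    out$regions <- do.call(rbind, regions)
    def <- !is.na(out$regions$proportion)
    out$region_mean <- if (any(def)) mean(out$regions$proportion[def])
                       else NA_real_
  }
  structure(out, class = "vessel_coating_result")
}

#' @exportS3Method base::print
print.vessel_coating_result <- function(x, ...) {
  cat("vessel coating:", x$n_vessels, "vessels;",
      sprintf("proportion coated = %.3f", x$proportion_coated),
      sprintf("(threshold %.2f, %s probe, radius %g px)\n",
              x$coated_threshold, x$pairing_mode, x$pairing_radius_px))
  invisible(x)
}

#' Generate a synthetic two-channel immunofluorescence field
#'
#' Places non-overlapping annular CD31 vessels and paints AQP4 on a
#' contiguous arc of each vessel's outer perimeter covering exactly the
#' requested fraction of perimeter pixels (an endfoot sheath hugging the
#' vessel wall). The arc start is chosen (seeded) such that the package's
#' default radial pairing recovers exactly the painted pixels, so the
#' recovered coated fraction equals the request to within one
#' perimeter-pixel quantum. Optional Gaussian intensity noise is added on
#' top; with \code{noise_sd = 0} the field is noise-free.
#'
#' @param n_vessels number of vessels.
#' @param coated_fractions vector of length \code{n_vessels}, each in
#'   [0, 1].
#' @param noise_sd Gaussian intensity noise (16-bit units; default 0).
#' @param dim raster dimensions (rows, cols), default 400 x 400.
#' @param radius_range outer-radius range in pixels.
#' @param um_per_px raster scale (default 1).
#' @param seed integer seed.
#' @param max_retries placement retries before giving up.
#' @return A \code{fluorescence_field}: list with \code{cd31} and
#'   \code{aqp4} intensity matrices, \code{um_per_px}, and
#'   \code{annotations} (per-vessel center, radius, requested fraction,
#'   perimeter pixel count and painted pixel count).
#' @export
generate_if_field <- function(n_vessels, coated_fractions, noise_sd = 0,
                              dim = c(400, 400), radius_range = c(12, 18),
                              um_per_px = 1, seed = 1L, max_retries = 200L) {
  if (length(coated_fractions) != n_vessels)
    stop("generate_if_field: coated_fractions must have length n_vessels")
  if (any(coated_fractions < 0 | coated_fractions > 1))
    stop("generate_if_field: coated fractions must lie in [0, 1]")
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  H <- dim[1]; W <- dim[2]
  cd31 <- matrix(0, H, W); aqp4 <- matrix(0, H, W)
  centers <- matrix(numeric(0), 0, 2); radii <- numeric(0)
  for (i in seq_len(n_vessels)) {
    placed <- FALSE
    for (t in seq_len(max_retries)) {
      rr <- stats::runif(1, radius_range[1], radius_range[2])
      margin <- rr + 6
      cy <- stats::runif(1, margin, H - margin)
      cx <- stats::runif(1, margin, W - margin)
      if (nrow(centers)) {
        dd <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
        if (any(dd < radii + rr + 10)) next
      }
      centers <- rbind(centers, c(cy, cx)); radii <- c(radii, rr)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("generate_if_field: could not place ", n_vessels,
           " non-overlapping vessels in a ", H, "x", W, " field")
  }
  ann <- vector("list", n_vessels)
  for (i in seq_len(n_vessels)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]; rr <- radii[i]
    rs <- max(1, floor(cy - rr - 2)):min(H, ceiling(cy + rr + 2))
    cs <- max(1, floor(cx - rr - 2)):min(W, ceiling(cx + rr + 2))
    dmat <- sqrt(outer(rs - cy, cs - cx, function(a, b) a^2 + b^2))
    ring <- dmat >= rr - 2 & dmat <= rr
    cd31[rs, cs][ring] <- 60000
    # perimeter pixels exactly as the quantifier will see them
    sub <- matrix(FALSE, H, W)
    sub[rs, cs] <- ring
    vs <- detect_vessels(sub, min_lumen_px = 1)
    stopifnot(length(vs) == 1L)
    per <- vs[[1]]$perimeter
    n_per <- nrow(per)
    f <- coated_fractions[i]
    k <- round(f * n_per)
    chosen <- choose_arc(vs[[1]], k, seed_start = sample.int(n_per, 1))
    if (length(chosen))
      aqp4[per[chosen, , drop = FALSE]] <- 60000
    ann[[i]] <- data.frame(vessel = i, center_row = cy, center_col = cx,
                           radius = rr, requested_fraction = f,
                           perimeter_px = n_per, painted_px = length(chosen))
  }
  if (noise_sd > 0) {
    cd31 <- pmax(cd31 + stats::rnorm(length(cd31), 0, noise_sd), 0)
    aqp4 <- pmax(aqp4 + stats::rnorm(length(aqp4), 0, noise_sd), 0)
  }
  structure(list(cd31 = cd31, aqp4 = aqp4, um_per_px = um_per_px,
                 annotations = do.call(rbind, ann)),
            class = "fluorescence_field")
}

# Pick k contiguous perimeter pixels (by angular order) such that the
# default radial probe recovers exactly those pixels: candidate starts are
# tried until the probe agrees (rasterized circle boundaries occasionally
# stack two pixels radially; a run boundary between them would leak).
choose_arc <- function(vessel, k, seed_start = 1L) {
  per <- vessel$perimeter
  n <- nrow(per)
  if (k <= 0) return(integer(0))
  if (k >= n) return(seq_len(n))
  ang <- atan2(per[, 2] - vessel$centroid[2], per[, 1] - vessel$centroid[1])
  ord <- order(ang)
  for (off in seq_len(n)) {
    s <- ((seed_start - 1L + off - 1L) %% n)
    idx <- ord[(s + seq_len(k) - 1L) %% n + 1L]
    mask_idx <- per[idx, , drop = FALSE]
    rec <- coated_pixels(vessel, mask_idx, pairing_radius_px = 3,
                         pairing_mode = "radial", tangential_tol = 0.75)
    if (sum(rec) == k && all(which(rec) %in% idx)) return(idx)
  }
  # fall back to the seeded start if no split point is leak-free
  s <- (seed_start - 1L) %% n
  ord[(s + seq_len(k) - 1L) %% n + 1L]
}

#' Write / read a fluorescence field as 16-bit two-channel TIFF + JSON
#'
#' The TIFF stores CD31 and AQP4 as two 16-bit pages; the JSON carries
#' the scale and the ground-truth vessel annotations.
#'
#' @param field a \code{fluorescence_field}.
#' @param tiff_path,json_path output paths.
#' @return Invisibly, \code{tiff_path}.
#' @export
write_if_field <- function(field, tiff_path, json_path = NULL) {
  stopifnot(inherits(field, "fluorescence_field"))
  pages <- list(field$cd31 / 65535, field$aqp4 / 65535)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16)
  if (is.null(json_path))
    json_path <- sub("\\.tiff?$", ".json", tiff_path)
  jsonlite::write_json(list(um_per_px = field$um_per_px,
                            channels = c("CD31", "AQP4"),
                            annotations = field$annotations),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' @rdname write_if_field
#' @param tiff_path path to a two-page 16-bit TIFF.
#' @export
read_if_field <- function(tiff_path, json_path = NULL) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (length(pages) != 2)
    stop("read_if_field: expected a two-channel (two-page) TIFF")
  if (is.null(json_path))
    json_path <- sub("\\.tiff?$", ".json", tiff_path)
  meta <- if (file.exists(json_path)) jsonlite::read_json(json_path,
                                                          simplifyVector = TRUE)
          else list(um_per_px = 1, annotations = NULL)
  structure(list(cd31 = pages[[1]] * 65535, aqp4 = pages[[2]] * 65535,
                 um_per_px = meta$um_per_px,
                 annotations = meta$annotations),
            class = "fluorescence_field")
}
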