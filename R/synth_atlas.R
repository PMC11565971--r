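# Synthetic mini reference atlas: a 3D label volume with a region table,
# programmatic fiducial landmarks, and per-plane bounding boxes. Serves as the
# registration target for synthetic experimental brains. Regions are
# axis-aligned ellipsoids carrying stand-in thalamic nucleus names; region
# assignment downstream only needs a label grid, not real anatomy.

.REGION_NAMES <- c("VM", "VAL", "VPM", "VPL", "ZI", "PF", "MD", "CM")

#' Generate a synthetic mini label atlas
#'
#' Builds a 3D region-label volume at a fixed voxel pitch together with a
#' region table, five midline fiducial landmarks (anterior/posterior corpus
#' callosum, posterior anterior commissure, anterior dentate gyrus, SCO) and
#' two lateral fiducial pairs (stria terminalis, posterior LGN), plus
#' per-plane bounding boxes that collectively define a 3D registration
#' volume. Fiducial coordinates lie on the voxel grid, so at a pitch of
#' \code{voxel_um} they are voxel indices times \code{voxel_um}.
#'
#' The atlas coordinate frame is (ap, dv, ml) in micrometers with AP
#' increasing posteriorly, DV ventrally, and ML signed with midline = 0.
#'
#' @param n_regions Number of labeled regions (2 to 8).
#' @param shape Integer triple: voxel counts along (ap, dv, ml).
#' @param voxel_um Voxel pitch in micrometers.
#' @param section_um Bounding-box plane spacing in micrometers (matches the
#'   physical section thickness of the brains to be registered).
#' @param seed Integer seed; identical parameters and seed give a
#'   bit-identical atlas.
#' @return An object of class \code{atlas_volume}: list with \code{labels}
#'   (3D integer array indexed \[ap, dv, ml\]), \code{voxel_um},
#'   \code{ml_offset_um} (subtracted from the raw ML coordinate so midline
#'   is 0), \code{regions} (data.frame id, acronym), \code{fiducials},
#'   \code{lateral_pairs}, \code{boxes}, \code{section_um}, and
#'   \code{region_voxels} (per-region voxel index matrices for sampling).
#' @export
gen_mini_atlas <- function(n_regions = 6, shape = c(240, 160, 160),
                           voxel_um = 25, section_um = 40, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(!is.finite(shape)) || any(shape < 8)) {
    stop("invalid shape: need three voxel counts, each >= 8")
  }
  if (n_regions < 2 || n_regions > length(.REGION_NAMES)) {
    stop("n_regions must be between 2 and ", length(.REGION_NAMES))
  }
  stopifnot(voxel_um > 0, section_um > 0)
  set.seed(seed)

  v <- voxel_um
  ext <- (shape - 1L) * v                       # physical extent per axis
  ml_offset <- v * floor((shape[3] - 1) / 2)    # midline voxel column

  snap <- function(x) round(x / v) * v

  # Midline fiducials at fixed fractions of the volume, snapped to the grid.
  fid <- data.frame(
    name  = c("cc_anterior", "ac_posterior", "dg_anterior", "cc_posterior", "sco"),
    ap_um = snap(c(0.10, 0.22, 0.38, 0.48, 0.55) * ext[1]),
    dv_um = snap(c(0.15, 0.55, 0.30, 0.18, 0.25) * ext[2]),
    ml_um = 0,
    stringsAsFactors = FALSE
  )

  lat_ml <- snap(c(0.30, 0.38) * ext[3] / 2)
  lateral_pairs <- data.frame(
    name  = rep(c("stria_terminalis", "lgn_posterior"), each = 2),
    side  = rep(c("left", "right"), 2),
    ap_um = snap(rep(c(0.40, 0.62) * ext[1], each = 2)),
    dv_um = snap(rep(c(0.35, 0.45) * ext[2], each = 2)),
    ml_um = c(lat_ml[1], -lat_ml[1], lat_ml[2], -lat_ml[2]),
    stringsAsFactors = FALSE
  )

  # Bounding boxes: half-ellipse width/height profiles over a contiguous AP
  # range spanning both sides of the SCO. Left hemisphere is the positive-ML
  # side here, so boxes run from the midline (medial = 0) to lateral = +w.
  ap_lo <- 0.25 * ext[1]
  ap_hi <- 0.85 * ext[1]
  ks <- seq(ceiling(ap_lo / section_um), floor(ap_hi / section_um))
  ap_k <- ks * section_um
  apc <- (ap_lo + ap_hi) / 2
  apr <- (ap_hi - ap_lo) / 2 * 1.02
  prof <- sqrt(pmax(0.04, 1 - ((ap_k - apc) / apr)^2))
  wmax <- 0.45 * ext[3] / 2 * 2                 # max ML width of the volume
  hmax <- 0.40 * ext[2]
  dv_c <- 0.45 * ext[2]
  boxes <- data.frame(
    section_index = ks,
    ap_um      = ap_k,
    medial_um  = 0,
    lateral_um = wmax * prof,
    dorsal_um  = dv_c - hmax * prof / 2,
    ventral_um = dv_c + hmax * prof / 2
  )

  # Ellipsoidal regions inside the registration volume (left hemisphere,
  # positive ML), placed so they sit well inside every bounding box. Radii
  # scale to a few hundred micrometers at the default extent, the scale of
  # real motor-thalamic nuclei.
  rad <- c(0.04 * ext[1], 0.08 * ext[2], 0.08 * ext[3])
  idx <- seq_len(n_regions)
  centers <- cbind(
    ap = apc + (idx - (n_regions + 1) / 2) * (2.0 * rad[1]),
    dv = dv_c + ifelse(idx %% 2 == 0, 1, -1) * 0.7 * rad[2],
    ml = 0.08 * ext[3] + rad[3] + ((idx %% 3) - 1) * 0.5 * rad[3]
  )

  labels <- array(0L, dim = shape)
  ax_ap <- (seq_len(shape[1]) - 1) * v
  ax_dv <- (seq_len(shape[2]) - 1) * v
  ax_ml <- (seq_len(shape[3]) - 1) * v - ml_offset
  region_voxels <- vector("list", n_regions)
  for (r in idx) {
    ci <- centers[r, ]
    ii <- which(abs(ax_ap - ci[1]) <= rad[1])
    jj <- which(abs(ax_dv - ci[2]) <= rad[2])
    kk <- which(abs(ax_ml - ci[3]) <= rad[3])
    a2 <- ((ax_ap[ii] - ci[1]) / rad[1])^2
    d2 <- ((ax_dv[jj] - ci[2]) / rad[2])^2
    m2 <- ((ax_ml[kk] - ci[3]) / rad[3])^2
    mask <- outer(outer(a2, d2, "+"), m2, "+") <= 1
    sub <- which(mask, arr.ind = TRUE)
    vox <- cbind(ii[sub[, 1]], jj[sub[, 2]], kk[sub[, 3]])
    labels[vox] <- r
    region_voxels[[r]] <- vox
  }
  # Later labels overwrite overlaps; keep only voxels still carrying r.
  for (r in idx) {
    vox <- region_voxels[[r]]
    region_voxels[[r]] <- vox[labels[vox] == r, , drop = FALSE]
  }

  structure(list(
    labels = labels,
    voxel_um = v,
    ml_offset_um = ml_offset,
    regions = data.frame(id = idx, acronym = .REGION_NAMES[idx],
                         stringsAsFactors = FALSE),
    fiducials = fid,
    lateral_pairs = lateral_pairs,
    boxes = boxes,
    section_um = section_um,
    region_voxels = region_voxels,
    seed = seed
  ), class = "atlas_volume")
}

#' Atlas voxel centers in micrometers
#'
#' @param atlas An \code{atlas_volume}.
#' @param vox n x 3 matrix of 1-based voxel indices (ap, dv, ml).
#' @return n x 3 matrix of (ap, dv, ml) micrometer coordinates.
#' @export
voxel_to_um <- function(atlas, vox) {
  if (is.null(dim(vox))) vox <- matrix(vox, nrow = 1)
  v <- atlas$voxel_um
  cbind(ap_um = (vox[, 1] - 1) * v,
        dv_um = (vox[, 2] - 1) * v,
        ml_um = (vox[, 3] - 1) * v - atlas$ml_offset_um)
}

# Internal: micrometer coordinates -> nearest 1-based voxel indices.
# Half-voxel ties round toward the larger index, which orders candidates
# lexicographically by (ap, dv, ml) and keeps assignment deterministic.
um_to_voxel <- function(atlas, pts) {
  pts <- as_points(pts)
  v <- atlas$voxel_um
  cbind(floor(pts[, 1] / v + 0.5) + 1,
        floor(pts[, 2] / v + 0.5) + 1,
        floor((pts[, 3] + atlas$ml_offset_um) / v + 0.5) + 1)
}

#' Write an atlas to disk as a TIFF label stack plus JSON metadata
#'
#' The label volume is stored as a multi-page 16-bit TIFF (one AP plane per
#' page) and all tables (regions, fiducials, boxes, pitch metadata) in an
#' accompanying JSON file.
#'
#' @param atlas An \code{atlas_volume}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pages <- lapply(seq_len(dim(atlas$labels)[1]), function(i) {
    atlas$labels[i, , ] / 65535
  })
  tiff::writeTIFF(pages, file.path(dir, "labels.tif"), bits.per.sample = 16L)
  meta <- atlas[c("voxel_um", "ml_offset_um", "regions", "fiducials",
                  "lateral_pairs", "boxes", "section_um", "seed")]
  meta$shape <- dim(atlas$labels)
  jsonlite::write_json(meta, file.path(dir, "atlas.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an atlas written by \code{write_atlas}
#'
#' @param dir Directory containing \code{labels.tif} and \code{atlas.json}.
#' @return An \code{atlas_volume} (without cached \code{region_voxels}).
#' @export
read_atlas <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "atlas.json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, "labels.tif"), all = TRUE)
  shape <- as.integer(meta$shape)
  labels <- array(0L, dim = shape)
  for (i in seq_along(pages)) {
    labels[i, , ] <- as.integer(round(pages[[i]] * 65535))
  }
  n <- nrow(meta$regions)
  region_voxels <- lapply(seq_len(n), function(r) which(labels == r, arr.ind = TRUE))
  structure(list(
    labels = labels, voxel_um = meta$voxel_um, ml_offset_um = meta$ml_offset_um,
    regions = meta$regions, fiducials = meta$fiducials,
    lateral_pairs = meta$lateral_pairs, boxes = meta$boxes,
    section_um = meta$section_um, region_voxels = region_voxels,
    seed = meta$seed
  ), class = "atlas_volume")
}
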