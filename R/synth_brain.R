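# Synthetic experimental brain: the atlas pushed through a known affine chain
# (fiducial-plane affine, AP shear, SCO-anchored axis scales, extra
# translation) with optional per-slice jitter, carrying fiducial, bounding-box
# and cell annotations. The known chain and cell ground truth make downstream
# registration and mapping recoverable exactly in the noise-free limit.

#' Default ground-truth chain parameters
#'
#' @return A list with \code{step1_linear} (2x2 matrix acting on (ap, dv)),
#'   \code{step1_translation} (ap, dv), \code{shear} (AP-per-ML coefficient),
#'   \code{scales} named (ap, ml, dv), and \code{sco_offset} (ap, dv, ml)
#'   translation applied on top of the SCO anchoring.
#' @export
default_chain_params <- function() {
  list(step1_linear = diag(2), step1_translation = c(0, 0),
       shear = 0, scales = c(ap = 1, ml = 1, dv = 1),
       sco_offset = c(0, 0, 0))
}

# Internal: compose the ground-truth forward (atlas -> brain) 4x4 matrix.
# Scaling is applied about the (transformed) SCO, matching the structure of
# the fitted registration chain, then the SCO is displaced by sco_offset.
truth_chain_matrix <- function(atlas, params) {
  p <- utils::modifyList(default_chain_params(), params)
  if (any(p$scales <= 0)) stop("non-invertible chain: scales must be positive")
  if (abs(det(p$step1_linear)) < 1e-9) stop("non-invertible chain: singular step1_linear")
  m1 <- diag(4)
  m1[1:2, 1:2] <- p$step1_linear
  m1[1:2, 4] <- p$step1_translation
  m12 <- aff_compose(m1, aff_shear_ap_ml(p$shear))
  sco <- as_points(atlas$fiducials[atlas$fiducials$name == "sco", ])
  sco12 <- drop(apply_affine(m12, sco))
  sco_brain <- sco12 + p$sco_offset
  m <- aff_compose(
    m12,
    aff_translation(-sco12),
    aff_scale(ap = p$scales[["ap"]], dv = p$scales[["dv"]], ml = p$scales[["ml"]]),
    aff_translation(sco_brain)
  )
  list(matrix = m, params = p, sco_brain = sco_brain)
}

# Internal: push bounding boxes through an affine by transforming the eight
# corners of each section slab and taking axis-aligned extents.
transform_boxes <- function(m, boxes, section_um) {
  n <- nrow(boxes)
  out <- data.frame(ap_lo = numeric(n), ap_hi = numeric(n), ap_um = numeric(n),
                    medial_um = numeric(n), lateral_um = numeric(n),
                    dorsal_um = numeric(n), ventral_um = numeric(n))
  half <- section_um / 2
  for (i in seq_len(n)) {
    b <- boxes[i, ]
    corners <- as.matrix(expand.grid(ap = b$ap_um + c(-half, half),
                                     dv = c(b$dorsal_um, b$ventral_um),
                                     ml = c(b$medial_um, b$lateral_um)))
    tc <- apply_affine(m, corners)
    out$ap_lo[i] <- min(tc[, 1]); out$ap_hi[i] <- max(tc[, 1])
    out$ap_um[i] <- mean(range(tc[, 1]))
    out$medial_um[i] <- min(tc[, 3]); out$lateral_um[i] <- max(tc[, 3])
    out$dorsal_um[i] <- min(tc[, 2]); out$ventral_um[i] <- max(tc[, 2])
  }
  out
}

#' Generate an annotated synthetic brain from an atlas
#'
#' Applies a known affine chain to the atlas fiducials, bounding boxes and a
#' sampled set of labeled cells, resamples boxes onto the brain's section
#' grid, and adds independent per-slice (ml, dv) jitter emulating drift in
#' serial-section alignment. Cell AP positions are subsequently known only
#' through their section index (AP = index x section thickness), as in real
#' serial-section annotation; fiducial tables carry exact AP.
#'
#' @param atlas An \code{atlas_volume}.
#' @param chain_params Ground-truth chain parameters
#'   (see \code{\link{default_chain_params}}); scales must be positive.
#' @param n_cells Number of labeled cells to plant.
#' @param region_weights Sampling weights over atlas regions (default
#'   uniform). Names or order follow \code{atlas$regions$id}.
#' @param intensity List: \code{meanlog}, \code{sdlog} of the log-normal
#'   brightness distribution and \code{dim_fraction}, the fraction of cells
#'   drawn dim (off-target-like, scaled to 2\% brightness).
#' @param jitter_sd Per-slice jitter standard deviation in micrometers.
#' @param section_um Brain section thickness (default 40).
#' @param seed Integer seed.
#' @param brain_id Identifier carried into the annotation tables.
#' @return A list with \code{brain} (class \code{annotated_brain}: fiducials,
#'   lateral_pairs, boxes, cells, section_um, pixel_um, brain_id) and
#'   \code{truth} (class \code{synth_brain_truth}: chain matrix and params,
#'   per-cell atlas coordinates and true region ids, per-slice jitter table).
#' @export
gen_brain_from_atlas <- function(atlas, chain_params = list(), n_cells = 500,
                                 region_weights = NULL,
                                 intensity = list(meanlog = 4, sdlog = 0.5,
                                                  dim_fraction = 0.05),
                                 jitter_sd = 0, section_um = atlas$section_um,
                                 seed = 1, brain_id = "brain1") {
  stopifnot(n_cells >= 0, jitter_sd >= 0, section_um > 0)
  set.seed(seed)
  tc <- truth_chain_matrix(atlas, chain_params)
  m <- tc$matrix

  # Brain section grid covering the transformed registration volume.
  tboxes <- transform_boxes(m, atlas$boxes, atlas$section_um)
  ks <- seq(ceiling(min(tboxes$ap_lo) / section_um),
            floor(max(tboxes$ap_hi) / section_um))
  jitter <- data.frame(section_index = ks,
                       ml_um = stats::rnorm(length(ks), 0, jitter_sd),
                       dv_um = stats::rnorm(length(ks), 0, jitter_sd))
  if (jitter_sd == 0) jitter$ml_um <- jitter$dv_um <- rep(0, length(ks))
  jit_of <- function(k) {
    i <- match(k, jitter$section_index)
    miss <- is.na(i)
    if (any(miss)) {  # nearest annotated section inherits
      i[miss] <- vapply(k[miss], function(kk) which.min(abs(jitter$section_index - kk)), 1L)
    }
    cbind(ml = jitter$ml_um[i], dv = jitter$dv_um[i])
  }

  # Bounding boxes resampled at each brain section plane from the nearest
  # transformed atlas slab, then jittered with the section.
  bidx <- vapply(ks * section_um, function(a) which.min(abs(tboxes$ap_um - a)), 1L)
  jb <- jit_of(ks)
  boxes <- data.frame(
    section_index = ks,
    medial_um  = tboxes$medial_um[bidx] + jb[, "ml"],
    lateral_um = tboxes$lateral_um[bidx] + jb[, "ml"],
    dorsal_um  = tboxes$dorsal_um[bidx] + jb[, "dv"],
    ventral_um = tboxes$ventral_um[bidx] + jb[, "dv"]
  )

  # Fiducials: exact transformed coordinates (AP carried explicitly in the
  # table), jittered with their section.
  fid_xyz <- apply_affine(m, as_points(atlas$fiducials))
  fk <- round(fid_xyz[, 1] / section_um)
  jf <- jit_of(fk)
  fiducials <- data.frame(name = atlas$fiducials$name,
                          ap_um = fid_xyz[, 1],
                          dv_um = fid_xyz[, 2] + jf[, "dv"],
                          ml_um = fid_xyz[, 3] + jf[, "ml"],
                          section_index = fk, stringsAsFactors = FALSE)
  lat_xyz <- apply_affine(m, as_points(atlas$lateral_pairs))
  lk <- round(lat_xyz[, 1] / section_um)
  jl <- jit_of(lk)
  lateral_pairs <- data.frame(name = atlas$lateral_pairs$name,
                              side = atlas$lateral_pairs$side,
                              ap_um = lat_xyz[, 1],
                              dv_um = lat_xyz[, 2] + jl[, "dv"],
                              ml_um = lat_xyz[, 3] + jl[, "ml"],
                              section_index = lk, stringsAsFactors = FALSE)

  # Cells: sampled uniformly within region voxels (so the nearest atlas voxel
  # is the true region by construction), pushed through the chain, recorded
  # per section with jitter.
  nr <- nrow(atlas$regions)
  if (is.null(region_weights)) region_weights <- rep(1, nr)
  stopifnot(length(region_weights) == nr, all(region_weights >= 0))
  reg <- sample.int(nr, n_cells, replace = TRUE, prob = region_weights)
  v <- atlas$voxel_um
  cell_atlas <- matrix(0, n_cells, 3)
  for (i in seq_len(n_cells)) {
    vox <- atlas$region_voxels[[reg[i]]]
    pick <- vox[sample.int(nrow(vox), 1), ]
    cell_atlas[i, ] <- voxel_to_um(atlas, pick) + stats::runif(3, -v / 2, v / 2) * 0.999
  }
  colnames(cell_atlas) <- c("ap_um", "dv_um", "ml_um")
  cell_brain <- apply_affine(m, cell_atlas)
  ck <- round(cell_brain[, 1] / section_um)
  jc <- jit_of(ck)
  raw <- stats::rlnorm(n_cells, intensity$meanlog, intensity$sdlog)
  dim_mask <- stats::runif(n_cells) < intensity$dim_fraction
  raw[dim_mask] <- raw[dim_mask] * 0.02
  cells <- data.frame(section_index = ck,
                      ml_um = cell_brain[, 3] + jc[, "ml"],
                      dv_um = cell_brain[, 2] + jc[, "dv"],
                      raw_intensity = raw)

  brain <- structure(list(brain_id = brain_id, fiducials = fiducials,
                          lateral_pairs = lateral_pairs, boxes = boxes,
                          cells = cells, section_um = section_um,
                          pixel_um = 0.454), class = "annotated_brain")
  truth <- structure(list(chain_matrix = m, params = tc$params,
                          sco_brain = tc$sco_brain,
                          cell_atlas_coords = cell_atlas,
                          cell_true_regions = atlas$regions$id[reg],
                          jitter_per_slice = jitter),
                     class = "synth_brain_truth")
  list(brain = brain, truth = truth)
}

#' Write an annotated brain as CSV annotation tables
#'
#' Writes \code{fiducials.csv}, \code{lateral_pairs.csv}, \code{boxes.csv},
#' \code{cells.csv} and \code{brain.json} (pitch metadata) to \code{dir}.
#'
#' @param brain An \code{annotated_brain}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_brain <- function(brain, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(brain$fiducials, file.path(dir, "fiducials.csv"), row.names = FALSE)
  utils::write.csv(brain$lateral_pairs, file.path(dir, "lateral_pairs.csv"), row.names = FALSE)
  utils::write.csv(brain$boxes, file.path(dir, "boxes.csv"), row.names = FALSE)
  utils::write.csv(brain$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  jsonlite::write_json(list(brain_id = brain$brain_id,
                            section_um = brain$section_um,
                            pixel_um = brain$pixel_um),
                       file.path(dir, "brain.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an annotated brain written by \code{write_brain}
#'
#' @param dir Directory holding the annotation tables.
#' @return An \code{annotated_brain}.
#' @export
read_brain <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "brain.json"), simplifyVector = TRUE)
  structure(list(
    brain_id = meta$brain_id,
    fiducials = utils::read.csv(file.path(dir, "fiducials.csv")),
    lateral_pairs = utils::read.csv(file.path(dir, "lateral_pairs.csv")),
    boxes = utils::read.csv(file.path(dir, "boxes.csv")),
    cells = utils::read.csv(file.path(dir, "cells.csv")),
    section_um = meta$section_um, pixel_um = meta$pixel_um
  ), class = "annotated_brain")
}
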