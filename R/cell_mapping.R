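# Scoring, filtering and localization of labeled neurons: section level
# balancing, ROI-based intensity scoring, per-brain normalized-intensity
# exclusion, nearest-voxel region assignment, regional distributions and
# binned 3D densities.

#' Level-balance a stack of serial sections
#'
#' Globally rescales each section so that its mean background pixel
#' intensity equals the stack-wide target (the mean of all sections'
#' background means). Only whole-section multiplicative adjustments are
#' made, never local edits.
#'
#' @param stack List of numeric matrices (one image per section).
#' @param background_quantile Pixels at or below this intensity quantile of
#'   a section are treated as background (default 0.1).
#' @return List of rescaled matrices, with attributes \code{scale_factors}
#'   and \code{target_background}.
#' @export
level_balance_sections <- function(stack, background_quantile = 0.1) {
  stopifnot(is.list(stack), length(stack) >= 1)
  bg <- vapply(stack, function(im) {
    thr <- stats::quantile(im, background_quantile, names = FALSE)
    mean(im[im <= thr])
  }, 0)
  if (any(bg <= 0)) stop("section(s) with zero background mean: ",
                         paste(which(bg <= 0), collapse = ", "))
  target <- mean(bg)
  f <- target / bg
  out <- Map(function(im, k) im * k, stack, f)
  attr(out, "scale_factors") <- f
  attr(out, "target_background") <- target
  out
}

#' Neuron intensity in a circular ROI
#'
#' Mean of the brightest \code{top_fraction} of pixels within a circular ROI
#' of diameter \code{roi_diameter_um} centered on the annotation coordinate
#' (defaults: 25 um, top 20\%). ROIs extending past the image edge are
#' clipped to the pixels available.
#'
#' @param image Numeric matrix (row = y, col = x).
#' @param center Length-2 (x, y) center in pixels.
#' @param roi_diameter_um ROI diameter in micrometers.
#' @param top_fraction Fraction of brightest ROI pixels averaged.
#' @param pixel_um Image pixel pitch in micrometers (default 0.454).
#' @return The mean intensity of the top pixels (a.u.).
#' @export
cell_intensity <- function(image, center, roi_diameter_um = 25,
                           top_fraction = 0.2, pixel_um = 0.454) {
  stopifnot(length(center) == 2, top_fraction > 0, top_fraction <= 1)
  r_px <- roi_diameter_um / 2 / pixel_um
  if (center[1] + r_px < 1 || center[1] - r_px > ncol(image) ||
      center[2] + r_px < 1 || center[2] - r_px > nrow(image)) {
    stop("empty ROI: center outside image")
  }
  xs <- seq(max(1, floor(center[1] - r_px)), min(ncol(image), ceiling(center[1] + r_px)))
  ys <- seq(max(1, floor(center[2] - r_px)), min(nrow(image), ceiling(center[2] + r_px)))
  dx2 <- outer((ys - center[2])^2, (xs - center[1])^2, "+")
  vals <- image[ys, xs, drop = FALSE][dx2 <= r_px^2]
  if (length(vals) == 0) stop("empty ROI: no pixels within radius")
  k <- ceiling(top_fraction * length(vals))
  mean(sort(vals, decreasing = TRUE)[seq_len(k)])
}

#' Filter cells by per-brain normalized intensity
#'
#' Min-max normalizes \code{raw_intensity} to \[0, 1\] within each brain and
#' removes cells with normalized intensity at or below \code{threshold}
#' (default 5\%), the off-target exclusion rule. If all intensities in a
#' brain are equal the normalized value is defined as 1 and every cell is
#' retained.
#'
#' @param cells Data.frame with \code{raw_intensity} and optionally
#'   \code{brain_id} (single brain assumed if absent).
#' @param threshold Exclusion threshold on the normalized scale.
#' @return The retained cells with a \code{normalized_intensity} column;
#'   attribute \code{n_excluded} counts removals.
#' @export
filter_cells <- function(cells, threshold = 0.05) {
  stopifnot(nrow(cells) >= 1)
  if (is.null(cells$brain_id)) cells$brain_id <- "brain"
  norm <- stats::ave(cells$raw_intensity, cells$brain_id, FUN = function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(1, length(x)) else (x - rng[1]) / diff(rng)
  })
  cells$normalized_intensity <- norm
  keep <- norm > threshold
  out <- cells[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Assign atlas regions to mapped cells
#'
#' Labels each cell with the region id of the nearest atlas voxel to its
#' registered coordinate; cells beyond the atlas volume get region id NA
#' and acronym \code{"outside"}. Half-voxel ties resolve deterministically
#' toward the larger (ap, dv, ml) voxel index.
#'
#' @param cells_atlas Data.frame with \code{ap_um, dv_um, ml_um}.
#' @param atlas An \code{atlas_volume}.
#' @return The input with \code{region_id} and \code{region} columns;
#'   attribute \code{n_outside}.
#' @export
assign_regions <- function(cells_atlas, atlas) {
  stopifnot(all(is.finite(as.matrix(cells_atlas[, c("ap_um", "dv_um", "ml_um")]))))
  vox <- um_to_voxel(atlas, cells_atlas)
  dims <- dim(atlas$labels)
  inside <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
    vox[, 2] >= 1 & vox[, 2] <= dims[2] &
    vox[, 3] >= 1 & vox[, 3] <= dims[3]
  id <- rep(NA_integer_, nrow(vox))
  id[inside] <- atlas$labels[vox[inside, , drop = FALSE]]
  region <- rep("outside", nrow(vox))
  labeled <- inside & id > 0
  region[inside & id == 0] <- "unlabeled"
  region[labeled] <- atlas$regions$acronym[match(id[labeled], atlas$regions$id)]
  cells_atlas$region_id <- ifelse(inside, id, NA_integer_)
  cells_atlas$region <- region
  attr(cells_atlas, "n_outside") <- sum(!inside)
  cells_atlas
}

#' Per-region distribution of labeled cells
#'
#' Counts cells assigned to each region divided by the total per brain
#' (percentages sum to 100 within a brain), then averages across brains
#' (mean and SEM). Optionally produces a sub-table restricted to a set of
#' regions in which entries averaging below \code{other_threshold_pct} are
#' pooled as \code{"other"}.
#'
#' @param cells Data.frame with \code{region} and \code{brain_id}.
#' @param subset_regions Optional character vector of region acronyms for
#'   the pooled sub-table (e.g. thalamic nuclei only).
#' @param other_threshold_pct Pooling threshold in percent (default 1).
#' @return List with \code{per_brain} (brain x region percent matrix),
#'   \code{summary} (region, mean_pct, sem_pct) and, when
#'   \code{subset_regions} is given, \code{subset} with pooled "other".
#' @export
region_distribution <- function(cells, subset_regions = NULL,
                                other_threshold_pct = 1) {
  if (nrow(cells) == 0) stop("no cells to summarize")
  if (is.null(cells$brain_id)) cells$brain_id <- "brain"
  tab <- table(cells$brain_id, cells$region)
  pct <- sweep(unclass(tab), 1, rowSums(tab), "/") * 100
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  summary <- data.frame(region = colnames(pct),
                        mean_pct = colMeans(pct),
                        sem_pct = apply(pct, 2, sem),
                        row.names = NULL)
  out <- list(per_brain = pct, summary = summary)
  if (!is.null(subset_regions)) {
    sub <- cells[cells$region %in% subset_regions, , drop = FALSE]
    if (nrow(sub) == 0) stop("no cells in the requested region subset")
    stab <- table(factor(sub$brain_id, levels = rownames(pct)),
                  factor(sub$region, levels = subset_regions))
    spct <- sweep(unclass(stab), 1, pmax(rowSums(stab), 1), "/") * 100
    keep <- colMeans(spct) >= other_threshold_pct
    pooled <- cbind(spct[, keep, drop = FALSE],
                    other = rowSums(spct[, !keep, drop = FALSE]))
    out$subset <- data.frame(region = colnames(pooled),
                             mean_pct = colMeans(pooled),
                             sem_pct = apply(pooled, 2, sem),
                             row.names = NULL)
  }
  out
}

#' Binned 3D density of mapped cells
#'
#' Computes, per brain, the percentage of its cells falling in each
#' \code{bin_um}-sided cube of atlas space (default 100 um), then averages
#' the binned percentages across brains without weighting. Bin edges are
#' anchored at the atlas coordinate origin so bins coincide across brains.
#'
#' @param cells Data.frame with \code{brain_id, ap_um, dv_um, ml_um}.
#' @param bin_um Bin side length in micrometers.
#' @return Data.frame of nonzero bins: bin indices \code{i_ap, i_dv, i_ml},
#'   bin-center coordinates, and \code{mean_pct}; attributes
#'   \code{per_brain_sums} (should each be 100) and \code{bin_um}.
#' @export
density_grid <- function(cells, bin_um = 100) {
  stopifnot(nrow(cells) >= 1)
  if (is.null(cells$brain_id)) cells$brain_id <- "brain"
  idx <- cbind(floor(cells$ap_um / bin_um),
               floor(cells$dv_um / bin_um),
               floor(cells$ml_um / bin_um))
  key <- paste(idx[, 1], idx[, 2], idx[, 3], sep = ":")
  brains <- sort(unique(cells$brain_id))
  keys <- sort(unique(key))
  pct <- matrix(0, length(keys), length(brains),
                dimnames = list(keys, brains))
  for (b in brains) {
    sel <- cells$brain_id == b
    t <- table(key[sel])
    pct[names(t), b] <- as.numeric(t) / sum(sel) * 100
  }
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  parts <- matrix(as.integer(parts), ncol = 3)
  out <- data.frame(i_ap = parts[, 1], i_dv = parts[, 2], i_ml = parts[, 3],
                    ap_um = (parts[, 1] + 0.5) * bin_um,
                    dv_um = (parts[, 2] + 0.5) * bin_um,
                    ml_um = (parts[, 3] + 0.5) * bin_um,
                    mean_pct = rowMeans(pct))
  out <- out[order(out$i_ap, out$i_dv, out$i_ml), ]
  rownames(out) <- NULL
  attr(out, "per_brain_sums") <- colSums(pct)
  attr(out, "per_brain_pct") <- pct
  attr(out, "bin_um") <- bin_um
  out
}
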