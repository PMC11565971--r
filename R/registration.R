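# Fiducial/bounding-box affine registration chain.
#
# The atlas (source) is mapped onto an experimental brain (target) by six
# ordered steps: (1) a best-fit affine over the four non-SCO midline
# fiducials, (2) an AP shear fitted on the lateral fiducial pairs, (3) a
# translation anchoring the SCO at the coordinate origin, (4) an AP scale
# matching a cumulative bounding-box volume quantile anterior of the SCO,
# (5-6) ML and DV scales matching mean box width/height within +/-1 mm of
# the SCO, followed by a per-slice (ml, dv) translation compensating serial
# alignment drift. Experimental coordinates are carried back to atlas space
# through the slice-specific inverse.

.MIDLINE_FIT_NAMES <- c("cc_anterior", "ac_posterior", "dg_anterior", "cc_posterior")

#' Fit the midline-fiducial affine step
#'
#' Least-squares affine over the four non-SCO midline fiducials (anterior
#' and posterior corpus callosum, posterior anterior commissure, anterior
#' dentate gyrus). Because the midline points vary only in AP and DV, the
#' fitted linear map takes (ap, dv) as inputs; \code{axes_mode} selects
#' which output axes it is applied to: \code{"ap_dv"} (default; the
#' midsagittal-plane reading) refits AP and DV and passes ML through, the
#' literal \code{"ap_ml"} mode refits AP and ML and passes DV through.
#'
#' @param source_fids,target_fids Fiducial data.frames with columns
#'   \code{name, ap_um, dv_um, ml_um} containing the four fit landmarks.
#' @param axes_mode \code{"ap_dv"} or \code{"ap_ml"}.
#' @return List with \code{matrix} (4x4), \code{residuals} (per-point, um)
#'   and \code{rms_um}.
#' @export
fit_midline_affine <- function(source_fids, target_fids, axes_mode = c("ap_dv", "ap_ml")) {
  axes_mode <- match.arg(axes_mode)
  s <- fid_rows(source_fids, .MIDLINE_FIT_NAMES)
  t <- fid_rows(target_fids, .MIDLINE_FIT_NAMES)

  # Degeneracy: the fit is over (ap, dv); collinear fiducials leave the
  # affine under-determined.
  cs <- scale(s[, c("ap_um", "dv_um")], scale = FALSE)
  sv <- svd(cs)$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    stop("degenerate midline fiducials (collinear in the AP-DV plane): ",
         paste(.MIDLINE_FIT_NAMES, collapse = ", "))
  }

  x <- cbind(s[, "ap_um"], s[, "dv_um"], 1)
  out_axes <- if (axes_mode == "ap_dv") c(1L, 2L) else c(1L, 3L)
  m <- diag(4)
  m[out_axes, c(1, 2, 4)] <- 0
  res <- matrix(0, nrow(s), length(out_axes))
  for (j in seq_along(out_axes)) {
    y <- t[, c("ap_um", "dv_um", "ml_um")[out_axes[j]]]
    beta <- qr.solve(x, y)
    m[out_axes[j], c(1, 2, 4)] <- beta
    res[, j] <- y - x %*% beta
  }
  list(matrix = m, residuals = res, rms_um = sqrt(mean(res^2)))
}

# Internal: pull named fiducial rows as a matrix, erroring on absences.
fid_rows <- function(fids, names_needed) {
  i <- match(names_needed, fids$name)
  if (anyNA(i)) stop("missing fiducial(s): ", paste(names_needed[is.na(i)], collapse = ", "))
  as.matrix(fids[i, c("ap_um", "dv_um", "ml_um")])
}

#' Fit the AP shear step from the lateral fiducial pairs
#'
#' Finds the shear coefficient s of ap' = ap + s * ml that best aligns the
#' left/right AP offsets of the two lateral pairs (stria terminalis,
#' posterior LGN), by least squares over both pairs jointly: s minimizes
#' sum over pairs of (dAP_source + s * dML_source - dAP_target)^2, where d
#' is the left-minus-right difference within a pair.
#'
#' @param lateral_pairs_source,lateral_pairs_target Data.frames with columns
#'   \code{name, side, ap_um, ml_um} (both sides of both pairs).
#' @return List with \code{s} (shear coefficient) and \code{matrix} (4x4).
#' @export
fit_shear <- function(lateral_pairs_source, lateral_pairs_target) {
  d <- function(p) {
    pairs <- unique(p$name)
    t(vapply(pairs, function(nm) {
      l <- p[p$name == nm & p$side == "left", ]
      r <- p[p$name == nm & p$side == "right", ]
      if (nrow(l) != 1 || nrow(r) != 1) stop("lateral pair '", nm, "' missing a side")
      c(dap = l$ap_um - r$ap_um, dml = l$ml_um - r$ml_um)
    }, c(dap = 0, dml = 0)))
  }
  ds <- d(lateral_pairs_source)
  dt <- d(lateral_pairs_target)
  if (any(abs(ds[, "dml"]) < 1e-6)) {
    stop("coincident left/right lateral points (zero ML separation)")
  }
  s <- sum(ds[, "dml"] * (dt[, "dap"] - ds[, "dap"])) / sum(ds[, "dml"]^2)
  list(s = s, matrix = aff_shear_ap_ml(s))
}

#' Anchor the chain at the SCO fiducial
#'
#' Returns the translation that brings the (already transformed) source SCO
#' to the coordinate origin; the target volume is anchored by subtracting
#' its own SCO, which is restored at the end of the chain. After this step
#' both volumes have the SCO at the origin.
#'
#' @param chain_so_far 4x4 matrix of the composed steps so far.
#' @param source_sco,target_sco Length-3 (ap, dv, ml) SCO coordinates, or
#'   one-row fiducial data.frames.
#' @return List with \code{matrix} (source anchoring translation) and
#'   \code{target_sco}.
#' @export
anchor_at_sco <- function(chain_so_far, source_sco, target_sco) {
  if (is.data.frame(source_sco)) source_sco <- drop(as_points(source_sco))
  if (is.data.frame(target_sco)) target_sco <- drop(as_points(target_sco))
  if (length(source_sco) != 3 || anyNA(source_sco)) stop("missing source SCO")
  if (length(target_sco) != 3 || anyNA(target_sco)) stop("missing target SCO")
  sco12 <- drop(apply_affine(chain_so_far, source_sco))
  list(matrix = aff_translation(-sco12), target_sco = as.numeric(target_sco))
}

# Internal: AP length from the anterior pole at which cumulative bounding-box
# volume reaches `fraction` of the total volume anterior of the SCO
# (boxes in SCO-anchored coordinates; anterior = negative AP). 1 um steps.
ap_quantile_length <- function(boxes, fraction, step_um = 1) {
  lo <- pmin(boxes$ap_lo, 0)
  hi <- pmin(boxes$ap_hi, 0)
  keep <- hi > lo
  if (!any(keep)) stop("no bounding-box volume anterior of the SCO")
  lo <- lo[keep]; hi <- hi[keep]
  area <- (boxes$lateral_um - boxes$medial_um)[keep] *
    (boxes$ventral_um - boxes$dorsal_um)[keep]
  pole <- min(lo)
  grid <- seq(pole + step_um / 2, 0, by = step_um)
  dens <- numeric(length(grid))
  for (i in seq_along(lo)) {
    cover <- grid >= lo[i] & grid < hi[i]
    dens[cover] <- dens[cover] + area[i]
  }
  cum <- cumsum(dens * step_um)
  total <- cum[length(cum)]
  if (total <= 0) stop("no bounding-box volume anterior of the SCO")
  j <- which(cum >= fraction * total - 1e-9)[1]
  grid[j] - pole + step_um / 2
}

#' Fit the AP scale step from bounding-box volumes
#'
#' In SCO-anchored coordinates, computes for each box series the AP distance
#' from the anterior pole at which the cumulative bounding-box volume
#' reaches \code{volume_fraction} (default 0.99) of the total volume between
#' the anterior pole and the SCO, and returns the target/source length
#' ratio. The cumulative volume is integrated at 1 um AP steps.
#'
#' @param source_boxes,target_boxes Box data.frames in anchored coordinates
#'   with columns \code{ap_lo, ap_hi, medial_um, lateral_um, dorsal_um,
#'   ventral_um} (see \code{\link{anchored_boxes}}).
#' @param volume_fraction Volume quantile (default 0.99).
#' @return The AP scale factor (target length / source length).
#' @export
fit_ap_scale <- function(source_boxes, target_boxes, volume_fraction = 0.99) {
  stopifnot(volume_fraction > 0, volume_fraction <= 1)
  ap_quantile_length(target_boxes, volume_fraction) /
    ap_quantile_length(source_boxes, volume_fraction)
}

#' Fit the ML and DV scale steps from bounding boxes near the SCO
#'
#' Matches the average width (ML) and height (DV) of individual bounding
#' boxes within \code{window_mm} anterior and posterior of the SCO:
#' ml_scale = mean target width / mean source width, and analogously for
#' heights.
#'
#' @param source_boxes,target_boxes Anchored box data.frames (see
#'   \code{\link{fit_ap_scale}}); the source should already carry the AP
#'   scale so the windows select corresponding boxes.
#' @param window_mm Half-window around the SCO in millimeters (default 1).
#' @return Named numeric c(ml, dv) of scale factors.
#' @export
fit_ml_dv_scales <- function(source_boxes, target_boxes, window_mm = 1) {
  w <- window_mm * 1000
  sel <- function(b, side) {
    k <- abs(b$ap_um) <= w
    if (!any(k)) {
      stop("no ", side, " bounding boxes within +/-", window_mm, " mm of the SCO")
    }
    b[k, ]
  }
  s <- sel(source_boxes, "source"); t <- sel(target_boxes, "target")
  c(ml = mean(t$lateral_um - t$medial_um) / mean(s$lateral_um - s$medial_um),
    dv = mean(t$ventral_um - t$dorsal_um) / mean(s$ventral_um - s$dorsal_um))
}

# Internal: brain boxes (section grid) to the common anchored/augmented form.
brain_boxes_augmented <- function(brain) {
  b <- brain$boxes
  data.frame(ap_lo = b$section_index * brain$section_um - brain$section_um / 2,
             ap_hi = b$section_index * brain$section_um + brain$section_um / 2,
             ap_um = b$section_index * brain$section_um,
             medial_um = b$medial_um, lateral_um = b$lateral_um,
             dorsal_um = b$dorsal_um, ventral_um = b$ventral_um,
             section_index = b$section_index)
}

# Internal: shift augmented boxes by -origin (anchoring).
shift_boxes <- function(boxes, origin) {
  boxes$ap_lo <- boxes$ap_lo - origin[1]
  boxes$ap_hi <- boxes$ap_hi - origin[1]
  boxes$ap_um <- boxes$ap_um - origin[1]
  boxes$dorsal_um <- boxes$dorsal_um - origin[2]
  boxes$ventral_um <- boxes$ventral_um - origin[2]
  boxes$medial_um <- boxes$medial_um - origin[3]
  boxes$lateral_um <- boxes$lateral_um - origin[3]
  boxes
}

#' Anchored box series for an annotated brain or atlas
#'
#' Utility producing the augmented box representation (AP slab extents plus
#' ML/DV limits) in SCO-anchored coordinates, as consumed by
#' \code{\link{fit_ap_scale}} and \code{\link{fit_ml_dv_scales}}.
#'
#' @param boxes Augmented box data.frame (from \code{\link{transform_boxes}}
#'   or internal brain conversion).
#' @param sco Length-3 SCO coordinate in the same frame.
#' @return The anchored box data.frame.
#' @export
anchored_boxes <- function(boxes, sco) shift_boxes(boxes, sco)

#' Fit per-slice drift corrections
#'
#' For each annotated brain section, computes the (ml, dv) translation that
#' moves the dorsomedial corner of the transformed registration volume's
#' bounding box at that AP plane onto the annotated box's dorsomedial
#' corner. Sections whose plane lies outside the transformed volume get a
#' zero correction with a warning.
#'
#' @param chain_matrix Composed 4x4 forward (atlas to brain) matrix of
#'   steps 1-6.
#' @param atlas_boxes Atlas box data.frame (\code{section_index, ap_um,
#'   medial_um, lateral_um, dorsal_um, ventral_um}).
#' @param brain An \code{annotated_brain} (supplies boxes and section pitch).
#' @param atlas_section_um AP slab thickness of the atlas boxes.
#' @return Data.frame \code{section_index, ml_um, dv_um} of translations.
#' @export
fit_per_slice_drift <- function(chain_matrix, atlas_boxes, brain,
                                atlas_section_um) {
  tb <- transform_boxes(chain_matrix, atlas_boxes, atlas_section_um)
  bb <- brain$boxes
  n <- nrow(bb)
  out <- data.frame(section_index = bb$section_index,
                    ml_um = numeric(n), dv_um = numeric(n))
  ap_range <- range(c(tb$ap_lo, tb$ap_hi))
  outside <- 0L
  for (i in seq_len(n)) {
    ap <- bb$section_index[i] * brain$section_um
    if (ap < ap_range[1] - brain$section_um || ap > ap_range[2] + brain$section_um) {
      outside <- outside + 1L
      next
    }
    j <- which.min(abs(tb$ap_um - ap))
    out$ml_um[i] <- bb$medial_um[i] - tb$medial_um[j]
    out$dv_um[i] <- bb$dorsal_um[i] - tb$dorsal_um[j]
  }
  if (outside > 0) {
    warning(outside, " section(s) outside the transformed registration volume; ",
            "zero correction applied")
  }
  out
}

#' Register an annotated brain to an atlas
#'
#' Runs the six affine steps in order (midline-fiducial affine, AP shear,
#' SCO anchoring, AP scale, ML scale, DV scale) followed by the per-slice
#' drift correction, and returns the fitted chain with a per-step report.
#'
#' @param brain An \code{annotated_brain}.
#' @param atlas An \code{atlas_volume} (supplies its programmatic fiducials
#'   and bounding boxes).
#' @param axes_mode Passed to \code{\link{fit_midline_affine}}.
#' @param volume_fraction Passed to \code{\link{fit_ap_scale}}.
#' @param window_mm Passed to \code{\link{fit_ml_dv_scales}}.
#' @return An object of class \code{affine_chain}: composed forward
#'   \code{matrix} (atlas to brain), \code{per_slice} translation table,
#'   \code{section_um}, fitted \code{params} and \code{report}.
#' @export
register_brain <- function(brain, atlas, axes_mode = "ap_dv",
                           volume_fraction = 0.99, window_mm = 1) {
  step1 <- fit_midline_affine(atlas$fiducials, brain$fiducials, axes_mode)
  src_lat <- atlas$lateral_pairs
  src_lat_t <- apply_affine(step1$matrix, as_points(src_lat))
  src_lat_df <- data.frame(name = src_lat$name, side = src_lat$side,
                           ap_um = src_lat_t[, 1], ml_um = src_lat_t[, 3])
  step2 <- fit_shear(src_lat_df, brain$lateral_pairs)
  m12 <- aff_compose(step1$matrix, step2$matrix)

  step3 <- anchor_at_sco(m12,
                         atlas$fiducials[atlas$fiducials$name == "sco", ],
                         brain$fiducials[brain$fiducials$name == "sco", ])
  m123 <- aff_compose(m12, step3$matrix)

  src_anch <- transform_boxes(m123, atlas$boxes, atlas$section_um)
  tgt_anch <- shift_boxes(brain_boxes_augmented(brain), step3$target_sco)
  s_ap <- fit_ap_scale(src_anch, tgt_anch, volume_fraction)
  src_scaled <- transform_boxes(aff_compose(m123, aff_scale(ap = s_ap)),
                                atlas$boxes, atlas$section_um)
  s_mldv <- fit_ml_dv_scales(src_scaled, tgt_anch, window_mm)

  m <- aff_compose(m123,
                   aff_scale(ap = s_ap, dv = s_mldv[["dv"]], ml = s_mldv[["ml"]]),
                   aff_translation(step3$target_sco))
  per_slice <- fit_per_slice_drift(m, atlas$boxes, brain, atlas$section_um)

  structure(list(
    matrix = m,
    per_slice = per_slice,
    section_um = brain$section_um,
    params = list(ap_scale = s_ap, ml_scale = s_mldv[["ml"]],
                  dv_scale = s_mldv[["dv"]], shear = step2$s,
                  axes_mode = axes_mode, volume_fraction = volume_fraction,
                  window_mm = window_mm),
    report = list(midline_rms_um = step1$rms_um,
                  midline_residuals = step1$residuals,
                  steps = list(midline = step1$matrix, shear = step2$matrix,
                               anchor = step3$matrix,
                               target_sco = step3$target_sco))
  ), class = "affine_chain")
}

# Internal: per-slice translation rows for given section indices, with
# nearest-annotated-section fallback (alignment drift is smooth).
per_slice_of <- function(chain, section_index) {
  ps <- chain$per_slice
  if (is.null(ps) || nrow(ps) == 0) {
    return(cbind(ml = numeric(length(section_index)), dv = numeric(length(section_index))))
  }
  i <- match(section_index, ps$section_index)
  miss <- is.na(i)
  if (any(miss)) {
    i[miss] <- vapply(section_index[miss],
                      function(k) which.min(abs(ps$section_index - k)), 1L)
  }
  cbind(ml = ps$ml_um[i], dv = ps$dv_um[i])
}

#' Apply a fitted chain forward (atlas coordinates to brain coordinates)
#'
#' @param chain An \code{affine_chain}.
#' @param pts n x 3 matrix of atlas (ap, dv, ml) micrometers.
#' @return n x 3 matrix of brain coordinates, per-slice correction included
#'   (the slice is taken from the transformed AP position).
#' @export
chain_apply <- function(chain, pts) {
  q <- apply_affine(chain$matrix, as_points(pts))
  k <- round(q[, 1] / chain$section_um)
  t <- per_slice_of(chain, k)
  q[, 3] <- q[, 3] + t[, "ml"]
  q[, 2] <- q[, 2] + t[, "dv"]
  colnames(q) <- c("ap_um", "dv_um", "ml_um")
  q
}

#' Map brain coordinates to atlas space (inverse chain)
#'
#' Applies the slice-specific inverse transformation: the per-slice
#' translation for the point's section is removed, then the inverse of the
#' composed affine is applied.
#'
#' @param chain An \code{affine_chain}.
#' @param pts n x 3 matrix (or data.frame with \code{ap_um, dv_um, ml_um})
#'   of brain coordinates.
#' @param section_index Integer vector of section indices per point; if
#'   NULL, inferred from AP as round(ap / section_um).
#' @return n x 3 matrix of atlas (ap, dv, ml) micrometers.
#' @export
map_to_atlas <- function(chain, pts, section_index = NULL) {
  p <- as_points(pts)
  if (is.null(section_index)) section_index <- round(p[, 1] / chain$section_um)
  t <- per_slice_of(chain, section_index)
  p[, 3] <- p[, 3] - t[, "ml"]
  p[, 2] <- p[, 2] - t[, "dv"]
  out <- apply_affine(aff_invert(chain$matrix), p)
  colnames(out) <- c("ap_um", "dv_um", "ml_um")
  out
}

#' Serialize a fitted chain to JSON
#'
#' @param chain An \code{affine_chain}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
chain_to_json <- function(chain, path) {
  obj <- list(schema = "thalint-chain/1",
              matrix = as.numeric(chain$matrix),  # column-major 4x4
              per_slice = chain$per_slice,
              section_um = chain$section_um,
              params = chain$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a chain serialized by \code{chain_to_json}
#'
#' @param path JSON file path.
#' @return An \code{affine_chain}.
#' @export
chain_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "thalint-chain/1")) stop("unrecognized chain schema")
  structure(list(matrix = matrix(as.numeric(obj$matrix), 4, 4, byrow = FALSE),
                 per_slice = as.data.frame(obj$per_slice),
                 section_um = obj$section_um,
                 params = obj$params), class = "affine_chain")
}
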