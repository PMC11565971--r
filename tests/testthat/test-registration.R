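# Registration chain: each fitting step against an independent oracle,
# composition/inversion identities, order sensitivity, and ground-truth
# recovery on synthetic brains.

fid_df <- function(m) {
  data.frame(name = c("cc_anterior", "ac_posterior", "dg_anterior",
                      "cc_posterior", "sco"),
             ap_um = m[, 1], dv_um = m[, 2], ml_um = m[, 3])
}

test_that("midline affine: identity, exact translation, oracle recovery", {
  src <- cbind(c(500, 1100, 1900, 2400, 2750),
               c(300, 1100, 600, 360, 500), 0)
  s <- fid_df(src)
  f <- fit_midline_affine(s, s)
  expect_equal(f$matrix, diag(4), tolerance = 1e-9)
  expect_lt(f$rms_um, 1e-9)

  t <- s; t$ap_um <- t$ap_um + 1000
  ft <- fit_midline_affine(s, t)
  expect_equal(ft$matrix, aff_translation(c(1000, 0, 0)), tolerance = 1e-9)

  # random invertible 2D affines recovered against a normal-equations oracle
  set.seed(11)
  for (i in 1:50) {
    ab <- matrix(stats::rnorm(4, sd = 0.2), 2) + diag(2)
    tr <- stats::rnorm(2, sd = 500)
    tgt <- s
    xy <- as.matrix(s[, c("ap_um", "dv_um")]) %*% t(ab) +
      matrix(tr, nrow(s), 2, byrow = TRUE)
    tgt$ap_um <- xy[, 1]; tgt$dv_um <- xy[, 2]
    fit <- fit_midline_affine(s, tgt)
    # oracle: explicit normal equations on the four fit landmarks
    x <- cbind(src[1:4, 1], src[1:4, 2], 1)
    for (ax in 1:2) {
      beta_o <- solve(t(x) %*% x, t(x) %*% xy[1:4, ax])
      expect_equal(unname(fit$matrix[ax, c(1, 2, 4)]), drop(beta_o),
                   tolerance = 1e-9)
    }
    expect_equal(unname(fit$matrix[1, 1:2]), ab[1, ], tolerance = 1e-9)
  }

  bad <- s; bad$dv_um <- 2 * bad$ap_um + 5   # collinear
  expect_error(fit_midline_affine(bad, bad), "collinear")
})

pairs_df <- function(ap_l, ap_r, ml = 2000, dv = 1000) {
  data.frame(name = rep(c("stria_terminalis", "lgn_posterior"), each = 2),
             side = rep(c("left", "right"), 2),
             ap_um = c(ap_l[1], ap_r[1], ap_l[2], ap_r[2]),
             dv_um = dv, ml_um = c(ml, -ml, ml, -ml))
}

test_that("shear fit: symmetry, closed form, idempotence, grid oracle", {
  sym <- pairs_df(c(1000, 2000), c(1000, 2000))
  expect_equal(fit_shear(sym, sym)$s, 0, tolerance = 1e-12)

  # target's left points 200 um posterior of right at |ml| = 2000
  tgt <- pairs_df(c(1200, 2200), c(1000, 2000))
  f <- fit_shear(sym, tgt)
  expect_equal(abs(f$s), 0.05, tolerance = 1e-9)

  # idempotence: apply the fitted shear to the source, refit -> 0
  shifted <- sym
  shifted$ap_um <- sym$ap_um + f$s * sym$ml_um
  expect_equal(fit_shear(shifted, tgt)$s, 0, tolerance = 1e-9)

  # brute-force 1D minimization oracle on random asymmetric instances
  set.seed(12)
  for (i in 1:50) {
    src <- pairs_df(stats::rnorm(2, 1500, 300), stats::rnorm(2, 1500, 300),
                    ml = stats::runif(1, 1000, 3000))
    tg <- pairs_df(stats::rnorm(2, 1500, 300), stats::rnorm(2, 1500, 300),
                   ml = src$ml_um[1])
    obj <- function(s) {
      d <- function(p, nm) {
        l <- p[p$name == nm & p$side == "left", ]
        r <- p[p$name == nm & p$side == "right", ]
        c(l$ap_um - r$ap_um, l$ml_um - r$ml_um)
      }
      tot <- 0
      for (nm in unique(src$name)) {
        ds <- d(src, nm); dt <- d(tg, nm)
        tot <- tot + (ds[1] + s * ds[2] - dt[1])^2
      }
      tot
    }
    s_oracle <- stats::optimize(obj, c(-3, 3), tol = 1e-12)$minimum
    expect_equal(fit_shear(src, tg)$s, s_oracle, tolerance = 1e-6)
  }

  coincident <- sym; coincident$ml_um <- 0
  expect_error(fit_shear(coincident, sym), "coincident")
})

test_that("SCO anchoring sends the source SCO to the origin, idempotently", {
  chain <- aff_compose(aff_shear_ap_ml(0.03), aff_translation(c(100, -50, 20)))
  sco_s <- c(2750, 500, 0); sco_t <- c(3100, 640, 35)
  a <- anchor_at_sco(chain, sco_s, sco_t)
  moved <- apply_affine(aff_compose(chain, a$matrix), sco_s)
  expect_equal(drop(moved), c(0, 0, 0), tolerance = 1e-9, ignore_attr = TRUE)

  # already at the origin -> zero translation; applying twice changes nothing
  a2 <- anchor_at_sco(aff_compose(chain, a$matrix), sco_s, sco_t)
  expect_equal(a2$matrix, diag(4), tolerance = 1e-9)
  expect_error(anchor_at_sco(chain, c(1, NA, 0), sco_t), "SCO")
})

# Uniform anchored box series: slabs of given thickness, anterior of SCO.
uniform_boxes <- function(ap_centers, width = 1000, height = 800, th = 40) {
  data.frame(ap_lo = ap_centers - th / 2, ap_hi = ap_centers + th / 2,
             ap_um = ap_centers, medial_um = 0, lateral_um = width,
             dorsal_um = 0, ventral_um = height)
}

# Independent 1-um-step cumulative-volume oracle (different code path:
# edge-sorted piecewise accumulation over an explicit grid loop).
ap_quantile_oracle <- function(boxes, fraction) {
  lo <- pmin(boxes$ap_lo, 0); hi <- pmin(boxes$ap_hi, 0)
  keep <- hi > lo
  lo <- lo[keep]; hi <- hi[keep]
  area <- ((boxes$lateral_um - boxes$medial_um) *
             (boxes$ventral_um - boxes$dorsal_um))[keep]
  pole <- min(lo)
  xs <- seq(pole + 0.5, 0, by = 1)
  cum <- 0
  total <- sum(area * (hi - lo))
  for (x in xs) {
    cum <- cum + sum(area[x >= lo & x < hi])
    if (cum >= fraction * total - 1e-9) return(x - pole + 0.5)
  }
  xs[length(xs)] - pole + 0.5
}

test_that("AP scale: identity, doubling, quantile oracle, limiting case", {
  src <- uniform_boxes(seq(-2000, -40, by = 40))
  expect_equal(fit_ap_scale(src, src), 1, tolerance = 1e-9)

  # doubling AP positions doubles the quantile length
  tgt <- uniform_boxes(seq(-4000, -80, by = 80), th = 80)
  expect_equal(fit_ap_scale(src, tgt), 2, tolerance = 1e-3)

  # non-uniform series against the independent oracle
  set.seed(13)
  for (i in 1:50) {
    n <- sample(10:30, 1)
    b1 <- uniform_boxes(seq(-n * 40, -40, by = 40),
                        width = stats::runif(n, 500, 1500),
                        height = stats::runif(n, 400, 1200))
    m <- sample(10:30, 1)
    b2 <- uniform_boxes(seq(-m * 40, -40, by = 40),
                        width = stats::runif(m, 500, 1500),
                        height = stats::runif(m, 400, 1200))
    got <- fit_ap_scale(b1, b2, 0.99)
    want <- ap_quantile_oracle(b2, 0.99) / ap_quantile_oracle(b1, 0.99)
    expect_equal(got, want, tolerance = 1e-6)
  }

  # volume_fraction = 1 on uniform boxes: ratio of full AP extents
  full_t <- uniform_boxes(seq(-3000, -40, by = 40))
  expect_equal(fit_ap_scale(src, full_t, volume_fraction = 1), 3000 / 2000,
               tolerance = 1e-3)

  posterior_only <- uniform_boxes(seq(40, 2000, by = 40))
  expect_error(fit_ap_scale(posterior_only, src), "anterior")
})

test_that("ML/DV scales: identity, planted ratios, window errors", {
  src <- uniform_boxes(seq(-1200, 1200, by = 40))
  expect_equal(fit_ml_dv_scales(src, src), c(ml = 1, dv = 1), tolerance = 1e-12)

  tgt <- src
  tgt$lateral_um <- tgt$lateral_um * 1.5
  tgt$ventral_um <- tgt$dorsal_um + (tgt$ventral_um - tgt$dorsal_um) * 0.5
  expect_equal(fit_ml_dv_scales(src, tgt), c(ml = 1.5, dv = 0.5), tolerance = 1e-12)

  # direct mean-ratio oracle with randomized per-box sizes
  set.seed(14)
  for (i in 1:50) {
    a <- uniform_boxes(seq(-1000, 1000, by = 40),
                       width = stats::runif(51, 500, 1500),
                       height = stats::runif(51, 400, 1200))
    b <- uniform_boxes(seq(-1000, 1000, by = 40),
                       width = stats::runif(51, 500, 1500),
                       height = stats::runif(51, 400, 1200))
    got <- fit_ml_dv_scales(a, b)
    expect_equal(got[["ml"]], mean(b$lateral_um - b$medial_um) /
                   mean(a$lateral_um - a$medial_um), tolerance = 1e-9)
    expect_equal(got[["dv"]], mean(b$ventral_um - b$dorsal_um) /
                   mean(a$ventral_um - a$dorsal_um), tolerance = 1e-9)
  }

  far <- uniform_boxes(seq(3000, 4000, by = 40))
  expect_error(fit_ml_dv_scales(far, src), "mm of the SCO")
})

test_that("per-slice drift recovers planted section displacements", {
  atlas <- test_atlas()
  g <- gen_brain_from_atlas(atlas, list(), n_cells = 10, jitter_sd = 0, seed = 6)
  chain <- register_brain(g$brain, atlas)
  # corners already coincide (up to the fitted chain's residual)
  expect_lt(max(abs(chain$per_slice$ml_um)), 1e-6)
  expect_lt(max(abs(chain$per_slice$dv_um)), 1e-6)

  # displace one annotated section by (+30, -20): that section's correction
  # becomes exactly (+30, -20), the rest stay 0
  brain2 <- g$brain
  i <- 5
  brain2$boxes$medial_um[i] <- brain2$boxes$medial_um[i] + 30
  brain2$boxes$lateral_um[i] <- brain2$boxes$lateral_um[i] + 30
  brain2$boxes$dorsal_um[i] <- brain2$boxes$dorsal_um[i] - 20
  brain2$boxes$ventral_um[i] <- brain2$boxes$ventral_um[i] - 20
  ps <- fit_per_slice_drift(chain$matrix, atlas$boxes, brain2, atlas$section_um)
  expect_equal(ps$ml_um[i], 30, tolerance = 1e-6)
  expect_equal(ps$dv_um[i], -20, tolerance = 1e-6)
  expect_lt(max(abs(ps$ml_um[-i])), 1e-6)
  expect_lt(max(abs(ps$dv_um[-i])), 1e-6)
})

test_that("composed chain: inverse round trip, serialization, order pinning", {
  atlas <- test_atlas()
  set.seed(15)
  g <- gen_brain_from_atlas(atlas, random_chain_params(), n_cells = 50,
                            jitter_sd = 15, seed = 16)
  chain <- register_brain(g$brain, atlas)

  pts <- cbind(stats::runif(1000, 500, 2500), stats::runif(1000, 300, 1700),
               stats::runif(1000, 0, 800))
  fwd <- chain_apply(chain, pts)
  expect_lt(max(abs(map_to_atlas(chain, fwd) - pts)), 1e-6)

  f <- withr::local_tempfile(fileext = ".json")
  chain_to_json(chain, f)
  chain2 <- chain_from_json(f)
  expect_lt(max(abs(chain_apply(chain2, pts) - fwd)), 1e-8)

  # the composed matrix equals deanchor . scales . anchor . shear . midline
  st <- chain$report$steps
  p <- chain$params
  recomposed <- aff_compose(st$midline, st$shear, st$anchor,
                            aff_scale(ap = p$ap_scale, dv = p$dv_scale,
                                      ml = p$ml_scale),
                            aff_translation(st$target_sco))
  expect_equal(chain$matrix, recomposed, tolerance = 1e-9)

  # order sensitivity: permuting the steps changes the mapping
  permuted <- aff_compose(st$shear, st$midline, st$anchor,
                          aff_scale(ap = p$ap_scale, dv = p$dv_scale,
                                    ml = p$ml_scale),
                          aff_translation(st$target_sco))
  expect_gt(max(abs(apply_affine(permuted, pts) - apply_affine(chain$matrix, pts))),
            1)
})

test_that("known ground-truth chains are recovered (composed map and ML scale)", {
  atlas <- test_atlas()
  cp <- list(shear = 0.04, scales = c(ap = 1.15, ml = 0.9, dv = 1.05),
             step1_translation = c(800, -500), sco_offset = c(300, -200, 100))
  g <- gen_brain_from_atlas(atlas, cp, n_cells = 100, jitter_sd = 0, seed = 17)
  chain <- register_brain(g$brain, atlas)

  # the ML scale is not absorbed by the midline fit and must come back to 1%
  expect_lt(abs(chain$params$ml_scale - 0.9) / 0.9, 0.01)
  # composed linear part agrees with the ground-truth matrix to 1%
  lin_rel <- abs(chain$matrix[1:3, 1:3] - g$truth$chain_matrix[1:3, 1:3]) /
    pmax(abs(g$truth$chain_matrix[1:3, 1:3]), 0.5)
  expect_lt(max(lin_rel), 0.01)
  # identity brain: whole chain collapses to the identity
  gid <- gen_brain_from_atlas(atlas, list(), n_cells = 20, jitter_sd = 0, seed = 18)
  cid <- register_brain(gid$brain, atlas)
  expect_lt(max(abs(cid$matrix - diag(4))), 1e-6)
})

test_that("cells map back to truth within tolerance under jitter", {
  atlas <- test_atlas()
  g <- gen_brain_from_atlas(atlas, list(shear = 0.03,
                                        scales = c(ap = 1.1, ml = 0.95, dv = 1.02),
                                        sco_offset = c(200, 100, -50)),
                            n_cells = 300, jitter_sd = 20, seed = 19)
  err <- cell_map_errors(atlas, g)
  expect_lte(stats::median(err), 25)
})
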