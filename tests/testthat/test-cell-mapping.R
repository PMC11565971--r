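# Cell scoring, filtering, region assignment and density binning, each
# against enumeration oracles.

test_that("level balancing equalizes background means by global scaling only", {
  set.seed(21)
  base <- matrix(stats::runif(400, 10, 20), 20)
  stack <- list(base, base * 2, base * 0.7)
  out <- level_balance_sections(stack)
  f <- attr(out, "scale_factors")
  expect_equal(f[2] / f[1], 0.5, tolerance = 1e-12)
  bg <- vapply(out, function(im) {
    thr <- stats::quantile(im, 0.1, names = FALSE); mean(im[im <= thr])
  }, 0)
  expect_lt(diff(range(bg)), 1e-9)
  # already balanced -> unchanged
  out2 <- level_balance_sections(out)
  expect_equal(out2[[1]], out[[1]], tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(level_balance_sections(list(matrix(0, 4, 4))), "zero background")
})

test_that("ROI intensity averages the brightest pixels, clipped at edges", {
  img <- matrix(5, 60, 60)
  expect_equal(cell_intensity(img, c(30, 30), pixel_um = 1), 5)

  # plant the values 1..100 in a disc that holds exactly 100 lattice pixels:
  # mean of the top 20 of 1..100 is 90.5
  img2 <- matrix(0, 60, 60)
  set.seed(22)
  ctr <- c(30, 30.4)
  d2 <- sort(outer((1:60 - ctr[2])^2, (1:60 - ctr[1])^2, "+"))
  r <- sqrt((d2[100] + d2[101]) / 2)   # disc holding exactly 100 pixels
  coords <- which(outer((1:60 - ctr[2])^2, (1:60 - ctr[1])^2, "+") <= r^2,
                  arr.ind = TRUE)
  expect_identical(nrow(coords), 100L)
  img2[coords] <- sample(1:100)
  got <- cell_intensity(img2, ctr, roi_diameter_um = 2 * r, top_fraction = 0.2,
                        pixel_um = 1)
  vals <- img2[coords]
  expect_equal(got, mean(sort(vals, decreasing = TRUE)[1:20]))
  expect_equal(got, 90.5)

  # shrinking top_fraction never decreases the top-k mean
  fr <- c(1, 0.5, 0.2, 0.1, 0.05)
  res <- vapply(fr, function(tf) cell_intensity(img2, ctr, 2 * r, tf, 1), 0)
  expect_true(all(diff(res) >= 0))

  # edge clipping still returns a value; fully outside errors
  expect_gt(cell_intensity(img2, c(1, 1), 25, 0.2, 1), -Inf)
  expect_error(cell_intensity(img2, c(-100, -100), 25, 0.2, 1), "ROI")
})

test_that("intensity filter matches the min-max enumeration oracle", {
  cells <- data.frame(raw_intensity = 1:100)
  out <- filter_cells(cells)
  expect_identical(nrow(out), 95L)
  expect_identical(attr(out, "n_excluded"), 5L)
  # oracle on random instances, including multi-brain normalization
  set.seed(23)
  for (i in 1:20) {
    d <- data.frame(raw_intensity = stats::rlnorm(500, 4, 1),
                    brain_id = sample(c("a", "b"), 500, TRUE))
    got <- filter_cells(d, 0.05)
    keep_oracle <- unlist(lapply(split(seq_len(500), d$brain_id), function(ix) {
      x <- d$raw_intensity[ix]
      ix[(x - min(x)) / (max(x) - min(x)) > 0.05]
    }))
    expect_setequal(as.integer(rownames(got)), keep_oracle)
  }
  # all-equal intensities: everything retained
  eq <- filter_cells(data.frame(raw_intensity = rep(3, 10)))
  expect_identical(nrow(eq), 10L)
  expect_true(all(eq$normalized_intensity == 1))
  # retained count non-increasing in threshold
  d <- data.frame(raw_intensity = stats::runif(200))
  ns <- vapply(c(0, 0.05, 0.2, 0.5, 0.9),
               function(th) nrow(filter_cells(d, th)), 0L)
  expect_true(all(diff(ns) <= 0))
})

test_that("region assignment equals per-axis nearest-center enumeration", {
  atlas <- test_atlas()
  v <- atlas$voxel_um
  dims <- dim(atlas$labels)
  set.seed(24)
  n <- 10000
  pts <- data.frame(
    ap_um = stats::runif(n, -2 * v, (dims[1] + 1) * v),
    dv_um = stats::runif(n, -2 * v, (dims[2] + 1) * v),
    ml_um = stats::runif(n, -atlas$ml_offset_um - 2 * v,
                         (dims[3] - 1) * v - atlas$ml_offset_um + 2 * v))
  got <- assign_regions(pts, atlas)
  # oracle: argmin over explicit per-axis center lists
  ax <- list((seq_len(dims[1]) - 1) * v,
             (seq_len(dims[2]) - 1) * v,
             (seq_len(dims[3]) - 1) * v - atlas$ml_offset_um)
  want <- vapply(seq_len(n), function(i) {
    p <- c(pts$ap_um[i], pts$dv_um[i], pts$ml_um[i])
    idx <- vapply(1:3, function(a) which.min(abs(ax[[a]] - p[a])), 1L)
    near <- vapply(1:3, function(a) abs(ax[[a]][idx[a]] - p[a]) <= v / 2 + 1e-9, TRUE)
    # outside the volume when the point is farther than half a voxel beyond
    # the outermost center
    if (any(p < c(0, 0, -atlas$ml_offset_um) - v / 2 |
              p > c(ax[[1]][dims[1]], ax[[2]][dims[2]], ax[[3]][dims[3]]) + v / 2)) {
      return(NA_integer_)
    }
    atlas$labels[idx[1], idx[2], idx[3]]
  }, 1L)
  expect_identical(got$region_id, want)
  # a point at an exact voxel center of region r maps to r
  vox <- atlas$region_voxels[[2]][1, ]
  ctr <- voxel_to_um(atlas, vox)
  one <- assign_regions(data.frame(ap_um = ctr[1], dv_um = ctr[2], ml_um = ctr[3]),
                        atlas)
  expect_identical(one$region_id, 2L)
  far <- assign_regions(data.frame(ap_um = -1e6, dv_um = 0, ml_um = 0), atlas)
  expect_identical(far$region, "outside")
})

test_that("region distribution normalizes per brain and recovers planted splits", {
  one <- data.frame(region = rep("VM", 7), brain_id = "b1")
  d1 <- region_distribution(one)
  expect_equal(unname(d1$per_brain[1, "VM"]), 100)

  atlas <- test_atlas()
  weights <- c(60, 30, 10, 0)
  cells <- list()
  for (b in 1:3) {
    g <- gen_brain_from_atlas(atlas, list(), n_cells = 1000,
                              region_weights = weights, jitter_sd = 0,
                              seed = 30 + b, brain_id = paste0("b", b))
    ca <- as.data.frame(g$truth$cell_atlas_coords)
    ca$brain_id <- paste0("b", b)
    cells[[b]] <- assign_regions(ca, atlas)
  }
  cells <- do.call(rbind, cells)
  dist <- region_distribution(cells)
  expect_true(all(abs(rowSums(dist$per_brain) - 100) < 1e-9))
  m <- dist$summary
  expect_lt(abs(m$mean_pct[m$region == "VM"] - 60), 2)
  expect_lt(abs(m$mean_pct[m$region == "VAL"] - 30), 2)
  expect_lt(abs(m$mean_pct[m$region == "VPM"] - 10), 2)
  expect_error(region_distribution(cells[0, ]), "no cells")
})

test_that("density grid sums to 100 per brain and is permutation invariant", {
  single <- data.frame(brain_id = "b", ap_um = 151, dv_um = 49, ml_um = -12)
  dg <- density_grid(single)
  expect_identical(nrow(dg), 1L)
  expect_equal(dg$mean_pct, 100)

  set.seed(25)
  cells <- data.frame(brain_id = sample(c("b1", "b2", "b3"), 2000, TRUE),
                      ap_um = stats::rnorm(2000, 2000, 300),
                      dv_um = stats::rnorm(2000, 1000, 200),
                      ml_um = stats::rnorm(2000, 0, 250))
  g1 <- density_grid(cells)
  expect_true(all(abs(attr(g1, "per_brain_sums") - 100) < 1e-9))
  perm <- cells[sample(nrow(cells)), ]
  g2 <- density_grid(perm)
  expect_equal(g1, g2, ignore_attr = TRUE)

  # enumeration oracle for one brain's bin percentages
  b1 <- cells[cells$brain_id == "b1", ]
  pct <- attr(g1, "per_brain_pct")[, "b1"]
  for (k in sample(length(pct), 25)) {
    key <- strsplit(names(pct)[k], ":", fixed = TRUE)[[1]]
    i <- as.integer(key)
    n_in <- sum(floor(b1$ap_um / 100) == i[1] &
                  floor(b1$dv_um / 100) == i[2] &
                  floor(b1$ml_um / 100) == i[3])
    expect_equal(unname(pct[k]), n_in / nrow(b1) * 100)
  }

  # planted cluster: argmax bin lands within one bin of the planted center
  planted <- data.frame(brain_id = "p",
                        ap_um = stats::rnorm(500, 1550, 60),
                        dv_um = stats::rnorm(500, 850, 60),
                        ml_um = stats::rnorm(500, 250, 60))
  gp <- density_grid(planted)
  top <- gp[which.max(gp$mean_pct), ]
  expect_lte(abs(top$i_ap - 15), 1)
  expect_lte(abs(top$i_dv - 8), 1)
  expect_lte(abs(top$i_ml - 2), 1)
})
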