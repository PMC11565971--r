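# Shared fixtures, memoized per test run. The small atlas keeps unit tests
# fast; acceptance tests build the default-size atlas themselves.

.fixture_env <- new.env()

test_atlas <- function() {
  if (is.null(.fixture_env$atlas)) {
    .fixture_env$atlas <- gen_mini_atlas(n_regions = 4, shape = c(120, 80, 80),
                                         voxel_um = 25, seed = 42)
  }
  .fixture_env$atlas
}

default_atlas <- function() {
  if (is.null(.fixture_env$default_atlas)) {
    .fixture_env$default_atlas <- gen_mini_atlas(seed = 1)
  }
  .fixture_env$default_atlas
}

# Random ground-truth chain parameters within the study conditions:
# scales 0.8-1.2, |shear| <= 0.06, |translations| <= 2 mm.
random_chain_params <- function() {
  list(shear = stats::runif(1, -0.06, 0.06),
       scales = c(ap = stats::runif(1, 0.8, 1.2),
                  ml = stats::runif(1, 0.8, 1.2),
                  dv = stats::runif(1, 0.8, 1.2)),
       step1_translation = stats::runif(2, -2000, 2000),
       sco_offset = stats::runif(3, -1000, 1000))
}

# Brain-frame cell coordinates as consumed by map_to_atlas (AP known only
# through the section index).
brain_cell_points <- function(brain) {
  cbind(ap_um = brain$cells$section_index * brain$section_um,
        dv_um = brain$cells$dv_um, ml_um = brain$cells$ml_um)
}

cell_map_errors <- function(atlas, g, chain = NULL) {
  if (is.null(chain)) chain <- register_brain(g$brain, atlas)
  mapped <- map_to_atlas(chain, brain_cell_points(g$brain),
                         g$brain$cells$section_index)
  sqrt(rowSums((mapped - g$truth$cell_atlas_coords)^2))
}
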