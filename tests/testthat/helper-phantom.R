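# Small phantom specs shared across test files. Sizes are chosen so a full
# generate + analyze cycle runs in well under a second.

tiny_spec <- function(...) {
  defaults <- list(
    grid_shape = c(16, 16, 8), n_volumes = 40,
    n_per_group = c(control = 3, patient = 3),
    networks = list(network_spec("net", rbind(c(0, -0.7, 0)), radius_vox = 2.5,
                                 amplitude_control = 25,
                                 amplitude_patient = 10)),
    seed = 42L)
  override <- list(...)
  args <- defaults
  args[names(override)] <- override
  do.call(phantom_spec, args)
}

# A run whose voxel series are fully specified: data is voxels x time matrix
# laid over a small grid.
run_from_matrix <- function(mat, grid = NULL, tr = 1.8) {
  nv <- nrow(mat)
  if (is.null(grid)) grid <- c(nv, 1, 1)
  stopifnot(prod(grid) == nv)
  bold_run(array(mat, c(grid, ncol(mat))), tr_seconds = tr)
}

# flat uniform cv_map on a grid (for analytic reference tests)
uniform_cv_map <- function(value, grid = c(4, 4, 3)) {
  structure(list(values = array(value, grid),
                 valid_mask = array(TRUE, grid), subject_id = "u"),
            class = "cv_map")
}
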