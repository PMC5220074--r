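#' A single subject's 4D BOLD run
#'
#' Container for one resting-state BOLD acquisition: a 4D intensity array
#' (x, y, z, t), the repetition time, and subject metadata. All downstream
#' maps (CV, tSNR) and the group ICA / dual regression machinery consume this
#' class.
#'
#' @param data 4D numeric array, dimensions x, y, z, t with t >= 2.
#' @param tr_seconds repetition time in seconds (> 0).
#' @param subject_id subject identifier (scalar character).
#' @param group group label (e.g., "control", "patient").
#' @param voxel_size_mm numeric length-3 voxel edge lengths in mm.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr_seconds, subject_id = "subj", group = "control",
                     voxel_size_mm = c(4, 4, 4)) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    stop("'data' must be a 4D array (x, y, z, t)")
  }
  if (dim(data)[4] < 2L) stop("a BOLD run needs at least 2 time points")
  if (!all(is.finite(data))) stop("BOLD intensities must all be finite")
  stopifnot_scalar(tr_seconds, "tr_seconds")
  if (tr_seconds <= 0) stop("'tr_seconds' must be positive")
  structure(
    list(data = data, tr_seconds = tr_seconds,
         subject_id = as.character(subject_id), group = as.character(group),
         voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %s (%s): %dx%dx%d voxels, %d volumes, TR %.3g s\n",
              x$subject_id, x$group, d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' @export
dim.bold_run <- function(x) dim(x$data)

n_volumes <- function(run) dim(run$data)[4]

grid_shape <- function(run) dim(run$data)[1:3]

# voxels x time matrix view of a run
run_matrix <- function(run) {
  d <- dim(run$data)
  matrix(run$data, prod(d[1:3]), d[4])
}

#' Read a 4D BOLD NIfTI file as a `bold_run`
#'
#' @param path path to a NIfTI-1 file (4D).
#' @param subject_id,group metadata to attach.
#' @return A `bold_run`.
#' @export
read_bold_run <- function(path, subject_id = basename(path), group = "control") {
  img <- RNifti::readNifti(path)
  arr <- nifti_to_array(img)
  if (length(dim(arr)) != 4L) stop("expected a 4D NIfTI at ", path)
  tr <- RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  bold_run(arr, tr_seconds = tr, subject_id = subject_id, group = group,
           voxel_size_mm = RNifti::pixdim(img)[1:3])
}

#' Write a `bold_run` to a NIfTI-1 file
#'
#' @param run a `bold_run`.
#' @param path output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold_run <- function(run, path) {
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(run$voxel_size_mm, run$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a 3D map to a NIfTI-1 file
#'
#' Accepts a plain 3D array or any of the package's map classes (`cv_map`,
#' `tsnr_map`), whose `values` field is written.
#'
#' @param map 3D array or map object.
#' @param path output path.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, voxel_size_mm = c(4, 4, 4)) {
  vals <- if (is.list(map) && !is.null(map$values)) map$values else map
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a tab-separated table with columns `subject_id`, `group`,
#' `bold_path`, `gm_path` (paths relative to the manifest's directory or
#' absolute).
#'
#' @param path manifest path.
#' @return A data.frame with the four columns, paths made absolute.
#' @export
read_manifest <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "bold_path", "gm_path")
  if (!all(need %in% names(tab))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  tab$bold_path <- fix(tab$bold_path)
  tab$gm_path <- fix(tab$gm_path)
  tab
}

#' Load a cohort from a manifest
#'
#' @param manifest path to a manifest file or a data.frame from
#'   [read_manifest()].
#' @return A `phantom_cohort`-shaped list with `runs` and `gm_maps` (no
#'   ground truth).
#' @export
load_cohort <- function(manifest) {
  tab <- if (is.character(manifest)) read_manifest(manifest) else manifest
  runs <- vector("list", nrow(tab))
  gm <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    runs[[i]] <- read_bold_run(tab$bold_path[i], tab$subject_id[i], tab$group[i])
    gm[[i]] <- nifti_to_array(RNifti::readNifti(tab$gm_path[i]))
  }
  names(runs) <- names(gm) <- tab$subject_id
  structure(list(runs = runs, gm_maps = gm, ground_truth = NULL),
            class = "phantom_cohort")
}
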