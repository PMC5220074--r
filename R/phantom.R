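#' Specify an embedded resting-state network for the phantom
#'
#' A network is a set of spherical blobs inside the gray-matter shell sharing
#' one band-limited time course per subject. Group connectivity deficits are
#' encoded as a reduced patient amplitude.
#'
#' @param name network label (e.g., `"pdmn"`, `"sln"`).
#' @param centers numeric matrix (n_blobs x 3) of blob centers in normalized
#'   coordinates, each axis in \[-1, 1\] (0 = grid center, 1 = grid edge).
#' @param radius_vox blob radius in voxels.
#' @param band frequency band in Hz of the shared fluctuation (default the
#'   standard resting-state band 0.01-0.1 Hz).
#' @param amplitude_control connectivity strength (signal units) in controls.
#' @param amplitude_patient strength in patients; `<= amplitude_control` for
#'   deficit networks.
#' @param subject_sd between-subject SD of the multiplicative amplitude
#'   factor (mean 1, truncated below at 0.3).
#' @return A `network_spec` list.
#' @export
network_spec <- function(name, centers, radius_vox = 3,
                         band = c(0.01, 0.1),
                         amplitude_control = 25,
                         amplitude_patient = amplitude_control,
                         subject_sd = 0.15) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  stopifnot(radius_vox > 0, length(band) == 2L, band[1] < band[2],
            amplitude_control >= 0, amplitude_patient >= 0)
  structure(list(name = name, centers = centers, radius_vox = radius_vox,
                 band = as.numeric(band),
                 amplitude_control = amplitude_control,
                 amplitude_patient = amplitude_patient,
                 subject_sd = subject_sd),
            class = "network_spec")
}

#' Default three-network layout
#'
#' A posterior default-mode-like network with a group deficit, a bilateral
#' salience-like network, and a visual-like network, all in the gray-matter
#' shell.
#'
#' @param amplitude_control control amplitude in signal units.
#' @param deficit_amplitude patient amplitude of the deficit (pdmn) network.
#' @return list of `network_spec`.
#' @export
default_networks <- function(amplitude_control = 25, deficit_amplitude = 10) {
  list(
    network_spec("pdmn", rbind(c(0, -0.75, 0)),
                 amplitude_control = amplitude_control,
                 amplitude_patient = deficit_amplitude),
    network_spec("sln", rbind(c(-0.72, 0.25, 0), c(0.72, 0.25, 0)),
                 amplitude_control = amplitude_control),
    network_spec("vis", rbind(c(0, 0.75, 0)),
                 amplitude_control = amplitude_control)
  )
}

#' Specify an injected artifact
#'
#' Two artifact classes are modelled: `stripe` (an additive offset on a small
#' set of slices along the slowest axis, for a subset of volumes, mimicking
#' within-TR motion / partial k-space corruption) and `signal_defect` (an
#' additive whole-brain offset on a subset of volumes).
#'
#' @param kind `"stripe"` or `"signal_defect"`.
#' @param target_subjects character vector of subject IDs to corrupt.
#' @param affected_slices integer slice indices (z axis); stripes only.
#'   `NULL` = 3 central slices.
#' @param affected_volumes integer time-point indices. `NULL` = first 20% of
#'   volumes.
#' @param amplitude additive offset in signal units (non-zero). The default
#'   160 is 8x the default phantom noise SD.
#' @return An `artifact_spec` list.
#' @export
artifact_spec <- function(kind = c("stripe", "signal_defect"),
                          target_subjects,
                          affected_slices = NULL,
                          affected_volumes = NULL,
                          amplitude = 160) {
  kind <- match.arg(kind)
  stopifnot_scalar(amplitude, "amplitude")
  if (amplitude == 0) stop("artifact amplitude must be non-zero")
  if (length(target_subjects) < 1L) stop("'target_subjects' must be non-empty")
  structure(list(kind = kind, target_subjects = as.character(target_subjects),
                 affected_slices = affected_slices,
                 affected_volumes = affected_volumes,
                 amplitude = amplitude),
            class = "artifact_spec")
}

#' Specify a synthetic BOLD phantom cohort
#'
#' Defines the geometry, timing, group structure, signal model and artifact
#' plan of a multi-subject phantom. Subjects share a grid of concentric
#' tissue compartments (CSF core, white-matter ring, gray-matter shell);
#' each subject's series is
#' `baseline + sum_k beta_sk * map_k(v) * tc_k(t) + noise`, with white noise
#' in all tissue and an added high-frequency pulsation regressor in CSF.
#' Patients lose a seeded random fraction of network-adjacent GM voxels
#' (atrophy), which acquire a partial-volume copy of the CSF pulsation.
#'
#' @param grid_shape integer length-3 voxel counts, all >= 8.
#' @param n_volumes number of time points (>= 20).
#' @param tr_seconds repetition time in seconds.
#' @param n_per_group named vector `c(control = ., patient = .)`.
#' @param networks list of [network_spec()].
#' @param noise_sd white-noise SD in signal units.
#' @param baseline mean tissue signal level (> 0).
#' @param csf_pulsation_amplitude amplitude of the CSF pulsation regressor.
#' @param atrophy_fraction fraction in \[0, 1) of network-adjacent GM voxels
#'   zeroed in patients.
#' @param artifact_specs list of [artifact_spec()].
#' @param seed RNG seed (integer).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24, 24, 12),
                         n_volumes = 100,
                         tr_seconds = 1.8,
                         n_per_group = c(control = 10, patient = 10),
                         networks = default_networks(),
                         noise_sd = 20,
                         baseline = 1000,
                         csf_pulsation_amplitude = 30,
                         atrophy_fraction = 0.15,
                         artifact_specs = list(),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
    stop("'grid_shape' must be 3 integers, all >= 8")
  }
  if (n_volumes < 20L) stop("'n_volumes' must be >= 20")
  if (atrophy_fraction < 0 || atrophy_fraction >= 1) {
    stop("'atrophy_fraction' must be in [0, 1)")
  }
  if (baseline <= 0) stop("'baseline' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (inherits(networks, "network_spec")) networks <- list(networks)
  if (inherits(artifact_specs, "artifact_spec")) artifact_specs <- list(artifact_specs)
  structure(
    list(grid_shape = grid_shape, n_volumes = as.integer(n_volumes),
         tr_seconds = tr_seconds, n_per_group = n_per_group,
         networks = networks, noise_sd = noise_sd, baseline = baseline,
         csf_pulsation_amplitude = csf_pulsation_amplitude,
         atrophy_fraction = atrophy_fraction,
         artifact_specs = artifact_specs, seed = as.integer(seed)),
    class = "phantom_spec")
}

# Concentric tissue compartments on a normalized-radius ellipsoid.
# Returns a 3D integer array: 0 air, 1 CSF, 2 WM, 3 GM.
tissue_compartments <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  ux <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2)
  uy <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2)
  uz <- (seq_len(nz) - (nz + 1) / 2) / (nz / 2)
  r <- sqrt(outer(outer(ux^2, uy^2, "+"), uz^2, "+"))
  lab <- array(0L, grid_shape)
  lab[r <= 0.95] <- 3L   # GM shell
  lab[r <= 0.60] <- 2L   # WM ring
  lab[r <= 0.30] <- 1L   # CSF core
  lab
}

# Resolve a network's voxel mask (indices into the flattened grid),
# restricted to the GM compartment. Errors if any blob falls outside the grid
# or the mask is empty.
resolve_network_mask <- function(net, grid_shape, tissue) {
  half <- grid_shape / 2
  idx <- integer(0)
  coords <- arrayInd(seq_len(prod(grid_shape)), grid_shape)
  for (b in seq_len(nrow(net$centers))) {
    cen <- (net$centers[b, ] * half) + (grid_shape + 1) / 2
    if (any(cen < 1) || any(cen > grid_shape)) {
      stop("network '", net$name, "' blob center outside grid")
    }
    d2 <- (coords[, 1] - cen[1])^2 + (coords[, 2] - cen[2])^2 +
      (coords[, 3] - cen[3])^2
    idx <- union(idx, which(d2 <= net$radius_vox^2))
  }
  idx <- idx[tissue[idx] == 3L]
  if (length(idx) == 0L) {
    stop("network '", net$name, "' has no voxels in the GM compartment")
  }
  sort(idx)
}

# Resolve artifact defaults and check for contradictory overlaps.
resolve_artifacts <- function(spec, subject_ids) {
  arts <- lapply(spec$artifact_specs, function(a) {
    if (a$kind == "stripe" && is.null(a$affected_slices)) {
      mid <- ceiling(spec$grid_shape[3] / 2)
      a$affected_slices <- (mid - 1):(mid + 1)
    }
    if (is.null(a$affected_volumes)) {
      a$affected_volumes <- seq_len(max(1L, round(0.2 * spec$n_volumes)))
    }
    a$affected_slices <- as.integer(a$affected_slices)
    a$affected_volumes <- as.integer(a$affected_volumes)
    if (a$kind == "stripe") {
      if (length(a$affected_slices) == 0L) stop("stripe with empty slice set")
      if (any(a$affected_slices < 1L | a$affected_slices > spec$grid_shape[3])) {
        stop("stripe slices outside grid")
      }
    }
    if (length(a$affected_volumes) == 0L ||
        any(a$affected_volumes < 1L | a$affected_volumes > spec$n_volumes)) {
      stop("artifact volumes empty or outside run")
    }
    unknown <- setdiff(a$target_subjects, subject_ids)
    if (length(unknown)) stop("artifact targets unknown subjects: ",
                              paste(unknown, collapse = ", "))
    a
  })
  # contradictory overlap: two artifacts hitting the same subject on
  # intersecting (slice, volume) footprints
  if (length(arts) > 1L) {
    for (i in seq_along(arts)) for (j in seq_len(i - 1L)) {
      shared <- intersect(arts[[i]]$target_subjects, arts[[j]]$target_subjects)
      if (length(shared) == 0L) next
      vols <- intersect(arts[[i]]$affected_volumes, arts[[j]]$affected_volumes)
      if (length(vols) == 0L) next
      sl_i <- if (arts[[i]]$kind == "stripe") arts[[i]]$affected_slices else
        seq_len(spec$grid_shape[3])
      sl_j <- if (arts[[j]]$kind == "stripe") arts[[j]]$affected_slices else
        seq_len(spec$grid_shape[3])
      if (length(intersect(sl_i, sl_j))) {
        stop("contradictory overlapping artifact specs on subject(s) ",
             paste(shared, collapse = ", "))
      }
    }
  }
  arts
}

#' Generate a synthetic phantom cohort
#'
#' Deterministic for a fixed spec (including its seed). Artifacts are applied
#' last, as pure additive offsets, so an artifact-free respecification of the
#' same spec differs from the artifacted cohort exactly on the artifact
#' footprint.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_cohort`: list with `runs` (named list of [bold_run()]),
#'   `gm_maps` (named list of 3D partial-volume arrays in \[0,1\]) and
#'   `ground_truth` (network masks/maps, per-subject beta matrix, subject
#'   time courses, CSF regressors, atrophy voxel lists, resolved artifact
#'   ledger, tissue label array).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_con <- spec$n_per_group[["control"]]
  n_pat <- if ("patient" %in% names(spec$n_per_group))
    spec$n_per_group[["patient"]] else 0
  ids <- c(if (n_con > 0) sprintf("con%02d", seq_len(n_con)),
           if (n_pat > 0) sprintf("pat%02d", seq_len(n_pat)))
  groups <- c(rep("control", n_con), rep("patient", n_pat))
  generate_cohort_impl(spec, ids, groups)
}

#' Generate an artifact-free normative cohort
#'
#' All subjects are controls (control-level network amplitudes), with no
#' artifacts and no atrophy — the phantom analogue of a healthy normative
#' sample used to build reference CV maps.
#'
#' @param spec a [phantom_spec()] giving geometry and signal model.
#' @param n_subjects number of normative subjects (>= 2; the reference SD is
#'   undefined otherwise).
#' @return A `phantom_cohort`.
#' @export
generate_normative_cohort <- function(spec, n_subjects) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_subjects < 2) stop("'n_subjects' must be >= 2 (reference SD undefined)")
  spec$artifact_specs <- list()
  spec$atrophy_fraction <- 0
  ids <- sprintf("norm%03d", seq_len(n_subjects))
  generate_cohort_impl(spec, ids, rep("control", n_subjects))
}

generate_cohort_impl <- function(spec, subject_ids, groups) {
  tissue <- tissue_compartments(spec$grid_shape)
  V <- prod(spec$grid_shape)
  Tn <- spec$n_volumes
  idx_csf <- which(tissue == 1L)
  idx_wm <- which(tissue == 2L)
  idx_gm <- which(tissue == 3L)
  idx_brain <- which(tissue > 0L)
  net_masks <- lapply(spec$networks, resolve_network_mask,
                      grid_shape = spec$grid_shape, tissue = tissue)
  names(net_masks) <- vapply(spec$networks, `[[`, "", "name")
  arts <- resolve_artifacts(spec, subject_ids)

  # atrophy candidates: GM voxels near any network blob
  coords <- arrayInd(idx_gm, spec$grid_shape)
  near <- rep(FALSE, length(idx_gm))
  half <- spec$grid_shape / 2
  for (net in spec$networks) {
    for (b in seq_len(nrow(net$centers))) {
      cen <- (net$centers[b, ] * half) + (spec$grid_shape + 1) / 2
      d2 <- (coords[, 1] - cen[1])^2 + (coords[, 2] - cen[2])^2 +
        (coords[, 3] - cen[3])^2
      near <- near | d2 <= (net$radius_vox + 2)^2
    }
  }
  atrophy_pool <- idx_gm[near]

  nsub <- length(subject_ids)
  K <- length(spec$networks)
  beta <- matrix(0, nsub, K, dimnames = list(subject_ids, names(net_masks)))
  tcs <- vector("list", nsub); names(tcs) <- subject_ids
  csf_reg <- matrix(0, Tn, nsub, dimnames = list(NULL, subject_ids))
  atrophy <- vector("list", nsub); names(atrophy) <- subject_ids
  runs <- vector("list", nsub); names(runs) <- subject_ids
  gm_maps <- vector("list", nsub); names(gm_maps) <- subject_ids
  csf_band <- c(0.6, 0.9) / (2 * spec$tr_seconds)

  with_seed(spec$seed, {
    for (s in seq_len(nsub)) {
      M <- matrix(0, V, Tn)
      if (spec$noise_sd > 0) {
        M[idx_brain, ] <- matrix(stats::rnorm(length(idx_brain) * Tn,
                                              sd = spec$noise_sd),
                                 length(idx_brain), Tn)
      }
      M[idx_brain, ] <- M[idx_brain, ] + spec$baseline
      reg <- bandlimited_noise(Tn, spec$tr_seconds, csf_band)
      csf_reg[, s] <- reg
      if (spec$csf_pulsation_amplitude > 0) {
        M[idx_csf, ] <- M[idx_csf, ] +
          rep(spec$csf_pulsation_amplitude * reg, each = length(idx_csf))
      }
      # atrophy (patients): zero GM pv near networks; those voxels trade
      # network signal for partial-volume CSF pulsation
      pv <- array(0, spec$grid_shape)
      pv[idx_gm] <- 1
      atro <- integer(0)
      if (groups[s] == "patient" && spec$atrophy_fraction > 0 &&
          length(atrophy_pool) > 0) {
        n_rm <- round(spec$atrophy_fraction * length(atrophy_pool))
        atro <- sort(sample(atrophy_pool, n_rm))
        pv[atro] <- 0
        if (spec$csf_pulsation_amplitude > 0 && length(atro)) {
          M[atro, ] <- M[atro, ] +
            rep(0.5 * spec$csf_pulsation_amplitude * reg, each = length(atro))
        }
      }
      atrophy[[s]] <- atro
      TC <- matrix(0, Tn, K)
      for (k in seq_len(K)) {
        net <- spec$networks[[k]]
        amp <- if (groups[s] == "patient") net$amplitude_patient else
          net$amplitude_control
        b_sk <- amp * max(0.3, stats::rnorm(1, 1, net$subject_sd))
        beta[s, k] <- b_sk
        tc <- bandlimited_noise(Tn, spec$tr_seconds, net$band)
        TC[, k] <- tc
        vox <- setdiff(net_masks[[k]], atro)
        if (length(vox) && b_sk != 0) {
          M[vox, ] <- M[vox, ] + b_sk * rep(tc, each = length(vox))
        }
      }
      tcs[[s]] <- TC
      gm_maps[[s]] <- pv
      runs[[s]] <- M  # artifacts applied after the RNG loop
    }
  })

  ledger <- list()
  for (a in arts) {
    for (sid in a$target_subjects) {
      s <- match(sid, subject_ids)
      slices <- if (a$kind == "stripe") a$affected_slices else
        seq_len(spec$grid_shape[3])
      slice_vox <- idx_brain[arrayInd(idx_brain, spec$grid_shape)[, 3] %in% slices]
      runs[[s]][slice_vox, a$affected_volumes] <-
        runs[[s]][slice_vox, a$affected_volumes] + a$amplitude
      ledger[[length(ledger) + 1L]] <- list(
        subject_id = sid, kind = a$kind, affected_slices = slices,
        affected_volumes = a$affected_volumes, amplitude = a$amplitude)
    }
  }

  net_maps3d <- lapply(net_masks, function(ix) {
    m <- array(0, spec$grid_shape); m[ix] <- 1; m
  })
  for (s in seq_len(nsub)) {
    runs[[s]] <- bold_run(array(runs[[s]], c(spec$grid_shape, Tn)),
                          tr_seconds = spec$tr_seconds,
                          subject_id = subject_ids[s], group = groups[s])
  }
  structure(
    list(runs = runs, gm_maps = gm_maps,
         ground_truth = list(
           network_masks = net_masks, network_maps = net_maps3d,
           beta = beta, timecourses = tcs, csf_regressor = csf_reg,
           atrophy = atrophy, artifact_ledger = ledger, tissue = tissue),
         spec = spec),
    class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  groups <- vapply(x$runs, `[[`, "", "group")
  cat(sprintf("<phantom_cohort> %d subjects (%s)\n", length(x$runs),
              paste(sprintf("%s=%d", names(table(groups)), table(groups)),
                    collapse = ", ")))
  if (!is.null(x$ground_truth)) {
    cat(sprintf("  networks: %s; artifacts: %d\n",
                paste(names(x$ground_truth$network_masks), collapse = ", "),
                length(x$ground_truth$artifact_ledger)))
  }
  invisible(x)
}

#' Write a cohort to disk
#'
#' One 4D NIfTI per subject, one 3D GM partial-volume NIfTI per subject, a
#' tab-separated manifest (`subject_id`, `group`, `bold_path`, `gm_path`),
#' and — when ground truth is present — a JSON sidecar with the beta matrix
#' and artifact ledger.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(cohort$runs)
  tab <- data.frame(subject_id = ids,
                    group = vapply(cohort$runs, `[[`, "", "group"),
                    bold_path = paste0(ids, "_bold.nii.gz"),
                    gm_path = paste0(ids, "_gm.nii.gz"),
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    write_bold_run(cohort$runs[[i]], file.path(dir, tab$bold_path[i]))
    write_map(cohort$gm_maps[[i]], file.path(dir, tab$gm_path[i]),
              voxel_size_mm = cohort$runs[[i]]$voxel_size_mm)
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(tab, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$ground_truth)) {
    gt <- list(beta = as.data.frame(cohort$ground_truth$beta),
               artifact_ledger = cohort$ground_truth$artifact_ledger)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(manifest)
}
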