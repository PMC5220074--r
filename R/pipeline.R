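#' Study configuration
#'
#' Settings for the four-arm study design: whole-brain vs gray-matter group
#' ICA, each before and after CV-based quality control, plus the
#' random-exclusion control rerun.
#'
#' @param arms character subset of `wbica_before`, `wbica_after`,
#'   `gmica_before`, `gmica_after`.
#' @param k number of ICA components.
#' @param n_permutations permutations for group inference (>= 100).
#' @param alpha voxel-level significance level, in (0, 1).
#' @param thresholds optional list(`stripe`, `defect`) QC flagging
#'   thresholds; `NULL` derives them from the normative cohort
#'   (median + 5 MAD).
#' @param n_random_exclude optional named counts per group for the
#'   random-exclusion rerun; `NULL` mirrors the QC flag counts.
#' @param seed study seed; every stage derives its own named sub-seed.
#' @param n_drop,cutoff_seconds,fwhm_mm preprocessing settings.
#' @param n_normative normative phantom subjects generated when no
#'   reference is supplied.
#' @param r_min minimal template correlation for a network match.
#' @param gm_threshold binary threshold on GM partial volume.
#' @return A `study_config`.
#' @export
study_config <- function(arms = c("wbica_before", "wbica_after",
                                  "gmica_before", "gmica_after"),
                         k = 4, n_permutations = 1000, alpha = 0.05,
                         thresholds = NULL, n_random_exclude = NULL,
                         seed = 1, n_drop = 3, cutoff_seconds = 100,
                         fwhm_mm = 5, n_normative = 20, r_min = 0.2,
                         gm_threshold = 0.5) {
  arms <- match.arg(arms, c("wbica_before", "wbica_after",
                            "gmica_before", "gmica_after"),
                    several.ok = TRUE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (n_permutations < 100) stop("'n_permutations' must be >= 100")
  structure(list(arms = arms, k = k, n_permutations = n_permutations,
                 alpha = alpha, thresholds = thresholds,
                 n_random_exclude = n_random_exclude, seed = as.integer(seed),
                 n_drop = n_drop, cutoff_seconds = cutoff_seconds,
                 fwhm_mm = fwhm_mm, n_normative = n_normative,
                 r_min = r_min, gm_threshold = gm_threshold),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' @param path YAML file whose keys are [study_config()] arguments.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(study_config, vals[intersect(names(vals), names(formals(study_config)))])
}

# Build (or accept) the QC reference: a normative_reference plus flagging
# thresholds, from drop+highpass-filtered normative runs.
build_reference <- function(cohort, config, reference) {
  if (!is.null(reference) && !is.null(reference$reference)) return(reference)
  norm <- if (inherits(reference, "phantom_cohort")) reference else {
    if (is.null(cohort$spec)) {
      stop("no reference supplied and the cohort carries no phantom spec to generate one")
    }
    spec <- cohort$spec
    spec$seed <- derive_seed(config$seed, "normative")
    generate_normative_cohort(spec, config$n_normative)
  }
  filt <- lapply(norm$runs, function(r) {
    highpass_filter(drop_initial_volumes(r, min(config$n_drop, n_volumes(r) - 1)),
                    config$cutoff_seconds)
  })
  cvs <- lapply(filt, compute_cv_map)
  ref <- build_normative_reference(cvs)
  thr <- config$thresholds %||% qc_thresholds(score_runs(filt, ref))
  list(reference = ref, thresholds = thr)
}

arm_voxel_index <- function(kind, cohort, subjects, config, brain_mask) {
  if (kind == "wb") return(which(brain_mask))
  gm_union <- Reduce(`|`, lapply(cohort$gm_maps[subjects],
                                 function(pv) pv > config$gm_threshold))
  which(gm_union & brain_mask)
}

run_arm <- function(arm, cohort, smoothed, subjects, config, templates,
                    brain_mask) {
  kind <- if (startsWith(arm, "wb")) "wb" else "gm"
  vi <- arm_voxel_index(kind, cohort, subjects, config, brain_mask)
  runs <- smoothed[subjects]
  dm <- concatenate_runs(runs, voxel_index = vi)
  # the fixed point can stall on noise-dominated subspaces for an unlucky
  # initialization; restart from up to 3 deterministic sub-seeds
  decomp <- NULL
  for (attempt in 0:2) {
    decomp <- tryCatch(
      fit_group_ica(dm, k = config$k,
                    seed = derive_seed(config$seed,
                                       paste0("ica_", arm, "_", attempt))),
      error = function(e) if (grepl("converge", conditionMessage(e))) NULL else
        stop(e))
    if (!is.null(decomp)) break
  }
  if (is.null(decomp)) stop("group ICA failed to converge in arm ", arm)
  matches <- match_rsn(decomp, templates, r_min = config$r_min)
  dr <- dual_regression(runs, decomp)
  groups <- vapply(runs, `[[`, "", "group")
  nets <- list()
  rows <- list()
  for (nm in matches$template) {
    cand <- attr(matches, "candidates")[[nm]]
    if (length(cand) == 0L) {
      rows[[nm]] <- data.frame(arm = arm, template = nm, component = NA_integer_,
                               r = matches$r[matches$template == nm],
                               n_voxels = 0L, volume_mm3 = 0,
                               t_min = NA_real_, t_max = NA_real_)
      nets[[nm]] <- list(matched = FALSE, candidates = integer(0))
      next
    }
    m <- length(cand)
    per_comp <- lapply(cand, function(comp) {
      mats <- t(vapply(dr$maps, function(sm) sm$values[comp, ],
                       numeric(ncol(decomp$spatial_maps))))
      stat <- permutation_group_test(
        mats[groups == "control", , drop = FALSE],
        mats[groups == "patient", , drop = FALSE],
        n_perm = config$n_permutations,
        seed = derive_seed(config$seed, paste0("perm_", arm, "_", nm, "_", comp)))
      # Bonferroni over the m duplicate components matching this network,
      # applied voxelwise to the component's FWE p map
      stat$p_fwe <- pmin(1, stat$p_fwe * m)
      list(component = comp, stat = stat,
           summary = difference_map_stats(stat, alpha = config$alpha,
                                          voxel_index = decomp$voxel_index,
                                          grid_shape = decomp$grid_shape))
    })
    counts <- vapply(per_comp, function(p) p$summary$n_voxels, integer(1))
    best <- per_comp[[which.max(counts)]]
    nets[[nm]] <- list(matched = TRUE, candidates = cand,
                       bonferroni_m = m, results = per_comp, best = best)
    rows[[nm]] <- cbind(data.frame(arm = arm, template = nm,
                                   component = best$component,
                                   r = matches$r[matches$template == nm]),
                        best$summary[c("n_voxels", "volume_mm3", "t_min", "t_max")])
  }
  summary_table <- do.call(rbind, rows)
  rownames(summary_table) <- NULL
  list(arm = arm, subjects_used = subjects, voxel_index = vi,
       decomposition = decomp, matches = matches, networks = nets,
       summary = summary_table)
}

#' Run the full study design
#'
#' Executes quality control once (CV maps of drop+filtered data scored
#' against a normative reference), then each requested analysis arm
#' end-to-end: temporal-concatenation group ICA on whole-brain or
#' gray-matter voxels, template matching, dual regression, and
#' permutation-based two-group inference with Bonferroni correction over
#' duplicate network components. "Before" arms use all subjects; "after"
#' arms drop CV-flagged subjects.
#'
#' @param cohort a `phantom_cohort` (from [generate_cohort()] or
#'   [load_cohort()]).
#' @param config a [study_config()].
#' @param reference optional: a list(`reference`, `thresholds`) or a
#'   normative `phantom_cohort`; `NULL` generates a normative phantom from
#'   the cohort's spec.
#' @param templates named list of 3D template masks; default the cohort's
#'   ground-truth network maps.
#' @return A `study_result`: `arms` (list of arm results), `qc`
#'   (`qc_report`), `reference`, `config`.
#' @export
run_study <- function(cohort, config = study_config(), reference = NULL,
                      templates = NULL) {
  stopifnot(inherits(config, "study_config"))
  templates <- templates %||% cohort$ground_truth$network_maps
  if (is.null(templates)) stop("no templates supplied and no ground truth available")
  refthr <- build_reference(cohort, config, reference)
  pp <- lapply(cohort$runs, preprocess_run, n_drop = config$n_drop,
               cutoff_seconds = config$cutoff_seconds, fwhm_mm = config$fwhm_mm)
  filtered <- lapply(pp, `[[`, "filtered")
  smoothed <- lapply(pp, `[[`, "smoothed")
  brain_mask <- if (!is.null(cohort$ground_truth$tissue)) {
    cohort$ground_truth$tissue > 0L
  } else {
    brain_mask_from_run(cohort$runs[[1]])
  }
  qc <- flag_runs(score_runs(filtered, refthr$reference, brain_mask),
                  refthr$thresholds)
  all_ids <- names(cohort$runs)
  keep_after <- all_ids[!qc$flag[match(all_ids, qc$subject_id)]]
  arms <- list()
  for (arm in config$arms) {
    subjects <- if (endsWith(arm, "_after")) keep_after else all_ids
    arms[[arm]] <- tryCatch(
      run_arm(arm, cohort, smoothed, subjects, config, templates, brain_mask),
      error = function(e) list(arm = arm, subjects_used = subjects,
                               error = conditionMessage(e), summary = NULL))
    dropped <- setdiff(all_ids, subjects)
    arms[[arm]]$excluded <- data.frame(
      subject_id = dropped,
      reason = qc$reason[match(dropped, qc$subject_id)],
      stringsAsFactors = FALSE)
  }
  structure(list(arms = arms, qc = qc, reference = refthr, config = config,
                 templates = templates),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d arms, %d/%d runs flagged by QC\n",
              length(x$arms), sum(x$qc$flag), nrow(x$qc)))
  for (a in x$arms) {
    if (!is.null(a$error)) {
      cat(sprintf("  %s: FAILED (%s)\n", a$arm, a$error))
    } else {
      cat(sprintf("  %s (%d subjects): %s\n", a$arm, length(a$subjects_used),
                  paste(sprintf("%s=%d vox", a$summary$template,
                                a$summary$n_voxels), collapse = ", ")))
    }
  }
  invisible(x)
}

# Seeded draw of per-group random exclusions from the full subject list.
random_exclusion_draw <- function(all_ids, groups, n_exclude_per_group, seed) {
  with_seed(seed, {
    unlist(lapply(names(n_exclude_per_group), function(g) {
      pool <- all_ids[groups == g]
      n <- n_exclude_per_group[[g]]
      if (n == 0L) character(0) else sample(pool, n)
    }))
  })
}

#' Random-exclusion control rerun
#'
#' Restores the CV-flagged subjects and instead removes a seeded random
#' draw of the same per-group counts, then reruns the gray-matter ICA arm —
#' the control for "is the QC gain just a sample-size effect?".
#'
#' @param cohort the full `phantom_cohort`.
#' @param result a `study_result` from [run_study()] (provides QC flags,
#'   reference, templates).
#' @param n_exclude_per_group named integer vector (e.g.,
#'   `c(control = 1, patient = 3)`); default mirrors the QC flag counts.
#' @param seed seed of the random draw (default derived from the study
#'   seed).
#' @return The arm result (as in `run_study()$arms`), with `excluded`
#'   (data.frame of subject_id, reason = "random") attached.
#' @export
random_exclusion_rerun <- function(cohort, result, n_exclude_per_group = NULL,
                                   seed = NULL) {
  stopifnot(inherits(result, "study_result"))
  config <- result$config
  qc <- result$qc
  groups <- vapply(cohort$runs, `[[`, "", "group")
  if (is.null(n_exclude_per_group)) {
    fl <- qc$group[qc$flag]
    n_exclude_per_group <- vapply(unique(groups), function(g) sum(fl == g),
                                  integer(1))
    names(n_exclude_per_group) <- unique(groups)
  }
  for (g in names(n_exclude_per_group)) {
    if (n_exclude_per_group[[g]] >= sum(groups == g)) {
      stop("cannot exclude ", n_exclude_per_group[[g]], " of ",
           sum(groups == g), " '", g, "' subjects")
    }
  }
  seed <- seed %||% derive_seed(config$seed, "random_exclude")
  all_ids <- names(cohort$runs)
  excluded <- random_exclusion_draw(all_ids, groups, n_exclude_per_group, seed)
  subjects <- setdiff(all_ids, excluded)
  pp <- lapply(cohort$runs[subjects], preprocess_run, n_drop = config$n_drop,
               cutoff_seconds = config$cutoff_seconds, fwhm_mm = config$fwhm_mm)
  smoothed <- lapply(pp, `[[`, "smoothed")
  brain_mask <- if (!is.null(cohort$ground_truth$tissue)) {
    cohort$ground_truth$tissue > 0L
  } else brain_mask_from_run(cohort$runs[[1]])
  arm <- run_arm("gmica_random", cohort, smoothed, subjects, config,
                 result$templates, brain_mask)
  arm$excluded <- data.frame(subject_id = excluded,
                             reason = rep("random", length(excluded)),
                             stringsAsFactors = FALSE)
  arm
}

#' Write a human-readable study report
#'
#' QC table, one difference-map table per arm (voxels, volume, peak, t
#' statistics), and a cross-arm comparison line of significant voxel
#' counts.
#'
#' @param result a `study_result`.
#' @param path output text file.
#' @param extra_arms optional additional arm results (e.g., the
#'   random-exclusion rerun) to include.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, extra_arms = list()) {
  stopifnot(inherits(result, "study_result"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Study report")
  w("")
  w("## Quality control (thresholds: stripe > %.4g, defect > %.4g)",
    attr(result$qc, "thresholds")$stripe, attr(result$qc, "thresholds")$defect)
  utils::capture.output(print.data.frame(as.data.frame(result$qc), digits = 4),
                        file = con, append = TRUE)
  arms <- c(result$arms, extra_arms)
  for (a in arms) {
    w("")
    w("## Arm %s (%d subjects)", a$arm, length(a$subjects_used))
    if (!is.null(a$excluded) && nrow(a$excluded)) {
      w("excluded: %s", paste(sprintf("%s(%s)", a$excluded$subject_id,
                                      a$excluded$reason), collapse = ", "))
    }
    if (!is.null(a$error)) {
      w("arm failed: %s", a$error)
      next
    }
    if (is.null(a$summary) || nrow(a$summary) == 0L ||
        all(a$summary$n_voxels == 0)) {
      w("no significant voxels")
    }
    if (!is.null(a$summary)) {
      utils::capture.output(print.data.frame(a$summary, digits = 4),
                            file = con, append = TRUE)
    }
  }
  w("")
  w("## Cross-arm comparison (total significant voxels)")
  w("%s", paste(vapply(arms, function(a) {
    sprintf("%s=%d", a$arm, sum(a$summary$n_voxels %||% 0L))
  }, character(1)), collapse = "  "))
  invisible(path)
}
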