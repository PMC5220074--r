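test_that("cohort generation is deterministic for a fixed spec and seed", {
  spec <- tiny_spec()
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$runs[["con01"]]$data, b$runs[["con01"]]$data)
  expect_identical(a$runs[["pat03"]]$data, b$runs[["pat03"]]$data)
  expect_identical(a$gm_maps, b$gm_maps)
  expect_identical(a$ground_truth$beta, b$ground_truth$beta)
})

test_that("noise-free construction is exactly baseline + beta * timecourse", {
  spec <- tiny_spec(noise_sd = 0, csf_pulsation_amplitude = 0,
                    atrophy_fraction = 0,
                    networks = list(network_spec("net", rbind(c(0, -0.7, 0)),
                                                 radius_vox = 2.5,
                                                 amplitude_control = 20,
                                                 amplitude_patient = 20,
                                                 subject_sd = 0)))
  coh <- generate_cohort(spec)
  gt <- coh$ground_truth
  for (sid in c("con01", "pat02")) {
    run <- coh$runs[[sid]]
    X <- matrix(run$data, prod(dim(run$data)[1:3]), dim(run$data)[4])
    vox <- setdiff(gt$network_masks$net, gt$atrophy[[sid]])
    beta <- gt$beta[sid, "net"]
    expect_equal(beta, 20)  # subject_sd = 0 pins beta to the group amplitude
    tc <- gt$timecourses[[sid]][, 1]
    for (v in vox[c(1, length(vox))]) {
      expect_equal(X[v, ], spec$baseline + beta * tc, tolerance = 1e-12)
    }
    # a WM voxel is pure baseline
    wm <- which(gt$tissue == 2L)[1]
    expect_equal(X[wm, ], rep(spec$baseline, spec$n_volumes), tolerance = 1e-12)
  }
})

test_that("all runs share grid and TR, and GM maps are proper partial volumes", {
  coh <- generate_cohort(tiny_spec())
  dims <- lapply(coh$runs, function(r) dim(r$data))
  expect_true(all(vapply(dims, function(d) all(d == dims[[1]]), logical(1))))
  expect_true(all(vapply(coh$runs, `[[`, 1, "tr_seconds") == 1.8))
  for (pv in coh$gm_maps) expect_true(all(pv >= 0 & pv <= 1))
  # patients lose network-adjacent GM; controls do not
  expect_gt(sum(coh$gm_maps[["con01"]]), sum(coh$gm_maps[["pat01"]]))
})

test_that("a stripe artifact raises within-slice temporal SD on affected slices", {
  spec <- tiny_spec(
    n_volumes = 100,
    artifact_specs = list(artifact_spec("stripe", "con01",
                                        affected_slices = 4:6,
                                        affected_volumes = 1:20,
                                        amplitude = 200)))  # 10 x noise_sd
  coh <- generate_cohort(spec)
  run <- coh$runs[["con01"]]
  X <- matrix(run$data, prod(dim(run$data)[1:3]), 100)
  tis <- coh$ground_truth$tissue
  z_of <- arrayInd(seq_len(prod(dim(tis))), dim(tis))[, 3]
  sds <- apply(X, 1, sd)
  affected <- mean(sds[tis > 0 & z_of %in% 4:6])
  unaffected <- mean(sds[tis > 0 & !(z_of %in% 4:6)])
  expect_gt(affected, unaffected)
})

test_that("CSF voxels fluctuate more than WM voxels when pulsation is on", {
  spec <- tiny_spec(networks = list(), csf_pulsation_amplitude = 30)
  coh <- generate_cohort(spec)
  run <- coh$runs[[1]]
  X <- matrix(run$data, prod(dim(run$data)[1:3]), dim(run$data)[4])
  tis <- coh$ground_truth$tissue
  v_csf <- mean(apply(X[tis == 1L, ], 1, var))
  v_wm <- mean(apply(X[tis == 2L, ], 1, var))
  expect_gt(v_csf, v_wm)
})

test_that("every voxel that differs from the seed-matched clean cohort lies in the artifact ledger footprint", {
  art <- list(artifact_spec("stripe", "pat01", affected_slices = 3:4,
                            affected_volumes = 5:10, amplitude = 100),
              artifact_spec("signal_defect", "con02",
                            affected_volumes = 30:35, amplitude = 80))
  dirty <- generate_cohort(tiny_spec(artifact_specs = art))
  clean <- generate_cohort(tiny_spec())
  dims <- dim(dirty$runs[[1]]$data)
  z_of <- arrayInd(seq_len(prod(dims[1:3])), dims[1:3])[, 3]
  ledger <- dirty$ground_truth$artifact_ledger
  expect_length(ledger, 2L)
  for (sid in names(dirty$runs)) {
    diff <- matrix(dirty$runs[[sid]]$data != clean$runs[[sid]]$data,
                   prod(dims[1:3]), dims[4])
    entries <- Filter(function(e) e$subject_id == sid, ledger)
    if (length(entries) == 0L) {
      expect_false(any(diff), info = sid)
    } else {
      allowed <- matrix(FALSE, prod(dims[1:3]), dims[4])
      for (e in entries) {
        allowed[z_of %in% e$affected_slices, e$affected_volumes] <- TRUE
      }
      expect_true(all(allowed[diff]), info = sid)
    }
  }
})

test_that("invalid specs and artifacts are rejected", {
  expect_error(phantom_spec(grid_shape = c(4, 16, 8)), ">= 8")
  expect_error(phantom_spec(n_volumes = 10), ">= 20")
  expect_error(phantom_spec(atrophy_fraction = 1), "atrophy")
  expect_error(phantom_spec(baseline = 0), "baseline")
  # network blob outside the grid
  bad <- tiny_spec(networks = list(network_spec("far", rbind(c(0, 3, 0)))))
  expect_error(generate_cohort(bad), "outside grid")
  # contradictory overlapping artifacts on the same subject
  overlap <- tiny_spec(artifact_specs = list(
    artifact_spec("stripe", "con01", affected_slices = 3:4,
                  affected_volumes = 1:10, amplitude = 50),
    artifact_spec("signal_defect", "con01", affected_volumes = 8:12,
                  amplitude = 60)))
  expect_error(generate_cohort(overlap), "contradictory")
  expect_error(artifact_spec("stripe", "s1", amplitude = 0), "non-zero")
  expect_error(artifact_spec("stripe", character(0)), "non-empty")
})

test_that("normative cohorts are clean, control-amplitude, and need n >= 2", {
  spec <- tiny_spec()
  expect_error(generate_normative_cohort(spec, 1), ">= 2")
  norm <- generate_normative_cohort(spec, 4)
  expect_length(norm$runs, 4L)
  expect_true(all(vapply(norm$runs, `[[`, "", "group") == "control"))
  expect_length(norm$ground_truth$artifact_ledger, 0L)
  # noise-free pair: normative SD map vanishes where the signal is shared
  spec0 <- tiny_spec(noise_sd = 0, csf_pulsation_amplitude = 0,
                     networks = list())
  norm0 <- generate_normative_cohort(spec0, 2)
  cvs <- lapply(norm0$runs, compute_cv_map)
  ref <- build_normative_reference(cvs)
  expect_equal(max(abs(ref$sd_cv)), 0)
})

test_that("mean GM CV of clean subjects tracks the analytic noise_sd/baseline", {
  spec <- tiny_spec(n_volumes = 60)
  norm <- generate_normative_cohort(spec, 20)
  gm <- which(norm$ground_truth$tissue == 3L)
  target <- spec$noise_sd / spec$baseline
  for (run in norm$runs[1:5]) {
    cv <- compute_cv_map(run)
    expect_lt(abs(mean(cv$values[gm]) - target), 0.5 * target)
  }
})

test_that("a cohort round-trips through NIfTI files and a manifest", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(tiny_spec(n_per_group = c(control = 2, patient = 1)))
  manifest <- write_cohort(coh, dir)
  expect_true(file.exists(manifest))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- load_cohort(manifest)
  expect_equal(names(back$runs), names(coh$runs))
  expect_equal(back$runs[["con01"]]$group, "control")
  expect_equal(back$runs[["pat01"]]$group, "patient")
  expect_equal(back$runs[["con01"]]$data, coh$runs[["con01"]]$data,
               tolerance = 1e-6)
  expect_equal(back$gm_maps[["pat01"]], coh$gm_maps[["pat01"]],
               tolerance = 1e-6)
  expect_equal(back$runs[["con01"]]$tr_seconds, 1.8, tolerance = 1e-6)
})
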