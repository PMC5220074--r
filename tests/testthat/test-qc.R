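test_that("CV map matches hand-computed values and handles degenerate voxels", {
  # voxel 1: (1,2,3) -> CV 0.5; voxel 2: constant 5 -> CV 0;
  # voxel 3: tiny mean below the floor -> invalid
  mat <- rbind(c(1, 2, 3), c(5, 5, 5), c(1e-9, 1e-9, 1e-9))
  run <- run_from_matrix(mat)
  cv <- compute_cv_map(run, mean_floor = 1e-6)
  expect_equal(as.numeric(cv$values), c(0.5, 0, 0))
  expect_equal(as.logical(cv$valid_mask), c(TRUE, TRUE, FALSE))
  expect_error(compute_cv_map(run, mean_floor = 0), "positive")
  one_vol <- bold_run(array(1, c(2, 2, 2, 2)), 1)
  one_vol$data <- one_vol$data[, , , 1, drop = FALSE]  # force t = 1
  expect_error(compute_cv_map(one_vol), "at least 2")
})

test_that("tSNR is the reciprocal of CV and constant series are invalid, not infinite", {
  mat <- rbind(c(1, 2, 3), c(5, 5, 5))
  run <- run_from_matrix(mat)
  ts <- compute_tsnr_map(run, sd_floor = 1e-6)
  expect_equal(ts$values[1, 1, 1], 2.0)
  expect_false(ts$valid_mask[2, 1, 1])
  expect_equal(ts$values[2, 1, 1], 0)

  coh <- generate_cohort(tiny_spec())
  r <- coh$runs[[1]]
  cv <- compute_cv_map(r)
  tsnr <- compute_tsnr_map(r)
  joint <- cv$valid_mask & tsnr$valid_mask
  expect_true(any(joint))
  expect_lt(max(abs(cv$values[joint] * tsnr$values[joint] - 1)), 1e-10)
})

test_that("CV and tSNR maps are invariant to global intensity scaling", {
  coh <- generate_cohort(tiny_spec())
  r <- coh$runs[[1]]
  r2 <- r
  r2$data <- r$data * 3.7
  expect_equal(compute_cv_map(r2)$values, compute_cv_map(r)$values,
               tolerance = 1e-12)
  expect_equal(compute_tsnr_map(r2)$values, compute_tsnr_map(r)$values,
               tolerance = 1e-12)
})

test_that("mean tSNR averages over the brain mask and drops with artifacts", {
  vals <- array(50, c(3, 3, 3))
  map <- structure(list(values = vals, valid_mask = array(TRUE, c(3, 3, 3))),
                   class = "tsnr_map")
  expect_equal(mean_tsnr(map, array(TRUE, c(3, 3, 3))), 50)
  vals2 <- array(0, c(3, 3, 3)); vals2[1, 1, 1] <- 10; vals2[2, 1, 1] <- 30
  mask2 <- array(FALSE, c(3, 3, 3)); mask2[1:2, 1, 1] <- TRUE
  map2 <- structure(list(values = vals2, valid_mask = array(TRUE, c(3, 3, 3))),
                    class = "tsnr_map")
  expect_equal(mean_tsnr(map2, mask2), 20)
  expect_error(mean_tsnr(map2, array(FALSE, c(3, 3, 3))), "overlap")

  art <- tiny_spec(artifact_specs = list(artifact_spec("stripe", "con01")))
  dirty <- generate_cohort(art)
  clean <- generate_cohort(tiny_spec())
  bm <- dirty$ground_truth$tissue > 0L
  expect_lt(mean_tsnr(compute_tsnr_map(dirty$runs[["con01"]]), bm),
            mean_tsnr(compute_tsnr_map(clean$runs[["con01"]]), bm))
})

test_that("normative reference is the voxelwise mean and sample SD across maps", {
  ref <- build_normative_reference(list(uniform_cv_map(0.1), uniform_cv_map(0.3)))
  expect_equal(unique(as.numeric(ref$mean_cv)), 0.2)
  expect_equal(unique(as.numeric(ref$sd_cv)), sd(c(0.1, 0.3)))
  expect_equal(unique(round(as.numeric(ref$sd_cv), 4)), 0.1414)
  same <- build_normative_reference(replicate(4, uniform_cv_map(0.2),
                                              simplify = FALSE))
  expect_equal(max(abs(same$sd_cv)), 0)
  expect_error(build_normative_reference(list(uniform_cv_map(0.1))), "at least 2")
  expect_error(build_normative_reference(list(uniform_cv_map(0.1),
                                              uniform_cv_map(0.1, c(5, 4, 3)))),
               "mismatch")
})

test_that("normative mean CV in WM agrees with the generative model", {
  spec <- tiny_spec(n_volumes = 60)
  norm <- generate_normative_cohort(spec, 20)
  ref <- build_normative_reference(lapply(norm$runs, compute_cv_map))
  wm <- norm$ground_truth$tissue == 2L
  # analytic CV of white noise around baseline; SE of the voxelwise mean CV
  target <- spec$noise_sd / spec$baseline
  se <- target / sqrt(2 * (spec$n_volumes - 1)) / sqrt(ref$n_subjects)
  expect_lt(abs(mean(ref$mean_cv[wm]) - target), 3 * se + 0.02 * target)
})

test_that("deviation z-maps are zero at the reference and scale with the SD", {
  ref <- build_normative_reference(list(uniform_cv_map(0.1), uniform_cv_map(0.3)))
  z0 <- deviation_zmap(uniform_cv_map(0.2), ref)
  expect_equal(max(abs(z0$values)), 0)
  bumped <- uniform_cv_map(0.2)
  bumped$values[2, 2, 2] <- 0.2 + 2 * sd(c(0.1, 0.3))
  z2 <- deviation_zmap(bumped, ref)
  expect_equal(z2$values[2, 2, 2], 2, tolerance = 1e-12)
  expect_error(deviation_zmap(uniform_cv_map(0.2, c(5, 5, 5)), ref), "mismatch")

  # stripe subject: affected slices deviate more than unaffected slices
  art <- tiny_spec(artifact_specs = list(
    artifact_spec("stripe", "con01", affected_slices = 4:5)))
  dirty <- generate_cohort(art)
  norm <- generate_normative_cohort(tiny_spec(), 10)
  refp <- build_normative_reference(lapply(norm$runs, compute_cv_map))
  z <- deviation_zmap(compute_cv_map(dirty$runs[["con01"]]), refp)
  z_of <- arrayInd(which(z$valid_mask), dim(z$values))[, 3]
  zv <- abs(z$values[z$valid_mask])
  expect_gt(mean(zv[z_of %in% 4:5]), mean(zv[!(z_of %in% 4:5)]))
})

test_that("stripe score isolates slice-localized deviation and ignores global offsets", {
  z <- array(0, c(6, 6, 6))
  expect_equal(stripe_score(z), 0)
  expect_equal(stripe_score(z + 2.5), 0)  # global offset is not a stripe
  z[, , 3] <- 5
  expect_gt(stripe_score(z), 4)
  expect_error(stripe_score(array(0, c(6, 6, 2))), "3 slices")
})

test_that("defect score is the fraction of valid voxels beyond the z threshold", {
  z <- array(0, c(10, 10, 10))
  expect_equal(defect_score(z), 0)
  z[seq_len(100)] <- 4  # 10% of voxels at |z| = 4
  expect_equal(defect_score(z, z_thresh = 3), 0.10)
  dz <- structure(list(values = z, valid_mask = array(FALSE, c(10, 10, 10))),
                  class = "deviation_zmap")
  expect_error(defect_score(dz), "empty valid mask")
})

test_that("stripe amplitude ladder never decreases the stripe score", {
  norm <- generate_normative_cohort(tiny_spec(), 10)
  ref <- build_normative_reference(lapply(norm$runs, compute_cv_map))
  scores <- vapply(c(20, 60, 120, 240), function(amp) {
    spec <- tiny_spec(artifact_specs = list(
      artifact_spec("stripe", "con01", amplitude = amp)))
    coh <- generate_cohort(spec)
    stripe_score(deviation_zmap(compute_cv_map(coh$runs[["con01"]]), ref))
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("flagging honors thresholds and reports reasons", {
  sc <- data.frame(subject_id = c("a", "b", "c"), group = "control",
                   mean_tsnr = 50, stripe_score = c(0, 0, 0),
                   defect_score = c(0, 0, 0))
  rep0 <- flag_runs(sc, list(stripe = 0.5, defect = 0.05))
  expect_false(any(rep0$flag))
  sc$stripe_score <- c(9, 0, 0)
  sc$defect_score <- c(0, 0.4, 0)
  rep1 <- flag_runs(sc, list(stripe = 0.5, defect = 0.05))
  expect_equal(rep1$flag, c(TRUE, TRUE, FALSE))
  expect_equal(rep1$reason, c("cv_stripe", "cv_defect", ""))
  # infinite thresholds flag nothing regardless of scores
  repinf <- flag_runs(sc, list(stripe = Inf, defect = Inf))
  expect_false(any(repinf$flag))
  sc$stripe_score[1] <- NA
  expect_error(flag_runs(sc, list(stripe = 1, defect = 1)), "complete")
})

test_that("flagged runs in a scored cohort are exactly the artifacted subjects", {
  spec <- tiny_spec(
    n_per_group = c(control = 6, patient = 6),
    artifact_specs = list(
      artifact_spec("stripe", c("con02", "pat03")),
      artifact_spec("signal_defect", "pat05", affected_volumes = 25:32,
                    amplitude = 100)))
  coh <- generate_cohort(spec)
  norm <- generate_normative_cohort(tiny_spec(), 12)
  ref <- build_normative_reference(lapply(norm$runs, compute_cv_map))
  thr <- qc_thresholds(score_runs(norm$runs, ref))
  report <- flag_runs(score_runs(coh$runs, ref), thr)
  expect_setequal(report$subject_id[report$flag], c("con02", "pat03", "pat05"))
})

test_that("Mann-Whitney exact enumeration matches analytic and library results", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(mann_whitney_u(rep(2, 3), rep(2, 4))$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
  # tie-free small samples: exact p agrees with stats::wilcox.test
  set.seed(9)
  for (i in 1:5) {
    a <- round(rnorm(4), 6); b <- round(rnorm(5, 0.5), 6)
    ours <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney p agrees with a Monte-Carlo permutation oracle", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  b <- c(4.0, 6.5, 5.9)
  exact <- mann_whitney_u(a, b)
  pooled <- c(a, b)
  n1 <- length(a); npool <- length(pooled)
  u_of <- function(ix) sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2
  lo <- min(exact$U, n1 * length(b) - exact$U)
  hi <- n1 * length(b) - lo
  set.seed(31)
  draws <- replicate(10000, u_of(sample.int(npool, n1)))
  mc <- mean(draws <= lo | draws >= hi)
  se <- sqrt(mc * (1 - mc) / 10000)
  expect_lt(abs(exact$p - mc), 3 * se + 1e-12)
})

test_that("large-sample Mann-Whitney uses the tie-corrected normal approximation", {
  set.seed(4)
  a <- rnorm(10); b <- rnorm(12, 0.8)
  ours <- mann_whitney_u(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  # with ties present
  a2 <- round(rnorm(10), 0); b2 <- round(rnorm(12, 0.8), 0)
  ours2 <- mann_whitney_u(a2, b2)
  ref2 <- wilcox.test(a2, b2, exact = FALSE, correct = FALSE)
  expect_equal(ours2$p, ref2$p.value, tolerance = 1e-10)
})
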