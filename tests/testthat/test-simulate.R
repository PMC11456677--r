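test_that("target correlation encodes the manifest and the group effect", {
  m <- default_loop_manifest()
  ctl <- build_target_correlation(m, 0.3, "control")
  expect_true(isSymmetric(ctl))
  expect_equal(unname(diag(ctl)), rep(1, nrow(ctl)))
  # sparse manifest at rho0 = 0.3 is already PSD: repair is the identity
  expect_equal(attr(ctl, "repair_delta"), 0)
  expect_gte(min(eigen(ctl, symmetric = TRUE)$values), 0)
  expect_equal(ctl["L:M1", "L:CAU_M1"], 0.3)
  expect_equal(ctl["L:M1", "L:OFC"], 0)  # off-manifest

  aff <- "short:R:M1-CAU_M1"
  pat <- build_target_correlation(m, 0.3, "patient", aff, delta = 0.1)
  expect_equal(pat["R:M1", "R:CAU_M1"], 0.2)
  expect_equal(pat["L:M1", "L:CAU_M1"], 0.3)  # contralesional untouched

  same <- build_target_correlation(m, 0.3, "patient", aff, delta = 0)
  expect_equal(same, ctl, ignore_attr = TRUE)
})

test_that("an unrepairable rho0 errors with advice rather than distorting", {
  m <- default_loop_manifest()
  expect_error(build_target_correlation(m, 0.95, "control"), "lower rho0")
})

test_that("simulated series reproduce the target correlations", {
  m <- default_loop_manifest()
  corr <- build_target_correlation(m, 0.5, "control")
  s <- simulate_timeseries(corr, 5000, seed = 21)
  r_edge <- cor(s["L:M1", ], s["L:CAU_M1", ])
  expect_lt(abs(r_edge - 0.5), 0.05)

  id <- diag(4)
  rownames(id) <- colnames(id) <- paste0("r", 1:4)
  s0 <- simulate_timeseries(id, 2000, seed = 22)
  C <- cor(t(s0))
  expect_lt(max(abs(C[upper.tri(C)])), 0.1)
})

test_that("series simulation is seed-deterministic and rejects non-PSD", {
  id <- diag(3)
  expect_identical(simulate_timeseries(id, 50, seed = 5),
                   simulate_timeseries(id, 50, seed = 5))
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulate_timeseries(bad, 10, seed = 1),
               "positive semidefinite")
})

test_that("behaviour scores follow the clipped affine model", {
  z <- c(a = 0.5, b = -0.2)
  be <- data.frame(edge = c("a", "b"), weight = c(0, 0))
  expect_equal(simulate_behavior(z, be, noise_sd = 0, offset = 30), 30L)
  expect_equal(simulate_behavior(z, be, noise_sd = 0, offset = 100), 66L)
  expect_equal(simulate_behavior(z, be, noise_sd = 0, offset = -5), 0L)

  be1 <- data.frame(edge = "a", weight = 2)
  lo <- simulate_behavior(c(a = 0.1), be1, offset = 30, scale = 10)
  hi <- simulate_behavior(c(a = 0.9), be1, offset = 30, scale = 10)
  expect_gte(hi, lo)  # monotone in the positive-weight edge

  expect_identical(
    simulate_behavior(z, be1, noise_sd = 3, offset = 30, seed = 9),
    simulate_behavior(z, be1, noise_sd = 3, offset = 30, seed = 9))
  expect_error(simulate_behavior(z, data.frame(edge = "zz", weight = 1)),
               "not present")
})

test_that("voxel profiles are Dirichlet rows with planted labels", {
  vp <- simulate_voxel_profiles("CAU", voxels_per_subdivision = 20,
                                kappa = 30, seed = 3)
  expect_equal(dim(vp$profiles), c(100, 5))
  expect_equal(unname(rowSums(vp$profiles)), rep(1, 100), tolerance = 1e-12)
  expect_true(all(vp$profiles >= 0))
  expect_equal(table(vp$truth)[["CAU_M1"]], 20)
  expect_identical(vp$profiles,
                   simulate_voxel_profiles("CAU", voxels_per_subdivision = 20,
                                           kappa = 30, seed = 3)$profiles)
  expect_error(simulate_voxel_profiles("CAU", kappa = 0), "kappa")
})

test_that("a simulated cohort is structurally complete and reproducible", {
  coh <- small_cohort()
  expect_s3_class(coh, "cbtc_cohort")
  expect_equal(as.vector(table(coh$subjects$group)[c("patient", "control")]),
               c(10, 10))
  expect_equal(length(coh$series), 20)
  expect_equal(dim(coh$series[[1]]), c(50, 120))
  pat <- coh$subjects$group == "patient"
  expect_true(all(coh$subjects$ue_fma[pat] >= 0 &
                  coh$subjects$ue_fma[pat] <= 66))
  expect_true(all(is.na(coh$subjects$ue_fma[!pat])))
  expect_true(all(coh$subjects$age >= 30 & coh$subjects$age <= 80))

  coh2 <- simulate_cohort(sim_config(
    n_patients = 10, n_controls = 10, n_timepoints = 120,
    voxels_per_subdivision = 10, seed = 101))
  expect_identical(coh$subjects, coh2$subjects)
  expect_identical(coh$series, coh2$series)
})

test_that("the planted decrement lowers patient z on affected edges", {
  cfg <- sim_config(n_patients = 32, n_controls = 32, n_timepoints = 300,
                    rho0 = 0.4, delta = 0.2,
                    affected_edges = "short:R:M1-CAU_M1",
                    voxels_per_subdivision = 5, seed = 77)
  coh <- simulate_cohort(cfg)
  fc <- extract_fc_vector(coh, scheme = "loops")
  pat <- coh$subjects$group == "patient"
  zp <- fc[pat, "short:R:M1-CAU_M1"]
  zc <- fc[!pat, "short:R:M1-CAU_M1"]
  # planted gap atanh(0.4) - atanh(0.2) ~ 0.22; sampling sd per subject
  # ~ 1/sqrt(T-3) ~ 0.058, so the 3-sigma band of the mean difference is
  # well clear of zero at n = 32 per group
  se <- sqrt(var(zp) / length(zp) + var(zc) / length(zc))
  expect_lt(mean(zp) - mean(zc), -3 * se)
})

test_that("sim_config validates its own invariants", {
  expect_error(sim_config(rho0 = 1.2), "rho0")
  expect_error(sim_config(delta = 0.5, rho0 = 0.4), "delta")
  expect_error(sim_config(affected_edges = "short:R:nope-M1"),
               "not in manifest")
  expect_error(sim_config(behavior_noise_sd = -1), "noise_sd")
})
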