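test_that("phantom rendering is deterministic given config and seed", {
  a <- build_thorax_ct(burden = 0.25, seed = 42)
  b <- build_thorax_ct(burden = 0.25, seed = 42)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$truth$collagen, b$truth$collagen)
  expect_identical(a$truth$fibrosis_fraction, b$truth$fibrosis_fraction)
})

test_that("zero burden yields an essentially lesion-free lung", {
  ph <- build_thorax_ct(burden = 0, seed = 7, noise = "none")
  seg <- segment_density(ph$ct, ph$lung)
  expect_lt(ct_result(seg, ph$ct, ph$lung)$fibrosis_fraction, 0.02)
  expect_equal(ph$truth$fibrosis_fraction, 0)
  expect_true(all(ph$truth$collagen == 0))
})

test_that("achieved fibrosis fraction tracks the target and excess burden errors", {
  ph <- build_thorax_ct(burden = 0.3, seed = 3, noise = "none")
  expect_lt(abs(ph$truth$fibrosis_fraction - 0.3), 0.02)
  seg <- segment_density(ph$ct, ph$lung)
  est <- ct_result(seg, ph$ct, ph$lung)$fibrosis_fraction
  expect_lt(abs(est - 0.3), 0.02)
  expect_error(build_thorax_ct(burden = 0.9), "0.8")
})

test_that("collagen burden is nonnegative and confined to the lung", {
  ph <- build_thorax_ct(burden = 0.4, seed = 11)
  expect_true(all(ph$truth$collagen >= 0))
  expect_true(all(ph$truth$collagen[!ph$lung$membership] == 0))
  expect_gt(ph$truth$mean_burden, 0)
})

test_that("kinetic model limits: single-exponential washout and binding asymptote", {
  kin <- kinetic_params()
  meta <- acquisition_meta(injected_activity_MBq = 5)
  t <- seq(0, 75, by = 0.5)
  c0 <- lung_concentration(t, kin, burden = 0, meta)
  expect_equal(c0, 5 * (kin$perfusion_amplitude *
                          exp(-kin$washout_rate * t) + kin$baseline))
  expect_true(all(diff(c0) < 0))
  # saturation limit for a fibrotic voxel
  far <- lung_concentration(5000, kin, burden = 0.7, meta)
  expect_equal(far, 5 * (kin$baseline + kin$binding_amplitude * 0.7),
               tolerance = 1e-6)
  expect_error(lung_concentration(-1, kin, 0, meta), "negative time")
})

test_that("default kinetics separate control washout from fibrotic retention", {
  kin <- kinetic_params()
  meta <- acquisition_meta()
  ctrl <- lung_concentration(c(2, 12), kin, burden = 0, meta)
  fib <- lung_concentration(c(2, 12), kin, burden = 1, meta)
  expect_lt(ctrl[2] / ctrl[1], 0.10)
  expect_gt(fib[2] / fib[1], 0.50)
})

test_that("dynamic schedule reproduces 2-min reconstruction from 2 to 75 min p.i.", {
  sched <- dynamic_frame_schedule()
  expect_equal(nrow(sched), 37L)
  expect_equal(sched$start + sched$duration / 2, seq(3, 75, by = 2))
  bad <- data.frame(start = c(2, 3), duration = c(2, 2))
  ph <- fixture_phantom()
  expect_error(render_pet_series(ph$truth, ph$lung, kinetic_params(),
                                 frame_schedule = bad),
               "overlapping")
})

test_that("noise-free rendering matches the closed-form frame average voxelwise", {
  ph <- build_thorax_ct(burden = 0, seed = 9, noise = "none")
  truth <- ph$truth
  truth$collagen[ph$lung$membership] <- 0.5  # uniform burden
  kin <- kinetic_params(); meta <- acquisition_meta()
  sched <- data.frame(start = c(15, 40), duration = c(10, 10))
  frames <- render_pet_series(truth, ph$lung, kin, meta, sched,
                              noise = "none")
  pet_lung <- resample_mask(ph$lung, frames[[1]])
  for (f in seq_along(frames)) {
    expected <- frame_average_concentration(sched$start[f],
                                            sched$duration[f], kin, 0.5,
                                            meta, decayed = TRUE)
    vox <- frames[[f]]$values[pet_lung$membership]
    expect_equal(max(abs(vox - expected)) / expected, 0, tolerance = 1e-12)
  }
})

test_that("measured activity never exceeds the decay-free value", {
  kin <- kinetic_params(); meta <- acquisition_meta()
  for (t0 in c(2, 10, 40, 70)) {
    dec <- frame_average_concentration(t0, 2, kin, 0.4, meta, decayed = TRUE)
    free <- frame_average_concentration(t0, 2, kin, 0.4, meta,
                                        decayed = FALSE)
    expect_lt(dec, free)
    # for a short frame the ratio approaches the mid-time decay factor
    expect_equal(dec / free, 2^(-(t0 + 1) / meta$half_life_min),
                 tolerance = 1e-3)
  }
})

test_that("Poisson noise at high count level perturbs the ROI mean by < 1%", {
  ph <- build_thorax_ct(burden = 0.3, seed = 21, noise = "none")
  kin <- kinetic_params(); meta <- acquisition_meta()
  cfg <- phantom_config(sensitivity = 2e4)
  sched <- data.frame(start = 15, duration = 10)
  nf <- render_pet_series(ph$truth, ph$lung, kin, meta, sched,
                          noise = "none", config = cfg)
  ns <- render_pet_series(ph$truth, ph$lung, kin, meta, sched,
                          noise = "poisson", seed = 5, config = cfg)
  pl <- resample_mask(ph$lung, nf[[1]])
  m_nf <- mean(nf[[1]]$values[pl$membership])
  m_ns <- mean(ns[[1]]$values[pl$membership])
  expect_lt(abs(m_ns - m_nf) / m_nf, 0.01)
})

test_that("window-averaged uptake increases monotonically with burden", {
  kin <- kinetic_params(); meta <- acquisition_meta()
  sched <- static_frame_schedule()
  ups <- vapply(c(0, 0.1, 0.25, 0.4), function(b) {
    ph <- build_thorax_ct(burden = b, seed = 31, noise = "none")
    frames <- render_pet_series(ph$truth, ph$lung, kin, meta, sched,
                                noise = "none")
    window_uptake(frames, ph$lung, meta)$whole_lung
  }, numeric(1))
  expect_true(all(diff(ups) > 0))
})
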