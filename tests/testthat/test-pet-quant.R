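test_that("decay factor: closed-form values and multiplicativity", {
  expect_equal(decay_factor(0, 67.71), 1.0)
  expect_equal(decay_factor(67.71, 67.71), 2.0)
  expect_equal(decay_factor(135.42, 67.71), 4.0)
  ts <- seq(0, 120, by = 7.5)
  for (t1 in ts) for (t2 in c(0, 13, 41)) {
    expect_equal(decay_factor(t1 + t2, 67.71),
                 decay_factor(t1, 67.71) * decay_factor(t2, 67.71))
  }
  expect_true(all(diff(decay_factor(ts, 67.71)) > 0))
  expect_error(decay_factor(-1, 67.71), "negative elapsed")
})

test_that("%ID/g worked example: 50 kBq/mL corrected over 5 MBq at unit density", {
  meta <- acquisition_meta(injected_activity_MBq = 5, half_life_min = 67.71)
  # measured value chosen so the mid-time correction restores 50 kBq/mL
  mid <- 15 + 1
  pet <- uniform_pet(50 / decay_factor(mid, meta$half_life_min),
                     frame_start = 15, frame_duration = 2)
  expect_equal(percent_id_per_gram(pet, full_mask(pet), meta), 1.0)
  # null field
  expect_equal(percent_id_per_gram(uniform_pet(0), full_mask(uniform_pet(0)),
                                   meta), 0)
})

test_that("%ID/g is intensive: invariant to voxel refinement, linear in dose", {
  meta <- acquisition_meta(injected_activity_MBq = 5)
  coarse <- uniform_pet(30, shape = c(6, 6, 6), spacing = c(1, 1, 1))
  fine <- uniform_pet(30, shape = c(12, 12, 12), spacing = c(0.5, 0.5, 0.5))
  expect_equal(percent_id_per_gram(coarse, full_mask(coarse), meta),
               percent_id_per_gram(fine, full_mask(fine), meta))
  meta2 <- acquisition_meta(injected_activity_MBq = 10)
  expect_equal(percent_id_per_gram(coarse, full_mask(coarse), meta2),
               percent_id_per_gram(coarse, full_mask(coarse), meta) / 2)
})

test_that("compartment uptake localises binding to dense lesions", {
  ph <- fixture_phantom()
  meta <- acquisition_meta()
  frames <- render_pet_series(ph$truth, ph$lung, kinetic_params(), meta,
                              static_frame_schedule(), noise = "none")
  seg <- segment_density(ph$ct, ph$lung)
  up <- compartment_uptake(frames[[1]], seg, meta, lung = ph$lung)
  expect_gt(up$dense, up$aerated)
  expect_gt(up$dense / up$aerated, 5)

  # whole-lung equals the voxel-weighted compartment mean on the PET grid
  pa <- resample_mask(seg$aerated, frames[[1]])
  pd <- resample_mask(seg$dense, frames[[1]])
  na <- sum(pa$membership); nd <- sum(pd$membership)
  expect_equal(up$whole_lung * (na + nd), up$aerated * na + up$dense * nd,
               tolerance = 1e-9)
})

test_that("an empty dense compartment reports NA, not zero", {
  ctl <- build_thorax_ct(burden = 0, seed = 15, noise = "none")
  meta <- acquisition_meta()
  frames <- render_pet_series(ctl$truth, ctl$lung, kinetic_params(), meta,
                              static_frame_schedule(), noise = "none")
  seg <- segment_density(ctl$ct, ctl$lung)
  up <- compartment_uptake(frames[[1]], seg, meta, lung = ctl$lung)
  expect_true(is.na(up$dense))
  expect_gt(up$aerated, 0)
})

test_that("TAC construction: mid-times, flat curve under pure decay, monotone control", {
  meta <- acquisition_meta()
  # constant corrected field: measured values follow pure physical decay
  sched <- dynamic_frame_schedule()
  frames <- lapply(seq_len(nrow(sched)), function(i) {
    mid <- sched$start[i] + sched$duration[i] / 2
    uniform_pet(40 / decay_factor(mid, meta$half_life_min),
                frame_start = sched$start[i],
                frame_duration = sched$duration[i])
  })
  tac <- build_tac(frames, full_mask(frames[[1]]), meta)
  expect_equal(tac$mid_time_min, seq(3, 75, by = 2))
  expect_lt(diff(range(tac$pct_id_per_g)), 1e-9)

  # control phantom: decay-corrected TAC decreases after the first frame
  ctl <- build_thorax_ct(burden = 0, seed = 19, noise = "none")
  fr <- render_pet_series(ctl$truth, ctl$lung, kinetic_params(), meta,
                          sched, noise = "none")
  ct_tac <- build_tac(fr, ctl$lung, meta)
  expect_true(all(diff(ct_tac$pct_id_per_g) < 0))
  expect_equal(which.max(ct_tac$pct_id_per_g), 1L)

  expect_error(build_tac(frames[c(2, 1)], full_mask(frames[[1]]), meta),
               "unordered")
})

test_that("window uptake: single-frame and equal-weight reductions", {
  meta <- acquisition_meta()
  sched <- data.frame(start = c(5, 20, 40), duration = c(2, 2, 2))
  frames <- lapply(seq_len(nrow(sched)), function(i)
    uniform_pet(10 * i, frame_start = sched$start[i],
                frame_duration = sched$duration[i]))
  m <- full_mask(frames[[1]])
  one <- window_uptake(frames, m, meta, window = c(15, 30))
  expect_equal(one$whole_lung, percent_id_per_gram(frames[[2]], m, meta))
  both <- window_uptake(frames, m, meta, window = c(15, 75))
  expect_equal(both$whole_lung,
               mean(c(percent_id_per_gram(frames[[2]], m, meta),
                      percent_id_per_gram(frames[[3]], m, meta))))
  expect_error(window_uptake(frames, m, meta, window = c(60, 75)),
               "no frames in window")
})

test_that("noise-free end-to-end uptake matches the closed-form kinetic oracle", {
  ph <- build_thorax_ct(burden = 0, seed = 23, noise = "none")
  truth <- ph$truth
  truth$collagen[ph$lung$membership] <- 0.6
  kin <- kinetic_params(); meta <- acquisition_meta()
  sched <- static_frame_schedule()
  frames <- render_pet_series(truth, ph$lung, kin, meta, sched,
                              noise = "none")
  got <- window_uptake(frames, ph$lung, meta)$whole_lung
  mids <- sched$start + sched$duration / 2
  per_frame <- vapply(seq_len(nrow(sched)), function(i) {
    conc <- frame_average_concentration(sched$start[i], sched$duration[i],
                                        kin, 0.6, meta, decayed = TRUE)
    100 * conc * decay_factor(mids[i], meta$half_life_min) /
      (1000 * meta$injected_activity_MBq)
  }, numeric(1))
  oracle <- sum(sched$duration / sum(sched$duration) * per_frame)
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("tac_divergence finds the earliest persistent separation", {
  mk <- function(t, v) structure(data.frame(mid_time_min = t,
                                            pct_id_per_g = v),
                                 class = c("tac", "data.frame"))
  a <- mk(c(3, 5, 7, 9), c(6, 4, 2, 1))
  expect_null(tac_divergence(a, a, tolerance = 0.5))
  b_up <- mk(c(3, 5, 7, 9), c(6, 4, 2, 1) + 1.0)
  expect_equal(tac_divergence(a, b_up, tolerance = 0.5), 3)
  b <- mk(c(3, 5, 7, 9), c(6, 4.2, 4, 4.1))
  expect_equal(tac_divergence(a, b, tolerance = 0.5), 7)
  bad <- mk(c(3, 5, 7, 11), c(6, 4.2, 4, 4.1))
  expect_error(tac_divergence(a, bad, tolerance = 0.5), "mismatched")
})
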