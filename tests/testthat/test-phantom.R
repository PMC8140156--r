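test_that("cavity waveform hits its anchors", {
  m <- ventricle_model()
  # ED at t = 0 during expiration is exactly the expiratory EDV
  expect_identical(cavity_volume_at(m, 0), m$edv_exp)
  # ES anchor, evaluated without respiratory modulation (breath hold)
  m0 <- ventricle_model(resp_rate = 0)
  es_t <- m0$systole_fraction * 60 / m0$hr
  expect_equal(cavity_volume_at(m0, es_t), m0$esv_exp, tolerance = 1e-9)
  expect_error(cavity_volume_at(m, NaN), "finite")
  expect_error(cavity_volume_at(m, -1), "finite")
})

test_that("zero inspiratory gain removes respiratory modulation", {
  m <- ventricle_model(insp_gain_edv = 0, insp_gain_esv = 0,
                       hr = 120, resp_rate = 8)
  # t = 1.5 s is an ED on the inspiratory plateau, t = 4.5 s an ED in
  # expiration (Tc = 0.5 s, breath = 7.5 s)
  expect_equal(resp_activation(m, 1.5), 1)
  expect_equal(resp_activation(m, 4.5), 0)
  expect_equal(cavity_volume_at(m, 1.5), cavity_volume_at(m, 4.5),
               tolerance = 1e-12)
})

test_that("inspiratory gain scales EDV by its definition", {
  m <- ventricle_model(edv_exp = 10, esv_exp = 4, insp_gain_edv = 0.15,
                       hr = 120, resp_rate = 8)
  expect_equal(cavity_volume_at(m, 1.5), 11.5, tolerance = 1e-12)
})

test_that("short axis is derived so the analytic ellipsoid volume matches", {
  m <- ventricle_model()
  v <- (2 / 3) * pi * m$short_axis_mm^2 * m$long_axis_mm / 1000
  expect_equal(v, m$edv_exp, tolerance = 1e-3)
  expect_error(ventricle_model(short_axis_mm = m$short_axis_mm * 1.05),
               "inconsistent")
  expect_error(ventricle_model(edv_exp = 5, esv_exp = 6), "")
  expect_error(ventricle_model(hr = 300), "")
})

test_that("phantom truth satisfies the functional identities", {
  tr <- paper_phantom()$truth
  expect_equal(tr$phases$sv, tr$phases$edv - tr$phases$esv)
  expect_equal(tr$phases$ef, tr$phases$sv / tr$phases$edv)
  i <- tr$phases$resp_phase == "inspiration"
  expect_true(tr$phases$edv[i] >= tr$phases$edv[!i])
})

test_that("every inspiratory per-cycle true EDV exceeds every expiratory one", {
  ph <- paper_phantom()
  ev <- ph$truth$events
  pf <- ph$truth$per_frame
  vol_at <- function(s, f) pf$volume_ml[pf$slice == s & pf$frame == f]
  ed_v <- mapply(vol_at, ev$slice, ev$ed_frame)
  insp <- ev$valid & ev$resp_phase == "inspiration"
  exp_ <- ev$valid & ev$resp_phase == "expiration"
  expect_true(min(ed_v[insp]) > max(ed_v[exp_]))
})

test_that("rendering is deterministic for a fixed seed", {
  m <- ventricle_model()
  g <- acquisition_geometry(frames_per_slice = 12)
  a <- render_mask_series(m, g, mode = "rt", noise_seed = 7)
  b <- render_mask_series(m, g, mode = "rt", noise_seed = 7)
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$truth$per_frame, b$truth$per_frame)
})

test_that("breath-hold emulation labels every frame expiration", {
  m <- ventricle_model(resp_rate = 0)
  g <- acquisition_geometry(frames_per_slice = 12)
  ph <- render_mask_series(m, g, mode = "rt")
  expect_true(all(ph$truth$per_frame$resp_label == "expiration"))
  expect_true(all(ph$truth$per_frame$activation == 0))
})

test_that("undersized geometry is rejected with a message", {
  m <- ventricle_model()
  expect_error(render_mask_series(m, acquisition_geometry(matrix_size = 24,
                                                          frames_per_slice = 4)),
               "FOV too small")
  expect_error(render_mask_series(m, acquisition_geometry(n_slices = 8,
                                                          frames_per_slice = 4)),
               "apex-to-base")
})

test_that("voxel-counted ED volume matches a brute-force ellipsoid oracle", {
  ph <- paper_phantom()
  g <- ph$series$geom
  evs <- ph$truth$events
  evs <- evs[evs$valid & evs$resp_phase == "expiration", ]
  areas <- vapply(seq_len(g$n_slices), function(s) {
    e <- evs[evs$slice == s, ]
    if (!nrow(e)) return(0)
    slice_area(ph$series$data[, , s, e$ed_frame[1]], "cavity",
               "pm_in_cavity", g$pixel_spacing)
  }, numeric(1))
  v_vox <- simpsons_volume(areas, g$slice_thickness, g$slice_gap)
  # brute-force numeric integration of the half-ellipsoid on a 0.1 mm grid
  m <- ventricle_model()
  zs <- seq(0.05, m$long_axis_mm - 0.05, by = 0.1)
  v_oracle <- sum(pi * m$short_axis_mm^2 *
                    (1 - ((zs - m$long_axis_mm) / m$long_axis_mm)^2) * 0.1) /
    1000
  expect_equal(v_oracle, m$edv_exp, tolerance = 1e-4)
  expect_lt(abs(v_vox - v_oracle) / v_oracle, 0.05)
})

test_that("in-plane discretisation error shrinks roughly linearly with spacing", {
  m <- ventricle_model(resp_rate = 0)
  err_at <- function(px, msz) {
    g <- acquisition_geometry(pixel_spacing = c(px, px), matrix_size = msz,
                              frames_per_slice = 8)
    ph <- render_mask_series(m, g, mode = "cine")
    tt <- frame_times(g, 1, "cine", hr = m$hr)
    v <- cavity_volume_at(m, tt)
    f_ed <- which.max(v)
    a2 <- m$short_axis_mm^2 * v[f_ed] / m$edv_exp
    cc <- m$long_axis_mm
    ar <- vapply(seq_len(g$n_slices), function(s)
      slice_area(ph$series$data[, , s, f_ed], "cavity", "pm_in_cavity",
                 c(px, px)), numeric(1))
    an <- vapply((seq_len(g$n_slices) - 0.5) * 3.5, function(z) {
      h <- z - 1
      if (h > 0 && h < cc && z <= 42) pi * a2 * (1 - ((h - cc) / cc)^2)
      else 0
    }, numeric(1))
    sum(abs(ar - an))
  }
  expect_lt(err_at(0.45, 128), 0.75 * err_at(0.9, 64))
})

test_that("signal traces are anchored to the physiology and reproducible", {
  m <- ventricle_model()
  g <- acquisition_geometry()
  tr <- make_signal_traces(m, g, noise_sd = 0)
  # noise-free LV-trace maxima coincide with true ED frames within 1 frame
  truth <- phantom_truth_tables(m, g, "rt")
  mid <- unique(truth$per_frame$slice)[7]
  tru <- detectable_truth(truth, g$frames_per_slice)
  tru <- tru[tru$slice == 7, ]
  v <- tr$lv$values
  maxima <- which(diff(sign(diff(v))) < 0) + 1
  for (f in tru$ed_frame)
    expect_lte(min(abs(maxima - f)), 1)
  # breath hold: liver trace constant
  m0 <- ventricle_model(resp_rate = 0)
  tr0 <- make_signal_traces(m0, g, noise_sd = 0)
  expect_equal(diff(range(tr0$liver$values)), 0)
  # seeded noise is reproducible
  n1 <- make_signal_traces(m, g, noise_sd = 3, seed = 11)
  n2 <- make_signal_traces(m, g, noise_sd = 3, seed = 11)
  expect_identical(n1$lv$values, n2$lv$values)
  expect_identical(n1$liver$values, n2$liver$values)
})

test_that("contrast ratio follows its definition and the rt degradation", {
  lab <- lv_labels()
  masks <- matrix(c(rep(lab[["blood"]], 50), rep(lab[["myocardium"]], 50)),
                  10, 10)
  inten <- ifelse(masks == lab[["blood"]], 200, 100)
  expect_equal(contrast_ratio(inten, masks), 2)
  expect_equal(contrast_ratio(inten * 0 + 7, masks), 1)
  expect_error(contrast_ratio(inten, matrix(lab[["lung"]], 10, 10)),
               "empty")
  # rt intensity model yields ~10% lower blood/myocardium ratio than cine
  ph <- paper_phantom()
  sl <- ph$series$data[, , 7, 1]
  r_rt <- contrast_ratio(render_intensity(sl, mode = "rt"), sl)
  r_cine <- contrast_ratio(render_intensity(sl, mode = "cine"), sl)
  expect_equal(r_rt / r_cine, 0.9, tolerance = 1e-10)
})

test_that("cycle jitter produces variable periods but keeps the anchors", {
  m <- ventricle_model(hr_jitter = 0.05, resp_jitter = 0.05, jitter_seed = 3)
  expect_equal(cavity_volume_at(m, 0), m$edv_exp)
  g <- acquisition_geometry(frames_per_slice = 210)
  truth <- phantom_truth_tables(m, g, "rt")
  ev <- truth$events[truth$events$slice == 1, ]
  periods <- diff(ev$ed_time)
  expect_gt(stats::sd(periods) / mean(periods), 0.01)
  # deterministic given the same jitter seed
  m2 <- ventricle_model(hr_jitter = 0.05, resp_jitter = 0.05, jitter_seed = 3)
  expect_identical(m$beat_times, m2$beat_times)
})
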