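# shared fixtures, rendered once per test run
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]]))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# the study-condition phantom: 105 bpm, 8 breaths/min, 13 slices x 210
# frames of 37 ms at 0.9 mm pixels, real-time mode
paper_phantom <- function() fixture("paper_rt", {
  render_mask_series(ventricle_model(), acquisition_geometry(),
                     mode = "rt", noise_seed = 1)
})

paper_cycles <- function() fixture("paper_cyc", {
  sort_series(paper_phantom()$series, hr_hint = 105)
})

paper_lvfun <- function() fixture("paper_lf", {
  lv_function(paper_phantom()$series, paper_cycles(), hr = 105)
})

# truth cycles a detector can see: complete (next ED known) and interior
detectable_truth <- function(truth, Fn) {
  ev <- truth$events
  ev[!is.na(ev$ed_frame) & !is.na(ev$es_frame) & !is.na(ev$next_ed_frame) &
       ev$ed_frame >= 2 & ev$next_ed_frame <= Fn - 1, ]
}

# minimal hand-built mask series (for contract tests)
toy_series <- function(arr, pixel_spacing = c(1, 1), thickness = 3,
                       gap = 0.5, frame_duration = 37) {
  d <- dim(arr)
  geom <- acquisition_geometry(
    n_slices = d[3], slice_thickness = thickness, slice_gap = gap,
    pixel_spacing = pixel_spacing, frames_per_slice = d[4],
    frame_duration = frame_duration, matrix_size = d[1])
  tmat <- t(vapply(seq_len(d[3]), function(s) frame_times(geom, s, "rt"),
                   numeric(d[4])))
  structure(list(data = arr, geom = geom, labels = lv_labels(),
                 mode = "cine", hr = 105, frame_times = tmat),
            class = "mask_series")
}

# independent brute-force ICC(2,1) from explicit sums of squares
icc2_1_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  ri <- rowMeans(m); cj <- colMeans(m)
  msr <- k * sum((ri - g)^2) / (n - 1)
  msc <- n * sum((cj - g)^2) / (k - 1)
  res <- sweep(sweep(m, 1, ri), 2, cj) + g
  mse <- sum(res^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
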