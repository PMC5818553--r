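test_that("uniform frames give identically zero background-subtracted traces", {
  img <- one_bouton_imaging(frame_shape = c(32L, 32L), radius = 3, f0 = 0,
                            background = 55)
  mv <- render_movie(matrix(0, 6, 1), img)
  rois <- rois_from_imaging(img)
  tr <- extract_traces(mv, rois)[[1]]
  expect_equal(tr$f_t, rep(0, 6))
  expect_equal(tr$f_raw, rep(55, 6))
})

test_that("a constant 10-unit offset over the bouton yields f_t = 10", {
  sh <- c(32L, 32L)
  img <- one_bouton_imaging(frame_shape = sh, radius = 3, background = 20)
  rois <- rois_from_imaging(img)
  fr <- matrix(20, sh[1], sh[2])
  fr[rois$boutons[[1]]] <- 30
  mv <- frame_stack(array(fr, dim = c(sh, 3)), 25)
  tr <- extract_traces(mv, rois)[[1]]
  expect_equal(tr$f_t, rep(10, 3))
})

test_that("noiseless movie round trip recovers simulator dF/F", {
  preset <- linear_preset()
  protocol <- stimulus_protocol(20, record_duration = 6)
  sim <- simulate_nmj(preset, protocol, n_boutons = 2L, seed = 1)
  img <- grid_imaging(2, radius = 4, spacing = 20L)
  re <- render_and_extract(sim, img)
  for (tr in re$traces) {
    tr <- compute_dff(compute_baseline(tr, protocol))
    expect_lt(max(abs(tr$dff - sim$truth$dff)), 1e-6)
  }
})

test_that("baseline spans the 25 frames (1 s at 25 Hz) before onset", {
  protocol <- stimulus_protocol(20, onset_time = 2, record_duration = 6)
  tr <- bouton_trace(rep(100, 150), frame_rate = 25)
  tr <- compute_baseline(tr, protocol)
  expect_equal(tr$f_b, 100)
  expect_equal(tr$n_b, 0)
  expect_length(tr$baseline_idx, 25L)
  expect_equal(diff(range(tr$time[tr$baseline_idx])), 24 / 25)
  expect_true(all(tr$time[tr$baseline_idx] < 2))
  # onset earlier than frame 25 is an error
  early <- stimulus_protocol(20, onset_time = 0.5, record_duration = 6)
  expect_error(compute_baseline(tr, early), "before stimulation onset")
})

test_that("noise estimate converges to sigma over baseline", {
  # Monte-Carlo check of the N_B = sd/F_B identity
  set.seed(11)
  protocol <- stimulus_protocol(20, onset_time = 2, record_duration = 6)
  n_b <- replicate(2000, {
    tr <- bouton_trace(100 + rnorm(150, 0, 5), frame_rate = 25)
    compute_baseline(tr, protocol)$n_b
  })
  # RMS over n frames carries the sqrt((n-1)/n) population-SD factor
  expect_equal(mean(n_b), 0.05 * sqrt(24 / 25), tolerance = 0.01)
})

test_that("dF/F equals the element-wise definition on arbitrary traces", {
  protocol <- stimulus_protocol(20, onset_time = 2, record_duration = 6)
  set.seed(3)
  f_t <- 100 + cumsum(rnorm(150))
  tr <- compute_dff(compute_baseline(bouton_trace(f_t), protocol))
  expect_equal(tr$dff, (f_t - tr$f_b) / tr$f_b)
  expect_equal(mean(tr$dff[tr$baseline_idx]), 0, tolerance = 1e-14)
  # doubling f_b frame gives dff = 1 there
  f2 <- rep(100, 150); f2[80] <- 200
  tr2 <- compute_dff(compute_baseline(bouton_trace(f2), protocol))
  expect_equal(tr2$dff[80], 1)
})

test_that("QC flags low baselines, high noise and manual exclusions", {
  protocol <- stimulus_protocol(20, onset_time = 2, record_duration = 6)
  set.seed(5)
  mk <- function(level, sigma) compute_baseline(
    bouton_trace(level + rnorm(150, 0, sigma)), protocol)
  traces <- c(lapply(1:57, function(i) mk(100, 1)),
              list(mk(0.1, 0.01), mk(100, 30), mk(100, 1)))
  qc <- qc_filter(traces, f_b_floor = 1, n_b_ceiling = 0.1,
                  manual_exclude = 60L)
  expect_equal(qc$exclusion_fraction, 3 / 60)
  expect_true(qc$report$low_baseline[58])
  expect_true(qc$report$high_noise[59])
  expect_true(qc$report$contraction_artifact[60])
  expect_length(qc$passing, 57L)
  # all-clean population passes in full
  qc2 <- qc_filter(traces[1:57])
  expect_equal(qc2$exclusion_fraction, 0)
})

test_that("empty and mismatched ROIs raise informative errors", {
  expect_error(roi_set(list(integer(0)), list(1:4), c(8L, 8L)), "label 1")
  expect_error(roi_set(list(1:4), list(3:6), c(8L, 8L)), "overlaps")
  img <- one_bouton_imaging(frame_shape = c(32L, 32L), radius = 3)
  rois <- rois_from_imaging(img)
  small <- frame_stack(array(1, dim = c(16, 16, 2)), 25)
  expect_error(extract_traces(small, rois), "frame_shape")
})
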