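test_that("empty noiseless frames equal the background exactly", {
  img <- imaging_model(frame_shape = c(32L, 32L),
                       bouton_specs = data.frame(x = 16, y = 16, radius = 3,
                                                 f0 = 0, type = "Ib"),
                       background_level = 7, noise_sigma = 0)
  mv <- render_movie(matrix(0, 4, 1), img)
  expect_equal(as.vector(mv$data), rep(7, 32 * 32 * 4))
})

test_that("mean footprint intensity reproduces the tapered signal", {
  img <- one_bouton_imaging()
  fp <- bouton_footprints(img)[[1]]
  dff <- c(0, 0.5, 2)
  mv <- render_movie(matrix(dff, ncol = 1), img)
  taper <- mean(fp$weight)
  for (i in seq_along(dff)) {
    inside <- mean(mv$data[, , i][fp$idx]) - img$background_level
    expect_equal(inside, 100 * (1 + dff[i]) * taper, tolerance = 1e-12)
  }
})

test_that("seeded rendering is bit-identical and noise averages out", {
  img <- one_bouton_imaging(noise_sigma = 5, rng_seed = 42L,
                            frame_shape = c(24L, 24L), radius = 3)
  a <- render_movie(matrix(0.2, 2, 1), img)
  b <- render_movie(matrix(0.2, 2, 1), img)
  expect_identical(a$data, b$data)

  quiet <- img; quiet$noise_sigma <- 0
  clean <- render_movie(matrix(0.2, 1, 1), quiet)$data[, , 1]
  acc <- 0
  for (s in 1:100) {
    img$rng_seed <- s
    acc <- acc + render_movie(matrix(0.2, 1, 1), img)$data[, , 1]
  }
  # CLT: mean over 100 seeds within 3 sigma/sqrt(100) per pixel
  expect_true(all(abs(acc / 100 - clean) < 3 * 5 / sqrt(100)))
})

test_that("boutons outside the frame are rejected and overlaps reported", {
  expect_error(imaging_model(frame_shape = c(32L, 32L),
                             bouton_specs = data.frame(x = 2, y = 16,
                                                       radius = 5, f0 = 1,
                                                       type = "Ib")),
               "inside the frame")
  img <- imaging_model(frame_shape = c(32L, 32L),
                       bouton_specs = data.frame(x = c(14, 17), y = 16,
                                                 radius = 4, f0 = 1,
                                                 type = "Ib"))
  expect_warning(bouton_footprints(img), "overlap")
})

test_that("colocalization pairs honor the occupancy flags", {
  img <- grid_imaging(3)
  none <- render_coloc_pair(img, occupied = c(FALSE, FALSE, FALSE))
  expect_equal(as.vector(none$red$data),
               rep(10, prod(img$frame_shape)))
  mixed <- render_coloc_pair(img, occupied = c(TRUE, FALSE, TRUE))
  expect_equal(mean(mixed$truth$occupied), 2 / 3)
  expect_gt(max(mixed$red$data), 10)
  # puncta larger than the host bouton rejected
  expect_error(render_coloc_pair(img, occupied = rep(TRUE, 3),
                                 punctum_radius = 5), "larger")
})

test_that("drawn occupancy equals the realized count, not the probability", {
  img <- grid_imaging(50, radius = 3, spacing = 12L)
  set.seed(7)
  occ <- runif(50) < 0.7
  pair <- render_coloc_pair(img, occupied = occ)
  expect_equal(pair$truth$occupied, occ)
  expect_equal(mean(pair$truth$occupied), sum(occ) / 50)
})

test_that("focal records place one stereotyped deflection per AP", {
  # silence is pure noise
  quiet <- generate_focal_record(numeric(0), 0.1, noise_sigma = 0)
  expect_true(all(quiet$amplitude == 0))
  # single AP peaks at exactly the quantal amplitude when noiseless
  one <- generate_focal_record(0.02, 0.1, quantal_amplitude = 3.5,
                               kernel_tau = 0.003)
  expect_equal(max(one$amplitude), 3.5, tolerance = 1e-9)
  # 8 APs at 100 Hz: peak times recovered within one sample
  aps <- 0.02 + (0:7) / 100
  tr <- generate_focal_record(aps, 0.15, kernel_tau = 0.002,
                              sample_rate = 10000)
  peaks <- which(diff(sign(diff(tr$amplitude))) == -2) + 1L
  expect_length(peaks, 8L)
  kernel_peak <- tr$time_s[which.max(generate_focal_record(
    0, 0.05, kernel_tau = 0.002, sample_rate = 10000)$amplitude)]
  expect_true(all(abs(tr$time_s[peaks] - (aps + kernel_peak)) <= 1e-4 + 1e-9))
  expect_error(generate_focal_record(0.01, 0.1, kernel_tau = 0.003,
                                     sample_rate = 100), "sample_rate")
})
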