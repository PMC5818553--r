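test_that("running average matches a direct convolution oracle", {
  expect_equal(smooth_dff(rep(3, 10)), rep(3, 10))
  imp <- c(rep(0, 10), 1, rep(0, 10))
  expect_equal(smooth_dff(imp)[11], 0.2)
  # random series against an independent window-mean oracle
  set.seed(2)
  x <- rnorm(40)
  oracle <- vapply(seq_along(x), function(i)
    mean(x[max(1, i - 2):min(length(x), i + 2)]), numeric(1))
  expect_equal(smooth_dff(x), oracle)
  # truncated edge windows: 3 points at the ends
  expect_equal(smooth_dff(x)[1], mean(x[1:3]))
  expect_equal(smooth_dff(x)[40], mean(x[38:40]))
  expect_error(smooth_dff(1:4), "at least 5")
})

test_that("peak search is confined to the 2-s post-onset window", {
  protocol <- stimulus_protocol(20, onset_time = 2, record_duration = 8)
  time <- (1:200 - 0.5) / 25
  ramp <- pmax(0, time - 2) / 6
  pk <- max_dff(ramp, time, protocol)
  expect_equal(pk$t_max, max(time[time <= 4]))
  # a larger late peak outside the window is ignored
  late <- ramp; late[time > 5] <- 10
  pk2 <- max_dff(late, time, protocol)
  expect_equal(pk2$max_dff, pk$max_dff)
  # record must cover the window
  short <- stimulus_protocol(20, train_duration = 1, onset_time = 2,
                             record_duration = 3.5)
  expect_error(max_dff(ramp[1:85], time[1:85], short), "window")
  # smoothing never raises the maximum
  set.seed(9)
  y <- runif(200)
  expect_lte(max(smooth_dff(y)), max(y))
})

test_that("half-rise matches closed forms for ramp, exponential and step", {
  protocol <- stimulus_protocol(20, onset_time = 2, record_duration = 8)
  time <- (1:200 - 0.5) / 25
  # linear ramp to peak over the 2-s train: half-rise at 1 s
  ramp <- pmin(pmax(0, time - 2), 2) / 2
  hr <- half_rise(ramp, time, protocol, peak = 1)
  expect_equal(hr$t_half_rise, 1, tolerance = 0.02)
  # saturating exponential: crossing at tau ln 2
  tau <- 0.4
  sat <- ifelse(time < 2, 0, 1 - exp(-(time - 2) / tau))
  hrs <- half_rise(sat, time, protocol, peak = 1)
  expect_equal(hrs$t_half_rise, tau * log(2), tolerance = 0.04)
  # immediate step: at most one frame interval
  step <- ifelse(time < 2, 0, 1)
  expect_lte(half_rise(step, time, protocol, peak = 1)$t_half_rise, 0.04)
})

test_that("half-decay matches ln2/k and censors plateaus", {
  protocol <- stimulus_protocol(20, onset_time = 2, record_duration = 10)
  time <- (1:250 - 0.5) / 25
  k <- 1.386
  te <- train_end(protocol)
  y <- ifelse(time < 2, 0,
              ifelse(time <= te, (time - 2) / 2, exp(-k * (time - te))))
  hd <- half_decay(y, time, protocol)
  expect_false(hd$decay_censored)
  expect_equal(hd$t_half_decay, log(2) / k, tolerance = 0.04)
  # plateau: censored with the elapsed record as lower bound
  plateau <- ifelse(time < 2, 0, pmin((time - 2) / 2, 1))
  hp <- half_decay(plateau, time, protocol)
  expect_true(hp$decay_censored)
  expect_equal(hp$t_half_decay, max(time) - te)
})

test_that("decay reference follows the trace value at train end", {
  # peak early in the train, signal declined by train end: the reference
  # is the (lower) value at train end, not the peak
  protocol <- stimulus_protocol(20, onset_time = 2, record_duration = 10)
  time <- (1:250 - 0.5) / 25
  k <- 2
  y <- ifelse(time < 2, 0,
              ifelse(time < 2.5, (time - 2) * 2,
                     exp(-k * (time - 2.5))))
  hd <- half_decay(y, time, protocol)
  ref <- exp(-k * (train_end(protocol) - 2.5))
  expect_equal(hd$decay_reference, ref, tolerance = 0.05)
  expect_equal(hd$t_half_decay, log(2) / k, tolerance = 0.04)
})

test_that("halving the frame interval moves half-times by less than a frame", {
  for (fr in list(c(25, 50))) {
    est <- lapply(fr, function(f) {
      preset <- linear_preset(k_leak = 1, frame_rate = f)
      protocol <- stimulus_protocol(20, record_duration = 8)
      sim <- simulate_nmj(preset, protocol, n_boutons = 1L, seed = 1)
      analyze_trace(sim$traces[[1]], protocol)
    })
    expect_lt(abs(est[[1]]$t_half_rise - est[[2]]$t_half_rise), 0.04)
    expect_lt(abs(est[[1]]$t_half_decay - est[[2]]$t_half_decay), 0.04)
  }
})

test_that("peak dF/F is nondecreasing in stimulus frequency", {
  peaks <- vapply(c(2, 10, 20, 40, 80), function(f) {
    preset <- linear_preset(k_leak = 1.386)
    protocol <- stimulus_protocol(f, record_duration = 6)
    sim <- simulate_nmj(preset, protocol, n_boutons = 1L, seed = 1)
    analyze_trace(sim$traces[[1]], protocol)$max_dff
  }, numeric(1))
  expect_true(all(diff(peaks) > -1e-9))
})

test_that("frequency-response summaries define threshold and saturation", {
  tab <- data.frame(
    bouton_id = rep(1:4, 3), nmj_id = rep(c(1, 1, 2, 2), 3),
    type = "Ib", frequency_hz = rep(c(2, 20, 40), each = 4),
    max_dff = c(0.01, 0.012, 0.009, 0.011,
                0.2, 0.22, 0.18, 0.2,
                0.21, 0.23, 0.19, 0.21),
    t_half_rise_s = NA, t_half_decay_s = NA,
    responder = rep(c(FALSE, TRUE, TRUE), each = 4),
    rise_censored = FALSE, decay_censored = FALSE, n_b = 0.02)
  fr <- frequency_response(tab)
  expect_equal(fr$threshold_frequency, 20)
  expect_equal(fr$saturation_frequency, 20)  # 0.2 >= 0.95 * 0.21
  expect_equal(fr$per_frequency$nmj_mean_max_dff[1],
               mean(c(mean(c(0.01, 0.012)), mean(c(0.009, 0.011)))))
  # all nonresponding: threshold undefined
  tab$responder <- FALSE
  expect_true(is.na(frequency_response(tab)$threshold_frequency))
  # single frequency, all responding: threshold = saturation = it
  one <- tab[tab$frequency_hz == 40, ]
  one$responder <- TRUE
  fr1 <- frequency_response(one)
  expect_equal(fr1$threshold_frequency, 40)
  expect_equal(fr1$saturation_frequency, 40)
})
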