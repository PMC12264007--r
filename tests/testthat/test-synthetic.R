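test_that("default protocol reproduces the study timeline arithmetic", {
  pr <- protocol_spec()
  expect_equal(protocol_volume(pr, "fill1"), 600)      # 90 ml/min x 6:40
  expect_equal(protocol_volume(pr, "fill2"), 690)
  expect_equal(protocol_volume(pr, "washout"), 0)      # emptied in full
  expect_equal(protocol_experiment_frames(pr), 1254)
  ph <- pr$phases
  expect_equal(sum(ph$duration_s[ph$label %in% c("baseline", "fill1")]), 700)
})

test_that("protocol_spec validates phases", {
  bad <- default_protocol_phases()
  bad$pump_rate_ml_min[bad$label == "hold1"] <- 5
  expect_error(protocol_spec(bad), "pump_rate")
  bad2 <- default_protocol_phases()
  bad2$duration_s[1] <- -1
  expect_error(protocol_spec(bad2), "durations")
  bad3 <- default_protocol_phases()
  bad3$pump_rate_ml_min[bad3$label == "fill1"] <- -90
  expect_error(protocol_spec(bad3), "fill")
})

test_that("pressure model obeys its contracts", {
  pr <- protocol_spec()
  # no pumping, no noise -> flat at P0
  flat <- protocol_spec(within(default_protocol_phases(),
                               pump_rate_ml_min <- pump_rate_ml_min * 0))
  tr0 <- simulate_bladder_pressure(flat, list(noise_sd = 0), seed = 1)
  expect_equal(tr0$pressure_cmH2O, rep(10, length(tr0$time_s)))

  tr <- simulate_bladder_pressure(pr, list(noise_sd = 0), seed = 1)
  expect_true(all(tr$pressure_cmH2O > 0))
  expect_equal(length(tr$time_s), protocol_duration(pr))
  expect_equal(diff(tr$time_s), rep(1, length(tr$time_s) - 1))
  # accommodation: strict decay over each hold
  for (h in c("hold1", "hold2")) {
    ph <- tr$pressure_cmH2O[tr$phase == h]
    expect_true(all(diff(ph) < 0), label = paste("strict decrease in", h))
    expect_lt(mean(utils::tail(ph, 10)), mean(utils::head(ph, 10)))
  }
  # washout relaxes back toward P0
  expect_lt(abs(utils::tail(tr$pressure_cmH2O, 1) - 10), 1.5)
  # bit-identical per seed
  tr2 <- simulate_bladder_pressure(pr, seed = 11)
  tr3 <- simulate_bladder_pressure(pr, seed = 11)
  expect_identical(tr2, tr3)
  expect_error(simulate_bladder_pressure(pr, list(tau = 0)), "tau")
})

test_that("percent_bp matches its pointwise definition", {
  pr <- short_protocol()
  tr <- simulate_bladder_pressure(pr, seed = 3)
  pb <- percent_bp(tr)
  ref <- mean(tr$pressure_cmH2O[1:30])
  expect_equal(pb, 100 * (tr$pressure_cmH2O - ref) / ref)   # brute force
  expect_equal(mean(pb[1:30]), 0, tolerance = 1e-12)
  # constant pressure -> identically zero; doubling -> 100
  trc <- tr
  trc$pressure_cmH2O <- rep(ref, length(pb))
  expect_equal(percent_bp(trc), rep(0, length(pb)))
  trd <- trc
  trd$pressure_cmH2O[100] <- 2 * ref
  expect_equal(percent_bp(trd)[100], 100)
  # peak within fill/hold equals the oracle max of the formula
  win <- tr$phase %in% c("fill1", "hold1", "fill2", "hold2")
  expect_equal(max(pb[win]),
               max(100 * (tr$pressure_cmH2O[win] - ref) / ref))
  trz <- trc; trz$pressure_cmH2O <- rep(-1, length(pb))
  expect_error(percent_bp(trz), "degenerate")
})

test_that("phantom generator plants the advertised structure", {
  expect_equal(dim(phantom_truth()$gains), c(91L, 128L))  # 9.1 x 12.8 mm FOV
  sp <- small_phantom(seed = 5, noise_sd = 0, hrf = 1)
  d <- dim(sp$stack$data)
  expect_equal(d[3], protocol_duration(sp$protocol))
  # no gains / no noise / no drift -> every frame equals the baseline map
  tr0 <- phantom_truth(n_depth = 16, n_width = 16,
                       pos_mask = matrix(FALSE, 16, 16),
                       neg_mask = matrix(FALSE, 16, 16),
                       noise_sd = 0, drift_amplitude = 0, seed = 2)
  ph0 <- generate_phantom(tr0, sp$trace, sp$protocol)
  for (i in c(1, 50, d[3])) {
    expect_equal(ph0$stack$data[, , i], ph0$truth$baseline_map)
  }
  # identity kernel, single planted pixel: %-change equals gain * response
  pm <- matrix(FALSE, 16, 16); pm[5, 7] <- TRUE
  tr1 <- phantom_truth(n_depth = 16, n_width = 16, pos_mask = pm,
                       neg_mask = matrix(FALSE, 16, 16), gain_pos = 37,
                       hrf = 1, noise_sd = 0, drift_amplitude = 0, seed = 2)
  ph1 <- generate_phantom(tr1, sp$trace, sp$protocol)
  B <- ph1$truth$baseline_map[5, 7]
  pct_series <- 100 * (ph1$stack$data[5, 7, ] - B) / B
  expect_equal(pct_series, 37 * ph1$truth$response, tolerance = 1e-10)
  # determinism
  ph2 <- generate_phantom(sp$truth, sp$trace, sp$protocol)
  expect_identical(ph2$stack$data, sp$stack$data)
  # overlapping masks rejected
  m <- matrix(FALSE, 16, 16); m[1:3, 1:3] <- TRUE
  expect_error(phantom_truth(16, 16, pos_mask = m, neg_mask = m), "overlap")
})

test_that("planted pixels correlate perfectly in the noiseless identity-kernel world", {
  sp <- small_phantom(seed = 9, noise_sd = 0, hrf = 1)
  pb <- percent_bp(sp$trace)
  pos_px <- which(sp$truth$pos_mask, arr.ind = TRUE)[1, ]
  neg_px <- which(sp$truth$neg_mask, arr.ind = TRUE)[1, ]
  expect_equal(cor(sp$stack$data[pos_px[1], pos_px[2], ], pb), 1,
               tolerance = 1e-9)
  expect_equal(cor(sp$stack$data[neg_px[1], neg_px[2], ], pb), -1,
               tolerance = 1e-9)
})

test_that("motion injection moves images as the moment oracle predicts", {
  img <- blob_image()
  st <- static_stack(img, 4)
  # all-zero shifts: unchanged
  expect_equal(inject_motion(st, matrix(0, 4, 2))$data, st$data,
               tolerance = 1e-9)
  # integer shift of a delta image moves the spike one row
  delta <- matrix(0, 16, 16); delta[8, 8] <- 1
  moved <- shift_image(delta, 1, 0)
  expect_equal(which(moved == max(moved), arr.ind = TRUE)[1, ],
               c(row = 9, col = 8))
  # fractional shift moves a smooth blob's center of mass accordingly
  blob <- exp(-((row(delta) - 8.5)^2 + (col(delta) - 8.5)^2) / 6)
  shifted <- shift_image(blob, 0.3, -0.7)
  expect_equal(center_of_mass(shifted) - center_of_mass(blob),
               c(0.3, -0.7), tolerance = 0.02)
  expect_error(inject_motion(st, matrix(20, 4, 2)), "10 px")
  expect_error(inject_motion(st, matrix(NaN, 4, 2)), "finite")
})

test_that("compound blocks have the stated rank/energy structure", {
  # tissue-only: Casorati numerical rank <= tissue_rank
  blk <- generate_compound_block(n_depth = 24, n_width = 24, tissue_rank = 3,
                                 blood_amp = 0, noise_sd = 0, seed = 4)
  expect_equal(dim(blk$frames)[3], 200)
  sv <- svd(matrix(blk$frames, nrow = 24 * 24))$d
  expect_lt(sv[4] / sv[1], 1e-10)
  # blood-only: per-pixel mean |signal|^2 equals blood_amp^2 on vessels
  vm <- matrix(FALSE, 16, 16); vm[4:12, 8] <- TRUE
  blood <- generate_compound_block(n_depth = 16, n_width = 16,
                                   tissue_rank = 0, tissue_amp = 0,
                                   blood_amp = 2, vessel_mask = vm,
                                   noise_sd = 0, seed = 5)
  power <- apply(Mod(blood$frames)^2, c(1, 2), mean)
  expect_equal(power[vm], rep(4, sum(vm)), tolerance = 1e-9)
  expect_equal(power[!vm], rep(0, sum(!vm)))
  expect_error(generate_compound_block(doppler_freq_hz = c(100, 300)),
               "Nyquist")
  # determinism
  expect_identical(generate_compound_block(seed = 8)$frames,
                   generate_compound_block(seed = 8)$frames)
})

test_that("volume is conserved over the full protocol", {
  pr <- protocol_spec()
  rates <- pr$phases$pump_rate_ml_min / 60
  expect_equal(sum(rates * pr$phases$duration_s), 0)  # 690 in - 690 out
  tr <- simulate_bladder_pressure(pr, list(noise_sd = 0), seed = 1)
  expect_equal(utils::tail(tr$volume_ml, 1), 0)
})
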