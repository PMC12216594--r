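# wide stimulus for long-ramp fixtures whose position would otherwise leave
# the real stimulus area
wide_stim <- stimulus_spec(width_deg = 1e4)

ramp_trace <- function(v_dps = 33.5, dur_ms = 10000, jumps_ms = integer(0),
                       jump_deg = 5, px_per_deg = 48) {
  t <- 0:(dur_ms - 1)
  x <- v_dps * t / 1000
  for (j in jumps_ms) x[t >= j] <- x[t >= j] + jump_deg
  gaze_trace(t, x * px_per_deg, trial_id = "fix")
}

test_that("validity marking flags blinks with guard margins and leaves clean data alone", {
  cfg <- run_config()
  tr <- ramp_trace(5, 2000)
  m <- mark_invalid_samples(tr, cfg, wide_stim)
  expect_true(all(m$valid))  # clean constant-velocity trace: zero new flags

  tr2 <- ramp_trace(5, 2000)
  tr2$valid[1001:1080] <- FALSE  # 80 ms blink
  m2 <- mark_invalid_samples(tr2, cfg, wide_stim)
  expect_true(all(!m2$valid[(1001 - 25):(1080 + 25)]))
  expect_true(all(m2$valid[1:(1001 - 26)]))
  expect_true(all(m2$valid[(1080 + 26):2000]))
})

test_that("validity marking flags speed-ceiling spikes plus margins", {
  cfg <- run_config()
  tr <- ramp_trace(5, 2000)
  x <- tr$x_px / 48
  x[1000] <- x[1000] + 2  # 2 deg in 1 ms: 2000 deg/s excursion
  tr$x_px <- x * 48
  m <- mark_invalid_samples(tr, cfg, wide_stim)
  # central differences implicate samples 999-1001; margins extend 25 ms
  expect_true(all(!m$valid[(999 - 25):(1001 + 25)]))
  expect_true(all(m$valid[1:(999 - 26)]))
  expect_true(all(m$valid[(1001 + 26):2000]))
  # out-of-area positions are flagged under the real stimulus geometry
  tr3 <- gaze_trace(0:99, rep(9.7 * 48, 100))
  m3 <- mark_invalid_samples(tr3, cfg, stimulus_spec())
  expect_true(all(!m3$valid))
})

test_that("slow-segment detection follows the velocity/acceleration/duration criteria", {
  cfg <- run_config()
  tr <- ramp_trace()
  seg <- detect_slow_segments(tr, cfg, wide_stim)
  expect_equal(nrow(seg), 1)  # pure ramp: one segment spanning the trace
  expect_gt(seg$end[1] - seg$start[1], 9900)
  expect_equal(seg$mean_v_dps[1], 33.5, tolerance = 1e-9)

  seg2 <- detect_slow_segments(ramp_trace(jumps_ms = 5000), cfg, wide_stim)
  expect_equal(nrow(seg2), 2)  # one saccadic jump: split at the jump
  expect_lt(abs(seg2$end[1] - 5000), 60)
  expect_lt(abs(seg2$start[2] - 5000), 60)

  # a 30 ms compliant run between two saccades falls below the minimum
  cfg_tight <- run_config(guard_ms = 1)
  tr3 <- ramp_trace(dur_ms = 2030, jumps_ms = c(1000, 1030))
  seg3 <- detect_slow_segments(tr3, cfg_tight, wide_stim)
  expect_true(all(seg3$start_i > 1030 | seg3$end_i < 1000))
  expect_equal(nrow(seg3), 2)

  # trace shorter than the minimum duration: empty result, no error
  expect_equal(nrow(detect_slow_segments(ramp_trace(dur_ms = 30), cfg,
                                         wide_stim)), 0)
})

test_that("cumulative pursuit aligns segments and bridges gaps continuously", {
  cfg <- run_config()
  tr <- ramp_trace()
  seg <- detect_slow_segments(tr, cfg, wide_stim)
  cum <- cumulative_pursuit(seg, tr, wide_stim)
  x_deg <- tr$x_px / 48
  idx <- seg$start_i[1]:seg$end_i[1]
  # one segment: identity up to a constant offset
  expect_equal(cum[idx], x_deg[idx] - x_deg[idx[1]], tolerance = 1e-12)

  tr2 <- ramp_trace(jumps_ms = 5000)
  seg2 <- detect_slow_segments(tr2, cfg, wide_stim)
  cum2 <- cumulative_pursuit(seg2, tr2, wide_stim)
  x2 <- tr2$x_px / 48
  disp <- sum(vapply(seq_len(nrow(seg2)), function(i)
    x2[seg2$end_i[i]] - x2[seg2$start_i[i]], numeric(1)))
  # total displacement equals the sum of within-segment displacements:
  # the 5 deg saccadic jump is removed
  expect_equal(cum2[seg2$end_i[2]], disp, tolerance = 1e-9)
  expect_lt(max(abs(diff(cum2))), 33.5 / 1000 + 1e-9)  # no discontinuity

  tr3 <- ramp_trace(jumps_ms = c(3000, 7000))
  seg3 <- detect_slow_segments(tr3, cfg, wide_stim)
  cum3 <- cumulative_pursuit(seg3, tr3, wide_stim)
  expect_equal(nrow(seg3), 3)
  expect_lt(max(abs(diff(cum3))), 33.5 / 1000 + 1e-9)

  expect_length(cumulative_pursuit(seg3[0, ], tr3, wide_stim), 0)
})

test_that("bagged profile recovers a constant slope with zero-width CI", {
  cfg <- run_config()
  tr <- ramp_trace(jumps_ms = 5000)  # two segments, both slope 33.5
  trm <- mark_invalid_samples(tr, cfg, wide_stim)
  seg <- detect_slow_segments(trm, cfg, wide_stim)
  cum <- cumulative_pursuit(seg, trm, wide_stim)
  set.seed(1)
  prof <- bagged_velocity_profile(cum, seg, trm, cfg)
  # away from the join and the edges the estimate is exact and degenerate
  interior <- prof$t > 500 & prof$t < 4800
  expect_equal(median(prof$median_v[interior]), 33.5, tolerance = 1e-9)
  expect_lt(max(prof$ci_high[interior] - prof$ci_low[interior]), 1e-9)
  expect_true(all(prof$ci_low <= prof$median_v + 1e-12, na.rm = TRUE))
  expect_true(all(prof$ci_high >= prof$median_v - 1e-12, na.rm = TRUE))
})

test_that("bagged profile tracks a slope reversal and is seed-deterministic", {
  # synthetic cumulative series: +33.5 deg/s for 5 s then -33.5 deg/s,
  # chopped into eight segments
  n <- 10000
  t_s <- (0:(n - 1)) / 1000
  cum <- ifelse(t_s < 5, 33.5 * t_s, 2 * 33.5 * 5 - 33.5 * t_s)
  tr <- gaze_trace(0:(n - 1), cum * 48)
  bounds <- round(seq(1, n, length.out = 9))
  seg <- data.frame(start_i = head(bounds, -1) + c(0, rep(5, 7)),
                    end_i = bounds[-1] - 5)
  seg$start <- seg$start_i - 1; seg$end <- seg$end_i
  cfg <- run_config()
  set.seed(2)
  prof <- bagged_velocity_profile(cum, seg, tr, cfg)
  left <- prof$t > 1000 & prof$t < 4500
  right <- prof$t > 5500 & prof$t < 9000
  expect_gt(min(prof$median_v[left], na.rm = TRUE), 30)
  expect_lt(max(prof$median_v[right], na.rm = TRUE), -30)
  cross <- prof$t[which(diff(sign(prof$median_v)) != 0)]
  expect_lt(min(abs(cross - 5000)), 150)

  set.seed(7); a <- bagged_velocity_profile(cum, seg, tr, cfg)
  set.seed(7); b <- bagged_velocity_profile(cum, seg, tr, cfg)
  expect_identical(a, b)
})

test_that("fewer than two segments give a flagged degenerate profile", {
  tr <- ramp_trace(dur_ms = 2000)
  cfg <- run_config()
  seg <- detect_slow_segments(tr, cfg, wide_stim)
  expect_equal(nrow(seg), 1)
  cum <- cumulative_pursuit(seg, tr, wide_stim)
  prof <- bagged_velocity_profile(cum, seg, tr, cfg)
  expect_true(attr(prof, "degenerate"))
  expect_true(all(is.infinite(prof$ci_low)))
  tl <- classify_percepts(prof, cfg)
  expect_equal(tl$label, "mixed")  # one all-mixed interval
  expect_equal(nrow(tl), 1)
})

test_that("classification thresholds the whole confidence interval", {
  cfg <- run_config()
  t <- seq(0, 995, by = 5)
  mk_prof <- function(lo, hi) {
    p <- data.frame(t = t, median_v = (lo + hi) / 2, ci_low = lo,
                    ci_high = hi)
    class(p) <- c("velocity_profile", "data.frame")
    p
  }
  right <- classify_percepts(mk_prof(20, 30), cfg)
  expect_equal(right$label, "right")
  expect_equal(nrow(right), 1)
  expect_equal(c(right$start, right$end), c(0, 1000))

  spans0 <- classify_percepts(mk_prof(-3, 3), cfg)
  expect_equal(spans0$label, "mixed")

  leftp <- classify_percepts(mk_prof(-30, -8), cfg)
  expect_equal(leftp$label, "left")

  # boundary: ci_low exactly at the threshold is not dominance
  at_thr <- classify_percepts(mk_prof(5, 30), cfg)
  expect_equal(at_thr$label, "mixed")
})

test_that("mirroring the stimulus swaps left and right labels exactly", {
  set.seed(12)
  tl <- sample_percept_sequence(sim_config(),
                                trial_descriptor("VISP", "right",
                                                 trial_id = "m"))
  tr <- render_okn_trace(tl, stimulus_spec(), sim_config())
  tr_m <- tr
  tr_m$x_px <- -tr$x_px
  cfg <- run_config()
  set.seed(55); a <- segment_trace(tr, cfg)
  set.seed(55); b <- segment_trace(tr_m, cfg)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$start, b$start)
  swap <- c(left = "right", right = "left", mixed = "mixed")
  expect_equal(unname(swap[a$label]), b$label)
})

test_that("timelines from csp tile the phase and csp methods are coherent", {
  set.seed(13)
  tl <- sample_percept_sequence(sim_config(),
                                trial_descriptor("CONP", "left",
                                                 trial_id = "c"))
  tr <- render_okn_trace(tl, stimulus_spec(), sim_config())
  fit <- csp(tr)
  est <- fit$timeline
  expect_equal(est$start[1], 0)
  expect_equal(est$end[nrow(est)], 10000)
  expect_equal(sum(est$end - est$start), 10000)
  if (nrow(est) > 1) expect_true(all(est$label[-1] != est$label[-nrow(est)]))
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-12)
  expect_length(fitted(fit), nrow(tr))
  s <- summary(fit)
  expect_equal(s$mixed_fraction, unname(coef(fit)["p_mixed"]),
               tolerance = 1e-12)
  expect_output(print(fit), "slow segments")
  # plotting works headlessly
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("CI width shrinks to zero as noise vanishes and is stable in B", {
  set.seed(14)
  tl <- tl_of(c(0, 4000, "right"), c(4000, 10000, "left"))
  width_at <- function(noise, B) {
    cfg_s <- sim_config(noise_sd_dps = noise, blink_rate_hz = 0)
    set.seed(100)
    tr <- render_okn_trace(tl, stimulus_spec(), cfg_s)
    cfg <- run_config(bag_resamples = B)
    tr <- mark_invalid_samples(tr, cfg)
    seg <- detect_slow_segments(tr, cfg)
    cum <- cumulative_pursuit(seg, tr)
    set.seed(200)
    p <- bagged_velocity_profile(cum, seg, tr, cfg)
    fin <- is.finite(p$ci_low) & is.finite(p$ci_high)
    median(p$ci_high[fin] - p$ci_low[fin])
  }
  expect_equal(width_at(0, 200), 0, tolerance = 1e-9)
  w50 <- width_at(2, 50); w200 <- width_at(2, 200)
  expect_lte(w200, w50 + 0.2)
})
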