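test_that("calibration maps a noise-free trace back to its true trajectory", {
  tr <- simulate_trace(helicase_params(rate_sd = 0), NULL,
                       noiseless_config(seed = 2))
  traj <- calibrate_trace(tr, L_SUB)
  pre <- traj$time_s < tr$truth$completion_time_s
  # half a frame of advance (v * dt / 2 = 41 bp) limits how well the
  # full-scale intensity can be anchored; stay within 1.6% of full scale
  expect_lt(max(abs(traj$bp[pre] - tr$truth$unwound_bp[pre])), 0.016 * L_SUB)
})

test_that("calibration is invariant to uniform intensity rescaling", {
  tr <- simulate_trace(helicase_params(), NULL, sim_config(seed = 14))
  tr2 <- tr
  tr2$intensity <- tr$intensity * 37.5
  expect_equal(calibrate_trace(tr, L_SUB)$bp,
               calibrate_trace(tr2, L_SUB)$bp, tolerance = 1e-10)
})

test_that("flat traces cannot be calibrated", {
  tr <- list(molecule_id = "m", times = seq(0, 400, 10),
             intensity = rep(3, 41), frame_interval_s = 10)
  expect_error(calibrate_trace(tr, L_SUB), "flat trace")
})

test_that("completion is detected within one frame and censoring works", {
  tr <- simulate_trace(helicase_params(rate_sd = 0), NULL,
                       sim_config(seed = 21))
  expect_lt(abs(detect_completion(tr) - tr$truth$completion_time_s), 10 + 1e-9)
  arr <- simulate_trace(helicase_params(), barrier_mh_lead(occupancy = 1),
                        sim_config(seed = 22))
  expect_true(is.na(detect_completion(arr)))
})

test_that("a single-frame 40% dip is not a completion", {
  tr <- simulate_trace(helicase_params(rate_sd = 0), NULL,
                       noiseless_config(duration_s = 360, seed = 3))
  tr$intensity[20] <- tr$intensity[20] * 0.6
  expect_equal(detect_completion(tr), tr$truth$completion_time_s,
               tolerance = 10 / 300)
})

test_that("an ideal staircase yields no pauses; an inserted flat does", {
  clean <- staircase_traj()
  expect_equal(nrow(detect_pauses(clean, barrier_bp = BARRIER_BP)), 0)

  flat300 <- staircase_traj(pause_s = 300)
  pp <- detect_pauses(flat300, barrier_bp = BARRIER_BP)
  expect_equal(nrow(pp), 1)
  expect_equal(pp$duration_s, 300, tolerance = 10 / 300)
  expect_equal(pp$position_bp, BARRIER_BP, tolerance = 20 / BARRIER_BP)
  expect_true(pp$near_barrier)

  flat20 <- staircase_traj(pause_s = 20)
  expect_equal(nrow(detect_pauses(flat20, barrier_bp = BARRIER_BP)), 0)
})

test_that("pause calls are invariant to intensity rescaling of the trace", {
  tr <- simulate_trace(helicase_params(rate_sd = 0, pause_probability = 1),
                       barrier_mh_lag(), sim_config(seed = 30))
  tr2 <- tr
  tr2$intensity <- tr$intensity * 0.01
  p1 <- detect_pauses(calibrate_trace(tr, L_SUB), barrier_bp = BARRIER_BP)
  p2 <- detect_pauses(calibrate_trace(tr2, L_SUB), barrier_bp = BARRIER_BP)
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("terminal plateaus are not pauses", {
  # arrest-style trajectory: rise then flat to the end
  tt <- seq(0, 1200, 10)
  bp <- pmin(8.2 * tt, BARRIER_BP)
  expect_equal(nrow(detect_pauses(data.frame(time_s = tt, bp = bp))), 0)
  # too-short trajectories error
  expect_error(detect_pauses(data.frame(time_s = c(0, 10), bp = c(0, 5))),
               "shorter")
})

test_that("estimate_rate returns exact slopes and rejects short intervals", {
  traj <- staircase_traj(v = 8.2, total_s = 600)
  expect_equal(estimate_rate(traj, c(0, 500)), 8.2, tolerance = 1e-10)
  expect_error(estimate_rate(traj, c(0, 30)), "too short")
})

test_that("pre-barrier rates on noisy traces track the molecule's truth", {
  trs <- simulate_traces(helicase_params(pause_probability = 1),
                         barrier_mh_lag(), 30, sim_config(), seed = 31)
  checked <- 0
  for (tr in trs) {
    if (is.na(tr$truth$completion_time_s) || nrow(tr$truth$pauses) == 0) next
    if (tr$truth$pauses$start_s[1] < 120) next
    traj <- calibrate_trace(tr, L_SUB)
    r <- estimate_rate(traj[traj$bp > 0.02 * L_SUB, ],
                       c(0, tr$truth$pauses$start_s[1]))
    expect_lt(abs(r - tr$truth$rate_bp_s) / tr$truth$rate_bp_s, 0.15)
    checked <- checked + 1
  }
  expect_gte(checked, 5)
})

test_that("truncation-corrected exponential fit is exact and unbiased", {
  f <- fit_pause_durations(c(2, 3, 4, 5, 6) * 60, min_pause_s = 0)
  expect_equal(f$mean_min, 4)
  expect_equal(f$se_min, 4 / sqrt(5))
  expect_error(fit_pause_durations(c(100, 200, 300)), "at least 5")
  expect_error(fit_pause_durations(c(10, 100, 200, 300, 400),
                                   min_pause_s = 30), "threshold")

  # unbiased across means on truncated-exponential draws
  set.seed(40)
  for (mean_min in c(1, 4.63, 10)) {
    est <- replicate(40, {
      d <- 30 + stats::rexp(500, 1 / (mean_min * 60))
      fit_pause_durations(d)$mean_min
    })
    se <- mean_min / sqrt(500)
    expect_lt(abs(mean(est) - mean_min), 2 * se / sqrt(40) * 3)
  }
})

test_that("fit from 109 draws at the published pause scale is within 2 SE", {
  set.seed(21)
  d <- 30 + stats::rexp(109, 1 / (4.63 * 60))
  f <- fit_pause_durations(d)
  expect_lt(abs(f$mean_min - 4.63), 2 * f$se_min)
})

test_that("population summaries count classifications faithfully", {
  mk <- function(cls, np = 0) structure(
    list(molecule_id = "m", classification = cls,
         pauses = data.frame(start_s = numeric(np), end_s = numeric(np),
                             duration_s = rep(200, np),
                             position_bp = rep(800, np),
                             near_barrier = rep(TRUE, np)),
         rate_bp_s = 8, rate_pre_bp_s = NA, rate_post_bp_s = NA,
         completion_time_s = 100, plateau_bp = NA),
    class = "trace_result")
  res <- list(mk("completed"), mk("completed"), mk("completed"),
              mk("stalled"))
  s <- summarize_population(res)
  expect_equal(s$frac_stalled, 0.25)
  expect_equal(s$frac_completed, 0.75)
  expect_error(summarize_population(list()), "no trace results")
})

test_that("no-barrier batches recover the population mean rate cleanly", {
  trs <- simulate_traces(helicase_params(), NULL, 200, sim_config(),
                         seed = 50)
  an <- analyze_traces(trs, L_SUB)
  expect_lt(abs(an$summary$mean_rate_bp_s - 8.2) / 8.2, 0.05)
  # spurious pause calls are rare, and every one of them sits below the
  # resolvability frontier (implied lost advance under 8x the frame
  # noise); no clearly-resolvable pause is ever invented
  for (noise_frac in c(0.02, 0.01)) {
    seed <- if (noise_frac == 0.02) 50 else 51
    ts <- simulate_traces(helicase_params(), NULL, 200,
                          sim_config(noise_sd = noise_frac * L_SUB),
                          seed = seed)
    a <- analyze_traces(ts, L_SUB)
    n_fp <- 0
    for (i in seq_along(ts)) {
      p <- a$results[[i]]$pauses
      if (nrow(p) == 0) next
      n_fp <- n_fp + nrow(p)
      implied <- ts[[i]]$truth$rate_bp_s * p$duration_s
      expect_true(all(implied < 8 * noise_frac * L_SUB))
    }
    expect_lt(n_fp / length(ts), 0.05)
  }
})

test_that("pause recall and precision exceed 0.9 on barrier batches", {
  trs <- simulate_traces(helicase_params(pause_probability = 1),
                         barrier_mh_lag(), 200, sim_config(), seed = 5)
  an <- analyze_traces(trs, L_SUB, barrier = barrier_mh_lag())
  detectable <- vapply(trs, function(tr) {
    nrow(tr$truth$pauses) == 1 && tr$truth$pauses$duration_s[1] >= 60 &&
      !is.na(tr$truth$completion_time_s)
  }, logical(1))
  detected <- vapply(an$results, function(r) {
    sum(r$pauses$near_barrier %in% TRUE) > 0
  }, logical(1))
  has_truth <- vapply(trs, function(tr) nrow(tr$truth$pauses) > 0, logical(1))
  expect_gte(sum(detected & detectable) / sum(detectable), 0.9)
  expect_gte(sum(detected & has_truth) / sum(detected), 0.9)
})

test_that("stalled molecules are classified via the batch plateau", {
  trs <- simulate_traces(helicase_params(), barrier_mh_lead(), 100,
                         sim_config(), seed = 8)
  an <- analyze_traces(trs, L_SUB, barrier = barrier_mh_lead())
  truth_arrested <- mean(vapply(trs, function(t) t$truth$arrested, logical(1)))
  expect_lt(abs(an$summary$frac_stalled - truth_arrested), 0.08)
  # stall positions read near the barrier
  pb <- vapply(an$results, function(r) r$plateau_bp, numeric(1))
  pb <- pb[vapply(an$results, function(r) r$classification == "stalled",
                  logical(1))]
  expect_lt(abs(stats::median(pb) - BARRIER_BP), 100)
})
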