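# Shared fixtures for the suite. All data are generated in code.

L_SUB <- 2700
BARRIER_BP <- 800

noiseless_config <- function(...) {
  sim_config(noise_sd = 0, ...)
}

# deterministic staircase trajectory: advance at `v` with an optional flat
# segment of `pause_s` seconds once `pause_at` bp is reached
staircase_traj <- function(v = 8.2, dt = 10, total_s = 1200,
                           pause_at = BARRIER_BP, pause_s = 0) {
  tt <- seq(0, total_s, by = dt)
  t_b <- pause_at / v
  bp <- if (pause_s > 0) {
    ifelse(tt < t_b, v * tt,
           ifelse(tt < t_b + pause_s, pause_at,
                  pause_at + v * (tt - t_b - pause_s)))
  } else v * tt
  data.frame(time_s = tt, bp = bp)
}

model_curve <- function(k_obs, m = 2, t_max_s = 3600, dt_s = 5,
                        shift_min = 0) {
  tt <- seq(0, t_max_s, by = dt_s)
  ensemble_curve(tt, fss_model(pmax(tt / 60 - shift_min, 0), k_obs, m))
}
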