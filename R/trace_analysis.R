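#' Detect completion (signal drop) in an intensity trace
#'
#' Completion of unwinding releases the strand not coupled to the surface
#' and its share of bound fluorescent protein, producing a sudden intensity
#' drop. The earliest time at which the (3-frame median filtered) intensity
#' falls by at least `drop_frac` of the running pre-drop maximum, and stays
#' below that level for at least 3 frames, is reported. Traces with no such
#' drop are censored (`NA`), which is a value, not an error.
#'
#' @param trace A `helicase_trace` (see [simulate_trace()]) or any list
#'   with `times` and `intensity`.
#' @param drop_frac Minimum fractional drop relative to the pre-drop
#'   plateau (default 0.3).
#' @return Completion time in seconds, or `NA_real_` if censored.
#' @export
detect_completion <- function(trace, drop_frac = 0.3) {
  y <- smooth_intensity(trace$intensity)
  n <- length(y)
  if (n < 5) return(NA_real_)
  noise <- stats::mad(diff(y)) / sqrt(2)
  # baseline from the opening frames (acquisition starts before appreciable
  # unwinding); a global quantile would sit mid-rise for fast traces
  baseline <- min(y[seq_len(max(5, ceiling(n / 20)))])
  peak <- cummax(y)
  rise <- peak - baseline
  thr <- peak - drop_frac * rise
  # a drop only counts once the signal has genuinely risen above noise and
  # above a quarter of the trace's full excursion
  ok <- rise >= pmax(8 * noise, 0.25 * (max(y) - baseline))
  cand <- ok & y <= thr
  # and must stay below the threshold for >= 3 frames
  for (i in which(cand)) {
    if (all(y[i:min(n, i + 2)] <= thr[i])) return(trace$times[i])
  }
  NA_real_
}

smooth_intensity <- function(y) {
  if (length(y) >= 3) stats::runmed(y, 3) else y
}

# Full-scale intensity of a completed trace. The signal rises until the
# moment of completion, so the level just before the drop is estimated by
# extrapolating a line through the last pre-drop frames to the midpoint
# between the last pre-drop frame and the first dropped frame (the expected
# completion time). Reading the maximum pre-drop sample instead would
# undershoot by about one frame's worth of advance.
predrop_plateau <- function(times, intensity, completion_time_s, k = 12) {
  pre <- which(times < completion_time_s)
  if (length(pre) < 5) return(max(intensity[pre]))
  tail_i <- pre[max(1, length(pre) - k + 1):length(pre)]
  fit <- stats::lm(intensity[tail_i] ~ times[tail_i])
  dt <- stats::median(diff(times))
  t_comp <- times[pre[length(pre)]] + dt / 2
  pred <- unname(stats::coef(fit)[1] + stats::coef(fit)[2] * t_comp)
  max(pred, max(intensity[tail_i]) * 0.8)  # guard against a pathological fit
}

#' Calibrate an intensity trace to base pairs
#'
#' Maps intensity to unwound bp by anchoring the pre-drop plateau intensity
#' to the substrate length: `bp(t) = L * I(t) / I_plateau`, clipped to
#' `[0, L]`, after a 3-frame median filter. For completed traces the
#' plateau is the pre-drop maximum of the filtered intensity; for censored
#' traces a `plateau` value must normally be supplied (e.g. the median
#' plateau of completed traces in the same batch, as [analyze_traces()]
#' does) — otherwise the global maximum is used with a warning, which
#' misreads arrested traces as fully unwound.
#'
#' @param trace A `helicase_trace`.
#' @param substrate_length_bp Substrate length L, bp.
#' @param plateau Optional plateau intensity to calibrate against.
#' @param completion_time_s Optional precomputed [detect_completion()] time.
#' @return Data frame of class `bp_trajectory`: `time_s`, `bp`, with
#'   attributes `substrate_length_bp`, `completion_time_s`, `plateau`.
#' @export
calibrate_trace <- function(trace, substrate_length_bp, plateau = NULL,
                            completion_time_s = NULL) {
  if (length(trace$intensity) < 20) stop("trace too short to calibrate")
  y <- smooth_intensity(trace$intensity)
  if (diff(range(y)) < .Machine$double.eps^0.5 ||
      max(y) <= 4 * stats::sd(diff(y)) / sqrt(2))
    stop("flat trace: no discernible rise")
  if (is.null(completion_time_s))
    completion_time_s <- detect_completion(trace)
  if (is.null(plateau)) {
    if (!is.na(completion_time_s)) {
      plateau <- predrop_plateau(trace$times, trace$intensity,
                                 completion_time_s)
    } else {
      warning("censored trace calibrated against its own maximum; ",
              "supply `plateau` from completed traces if available")
      plateau <- max(y)
    }
  }
  bp <- pmin(pmax(trace$intensity * substrate_length_bp / plateau, 0),
             substrate_length_bp)
  structure(
    data.frame(time_s = trace$times, bp = bp),
    class = c("bp_trajectory", "data.frame"),
    substrate_length_bp = substrate_length_bp,
    completion_time_s = completion_time_s,
    plateau = plateau
  )
}

# Least-squares slope of y on t over a centered sliding window of k frames
# (k odd). Uniform spacing assumed. Edge values take the nearest interior
# estimate.
sliding_slope <- function(y, dt, k) {
  n <- length(y)
  h <- (k - 1) / 2
  if (n < k) return(rep(NA_real_, n))
  j <- -h:h
  w <- j / (sum(j^2) * dt)
  sl <- as.numeric(stats::filter(y, rev(w), sides = 2))
  first <- h + 1; last <- n - h
  sl[seq_len(h)] <- sl[first]
  sl[(last + 1):n] <- sl[last]
  sl
}

#' Call pauses in a calibrated unwinding trajectory
#'
#' Segments the trajectory into pause intervals: stretches where the local
#' unwinding rate falls below `rate_floor_bp_s` for at least `min_pause_s`.
#' The trajectory is median-filtered (3 frames); candidate pause frames are
#' seeded where the local least-squares slope (5-frame window, plus pairs
#' of consecutive sub-floor 3-frame slopes to catch short pauses) drops
#' below the floor. Seed runs are extended outward while the trajectory
#' stays within a noise-scaled band of the pause level, and fragments of
#' one event (runs split by brief noise excursions at the same level) are
#' unioned. A candidate interval is kept as a pause only if
#' \itemize{
#'   \item it lasts at least `min_pause_s`;
#'   \item its interior neither advances appreciably (least-squares slope
#'     below twice the floor) nor hides a drift (within-interval variance
#'     consistent with flat signal plus measurement noise);
#'   \item the pause is resolvable on this molecule: the advance the
#'     molecule would have made during the interval, judged from its
#'     flanking rate, exceeds four times the frame noise, and the flanking
#'     rate itself exceeds twice the floor (on a molecule crawling near the
#'     floor a pause cannot be distinguished from its own progress);
#'   \item it is followed by at least `min_resume_bp` of further unwinding
#'     before the end of the trajectory (terminal plateaus of stalled or
#'     finished traces are never pauses).
#' }
#' `position_bp` is the median filtered position over the interval;
#' `near_barrier` flags pauses within `barrier_window_bp` of `barrier_bp`.
#'
#' Pass the pre-completion portion of a trace (as [analyze_trace()] does):
#' the post-drop segment of a completed trace is not unwinding signal.
#'
#' @param bp_traj A `bp_trajectory` from [calibrate_trace()], or any data
#'   frame with `time_s` and `bp`.
#' @param min_pause_s Minimum pause duration, seconds (default 30).
#' @param rate_floor_bp_s Rate threshold below which the molecule is
#'   considered paused, bp/s (default 1, about 12% of the mean rate).
#' @param barrier_bp Barrier position for `near_barrier`, or `NULL`.
#' @param barrier_window_bp Half-width of the barrier window, bp.
#' @param min_resume_bp Advance required after a pause (default 100 bp).
#' @return Data frame with one row per pause: `start_s`, `end_s`,
#'   `duration_s`, `position_bp`, `near_barrier`.
#' @export
detect_pauses <- function(bp_traj, min_pause_s = 30, rate_floor_bp_s = 1.0,
                          barrier_bp = NULL, barrier_window_bp = 150,
                          min_resume_bp = 100) {
  tt <- bp_traj$time_s
  bp <- bp_traj$bp
  n <- length(bp)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), position_bp = numeric(0),
                      near_barrier = logical(0))
  if (n < 3) stop("trajectory shorter than the minimum pause duration")
  dt <- stats::median(diff(tt))
  if ((n - 1) * dt < min_pause_s)
    stop("trajectory shorter than the minimum pause duration")

  bp_s <- if (n >= 3) stats::runmed(bp, 3) else bp
  # per-frame noise estimated from first differences (robust to the
  # constant advance offset and to pause frames); noise_f is the noise of
  # the median-filtered series
  noise <- stats::mad(diff(bp)) / sqrt(2)
  noise_f <- 0.7 * noise
  band <- max(2 * noise_f, 3 * rate_floor_bp_s * dt)

  sl5 <- sliding_slope(bp_s, dt, 5)
  sl3 <- sliding_slope(bp_s, dt, 3)
  c3 <- !is.na(sl3) & sl3 < rate_floor_bp_s
  pair3 <- c3 & (c(FALSE, c3[-n]) | c(c3[-1], FALSE))
  cand <- (!is.na(sl5) & sl5 < rate_floor_bp_s) | pair3
  cand[is.na(cand)] <- FALSE
  if (!any(cand)) return(empty)

  # bridge single-frame gaps
  r <- rle(cand)
  idx <- which(!r$values & r$lengths == 1)
  idx <- idx[idx > 1 & idx < length(r$values)]
  if (length(idx)) {
    r$values[idx] <- TRUE
    cand <- inverse.rle(r)
    r <- rle(cand)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])

  # refine boundaries: walk outward while the trajectory stays within the
  # noise band around the run's plateau level
  ref <- t(apply(runs, 1, function(rn) {
    s <- rn[1]; e <- rn[2]
    p <- stats::median(bp_s[s:e])
    while (s > 1 && abs(bp_s[s - 1] - p) <= band) s <- s - 1
    while (e < n && abs(bp_s[e + 1] - p) <= band) e <- e + 1
    c(s, e, stats::median(bp_s[s:e]))
  }))

  # union fragments of one pause before validating: overlapping or
  # near-adjacent refined runs at the same level are one event (a long
  # pause often seeds several runs split by brief noise excursions, and a
  # fragment's flanks would lie inside the pause, wrecking the flanking-
  # rate checks below)
  ref <- ref[order(ref[, 1]), , drop = FALSE]
  merged <- list(ref[1, ])
  if (nrow(ref) > 1) for (i in 2:nrow(ref)) {
    last <- merged[[length(merged)]]
    if (ref[i, 1] <= last[2] + 4 && abs(ref[i, 3] - last[3]) <= band) {
      s <- min(last[1], ref[i, 1]); e <- max(last[2], ref[i, 2])
      merged[[length(merged)]] <- c(s, e, stats::median(bp_s[s:e]))
    } else merged[[length(merged) + 1]] <- ref[i, ]
  }

  accepted <- lapply(merged, function(rn) {
    s <- rn[1]; e <- rn[2]
    dur <- tt[e] - tt[s]
    if (dur < min_pause_s) return(NULL)
    # interior frames (boundary frames straddle the advance/pause kink)
    ii <- if (e - s >= 4) (s + 1):(e - 1) else s:e
    # the interval as a whole must move well below twice the rate floor
    # (boundary contamination inflates the slope of genuinely short pauses,
    # so the hard floor itself is not applied here; drift-mimics are caught
    # by the flatness test)
    if (length(ii) >= 3) {
      sl <- stats::coef(stats::lm(bp_s[ii] ~ tt[ii]))[2]
      if (is.finite(sl) && sl >= 2 * rate_floor_bp_s) return(NULL)
    }
    # flatness: a genuine pause sits at one level with only measurement
    # noise around it, while a noise-mimicked "pause" on an advancing
    # molecule hides a linear drift that inflates the within-interval
    # variance
    flat_ms <- sum((bp_s[ii] - mean(bp_s[ii]))^2) / length(ii)
    if (flat_ms > 4 * noise_f^2 + 1e-12) return(NULL)
    # significance and crawler gate from the flanking rate: the advance the
    # molecule would have made during the interval must exceed 4x the frame
    # noise, and the molecule itself must clearly move faster than the rate
    # floor — otherwise a pause cannot be resolved at all
    fl_slope <- function(i1, i2) {
      if (i2 - i1 < 3) return(NA_real_)
      unname(stats::coef(stats::lm(bp_s[i1:i2] ~ tt[i1:i2]))[2])
    }
    v_fl <- suppressWarnings(
      min(c(fl_slope(max(1, s - 9), s - 1), fl_slope(e + 1, min(n, e + 9))),
          na.rm = TRUE))
    if (!is.finite(v_fl)) return(NULL)
    if (v_fl < 2 * rate_floor_bp_s) return(NULL)
    if (v_fl * dur < 4 * noise) return(NULL)
    p <- stats::median(bp_s[s:e])
    if (e >= n) return(NULL)                            # terminal plateau
    resumed <- stats::quantile(bp_s[(e + 1):n], 0.9, names = FALSE) - p
    if (resumed < min_resume_bp) return(NULL)
    data.frame(start_s = tt[s], end_s = tt[e], duration_s = dur,
               position_bp = p)
  })
  out <- do.call(rbind, accepted[!vapply(accepted, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) return(empty)
  out$near_barrier <- if (is.null(barrier_bp)) NA else
    abs(out$position_bp - barrier_bp) <= barrier_window_bp
  rownames(out) <- NULL
  out
}

#' Average unwinding rate over an interval
#'
#' Slope of the least-squares line of bp versus time over `interval`.
#'
#' @param bp_traj A `bp_trajectory` (or data frame with `time_s`, `bp`).
#' @param interval Numeric `c(t1, t2)` in seconds; must contain at least 5
#'   frames.
#' @return Rate in bp/s.
#' @export
estimate_rate <- function(bp_traj, interval) {
  stopifnot(length(interval) == 2, interval[2] > interval[1])
  sel <- bp_traj$time_s >= interval[1] & bp_traj$time_s <= interval[2]
  if (sum(sel) < 5) stop("interval too short: fewer than 5 frames")
  unname(stats::coef(stats::lm(bp ~ time_s,
                               data = bp_traj[sel, , drop = FALSE]))[2])
}

# Rate over the advancing portion of a trajectory with pause intervals
# excised. Pause gaps are closed by subtracting the elapsed pause time, so
# one straight line describes the composite advance.
excised_rate <- function(bp_traj, pauses, lo_bp, hi_bp) {
  tt <- bp_traj$time_s
  bp <- bp_traj$bp
  keep <- bp >= lo_bp & bp <= hi_bp
  shift <- numeric(length(tt))
  if (!is.null(pauses) && nrow(pauses) > 0) {
    for (i in seq_len(nrow(pauses))) {
      inpause <- tt > pauses$start_s[i] & tt < pauses$end_s[i]
      keep <- keep & !inpause
      shift <- shift + pmin(pmax(tt - pauses$start_s[i], 0),
                            pauses$duration_s[i])
    }
  }
  if (sum(keep) < 5) return(NA_real_)
  t_adj <- (tt - shift)[keep]
  unname(stats::coef(stats::lm(bp[keep] ~ t_adj))[2])
}

#' Exponential fit of pause durations with left truncation
#'
#' Maximum-likelihood fit of a single-exponential pause-duration
#' distribution, correcting for the fact that pauses shorter than the
#' detection threshold `min_pause_s` are never observed. For a left-
#' truncated exponential the MLE of the mean is the sample mean minus the
#' truncation point; the standard error is `mean / sqrt(n)`. With
#' `min_pause_s = 0` this reduces to the plain exponential MLE.
#'
#' @param durations_s Observed pause durations, seconds; all must be at
#'   least `min_pause_s`, and at least 5 are required.
#' @param min_pause_s Detection threshold, seconds (default 30).
#' @return Object of class `pause_fit`: `mean_min`, `se_min`, `n`,
#'   `min_pause_s`.
#' @export
fit_pause_durations <- function(durations_s, min_pause_s = 30) {
  if (length(durations_s) < 5) stop("need at least 5 pause durations")
  if (any(durations_s < min_pause_s - 1e-9))
    stop("durations below the detection threshold are not observable")
  mean_s <- mean(durations_s) - min_pause_s
  structure(
    list(mean_min = mean_s / 60,
         se_min = mean_s / 60 / sqrt(length(durations_s)),
         n = length(durations_s),
         min_pause_s = min_pause_s),
    class = "pause_fit"
  )
}

#' Pause-duration histogram table
#'
#' Bins pause durations (minutes) for plotting against the fitted
#' exponential.
#'
#' @param durations_s Pause durations, seconds.
#' @param binwidth_min Bin width, minutes.
#' @return Data frame with `mid_min` and `count`.
#' @export
pause_histogram <- function(durations_s, binwidth_min = 1) {
  d <- durations_s / 60
  breaks <- seq(0, ceiling(max(d) / binwidth_min) * binwidth_min,
                by = binwidth_min)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  data.frame(mid_min = h$mids, count = h$counts)
}

#' Analyze one unwinding trace
#'
#' Full per-molecule pipeline: completion detection, calibration, pause
#' calling on the pre-completion trajectory, rate estimation with pauses
#' excised, and classification into `completed`, `paused_then_completed`,
#' `stalled` (censored completion with a terminal plateau inside the
#' barrier window), or `ambiguous` (still rising at the end of the
#' acquisition, or plateaued away from the barrier, or too slow to
#' classify).
#'
#' @param trace A `helicase_trace`.
#' @param substrate_length_bp Substrate length, bp.
#' @param barrier A [barrier_spec()] or `NULL`.
#' @param min_pause_s,rate_floor_bp_s,barrier_window_bp,min_resume_bp
#'   Passed to [detect_pauses()].
#' @param plateau Optional calibration plateau (see [calibrate_trace()]).
#' @param include_pauses If `TRUE`, rates are fitted without excising
#'   pause intervals.
#' @param terminal_s Length of the terminal window used to decide whether
#'   a censored trace has plateaued, seconds.
#' @return Object of class `trace_result`: list with `molecule_id`,
#'   `classification`, `pauses` (data frame), `rate_bp_s`, `rate_pre_bp_s`,
#'   `rate_post_bp_s`, `completion_time_s`, `plateau_bp`.
#' @export
analyze_trace <- function(trace, substrate_length_bp, barrier = NULL,
                          min_pause_s = 30, rate_floor_bp_s = 1.0,
                          barrier_window_bp = 150, min_resume_bp = 100,
                          plateau = NULL, include_pauses = FALSE,
                          terminal_s = 120) {
  L <- substrate_length_bp
  barrier_bp <- if (is.null(barrier)) NULL else barrier$position_bp
  comp <- detect_completion(trace)
  traj <- calibrate_trace(trace, L, plateau = plateau,
                          completion_time_s = comp)
  pre <- if (!is.na(comp)) traj[traj$time_s < comp, , drop = FALSE] else traj

  pauses <- tryCatch(
    detect_pauses(pre, min_pause_s = min_pause_s,
                  rate_floor_bp_s = rate_floor_bp_s,
                  barrier_bp = barrier_bp,
                  barrier_window_bp = barrier_window_bp,
                  min_resume_bp = min_resume_bp),
    error = function(e) data.frame(start_s = numeric(0), end_s = numeric(0),
                                   duration_s = numeric(0),
                                   position_bp = numeric(0),
                                   near_barrier = logical(0))
  )

  px <- if (include_pauses) pauses[0, , drop = FALSE] else pauses
  rate <- excised_rate(pre, px, 0.05 * L, 0.95 * L)

  rate_pre <- rate_post <- NA_real_
  if (nrow(pauses) > 0) {
    t1 <- min(pauses$start_s); t2 <- max(pauses$end_s)
    rate_pre <- tryCatch(estimate_rate(pre[pre$bp >= 0.02 * L, , drop = FALSE],
                                       c(min(pre$time_s), t1)),
                         error = function(e) NA_real_)
    rate_post <- tryCatch(estimate_rate(pre, c(t2, max(pre$time_s))),
                          error = function(e) NA_real_)
  }

  dt <- stats::median(diff(traj$time_s))
  k_term <- max(5, ceiling(terminal_s / dt))
  plateau_bp <- NA_real_
  if (!is.na(comp)) {
    classification <- if (nrow(pauses) > 0) "paused_then_completed" else "completed"
  } else {
    nt <- nrow(traj)
    term <- traj[max(1, nt - k_term + 1):nt, , drop = FALSE]
    term_rate <- tryCatch(estimate_rate(term, range(term$time_s)),
                          error = function(e) NA_real_)
    if (!is.na(term_rate) && term_rate < rate_floor_bp_s) {
      plateau_bp <- stats::median(term$bp)
      near <- is.null(barrier_bp) ||
        abs(plateau_bp - barrier_bp) <= barrier_window_bp
      classification <- if (near) "stalled" else "ambiguous"
    } else {
      classification <- "ambiguous"
    }
  }

  structure(
    list(molecule_id = trace$molecule_id,
         classification = classification,
         pauses = pauses,
         rate_bp_s = rate,
         rate_pre_bp_s = rate_pre,
         rate_post_bp_s = rate_post,
         completion_time_s = comp,
         plateau_bp = plateau_bp),
    class = "trace_result"
  )
}

#' Analyze a batch of traces
#'
#' Runs [analyze_trace()] on every trace. Censored traces are calibrated
#' against the median pre-drop plateau intensity of the completed traces in
#' the batch, so an arrested molecule's stall position is read on the same
#' intensity scale as full unwinding.
#'
#' @param traces List of `helicase_trace` objects.
#' @param substrate_length_bp Substrate length, bp.
#' @param barrier A [barrier_spec()] or `NULL`.
#' @param ... Passed to [analyze_trace()].
#' @return List with `results` (list of `trace_result`), `summary` (a
#'   [summarize_population()] result) and `pauses` (pooled pause table with
#'   a `molecule_id` column).
#' @export
analyze_traces <- function(traces, substrate_length_bp, barrier = NULL, ...) {
  stopifnot(length(traces) >= 1)
  comp_times <- vapply(traces, detect_completion, numeric(1))
  plateaus <- vapply(seq_along(traces), function(i) {
    if (is.na(comp_times[i])) return(NA_real_)
    y <- smooth_intensity(traces[[i]]$intensity)
    max(y[traces[[i]]$times < comp_times[i]])
  }, numeric(1))
  batch_plateau <- stats::median(plateaus, na.rm = TRUE)

  results <- lapply(seq_along(traces), function(i) {
    pl <- if (is.na(comp_times[i]) && !is.na(batch_plateau)) batch_plateau else NULL
    tryCatch(
      analyze_trace(traces[[i]], substrate_length_bp, barrier = barrier,
                    plateau = pl, ...),
      error = function(e) structure(
        list(molecule_id = traces[[i]]$molecule_id,
             classification = "ambiguous",
             pauses = data.frame(start_s = numeric(0), end_s = numeric(0),
                                 duration_s = numeric(0),
                                 position_bp = numeric(0),
                                 near_barrier = logical(0)),
             rate_bp_s = NA_real_, rate_pre_bp_s = NA_real_,
             rate_post_bp_s = NA_real_, completion_time_s = NA_real_,
             plateau_bp = NA_real_),
        class = "trace_result")
    )
  })
  pauses <- do.call(rbind, lapply(results, function(r) {
    if (nrow(r$pauses) == 0) return(NULL)
    cbind(molecule_id = r$molecule_id, r$pauses)
  }))
  if (is.null(pauses))
    pauses <- data.frame(molecule_id = character(0), start_s = numeric(0),
                         end_s = numeric(0), duration_s = numeric(0),
                         position_bp = numeric(0), near_barrier = logical(0))
  list(results = results,
       summary = summarize_population(results, barrier = barrier),
       pauses = pauses)
}

#' Population summary of analyzed traces
#'
#' Aggregates per-molecule results: classification fractions, the fraction
#' of molecules with at least one (near-barrier, when a barrier is given)
#' pause, the mean +/- SD rate of fully unwound molecules, and a pooled
#' truncation-corrected exponential fit of pause durations (when at least
#' 5 pauses were observed). Ambiguous traces are counted and reported, not
#' dropped.
#'
#' @param results List of `trace_result` objects (or the `results` element
#'   of [analyze_traces()]).
#' @param barrier A [barrier_spec()] or `NULL`; when given, only
#'   near-barrier pauses enter `frac_paused` and the duration fit.
#' @param min_pause_s Truncation threshold passed to
#'   [fit_pause_durations()].
#' @return Object of class `population_summary`.
#' @export
summarize_population <- function(results, barrier = NULL, min_pause_s = 30) {
  if (length(results) == 0) stop("no trace results to summarize")
  cls <- vapply(results, function(r) r$classification, character(1))
  n <- length(results)
  sel_pauses <- function(r) {
    p <- r$pauses
    if (!is.null(barrier) && nrow(p) > 0) p <- p[p$near_barrier %in% TRUE, , drop = FALSE]
    p
  }
  paused <- vapply(results, function(r) nrow(sel_pauses(r)) > 0, logical(1))
  durations <- unlist(lapply(results, function(r) sel_pauses(r)$duration_s))
  full <- cls %in% c("completed", "paused_then_completed")
  rates <- vapply(results, function(r) r$rate_bp_s, numeric(1))[full]
  rates <- rates[is.finite(rates)]
  pf <- if (length(durations) >= 5)
    fit_pause_durations(durations, min_pause_s = min_pause_s) else NULL
  structure(
    list(
      n_total = n,
      frac_completed = mean(full),
      frac_stalled = mean(cls == "stalled"),
      frac_ambiguous = mean(cls == "ambiguous"),
      frac_paused = mean(paused),
      mean_rate_bp_s = if (length(rates)) mean(rates) else NA_real_,
      sd_rate_bp_s = if (length(rates) > 1) stats::sd(rates) else NA_real_,
      n_rates = length(rates),
      pause_fit = pf
    ),
    class = "population_summary"
  )
}
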