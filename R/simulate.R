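#' Simulate a single-molecule unwinding trace
#'
#' Generates one fluorescence intensity trajectory for a surface-tethered
#' DNA molecule unwound by a helicase, as observed through accumulation of
#' fluorescent ssDNA-binding protein. The molecule's unwinding rate is drawn
#' from a truncated Normal population (truncated to
#' `[0.5, 2 * rate_mean - 0.5]` bp/s, which floors the rate without shifting
#' the population mean); unwound bp then advances deterministically between
#' frames. A barrier, when present on the molecule (Bernoulli draw with the
#' barrier's occupancy), acts when unwinding reaches its position:
#' \describe{
#'   \item{pause}{with probability `pause_probability`, progress halts for
#'     an Exponential(`pause_mean_s`) duration, then resumes at the same
#'     rate;}
#'   \item{arrest}{progress halts permanently;}
#'   \item{transparent}{no effect — the trace is identical to a no-barrier
#'     trace under the same RNG state.}
#' }
#' Intensity is proportional to unwound bp (1 intensity unit per bp) with
#' additive Gaussian noise; on completion the signal drops to
#' `drop_factor` of full scale (release of the untethered strand removes
#' its share of bound protein).
#'
#' A `truth` list records the latent trajectory for validation: per-frame
#' unwound bp, the drawn rate, pause start/end, completion time, and
#' whether the barrier was present on this molecule.
#'
#' @param params A [helicase_params()].
#' @param barrier A [barrier_spec()] or `NULL` for an unmodified substrate.
#' @param config A [sim_config()].
#' @param molecule_id Identifier stored with the trace.
#' @return An object of class `helicase_trace`: list with `molecule_id`,
#'   `times` (s), `intensity`, `frame_interval_s`, and `truth`.
#' @examples
#' p <- helicase_params(rate_sd = 0)
#' tr <- simulate_trace(p, NULL, sim_config(noise_sd = 0, seed = 1))
#' tr$truth$completion_time_s  # 2700 / 8.2
#' @export
simulate_trace <- function(params, barrier = NULL, config = sim_config(),
                           molecule_id = "mol_1") {
  stopifnot(inherits(params, "helicase_params"), inherits(config, "sim_config"))
  if (!is.null(barrier)) {
    stopifnot(inherits(barrier, "barrier_spec"))
    if (barrier$position_bp >= config$substrate_length_bp)
      stop("barrier position must lie inside the substrate")
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  L <- config$substrate_length_bp
  dt <- config$frame_interval_s
  times <- seq(0, config$duration_s, by = dt)

  # Fixed RNG draw order regardless of barrier presence, so that a
  # transparent (or absent-by-occupancy) barrier leaves the trace identical
  # to the no-barrier trace under the same seed.
  v <- draw_rate(params$rate_mean, params$rate_sd)
  u_occ <- stats::runif(1)
  u_pause <- stats::runif(1)
  d_pause <- stats::rexp(1) * params$pause_mean_s

  bearing <- !is.null(barrier) && u_occ < barrier$occupancy
  mech <- if (bearing) barrier$mechanism else "none"
  pos <- if (bearing) barrier$position_bp else NA_real_

  pauses <- data.frame(start_s = numeric(0), end_s = numeric(0),
                       duration_s = numeric(0), position_bp = numeric(0))
  arrested <- FALSE
  if (mech == "arrest") {
    arrested <- TRUE
    unwound <- pmin(v * times, pos)
    completion <- NA_real_
  } else if (mech == "pause" && u_pause < params$pause_probability &&
             d_pause > 0) {
    t_b <- pos / v
    unwound <- ifelse(times < t_b, v * times,
                      ifelse(times < t_b + d_pause, pos,
                             pmin(pos + v * (times - t_b - d_pause), L)))
    completion <- L / v + d_pause
    pauses <- data.frame(start_s = t_b, end_s = t_b + d_pause,
                         duration_s = d_pause, position_bp = pos)
  } else {
    unwound <- pmin(v * times, L)
    completion <- L / v
  }
  if (!is.na(completion) && completion > config$duration_s)
    completion <- NA_real_  # censored: not observed within the acquisition

  base <- unwound
  if (!is.na(completion)) base[times > completion] <- config$drop_factor * L
  intensity <- base + stats::rnorm(length(times), 0, config$noise_sd)

  structure(
    list(
      molecule_id = molecule_id,
      times = times,
      intensity = intensity,
      frame_interval_s = dt,
      truth = list(
        unwound_bp = unwound,
        rate_bp_s = v,
        pauses = pauses,
        completion_time_s = completion,
        barrier_present = bearing,
        arrested = arrested
      )
    ),
    class = "helicase_trace"
  )
}

# Population rate draw: Normal(mean, sd) truncated to the interval
# [0.5, 2*mean - 0.5] bp/s. Symmetric truncation floors the rate (no
# stalled-by-birth molecules) while keeping the population mean at
# rate_mean, which one-sided truncation would inflate.
draw_rate <- function(rate_mean, rate_sd, floor_bp_s = 0.5) {
  if (rate_sd == 0) return(rate_mean)
  lo <- floor_bp_s
  hi <- 2 * rate_mean - floor_bp_s
  if (hi <= lo) stop("rate_mean too small for the 0.5 bp/s floor")
  repeat {
    v <- stats::rnorm(1, rate_mean, rate_sd)
    if (v >= lo && v <= hi) return(v)
  }
}

#' Simulate a batch of unwinding traces
#'
#' Calls [simulate_trace()] `n` times under a single seed; molecule ids are
#' `"mol_1" ... "mol_n"`.
#'
#' @inheritParams simulate_trace
#' @param n Number of molecules.
#' @param seed Integer seed for the whole batch (the per-trace seed in
#'   `config` must be unset).
#' @return List of `helicase_trace` objects.
#' @export
simulate_traces <- function(params, barrier = NULL, n,
                            config = sim_config(), seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(config$seed))
    stop("set the batch `seed` argument, not config$seed, for batches")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    simulate_trace(params, barrier, config, molecule_id = paste0("mol_", i))
  })
}

#' Simulate an ensemble unwinding curve
#'
#' Draws per-molecule completion times from the m-step sequential model
#' (sum of `m_steps` independent Exponential(1/k_obs) waiting times, i.e.
#' Erlang), adds barrier effects (an exponential pause for barrier-bearing,
#' pausing molecules; no completion for arrested molecules; nothing for
#' transparent ones), and returns the fraction of completed molecules at
#' each frame. With no barrier and large `n` the expected curve is the
#' closed-form m-step unwinding function [fss_model()].
#'
#' @inheritParams simulate_trace
#' @param n Number of molecules, >= 1.
#' @param noise_sd Additive Gaussian noise on the fraction scale (per
#'   frame); default 0.
#' @param seed Optional integer seed.
#' @return An [ensemble_curve()] (normalized: signal is a fraction).
#' @export
simulate_ensemble <- function(params, barrier = NULL, n,
                              config = sim_config(), noise_sd = 0,
                              seed = NULL) {
  stopifnot(inherits(params, "helicase_params"), n >= 1, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  m <- params$m_steps
  rate_s <- params$k_obs / 60  # k_obs is 1/min; internal clock is seconds
  comp <- rowSums(matrix(stats::rexp(n * m, rate_s), nrow = n))

  u_occ <- stats::runif(n)
  u_pause <- stats::runif(n)
  d_pause <- stats::rexp(n) * params$pause_mean_s
  if (!is.null(barrier)) {
    stopifnot(inherits(barrier, "barrier_spec"))
    bearing <- u_occ < barrier$occupancy
    if (barrier$mechanism == "pause") {
      pausing <- bearing & (u_pause < params$pause_probability)
      comp[pausing] <- comp[pausing] + d_pause[pausing]
    } else if (barrier$mechanism == "arrest") {
      comp[bearing] <- Inf
    }
  }

  times <- seq(0, config$duration_s, by = config$frame_interval_s)
  frac <- findInterval(times, sort(comp)) / n
  if (noise_sd > 0) frac <- frac + stats::rnorm(length(times), 0, noise_sd)
  ensemble_curve(times, frac, normalized = TRUE, n_molecules = n)
}

#' Ensemble unwinding curve container
#'
#' A two-column data frame (`time_s`, `signal`) with class
#' `ensemble_curve`; `normalized` marks dimensionless curves in `[0, 1]`.
#'
#' @param time_s Times, seconds, strictly increasing.
#' @param signal Signal values.
#' @param normalized Logical.
#' @param n_molecules Number of molecules behind the curve, if known.
#' @return A data frame of class `ensemble_curve`.
#' @export
ensemble_curve <- function(time_s, signal, normalized = FALSE,
                           n_molecules = NA_integer_) {
  stopifnot(length(time_s) == length(signal), !is.unsorted(time_s))
  structure(
    data.frame(time_s = time_s, signal = signal),
    class = c("ensemble_curve", "data.frame"),
    normalized = normalized,
    n_molecules = n_molecules
  )
}
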