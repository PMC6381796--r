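#' Helicase kinetic parameters
#'
#' Bundles the per-molecule and ensemble kinetic parameters used by the
#' simulator. Defaults describe CMG unwinding a linear substrate: a
#' population rate of 8.2 +/- 4.2 bp/s, exponentially distributed pauses
#' with mean 4.63 min at a duplex-stabilizing lagging-strand block, and an
#' m = 2 sequential-step ensemble model.
#'
#' The default `pause_probability` is calibrated so that the fraction of
#' barrier-bearing molecules showing a *discernible* pause (longer than the
#' 30 s detection threshold) is 26%: with exponential durations a fraction
#' `exp(-30 / pause_mean_s)` of pauses exceed the threshold, so the
#' underlying probability must be `0.26 / exp(-30 / pause_mean_s)`. See
#' [underlying_pause_probability()].
#'
#' @param rate_mean Mean unwinding rate, bp/s.
#' @param rate_sd Between-molecule SD of the rate, bp/s.
#' @param pause_mean_s Mean pause duration at a pause-type barrier, seconds.
#' @param pause_probability Probability that a barrier-bearing molecule
#'   pauses at all (including pauses too short to detect), in `[0, 1]`.
#' @param m_steps Number of sequential rate-limiting steps in the ensemble
#'   completion-time model (Erlang shape), integer >= 1.
#' @param k_obs Observed ensemble rate constant, 1/min.
#' @return An object of class `helicase_params`.
#' @seealso [simulate_trace()], [simulate_ensemble()]
#' @export
helicase_params <- function(rate_mean = 8.2,
                            rate_sd = 4.2,
                            pause_mean_s = 4.63 * 60,
                            pause_probability = underlying_pause_probability(),
                            m_steps = 2L,
                            k_obs = 0.2) {
  stopifnot(
    is.numeric(rate_mean), length(rate_mean) == 1, rate_mean > 0,
    is.numeric(rate_sd), length(rate_sd) == 1, rate_sd >= 0,
    is.numeric(pause_mean_s), length(pause_mean_s) == 1, pause_mean_s >= 0,
    is.numeric(pause_probability), length(pause_probability) == 1,
    pause_probability >= 0, pause_probability <= 1,
    length(m_steps) == 1, m_steps >= 1, m_steps == as.integer(m_steps),
    is.numeric(k_obs), length(k_obs) == 1, k_obs > 0
  )
  structure(
    list(
      rate_mean = rate_mean, rate_sd = rate_sd,
      pause_mean_s = pause_mean_s, pause_probability = pause_probability,
      m_steps = as.integer(m_steps), k_obs = k_obs
    ),
    class = "helicase_params"
  )
}

#' Underlying pause probability from an observed pausing fraction
#'
#' Converts the fraction of molecules with a *detectable* pause (duration
#' above `min_pause_s`) into the underlying per-encounter pause probability,
#' assuming exponentially distributed pause durations: a fraction
#' `exp(-min_pause_s / pause_mean_s)` of pauses are long enough to see.
#'
#' @param observed_frac Fraction of molecules with a detectable pause.
#' @param min_pause_s Detection threshold, seconds.
#' @param pause_mean_s Mean of the exponential pause-duration distribution,
#'   seconds.
#' @return Underlying pause probability in `[0, 1]`.
#' @export
underlying_pause_probability <- function(observed_frac = 0.26,
                                         min_pause_s = 30,
                                         pause_mean_s = 4.63 * 60) {
  stopifnot(observed_frac >= 0, observed_frac <= 1,
            min_pause_s >= 0, pause_mean_s > 0)
  p <- observed_frac / exp(-min_pause_s / pause_mean_s)
  if (p > 1) stop("observed fraction implies pause probability > 1")
  p
}

#' Strand-specific protein barrier specification
#'
#' Describes a site-specific DNA-protein block on the substrate: its
#' position (bp from the 3' ssDNA loading tail), the strand it is attached
#' to, its mechanistic class, and the fraction of substrate molecules that
#' actually carry it (conjugation is never complete).
#'
#' Mechanisms follow the strand logic of steric-exclusion unwinding: a
#' leading-strand block arrests the helicase permanently (`"arrest"`); a
#' lagging-strand block is either bypassed without effect (`"transparent"`,
#' e.g. a clicked streptavidin) or induces a transient pause by stabilizing
#' the duplex (`"pause"`, e.g. a trapped methyltransferase). Other
#' strand/mechanism combinations are rejected.
#'
#' @param position_bp Barrier position, bp from the loading tail; must lie
#'   strictly inside the substrate when simulated.
#' @param strand `"leading"` or `"lagging"`.
#' @param mechanism `"arrest"`, `"transparent"`, or `"pause"`.
#' @param occupancy Fraction of molecules bearing the block, in `[0, 1]`.
#' @return An object of class `barrier_spec`.
#' @export
barrier_spec <- function(position_bp,
                         strand = c("lagging", "leading"),
                         mechanism = c("pause", "transparent", "arrest"),
                         occupancy = 1) {
  strand <- match.arg(strand)
  mechanism <- match.arg(mechanism)
  stopifnot(
    is.numeric(position_bp), length(position_bp) == 1, position_bp > 0,
    is.numeric(occupancy), length(occupancy) == 1,
    occupancy >= 0, occupancy <= 1
  )
  if (mechanism == "arrest" && strand != "leading")
    stop("mechanism 'arrest' requires strand = 'leading'")
  if (mechanism %in% c("pause", "transparent") && strand != "lagging")
    stop("mechanisms 'pause' and 'transparent' require strand = 'lagging'")
  structure(
    list(position_bp = position_bp, strand = strand,
         mechanism = mechanism, occupancy = occupancy),
    class = "barrier_spec"
  )
}

#' Preset barriers
#'
#' Convenience constructors for the three barrier configurations studied on
#' the 2.7-kb single-molecule substrate: a duplex-stabilizing
#' methyltransferase on the lagging strand (`barrier_mh_lag`), the same
#' enzyme on the leading strand where it arrests the helicase
#' (`barrier_mh_lead`, default occupancy 0.8), and a clicked streptavidin on
#' the lagging strand that the helicase ignores (`barrier_clk_sa_lag`).
#'
#' @param position_bp Barrier position in bp (default 800).
#' @param occupancy Fraction of molecules bearing the block.
#' @return A [barrier_spec()].
#' @export
barrier_mh_lag <- function(position_bp = 800, occupancy = 1) {
  barrier_spec(position_bp, "lagging", "pause", occupancy)
}

#' @rdname barrier_mh_lag
#' @export
barrier_mh_lead <- function(position_bp = 800, occupancy = 0.8) {
  barrier_spec(position_bp, "leading", "arrest", occupancy)
}

#' @rdname barrier_mh_lag
#' @export
barrier_clk_sa_lag <- function(position_bp = 800, occupancy = 1) {
  barrier_spec(position_bp, "lagging", "transparent", occupancy)
}

#' Simulation configuration
#'
#' Observation-level settings for trace simulation. Defaults mirror the
#' single-molecule assay: 2.7-kb substrate, 10-s frame interval, 40-min
#' acquisition, additive Gaussian intensity noise of 2% of full scale, and
#' a halving of the fluorescence signal when the released strand leaves the
#' surface on completion.
#'
#' @param substrate_length_bp Substrate length, bp.
#' @param frame_interval_s Time between frames, seconds.
#' @param duration_s Total observation time, seconds.
#' @param noise_sd Additive per-frame Gaussian intensity noise, in intensity
#'   units (the noiseless full-scale signal is `substrate_length_bp` units).
#'   Default 2% of full scale.
#' @param drop_factor Fraction of intensity retained after completion, in
#'   `(0, 1)`.
#' @param seed Optional integer seed; when set, [simulate_trace()] seeds the
#'   RNG so identical configs give bit-identical traces.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(substrate_length_bp = 2700,
                       frame_interval_s = 10,
                       duration_s = 2400,
                       noise_sd = 0.02 * substrate_length_bp,
                       drop_factor = 0.5,
                       seed = NULL) {
  stopifnot(
    substrate_length_bp > 0,
    frame_interval_s > 0,
    duration_s >= frame_interval_s,
    noise_sd >= 0,
    drop_factor > 0, drop_factor < 1
  )
  structure(
    list(substrate_length_bp = substrate_length_bp,
         frame_interval_s = frame_interval_s,
         duration_s = duration_s,
         noise_sd = noise_sd,
         drop_factor = drop_factor,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config"
  )
}
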