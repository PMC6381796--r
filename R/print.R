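#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("m-step kinetic fit (m = %d)\n", x$m))
  cat(sprintf("  k_obs      : %.4g +/- %.2g /min\n", x$k_obs, x$k_obs_se))
  cat(sprintf("  amplitude  : %.4g   baseline: %.4g\n", x$amplitude, x$baseline))
  if (x$onset_min > 0) cat(sprintf("  onset      : %.3g min\n", x$onset_min))
  cat(sprintf("  residual   : %.3g (rms, normalized scale)\n", x$residual_rms))
  invisible(x)
}

#' @export
print.delay_estimate <- function(x, ...) {
  cat(sprintf("t50-shift delay: %.3f min (95%% CI %.3f to %.3f, %d bootstrap reps)\n",
              x$delay_min, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' @export
print.pause_fit <- function(x, ...) {
  cat(sprintf(
    "exponential pause fit: mean %.3f +/- %.3f min (n = %d, truncated at %g s)\n",
    x$mean_min, x$se_min, x$n, x$min_pause_s))
  invisible(x)
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("population of %d molecules\n", x$n_total))
  cat(sprintf("  completed : %.1f%%   stalled: %.1f%%   ambiguous: %.1f%%\n",
              100 * x$frac_completed, 100 * x$frac_stalled,
              100 * x$frac_ambiguous))
  cat(sprintf("  paused    : %.1f%%\n", 100 * x$frac_paused))
  if (!is.na(x$mean_rate_bp_s))
    cat(sprintf("  rate      : %.2f +/- %.2f bp/s (n = %d fully unwound)\n",
                x$mean_rate_bp_s, x$sd_rate_bp_s, x$n_rates))
  if (!is.null(x$pause_fit))
    cat(sprintf("  pauses    : mean %.2f +/- %.2f min (n = %d)\n",
                x$pause_fit$mean_min, x$pause_fit$se_min, x$pause_fit$n))
  invisible(x)
}

#' @export
print.helicase_trace <- function(x, ...) {
  cat(sprintf("helicase trace %s: %d frames, %g s interval\n",
              x$molecule_id, length(x$times), x$frame_interval_s))
  invisible(x)
}
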