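#' Background-corrected band fraction within a lane
#'
#' Percent of total signal carried by the numerator bands:
#' `100 * sum(numerator - bg) / sum(denominator - bg)`. Band intensities
#' come from a lane table with columns `band_label`, `intensity` and
#' optionally `background` (per-band local background); alternatively a
#' scalar `background` applies to every band. Negative background-corrected
#' intensities are clipped to zero with a warning. The result is invariant
#' to rescaling all intensities and backgrounds by a common factor.
#'
#' @param lane Data frame with `band_label`, `intensity`, and optionally
#'   `background` columns, describing one gel lane.
#' @param numerator Character vector of band labels in the numerator.
#' @param denominator Character vector of band labels in the denominator.
#' @param background Scalar background used when the lane table has no
#'   `background` column (default 0).
#' @return Percent (numeric scalar).
#' @examples
#' lane <- data.frame(band_label = c("unwound", "fork"),
#'                    intensity = c(520, 480))
#' band_fraction(lane, "unwound", c("unwound", "fork"))  # 52
#' @export
band_fraction <- function(lane, numerator, denominator, background = 0) {
  stopifnot(all(c("band_label", "intensity") %in% names(lane)))
  labs <- unique(c(numerator, denominator))
  missing <- setdiff(labs, lane$band_label)
  if (length(missing))
    stop("missing band(s): ", paste(missing, collapse = ", "))
  bg <- if ("background" %in% names(lane)) lane$background else
    rep(background, nrow(lane))
  corr <- lane$intensity - bg
  if (any(corr[lane$band_label %in% labs] < 0)) {
    warning("negative background-corrected intensities clipped to 0")
    corr <- pmax(corr, 0)
  }
  val <- function(set) sum(corr[match(set, lane$band_label)])
  den <- val(denominator)
  if (den <= 0) stop("denominator is zero after background subtraction")
  100 * val(numerator) / den
}

#' Percent-unwound series across gel lanes
#'
#' Applies [band_fraction()] to every lane of a multi-lane table and
#' returns a tidy table of percentages, ready for mean +/- SD aggregation
#' across replicates. All lanes must share the same band scheme.
#'
#' @param lanes Data frame with `lane_id`, `band_label`, `intensity`,
#'   optionally `background`, and optionally annotation columns such as
#'   `condition` or `replicate` (constant within a lane), which are carried
#'   through.
#' @inheritParams band_fraction
#' @return Data frame with one row per lane: `lane_id`, any annotation
#'   columns, and `percent`.
#' @export
percent_unwound_series <- function(lanes, numerator, denominator,
                                   background = 0) {
  stopifnot(all(c("lane_id", "band_label", "intensity") %in% names(lanes)))
  ids <- unique(lanes$lane_id)
  schemes <- lapply(ids, function(id)
    sort(unique(lanes$band_label[lanes$lane_id == id])))
  if (length(unique(vapply(schemes, paste, character(1), collapse = "|"))) > 1)
    stop("inconsistent band schemes across lanes")
  ann_cols <- setdiff(names(lanes),
                      c("lane_id", "band_label", "intensity", "background"))
  out <- lapply(ids, function(id) {
    lane <- lanes[lanes$lane_id == id, , drop = FALSE]
    row <- data.frame(lane_id = id)
    for (a in ann_cols) row[[a]] <- lane[[a]][1]
    row$percent <- band_fraction(lane, numerator, denominator,
                                 background = background)
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
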