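# Proteinase-K digestion time-course quantification: per-epitope signal at
# each cumulative digestion timepoint, internally normalised to the
# pre-treatment (t = 0) value so each timepoint reads as a relative
# percentage; retention estimation and exponential decay-rate fitting.

#' Measure per-epitope signal of one timepoint image
#'
#' Two quantities are supported. `"area"` (the documented default):
#' thresholded foreground area from [segment_channel()], optionally
#' restricted to the pre-treatment union footprint. `"intensity"`:
#' integrated background-subtracted intensity within the pre-treatment
#' union footprint (requires `footprint`). With a multiplicative-decay
#' digestion model the intensity mode tracks graded retention; thresholded
#' area only responds once signal crosses the threshold (see the methods
#' vignette), so the pipeline-level PK analysis defaults to intensity.
#'
#' @param image a [multiplex_image()] co-registered with the t = 0 image.
#' @param config an [analysis_config()].
#' @param mode `"area"` or `"intensity"`.
#' @param footprint optional logical matrix: the t = 0 union footprint.
#' @return named numeric vector, one quantity per epitope.
#' @export
measure_timepoint <- function(image, config = analysis_config(),
                              mode = c("area", "intensity"), footprint = NULL) {
  stopifnot(inherits(image, "multiplex_image"))
  mode <- match.arg(mode)
  labs <- names(image$channels)
  need <- names(config$channel_map)
  missing_ep <- setdiff(need, labs)
  if (length(missing_ep))
    stop_lq("missing epitope channel(s): ", paste(missing_ep, collapse = ", "))
  if (mode == "intensity" && is.null(footprint))
    stop_lq("intensity mode requires the t = 0 union `footprint`")
  vapply(labs, function(e) {
    if (mode == "area") {
      cm <- segment_channel(image$channels[[e]], config, epitope = e,
                            region_mask = image$region_mask)
      m <- cm$mask
      if (!is.null(footprint)) m <- m & footprint
      as.numeric(sum(m))
    } else {
      bg <- subtract_background(image$channels[[e]], config$blur_sigma_px)
      sum(bg[footprint])
    }
  }, 0)
}

#' Normalise a raw PK series to pre-treatment values
#'
#' @param raw data frame with columns `subject`, `epitope`,
#'   `timepoint_min`, `raw`. Every (subject, epitope) must include a
#'   timepoint-0 measurement; epitopes whose t = 0 value is zero are
#'   excluded with a warning. Values above 100% are legitimate (epitope
#'   unmasking).
#' @return object of class `pk_time_series`: the long data frame with an
#'   added `normalized_pct = 100 * raw(t)/raw(0)` column.
#' @export
normalize_series <- function(raw) {
  need <- c("subject", "epitope", "timepoint_min", "raw")
  if (!is.data.frame(raw) || !all(need %in% names(raw)))
    stop_lq("`raw` needs columns: ", paste(need, collapse = ", "))
  raw <- raw[order(raw$subject, raw$epitope, raw$timepoint_min), , drop = FALSE]
  out <- do.call(rbind, lapply(split(raw, list(raw$subject, raw$epitope), drop = TRUE),
    function(g) {
      i0 <- which(g$timepoint_min == 0)
      if (!length(i0))
        stop_lq("no t = 0 measurement for subject ", g$subject[1L],
                ", epitope ", g$epitope[1L])
      r0 <- g$raw[i0[1L]]
      if (r0 <= 0) {
        warning("excluding epitope ", g$epitope[1L], " of subject ",
                g$subject[1L], ": zero pre-treatment signal", call. = FALSE)
        return(NULL)
      }
      g$normalized_pct <- 100 * g$raw / r0
      g
    }))
  rownames(out) <- NULL
  structure(out, class = c("pk_time_series", "data.frame"))
}

#' Estimate retention factors and an exponential decay rate
#'
#' Retention at each timepoint is `normalized_pct / 100`. The decay rate
#' comes from a least-squares fit of log-retention against time over
#' timepoints strictly beyond 15 min, excluding the early unmasking
#' window; with fewer than two such timepoints the rate is `NA`. Under
#' `retention = exp(-rate * t)` a noiseless halving per 30 min gives
#' `rate = log(2)/30` per minute.
#'
#' @param series a `pk_time_series` from [normalize_series()].
#' @param unmasking_cutoff_min timepoints at or below this are excluded
#'   from the rate fit (default 15).
#' @return data frame with one row per (subject, epitope, timepoint)
#'   carrying `retention`, plus a `decay_rate_per_min` column (repeated
#'   within the group).
#' @export
fit_retention <- function(series, unmasking_cutoff_min = 15) {
  stopifnot(inherits(series, "pk_time_series"))
  out <- do.call(rbind, lapply(split(series,
                                     list(series$subject, series$epitope),
                                     drop = TRUE), function(g) {
    g$retention <- g$normalized_pct / 100
    late <- g$timepoint_min > unmasking_cutoff_min & g$retention > 0
    rate <- NA_real_
    if (sum(late) >= 2L) {
      fit <- stats::lm(log(g$retention[late]) ~ g$timepoint_min[late])
      rate <- -unname(stats::coef(fit)[2L])
    }
    g$decay_rate_per_min <- rate
    g
  }))
  rownames(out) <- NULL
  out
}
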