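#' Retention time indexing
#'
#' Converts retention times to retention indices against a calibration
#' table of `(rtime, rindex)` pairs (e.g. an n-alkane or N-alkyl-pyridinium
#' series). The default method interpolates linearly between the bracketing
#' calibration points; values outside the calibrated range are linearly
#' extrapolated from the terminal segment and flagged. A user-supplied
#' `method` function receives `(rt, calibration)` and its return value is
#' passed through unchanged.
#'
#' @param rt `numeric` retention times (seconds).
#' @param calibration `data.frame` with numeric columns `rtime` and
#'   `rindex`, both strictly increasing, at least two rows.
#' @param method `"linear"` or a `function(rt, calibration)`.
#' @return `numeric` of retention indices with a logical attribute
#'   `"out_of_range"` marking extrapolated values (linear method only).
#' @examples
#' cal <- data.frame(rtime = c(300, 420), rindex = c(1000, 1100))
#' index_rtime(c(300, 360, 480), cal)
#' @export
index_rtime <- function(rt, calibration, method = "linear") {
    if (!is.data.frame(calibration) ||
        !all(c("rtime", "rindex") %in% names(calibration)))
        stop("'calibration' must be a data.frame with columns 'rtime' ",
             "and 'rindex'")
    if (nrow(calibration) < 2L)
        stop("calibration needs at least two points")
    if (any(diff(calibration$rtime) <= 0) ||
        any(diff(calibration$rindex) <= 0))
        stop("calibration 'rtime' and 'rindex' must be strictly increasing")
    if (is.function(method))
        return(method(rt, calibration))
    method <- match.arg(method, "linear")
    ct <- calibration$rtime; ci <- calibration$rindex
    res <- stats::approx(ct, ci, xout = rt, rule = 1)$y
    low <- !is.na(rt) & rt < ct[1L]
    high <- !is.na(rt) & rt > ct[length(ct)]
    k <- length(ct)
    slope_lo <- (ci[2L] - ci[1L]) / (ct[2L] - ct[1L])
    slope_hi <- (ci[k] - ci[k - 1L]) / (ct[k] - ct[k - 1L])
    res[low] <- ci[1L] + (rt[low] - ct[1L]) * slope_lo
    res[high] <- ci[k] + (rt[high] - ct[k]) * slope_hi
    attr(res, "out_of_range") <- low | high
    res
}

#' Convert CE-MS migration times to effective mobilities
#'
#' Normalizes capillary-electrophoresis migration times into effective
#' electrophoretic mobilities using one or two mobility markers measured
#' in the same run. All times are first corrected for the voltage ramp at
#' the start of the separation, `t' = t - t_ramp / 2` (the average field
#' during a linear ramp is half the final field).
#'
#' With a single marker (migration time `t_M`, effective mobility `mu_M`)
#' the capillary length and field strength are used:
#' `mu(t) = mu_M + (L / E) * (1 / t' - 1 / t'_M)`.
#' With two markers, one of which must be the neutral (EOF) marker with
#' effective mobility 0 at time `t_0`, the instrument geometry cancels:
#' `mu(t) = C * (1 / t' - 1 / t'_0)` with
#' `C = mu_M / (1 / t'_M - 1 / t'_0)`.
#'
#' @param mt `numeric` migration times in minutes.
#' @param marker_mt `numeric` (length 1 or 2) marker migration times in
#'   minutes.
#' @param marker_mobility `numeric` same length: marker effective
#'   mobilities in 1e-9 m^2 V^-1 s^-1; in two-marker mode exactly one must
#'   be 0 (the neutral EOF marker).
#' @param capillary_length Total capillary length in m (single-marker mode
#'   only; detection is assumed at the capillary end).
#' @param field Applied electric field in V/m (single-marker mode only).
#' @param t_ramp Voltage ramp time in minutes (default 0).
#' @return `numeric` effective mobilities in 1e-9 m^2 V^-1 s^-1.
#' @examples
#' ## two-marker mode: neutral marker at 10 min, cation marker at 8 min
#' convert_mtime(9, marker_mt = c(10, 8), marker_mobility = c(0, 20))
#' @export
convert_mtime <- function(mt, marker_mt, marker_mobility,
                          capillary_length = NULL, field = NULL,
                          t_ramp = 0) {
    if (length(marker_mt) != length(marker_mobility))
        stop("'marker_mt' and 'marker_mobility' must have equal length")
    if (!length(marker_mt) %in% 1:2)
        stop("one or two mobility markers are required")
    if (any(marker_mt <= 0) || any(mt <= 0))
        stop("migration times must be > 0")
    corr <- function(t) (t - t_ramp / 2) * 60  # minutes -> seconds
    tp <- corr(mt); tm <- corr(marker_mt)
    if (any(c(tp, tm) <= 0))
        stop("ramp-corrected times must be > 0; check 't_ramp'")
    if (length(marker_mt) == 2L) {
        neutral <- which(marker_mobility == 0)
        if (length(neutral) != 1L)
            stop("two-marker conversion requires one marker to be the ",
                 "neutral marker, having an effective mobility of zero")
        t0 <- tm[neutral]
        tM <- tm[-neutral]; muM <- marker_mobility[-neutral]
        C <- muM / (1 / tM - 1 / t0)
        C * (1 / tp - 1 / t0)
    } else {
        if (is.null(capillary_length) || is.null(field))
            stop("single-marker conversion requires 'capillary_length' ",
                 "and 'field'")
        ## L/E has units m^2 / (V s) once divided by time in seconds;
        ## scale to 1e-9 m^2 V^-1 s^-1
        scale <- capillary_length / field * 1e9
        marker_mobility + scale * (1 / tp - 1 / tm)
    }
}
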