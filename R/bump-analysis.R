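#' dF/F from raw fluorescence
#'
#' Baseline `F` is a low percentile (default the 5th) of the raw trace over
#' the whole recording; `dF/F = (raw - F) / F`. Scale-invariant by
#' construction. An optional background series is subtracted first.
#'
#' @param raw positive raw fluorescence values.
#' @param baseline_percentile percentile (0-100) defining `F`.
#' @param background optional background fluorescence to subtract.
#' @return dF/F series.
#' @export
dff_from_raw <- function(raw, baseline_percentile = 5, background = NULL) {
  if (!is.null(background)) raw <- raw - background
  F0 <- quantile(raw, baseline_percentile / 100, names = FALSE)
  if (F0 <= 0) stop("nonpositive baseline fluorescence")
  (raw - F0) / F0
}

#' Gaussian smoothing with reflection padding
#'
#' FIR convolution with a normalized Gaussian kernel of full width `width_s`
#' (sigma = width/4, truncated at +/- 2 sigma), applied `passes` times.
#' Repeated passes of a narrow kernel approximate a single wider one
#' (effective width `width_s * sqrt(passes)`).
#'
#' @param x numeric series on a uniform grid.
#' @param width_s kernel full width in seconds.
#' @param rate_hz sampling rate of `x`.
#' @param passes number of repeated applications.
#' @return smoothed series, same length as `x`.
#' @export
smooth_gaussian <- function(x, width_s, rate_hz, passes = 1) {
  sigma <- width_s / 4 * rate_hz  # in samples
  half <- max(1L, ceiling(2 * sigma))
  kern <- exp(-0.5 * ((-half:half) / sigma)^2)
  kern <- kern / sum(kern)
  n <- length(x)
  for (p in seq_len(passes)) {
    pad <- c(x[pmin(half, n):1], x, x[n:max(1, n - half + 1)])
    sm <- stats::filter(pad, kern, sides = 2)
    x <- as.numeric(sm[(half + 1):(half + n)])
  }
  x
}

#' Align a behavioural speed series to an imaging time grid
#'
#' Downsamples (linear interpolation) to the imaging volume times, smooths
#' (10 passes of a 60 ms Gaussian kernel by default), and shifts the series
#' back in time by `shift_volumes` samples, so that the speed paired with an
#' imaging volume is the speed ~300 ms earlier — compensating the indicator
#' and coupling lag that maximizes the speed-activity correlation.
#'
#' @param t_speed,speed behavioural time stamps (s) and speed values.
#' @param t_target imaging volume times (s).
#' @param target_rate_hz imaging volume rate (Hz).
#' @param shift_volumes samples to shift back in time (0 = pure resampling).
#' @param smooth_width_s,smooth_passes smoothing kernel width and passes
#'   (set `smooth_passes = 0` to skip).
#' @return speed series on `t_target`.
#' @export
align_speed <- function(t_speed, speed, t_target, target_rate_hz,
                        shift_volumes = 2, smooth_width_s = 0.060,
                        smooth_passes = 10) {
  y <- approx(t_speed, speed, xout = t_target, rule = 2)$y
  if (smooth_passes > 0) {
    y <- smooth_gaussian(y, smooth_width_s, target_rate_hz,
                         passes = smooth_passes)
  }
  if (shift_volumes > 0) {
    n <- length(y)
    y <- c(rep(y[1], shift_volumes), y)[seq_len(n)]
  }
  y
}

#' Population vector average of one wedge sample
#'
#' Each wedge's dF/F becomes a vector pointing at the wedge's angular
#' position; the PVA is their sum. Uniform activity has no direction and is
#' reported as `NA`.
#'
#' @param dff_row dF/F values, one per wedge.
#' @param wedge_centers wedge angular positions in degrees.
#' @return list with `phase` (deg, `NA` if undefined) and `magnitude`.
#' @export
pva <- function(dff_row, wedge_centers = seq(0, 315, by = 45)) {
  th <- deg2rad(wedge_centers)
  s <- sum(dff_row * sin(th)); c <- sum(dff_row * cos(th))
  mag <- sqrt(s^2 + c^2)
  tot <- sum(abs(dff_row))
  if (tot < 1e-12 || mag / max(tot, 1e-12) < 1e-9) {
    return(list(phase = NA_real_, magnitude = 0))
  }
  list(phase = wrap360(rad2deg(atan2(s, c))), magnitude = mag)
}

#' Bump amplitude of one wedge sample
#'
#' Maximum minus minimum dF/F across the eight wedges.
#'
#' @param dff_row dF/F values, one per wedge.
#' @return amplitude (non-negative).
#' @export
bump_amplitude <- function(dff_row) max(dff_row) - min(dff_row)

#' Bump phase, magnitude and amplitude for a wedge series
#'
#' @param wedges an `fc_wedge_series` (columns `t`, `w1..w8`).
#' @return data frame of class `fc_bump_series` with `t`, `phase`,
#'   `magnitude`, `amplitude`.
#' @export
bump_series <- function(wedges) {
  centers <- attr(wedges, "wedge_centers")
  if (is.null(centers)) centers <- seq(0, 315, by = 45)
  m <- as.matrix(wedges[, paste0("w", 1:8)])
  ph <- apply(m, 1, function(r) unlist(pva(r, centers)))
  structure(data.frame(t = wedges$t, phase = ph["phase", ],
                       magnitude = ph["magnitude", ],
                       amplitude = apply(m, 1, bump_amplitude)),
            class = c("fc_bump_series", "data.frame"),
            volume_rate_hz = attr(wedges, "volume_rate_hz"))
}

#' Cue-bump offset series and windowed circular means
#'
#' The offset is the circular distance `cue - bump phase`, wrapped to
#' `(-180, 180]`. Samples where the cue is hidden behind the fly (azimuth in
#' 150-210 deg) are excluded when `exclude_hidden` is set; samples with an
#' undefined bump phase are always dropped.
#'
#' @param cue cue azimuths (deg) on the bump series' time grid.
#' @param bump an `fc_bump_series` (or anything with `t` and `phase`).
#' @param exclude_hidden drop hidden-cue samples.
#' @return data frame with `t`, `offset` (deg); attribute `n_dropped`.
#' @export
offset_series <- function(cue, bump, exclude_hidden = TRUE) {
  stopifnot(length(cue) == nrow(bump))
  keep <- !is.na(bump$phase)
  if (exclude_hidden) keep <- keep & !cue_hidden(cue)
  if (!any(keep)) stop("no usable samples: all hidden or undefined")
  structure(data.frame(t = bump$t[keep],
                       offset = circ_dist_deg(cue[keep], bump$phase[keep])),
            n_dropped = sum(!keep))
}

#' Circular-mean offset in a time window, and the pre-to-post offset change
#'
#' @param off an offset series from [offset_series()].
#' @param window numeric length-2 time interval (s); `NULL` = all samples.
#' @return `offset_mean`: circular mean offset in degrees (in
#'   `(-180, 180]`).
#' @export
offset_mean <- function(off, window = NULL) {
  x <- off$offset
  if (!is.null(window)) x <- x[off$t >= window[1] & off$t < window[2]]
  if (length(x) == 0) stop("empty window")
  wrap180(circ_mean_deg(x))
}

#' @rdname offset_mean
#' @param pre,post length-2 time windows (s).
#' @return `offset_change`: signed circular difference post - pre, degrees.
#' @export
offset_change <- function(off, pre, post) {
  circ_dist_deg(offset_mean(off, post), offset_mean(off, pre))
}

#' Bump amplitude vs rotational speed: binned curve and Pearson correlation
#'
#' Amplitude is smoothed (600 ms Gaussian), z-scored per fly, and binned by
#' the aligned rotational speed into equal-count bins; samples faster than
#' `cap` deg/s are excluded. The Pearson r between (smoothed, z-scored)
#' amplitude and speed is computed on the retained samples.
#'
#' @param bump an `fc_bump_series`.
#' @param speed aligned rotational speed (deg/s) on the same grid (see
#'   [align_speed()]).
#' @param n_bins number of equal-count speed bins.
#' @param cap exclusion threshold in deg/s.
#' @param smooth_width_s amplitude smoothing kernel width (s).
#' @return list: `curve` (data frame `speed`, `amplitude_z`, `n`), `r`,
#'   `n_used`.
#' @export
amplitude_speed_coupling <- function(bump, speed, n_bins = 10, cap = 100,
                                     smooth_width_s = 0.6) {
  stopifnot(length(speed) == nrow(bump))
  rate <- attr(bump, "volume_rate_hz")
  if (is.null(rate)) rate <- 1 / median(diff(bump$t))
  amp <- smooth_gaussian(bump$amplitude, smooth_width_s, rate)
  keep <- speed <= cap & !is.na(amp)
  amp <- amp[keep]; spd <- speed[keep]
  if (length(amp) < n_bins) stop("fewer samples than bins")
  ampz <- (amp - mean(amp)) / sd(amp)
  # equal-count bins; ties broken by stable order
  ord <- order(spd)
  bin <- integer(length(spd))
  bin[ord] <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  bin <- pmin(bin, n_bins)
  curve <- data.frame(
    speed = vapply(split(spd, bin), mean, numeric(1)),
    amplitude_z = vapply(split(ampz, bin), mean, numeric(1)),
    n = as.integer(table(bin)))
  list(curve = curve, r = cor(ampz, spd), n_used = length(amp))
}
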