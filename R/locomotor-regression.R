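#' Binned speed tuning curve of a neural activity series
#'
#' Samples are divided into `n_bins` equal-count rotational-speed bins (ties
#' broken by stable order, per-bin counts differ by at most 1) and the mean
#' activity per bin reported.
#'
#' @param activity activity series (e.g. dF/F), aligned to `speed`.
#' @param speed rotational speed, deg/s.
#' @param n_bins number of equal-count bins.
#' @return data frame with `speed` (bin mean), `activity` (bin mean), `n`.
#' @export
binned_speed_tuning <- function(activity, speed, n_bins = 45) {
  stopifnot(length(activity) == length(speed))
  n <- length(speed)
  if (n < n_bins) stop("fewer samples than bins")
  ord <- order(speed)
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) / (n / n_bins))
  bin <- pmin(bin, n_bins)
  data.frame(speed = vapply(split(speed, bin), mean, numeric(1)),
             activity = vapply(split(activity, bin), mean, numeric(1)),
             n = as.integer(table(bin)))
}

#' 2-D mean activity map over rotational and forward speed
#'
#' Fixed-width bins in each speed axis; samples from several flies may be
#' pooled before averaging. Empty bins are `NA`, never zero-filled.
#'
#' @param activity activity samples.
#' @param rot_speed,fwd_speed matching speeds.
#' @param rot_edges,fwd_edges bin edges (uniform width).
#' @return list: `map` (matrix rot x fwd of means, `NA` = empty), `n`
#'   (counts), `rot_centers`, `fwd_centers`.
#' @export
binned_2d_speed_map <- function(activity, rot_speed, fwd_speed,
                                rot_edges, fwd_edges) {
  ri <- cut(rot_speed, rot_edges, include.lowest = TRUE, labels = FALSE)
  fi <- cut(fwd_speed, fwd_edges, include.lowest = TRUE, labels = FALSE)
  nr <- length(rot_edges) - 1; nf <- length(fwd_edges) - 1
  m <- matrix(NA_real_, nr, nf)
  cnt <- matrix(0L, nr, nf)
  ok <- !is.na(ri) & !is.na(fi)
  for (idx in which(ok)) {
    r <- ri[idx]; f <- fi[idx]
    cnt[r, f] <- cnt[r, f] + 1L
    m[r, f] <- if (cnt[r, f] == 1L) activity[idx] else
      m[r, f] + (activity[idx] - m[r, f]) / cnt[r, f]
  }
  list(map = m, n = cnt,
       rot_centers = (rot_edges[-1] + rot_edges[-length(rot_edges)]) / 2,
       fwd_centers = (fwd_edges[-1] + fwd_edges[-length(fwd_edges)]) / 2)
}

#' Line fit to the linear regime of a speed tuning curve
#'
#' Ordinary least squares on the bins with speed above `min_speed`,
#' excluding the low-speed rest-move transition regime.
#'
#' @param curve data frame from [binned_speed_tuning()].
#' @param min_speed lower speed cutoff, deg/s.
#' @return list with `slope`, `intercept`, `n_bins`.
#' @export
linear_regime_fit <- function(curve, min_speed = 30) {
  d <- curve[curve$speed > min_speed, ]
  if (nrow(d) < 2) stop("fewer than 2 bins above min_speed")
  fit <- lm(activity ~ speed, data = d)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n_bins = nrow(d))
}

#' Nested linear models predicting activity from locomotor speed
#'
#' Fits two regressions on z-scored variables: activity ~ rotational speed,
#' and activity ~ rotational + forward speed, on identical samples, and
#' reports adjusted R-squared for both (comparable across model sizes).
#' Rotational speed enters unsigned; forward speed is unrectified.
#'
#' @param activity activity series.
#' @param rot_speed rotational speed (deg/s, unsigned).
#' @param fwd_speed forward velocity (mm/s).
#' @return list of class `fc_speed_fit`: `r2_rot_only`, `r2_rot_fwd`,
#'   `coefficients` (standardized), `n`.
#' @export
fit_speed_models <- function(activity, rot_speed, fwd_speed) {
  stopifnot(length(activity) == length(rot_speed),
            length(activity) == length(fwd_speed))
  zs <- function(x) {
    if (sd(x) == 0) stop("constant predictor or response")
    (x - mean(x)) / sd(x)
  }
  d <- data.frame(a = zs(activity), r = zs(rot_speed), f = zs(fwd_speed))
  m1 <- lm(a ~ r, data = d)
  m2 <- lm(a ~ r + f, data = d)
  structure(list(r2_rot_only = summary(m1)$adj.r.squared,
                 r2_rot_fwd = summary(m2)$adj.r.squared,
                 coefficients = list(rot_only = coef(m1)[-1],
                                     rot_fwd = coef(m2)[-1]),
                 n = nrow(d)),
            class = "fc_speed_fit")
}

#' Moving-epoch mask
#'
#' A sample counts as moving when rotational speed exceeds `rot_thresh` OR
#' forward speed exceeds `fwd_thresh`.
#'
#' @param rot_speed rotational speed, deg/s (unsigned).
#' @param fwd_speed forward speed, mm/s.
#' @param rot_thresh,fwd_thresh thresholds.
#' @return logical mask.
#' @export
moving_epoch_filter <- function(rot_speed, fwd_speed, rot_thresh = 15,
                                fwd_thresh = 2) {
  abs(rot_speed) > rot_thresh | fwd_speed > fwd_thresh
}
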