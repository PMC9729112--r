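#' Kraskov k-nearest-neighbour mutual information
#'
#' Algorithm 1 of the KSG estimator:
#' `I = psi(k) + psi(n) - < psi(n_x + 1) + psi(n_y + 1) >`, with
#' neighbourhoods in the max norm. A tiny uniform jitter (<= 1e-10) breaks
#' exact ties. The estimate is in nats and may be slightly negative near
#' independence.
#'
#' @param x,y numeric vectors or matrices (rows = samples).
#' @param k neighbour count (default 3).
#' @param jitter_sd amplitude of the tie-breaking jitter.
#' @return list of class `fc_mi`: `mi` (nats), `k`, `n`.
#' @export
ksg_mi <- function(x, y, k = 3, jitter_sd = 1e-10) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same sample count")
  n <- nrow(x)
  if (n < k + 2) stop("need at least k + 2 samples")
  if (jitter_sd > 0) {
    x <- x + matrix(runif(length(x), -jitter_sd, jitter_sd), nrow(x))
    y <- y + matrix(runif(length(y), -jitter_sd, jitter_sd), nrow(y))
  }
  structure(list(mi = ksg_mi_cpp(x, y, as.integer(k)), k = k, n = n),
            class = "fc_mi")
}

#' Embed circular samples on the unit circle
#'
#' Angles are mapped to `(cos, sin)` pairs before MI estimation, so that
#' 359 deg and 1 deg are close and the estimate is invariant to rigid
#' rotations of either series.
#'
#' @param angles angles in degrees.
#' @return two-column matrix `(cos, sin)`.
#' @export
circular_embed <- function(angles) {
  th <- deg2rad(angles)
  cbind(cos(th), sin(th))
}

#' Cue-bump mutual information per cue rotation cycle or in a window
#'
#' One KSG estimate per full 360-degree cue rotation (or per pooled time
#' window), between the embedded cue azimuth and the embedded bump phase.
#' Hidden-cue samples (azimuth 150-210 deg) are dropped when
#' `exclude_hidden` is set, as are samples with undefined bump phase; a
#' cycle left with fewer than `k + 2` usable samples yields `NA`.
#'
#' @param cue an `fc_angle_series` with `cycle_id` on the bump grid, or a
#'   vector of cue azimuths (then `cycle_id` must be given).
#' @param bump_phase bump phase series in degrees (may contain `NA`).
#' @param cycle_id integer cycle labels (taken from `cue` if absent).
#' @param exclude_hidden drop hidden-cue samples.
#' @param k neighbour count.
#' @return data frame with `cycle_id`, `mi` (nats), `n`.
#' @export
mi_per_cycle <- function(cue, bump_phase, cycle_id = NULL,
                         exclude_hidden = TRUE, k = 3) {
  if (is.data.frame(cue)) {
    cycle_id <- cue$cycle_id
    cue <- cue$angle
  }
  stopifnot(!is.null(cycle_id), length(cue) == length(bump_phase),
            length(cue) == length(cycle_id))
  keep <- !is.na(bump_phase)
  if (exclude_hidden) keep <- keep & !cue_hidden(cue)
  out <- lapply(sort(unique(cycle_id)), function(cc) {
    idx <- keep & cycle_id == cc
    n_use <- sum(idx)
    mi <- if (n_use >= k + 2) {
      ksg_mi(circular_embed(cue[idx]), circular_embed(bump_phase[idx]), k)$mi
    } else NA_real_
    data.frame(cycle_id = cc, mi = mi, n = n_use)
  })
  do.call(rbind, out)
}

#' @rdname mi_per_cycle
#' @param t time stamps matching `cue`.
#' @param window length-2 time interval (s).
#' @return `mi_window`: a single pooled `fc_mi` for the window.
#' @export
mi_window <- function(cue, bump_phase, t, window, exclude_hidden = TRUE,
                      k = 3) {
  if (is.data.frame(cue)) cue <- cue$angle
  keep <- !is.na(bump_phase) & t >= window[1] & t < window[2]
  if (exclude_hidden) keep <- keep & !cue_hidden(cue)
  if (sum(keep) < k + 2) stop("fewer than k + 2 usable samples in window")
  ksg_mi(circular_embed(cue[keep]), circular_embed(bump_phase[keep]), k)
}

#' Post-minus-pre change in windowed cue-bump mutual information
#'
#' @inheritParams mi_window
#' @param pre,post length-2 time windows (s).
#' @return difference in nats (post - pre).
#' @export
mi_change <- function(cue, bump_phase, t, pre, post, exclude_hidden = TRUE,
                      k = 3) {
  mi_window(cue, bump_phase, t, post, exclude_hidden, k)$mi -
    mi_window(cue, bump_phase, t, pre, exclude_hidden, k)$mi
}
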