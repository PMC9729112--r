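#' Population vector average of weighted angles
#'
#' `angle = atan2(sum(w sin), sum(w cos))`; `magnitude` is the resultant
#' length normalized by the total weight, so a single active element gives 1
#' and a symmetric profile gives 0 (undefined angle, reported as an error).
#'
#' @param weights non-negative weights.
#' @param angles matching angles in degrees.
#' @return list with `angle` (deg in `[0, 360)`) and `magnitude`.
#' @export
weight_pva <- function(weights, angles) {
  stopifnot(length(weights) == length(angles))
  if (all(weights == 0)) stop("undefined PVA: all weights are zero")
  th <- deg2rad(angles)
  s <- sum(weights * sin(th)); c <- sum(weights * cos(th))
  mag <- sqrt(s^2 + c^2) / sum(weights)
  if (mag < 1e-12) stop("undefined PVA: weights are circularly symmetric")
  list(angle = wrap360(rad2deg(atan2(s, c))), magnitude = mag)
}

#' Regularity of an ER->EPG weight map
#'
#' For every ER neuron, the PVA of its output-weight column over the EPG
#' angular positions; for every EPG neuron, the PVA of its input-weight row
#' over the ER preferred azimuths. Regularity is the circular correlation
#' between the two angle vectors, pairing each ER neuron with the EPG neuron
#' at the same azimuth: 1 for a perfectly ordered retinotopic-to-compass map,
#' near 0 for random weights. A percentile bootstrap over pairs gives the
#' 95% CI.
#'
#' @param W weight matrix (`n_epg x n_er`, `n_epg == n_er`).
#' @param er_prefs,epg_positions angle coordinates in degrees (defaults:
#'   even tilings of 360 degrees).
#' @param n_boot bootstrap resamples for the CI (0 disables).
#' @return list of class `fc_map_summary`: `er_output_pva`, `epg_input_pva`,
#'   `regularity`, `ci95`, `n_pairs`.
#' @export
map_regularity <- function(W, er_prefs = NULL, epg_positions = NULL,
                           n_boot = 0) {
  n_epg <- nrow(W); n_er <- ncol(W)
  if (n_epg != n_er) stop("map_regularity requires n_er == n_epg")
  if (is.null(er_prefs)) er_prefs <- seq(0, 360 - 360 / n_er, by = 360 / n_er)
  if (is.null(epg_positions))
    epg_positions <- seq(0, 360 - 360 / n_epg, by = 360 / n_epg)
  pva_or_na <- function(w, a) tryCatch(weight_pva(w, a)$angle,
                                       error = function(e) NA_real_)
  er_out <- vapply(seq_len(n_er), function(m) pva_or_na(W[, m], epg_positions),
                   numeric(1))
  epg_in <- vapply(seq_len(n_epg), function(n) pva_or_na(W[n, ], er_prefs),
                   numeric(1))
  ok <- !is.na(er_out) & !is.na(epg_in)
  if (sum(ok) < 3) stop("fewer than 3 well-defined PVA pairs")
  rho <- circular_correlation(er_out[ok], epg_in[ok])
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    a <- er_out[ok]; b <- epg_in[ok]; np <- length(a)
    boots <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(np, np, replace = TRUE)
      tryCatch(circular_correlation(a[idx], b[idx]),
               error = function(e) NA_real_)
    }, numeric(1))
    ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(er_output_pva = er_out, epg_input_pva = epg_in,
                 regularity = rho, ci95 = ci, n_pairs = sum(ok)),
            class = "fc_map_summary")
}

#' Map regularity over the snapshots of one or more simulations
#'
#' Computes the weight-map regularity at every stored snapshot. Given
#' several simulations (a list), also returns the across-simulation mean
#' with a bootstrap 95% CI (resampling simulations with replacement).
#'
#' @param sim an `fc_sim`, or a list of them on a common snapshot grid.
#' @param n_boot bootstrap resamples for the across-simulation CI.
#' @return data frame with columns `t`, `regularity` (single simulation) or
#'   `t`, `mean`, `ci_lo`, `ci_hi` (several).
#' @export
regularity_timeseries <- function(sim, n_boot = 1000) {
  one <- function(s) {
    ns <- dim(s$W)[3]
    vapply(seq_len(ns), function(i) {
      tryCatch(map_regularity(s$W[, , i])$regularity,
               error = function(e) NA_real_)
    }, numeric(1))
  }
  if (inherits(sim, "fc_sim")) {
    return(data.frame(t = sim$t, regularity = one(sim)))
  }
  stopifnot(is.list(sim), length(sim) >= 1)
  mat <- vapply(sim, one, numeric(length(sim[[1]]$t)))  # n_snap x n_sim
  mat <- matrix(mat, ncol = length(sim))
  mean_r <- rowMeans(mat, na.rm = TRUE)
  if (length(sim) == 1 || n_boot == 0) {
    return(data.frame(t = sim[[1]]$t, mean = mean_r, ci_lo = mean_r,
                      ci_hi = mean_r))
  }
  ns <- ncol(mat)
  boots <- replicate(n_boot, {
    rowMeans(mat[, sample.int(ns, ns, replace = TRUE), drop = FALSE],
             na.rm = TRUE)
  })
  data.frame(t = sim[[1]]$t, mean = mean_r,
             ci_lo = apply(boots, 1, quantile, 0.025, na.rm = TRUE),
             ci_hi = apply(boots, 1, quantile, 0.975, na.rm = TRUE))
}
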