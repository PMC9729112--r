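#' Circular helpers and statistics
#'
#' Angles throughout the package are in degrees, wrapped to `[0, 360)` for
#' positions and to `(-180, 180]` for differences. Positive rotational
#' velocity means rightward rotation.
#'
#' @name circular-utils
NULL

#' Wrap angles to `[0, 360)`
#' @param x angles in degrees.
#' @return wrapped angles.
#' @export
wrap360 <- function(x) {
  y <- x %% 360
  y[y == 360] <- 0
  y
}

#' Wrap angle differences to `(-180, 180]`
#' @param x angle differences in degrees.
#' @return wrapped differences.
#' @export
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Signed circular distance `a - b` in degrees
#' @param a,b angles in degrees.
#' @return signed difference in `(-180, 180]`.
#' @export
circ_dist_deg <- function(a, b) wrap180(a - b)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Circular mean and resultant length
#'
#' @param a angles in degrees.
#' @param w optional non-negative weights.
#' @return `circ_mean_deg`: mean angle in `[0, 360)`.
#'   `circ_r`: mean resultant length in `[0, 1]`.
#' @export
circ_mean_deg <- function(a, w = NULL) {
  if (is.null(w)) w <- rep(1, length(a))
  th <- deg2rad(a)
  wrap360(rad2deg(atan2(sum(w * sin(th)), sum(w * cos(th)))))
}

#' @rdname circ_mean_deg
#' @export
circ_r <- function(a, w = NULL) {
  if (is.null(w)) w <- rep(1, length(a))
  th <- deg2rad(a)
  sqrt(sum(w * sin(th))^2 + sum(w * cos(th))^2) / sum(w)
}

#' Circular standard deviation in degrees
#'
#' `sqrt(-2 log Rbar)` converted to degrees; `Inf` when the sample is
#' (numerically) uniform.
#'
#' @param a angles in degrees.
#' @return circular SD in degrees (possibly `Inf`).
#' @export
circ_sd_deg <- function(a) {
  r <- circ_r(a)
  if (r < .Machine$double.eps^0.5) return(Inf)
  rad2deg(sqrt(-2 * log(r)))
}

#' Rayleigh test for circular uniformity
#'
#' @param a angles in degrees.
#' @return list with `r` (resultant length), `z` (`n r^2`) and `p`
#'   (approximate p-value; accurate for n >= 10 and usable above n = 5).
#' @export
rayleigh_test <- function(a) {
  n <- length(a)
  if (n < 2) stop("rayleigh_test needs at least 2 angles")
  r <- circ_r(a)
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  list(r = r, z = z, p = p)
}

# Maximum-likelihood von Mises concentration from a mean resultant length
# (Fisher 1993 approximation).
a1inv <- function(r) {
  if (r >= 0 && r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Watson-Williams two-sample test for equal circular means
#'
#' Parametric F-test assuming von Mises samples with a common concentration;
#' includes the standard small-concentration correction factor
#' `1 + 3/(8 kappa)`. A warning flag is set when the pooled mean resultant
#' length falls below 0.45, where the parametric approximation degrades.
#'
#' @param a,b angle samples in degrees.
#' @return list with `F`, `df1`, `df2`, `p`, `kappa` and `low_concentration`.
#' @export
watson_williams_test <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  if (n1 < 3 || n2 < 3) stop("watson_williams_test needs >= 3 angles per sample")
  r1 <- n1 * circ_r(a)
  r2 <- n2 * circ_r(b)
  rall <- n * circ_r(c(a, b))
  rw <- (r1 + r2) / n
  kap <- a1inv(rw)
  K <- 1 + 3 / (8 * kap)
  Fst <- K * ((n - 2) * (r1 + r2 - rall)) / (n - r1 - r2)
  Fst <- max(Fst, 0)
  p <- pf(Fst, 1, n - 2, lower.tail = FALSE)
  list(F = Fst, df1 = 1, df2 = n - 2, p = p, kappa = kap,
       low_concentration = rw < 0.45)
}

#' Circular correlation coefficient (pairwise T-linear form)
#'
#' `rho = sum_{i<j} sin(a_i - a_j) sin(b_i - b_j) /
#'        sqrt(sum_{i<j} sin^2(a_i - a_j) * sum_{i<j} sin^2(b_i - b_j))`
#' (Fisher-Lee). Unlike the mean-centred variant, the pairwise form stays
#' well defined when the angles spread over the whole circle — the situation
#' of a weight map whose preferred directions tile 360 degrees — and is
#' invariant to rigid rotation of either series: 1 for `b = a + const`,
#' -1 for `b = -a + const`, near 0 for independent angles.
#'
#' @param a,b angle vectors in degrees, equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
circular_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 3) stop("need at least 3 angle pairs")
  ar <- deg2rad(a); br <- deg2rad(b)
  da <- sin(outer(ar, ar, `-`)); db <- sin(outer(br, br, `-`))
  up <- upper.tri(da)
  den <- sqrt(sum(da[up]^2) * sum(db[up]^2))
  if (den < .Machine$double.eps) {
    stop("degenerate input: one angle series has no circular spread")
  }
  sum(da[up] * db[up]) / den
}
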