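#' Write and read package time-series as plain CSV
#'
#' Trajectories, angle series, dF/F series and wedge series are stored as
#' columnar CSV with a leading `t_s` column; classes and key attributes are
#' restored on read from the column layout.
#'
#' @param x a package data frame (`fc_trajectory`, `fc_angle_series`,
#'   `fc_dff_series`, `fc_wedge_series`, `fc_bump_series`).
#' @param path output file.
#' @return `write_series_csv`: the path, invisibly.
#' @export
write_series_csv <- function(x, path) {
  d <- as.data.frame(x)
  names(d)[names(d) == "t"] <- "t_s"
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @param volume_rate_hz volume rate to attach when reading a wedge series.
#' @return `read_wedge_csv`: an `fc_wedge_series`.
#' @export
read_wedge_csv <- function(path, volume_rate_hz = NULL) {
  d <- read.csv(path)
  names(d)[names(d) == "t_s"] <- "t"
  need <- c("t", paste0("w", 1:8))
  if (!all(need %in% names(d))) stop("wedge CSV needs columns t_s, w1..w8")
  if (is.null(volume_rate_hz)) volume_rate_hz <- 1 / median(diff(d$t))
  structure(d[need], class = c("fc_wedge_series", "data.frame"),
            volume_rate_hz = volume_rate_hz,
            wedge_centers = seq(0, 315, by = 45))
}

#' @rdname write_series_csv
#' @return `read_series_csv`: a plain data frame with a `t` column.
#' @export
read_series_csv <- function(path) {
  d <- read.csv(path)
  names(d)[names(d) == "t_s"] <- "t"
  d
}
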