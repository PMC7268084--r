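#' Framewise displacement from realignment parameters
#'
#' Power-style framewise displacement: the sum of absolute backward
#' differences of the three translations (mm) plus the arc length of the
#' three rotation differences on a sphere of radius `head_radius_mm`.
#' Rotations MUST be in radians - a degree-valued trace cannot be detected
#' and will silently inflate FD by a factor of ~57.
#'
#' @param m numeric `T x 6` motion table: columns 1-3 translations in mm,
#'   columns 4-6 rotations in radians.
#' @param head_radius_mm sphere radius for the rotational term (default 50,
#'   the convention of the scrubbing literature).
#' @return Numeric length-`T` FD series; `FD[1] = 0`.
#' @export
framewise_displacement <- function(m, head_radius_mm = 50) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) != 6)
    stop("framewise_displacement: need a T x 6 table with T >= 2")
  if (any(!is.finite(m)))
    stop("framewise_displacement: non-finite motion parameters")
  d <- abs(diff(m))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

# Friston-24 expansion: 6 parameters, their one-volume lag, and both squared.
friston24 <- function(m) {
  m <- as.matrix(m)
  lag1 <- rbind(0, m[-nrow(m), , drop = FALSE])
  cbind(m, lag1, m^2, lag1^2)
}
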