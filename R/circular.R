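#' Smallest angle between two headings
#'
#' Absolute angular difference between two bearings, wrapped onto the circle,
#' in `[0, 180]` degrees. Used everywhere a step heading is compared with the
#' local flow direction or a previous heading.
#'
#' @param a,b headings in degrees (any real values; normalised mod 360).
#' @return numeric vector of differences in degrees, in `[0, 180]`.
#' @examples
#' circular_difference(350, 10)  # 20
#' circular_difference(0, 180)   # 180
#' @export
circular_difference <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# normalise a heading into [0, 360)
norm_heading <- function(h) h %% 360

# mathematical "to" bearing of displacement (dx, dy), degrees CCW from +x,
# in [0, 360); (0, 0) -> 0 by convention
bearing_deg <- function(dx, dy) {
  b <- atan2(dy, dx) * 180 / pi
  b[dx == 0 & dy == 0] <- 0
  norm_heading(b)
}
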