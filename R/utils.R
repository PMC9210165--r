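#' Azimuth of a planar direction
#'
#' Compass bearing of the vector (dx, dy) in plot coordinates (x east,
#' y north), measured clockwise from north in degrees.
#'
#' @param dx,dy Direction components (east, north), metres.
#' @return Bearing in [0, 360).
#' @keywords internal
azimuth_deg <- function(dx, dy) {
  (atan2(dx, dy) * 180 / pi) %% 360
}

#' Circular mean of bearings
#'
#' Mean direction of angles on the compass circle; an arithmetic mean is
#' wrong across the 0/360 wrap (e.g. mean of 350 and 10 degrees is 0, not
#' 180), so angles are averaged as unit vectors.
#'
#' @param deg Bearings in degrees.
#' @param na.rm Drop missing values first.
#' @return Mean bearing in [0, 360), or `NA` if no finite input remains or
#'   the resultant vector has zero length (perfectly opposed directions).
#' @export
#' @examples
#' circular_mean_deg(c(350, 10))  # 0, not 180
circular_mean_deg <- function(deg, na.rm = TRUE) {
  if (na.rm) deg <- deg[!is.na(deg)]
  if (length(deg) == 0L) return(NA_real_)
  rad <- deg * pi / 180
  s <- mean(sin(rad)); c <- mean(cos(rad))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  out <- (atan2(s, c) * 180 / pi) %% 360
  if (out >= 360 - 1e-9) out <- 0  # fold the floating wrap back to north
  out
}

# Derive independent integer sub-seeds from one global seed so that the
# point, mark, substrate and elevation streams can be regenerated
# independently of each other. Stays below 2^31 - 1.
derive_subseeds <- function(seed, n = 4L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Fixed-precision numeric serialization (9 significant digits) so pipeline
# outputs diff reproducibly across platforms.
format_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.9g", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
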