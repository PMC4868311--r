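## Circular statistics for backbone dihedral samples.
##
## Dihedral angles live on the circle, so arithmetic means and standard
## deviations are wrong near the +-180 branch cut (the mean of 170 and -170
## is 180, not 0).  The torso profiles are therefore built from the circular
## mean direction and the approximate circular standard deviation derived
## from the mean resultant length R.

#' Circular mean of an angle sample
#'
#' Mean direction `atan2(sum(sin a), sum(cos a))` of a sample of angles,
#' reported in degrees in (-180, 180].
#'
#' @param angles Numeric vector of angles in degrees (any branch; values are
#'   wrapped internally).
#' @return Circular mean in degrees.
#' @details The mean direction is undefined when the resultant vector is
#'   (numerically) zero, e.g. for perfectly antipodal samples; this raises
#'   an error rather than returning an arbitrary direction.
#' @examples
#' circ_mean(c(170, -170))  # 180, where the arithmetic mean would give 0
#' circ_mean(c(0, 90))      # 45
#' @export
circ_mean <- function(angles) {
  a <- .check_angles(angles)
  s <- sum(sin(a)); co <- sum(cos(a))
  if (sqrt(s^2 + co^2) / length(a) <= 1e-9)
    stop("circular mean undefined: resultant length is (numerically) zero",
         call. = FALSE)
  wrap180(atan2(s, co) * 180 / pi)
}

#' Mean resultant length
#'
#' Length R in [0, 1] of the average of the unit vectors
#' (cos a, sin a); R = 1 for perfectly concentrated samples, R -> 0 for
#' dispersed ones.
#'
#' @inheritParams circ_mean
#' @return R in [0, 1].
#' @export
circ_resultant <- function(angles) {
  a <- .check_angles(angles)
  r <- sqrt(sum(sin(a))^2 + sum(cos(a))^2) / length(a)
  min(1, r)
}

#' Approximate circular standard deviation
#'
#' The small-dispersion approximation `sqrt(2 * (1 - R))` (in radians,
#' reported in degrees), where R is the mean resultant length.  For tightly
#' concentrated samples this approaches the linear standard deviation.
#'
#' @inheritParams circ_mean
#' @param variant `"sqrt2(1-R)"` (default) or `"sqrt(-2lnR)"`, the exact
#'   circular standard deviation of directional statistics.  The two agree
#'   to first order for concentrated samples.
#' @return Approximate standard deviation in degrees (>= 0).
#' @examples
#' circ_std_approx(c(45, 45, 45))  # 0
#' circ_std_approx(c(0, 90))       # 43.85
#' @export
circ_std_approx <- function(angles, variant = c("sqrt2(1-R)", "sqrt(-2lnR)")) {
  variant <- match.arg(variant)
  r <- circ_resultant(angles)
  rad <- if (variant == "sqrt2(1-R)") sqrt(2 * (1 - r)) else sqrt(-2 * log(max(r, 1e-300)))
  rad * 180 / pi
}

#' Summarize an angle sample
#'
#' Bundles the circular mean, mean resultant length, approximate circular
#' standard deviation and the sample size into a `circular_summary`.
#'
#' @inheritParams circ_std_approx
#' @param label Optional label, e.g. `"bulged/T6/psi"`.
#' @return An object of class `circular_summary`: a list with `mean`, `r`,
#'   `sd` (degrees), `n` and `label`.
#' @export
circ_summary <- function(angles, label = NA_character_,
                         variant = c("sqrt2(1-R)", "sqrt(-2lnR)")) {
  variant <- match.arg(variant)
  structure(
    list(mean = circ_mean(angles),
         r = circ_resultant(angles),
         sd = circ_std_approx(angles, variant),
         n = length(angles),
         label = label),
    class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("circular_summary%s: mean %.2f deg, sd %.2f deg (R = %.4f, n = %d)\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              x$mean, x$sd, x$r, x$n))
  invisible(x)
}

#' Draw wrapped-normal angles
#'
#' Samples from a normal distribution with the given mean and standard
#' deviation (degrees) wrapped onto (-180, 180].  Adequate for the
#' concentrated case (sd up to roughly 60 degrees) that backbone dihedral
#' classes exhibit.
#'
#' @param n Number of draws.
#' @param mean,sd Mean direction and standard deviation in degrees.
#' @return Numeric vector of angles in (-180, 180].
#' @export
rwrappednorm <- function(n, mean, sd) {
  wrap180(stats::rnorm(n, mean = mean, sd = sd))
}

.check_angles <- function(angles) {
  angles <- as.numeric(angles)
  if (length(angles) < 1L || any(!is.finite(angles)))
    stop("need at least one finite angle", call. = FALSE)
  wrap180(angles) * pi / 180
}
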