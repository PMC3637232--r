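#' Scanner (digitizer) calibration profile
#'
#' Describes one site's film digitizer: spatial resolution, the form of its
#' optical-density response (linear or logarithmic in the recorded gray
#' level), the calibration coefficients of that response, the gray-level
#' dynamic range and the gray-level noise.  The calibration curve maps gray
#' levels to optical density (OD):
#' \deqn{\mathrm{linear:}\quad od = a + b \cdot g}
#' \deqn{\mathrm{logarithmic:}\quad od = a + b \cdot \log_{10} g}
#' with \eqn{g = 0} clamped to 1 before the logarithm.  [digitize()] applies
#' the inverse map.
#'
#' @param name Site / scanner identifier.
#' @param resolution_um Micrometers per pixel (positive).
#' @param response `"linear"` or `"logarithmic"`.
#' @param cal_a Offset coefficient, OD units.
#' @param cal_b Slope coefficient; must be non-zero (negative for film
#'   scanners, where darker film means higher OD and higher gray).
#' @param max_gray Maximum representable gray level (integer >= 255).
#' @param noise_sd Gray-level additive Gaussian noise standard deviation.
#' @return An object of class `scanner_profile`.
#' @examples
#' p <- scanner_profile("howtek", 43.5, "linear", cal_a = 3.789,
#'                      cal_b = -9e-4, max_gray = 4095)
#' od_range(p)
#' @export
scanner_profile <- function(name, resolution_um, response = c("linear", "logarithmic"),
                            cal_a, cal_b, max_gray = 4095L, noise_sd = 0) {
  response <- match.arg(response)
  stopifnot(is.character(name), length(name) == 1L, resolution_um > 0,
            is.numeric(cal_a), is.numeric(cal_b), noise_sd >= 0)
  if (cal_b == 0) stop("cal_b must be non-zero")
  max_gray <- as.integer(max_gray)
  if (max_gray < 255L) stop("max_gray must be >= 255")
  structure(list(name = name, resolution_um = resolution_um,
                 response = response, cal_a = cal_a, cal_b = cal_b,
                 max_gray = max_gray, noise_sd = noise_sd),
            class = "scanner_profile")
}

#' @export
print.scanner_profile <- function(x, ...) {
  cat(sprintf("scanner_profile '%s': %.1f um/px, %s response, od = %.4g %+.4g * %s, max gray %d, noise sd %.3g\n",
              x$name, x$resolution_um, x$response, x$cal_a, x$cal_b,
              if (x$response == "linear") "g" else "log10(g)",
              x$max_gray, x$noise_sd))
  invisible(x)
}

#' Optical-density range representable by a scanner profile
#'
#' @param profile A [scanner_profile()].
#' @return Numeric `c(lo, hi)`: the OD interval spanned as the gray level
#'   runs over its valid range (gray 1 used as the lower gray bound for
#'   logarithmic responses).
#' @export
od_range <- function(profile) {
  g <- c(if (profile$response == "linear") 0 else 1, profile$max_gray)
  od <- switch(profile$response,
               linear = profile$cal_a + profile$cal_b * g,
               logarithmic = profile$cal_a + profile$cal_b * log10(g))
  sort(od)
}

#' Convert gray levels to optical densities
#'
#' Applies the profile's calibration curve elementwise so that images from
#' digitizers with different responses become comparable.  Gray 0 under a
#' logarithmic response is clamped to 1 before taking the logarithm.
#'
#' @param img Numeric matrix (or vector) of gray levels, or a `gray_image`.
#' @param profile A [scanner_profile()].
#' @return Numeric array of the same shape, in OD units.
#' @export
to_optical_density <- function(img, profile) {
  stopifnot(inherits(profile, "scanner_profile"))
  g <- if (inherits(img, "gray_image")) img$pixels else img
  if (any(g < 0)) stop("gray levels must be non-negative")
  switch(profile$response,
         linear = profile$cal_a + profile$cal_b * g,
         logarithmic = profile$cal_a + profile$cal_b * log10(pmax(g, 1)),
         stop("unknown scanner response: ", profile$response))
}

#' Digitize an optical-density image through a scanner profile
#'
#' Inverse of [to_optical_density()]: maps OD back to gray levels through
#' the inverse calibration curve, adds Gaussian gray-level noise of standard
#' deviation `profile$noise_sd`, clips to `[0, max_gray]` and rounds to
#' integers.  With `noise_sd = 0` the round trip
#' `to_optical_density(digitize(X))` recovers `X` to within half a
#' quantization step.
#'
#' @param od Numeric matrix of optical densities; every value must lie in
#'   [od_range()] of the profile.
#' @param profile A [scanner_profile()].
#' @param seed Integer seed for the noise stream.
#' @return A `gray_image`: list with integer matrix `pixels` and `max_gray`.
#' @export
digitize <- function(od, profile, seed = 1L) {
  stopifnot(inherits(profile, "scanner_profile"), is.numeric(od))
  rng <- od_range(profile)
  tol <- 1e-9 * max(1, abs(rng))
  if (any(od < rng[1] - tol[1] | od > rng[2] + tol[length(tol)]))
    stop("optical density outside the range representable by profile '",
         profile$name, "' [", signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  g <- switch(profile$response,
              linear = (od - profile$cal_a) / profile$cal_b,
              logarithmic = 10 ^ ((od - profile$cal_a) / profile$cal_b))
  if (profile$noise_sd > 0) {
    set.seed(seed)
    g <- g + stats::rnorm(length(g), sd = profile$noise_sd)
  }
  g <- round(pmin(pmax(g, 0), profile$max_gray))
  px <- matrix(as.integer(g), nrow = if (is.matrix(od)) nrow(od) else 1L)
  gray_image(px, profile$max_gray)
}

#' Gray-level image container
#'
#' @param pixels Non-negative integer matrix.
#' @param max_gray Maximum representable gray level.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, max_gray) {
  stopifnot(is.matrix(pixels), all(pixels >= 0), all(pixels <= max_gray))
  structure(list(pixels = pixels, max_gray = as.integer(max_gray)),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("gray_image %d x %d, max gray %d\n",
              nrow(x$pixels), ncol(x$pixels), x$max_gray))
  invisible(x)
}
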