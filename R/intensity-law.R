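#' Intensity-response law linking fluence rate to the photograviceptive number
#'
#' The balance between gravisensing and photosensing, expressed by the
#' photograviceptive number `M = beta / nu`, depends on the fluence rate `I`
#' of the incident light, `M = Phi(I)`. Two classical psychophysical forms
#' are supported:
#' \describe{
#'   \item{`stevens_power`}{`Phi_S(I) = a * I^b` with `a > 0`. The exponent
#'     `b` is stored signed; since brighter light strengthens photosensing and
#'     so lowers `M`, empirical exponents are negative, with magnitude around
#'     0.4 for oat coleoptiles.}
#'   \item{`weber_fechner_log`}{`Phi_F(I) = c + d * log(I)` (natural log),
#'     defined for `I > 0`; negative outputs are flagged invalid rather than
#'     clamped, since `M` must be nonnegative.}
#' }
#'
#' @param kind `"stevens_power"` or `"weber_fechner_log"`.
#' @param a,b Power-law coefficients (`a > 0`, `b` signed exponent).
#' @param c,d Log-law intercept and slope.
#' @return An object of class `intensity_law`.
#' @examples
#' law <- intensity_law("stevens_power", a = 1, b = -0.4)
#' intensity_to_M(100, law)
#' @export
intensity_law <- function(kind = c("stevens_power", "weber_fechner_log"),
                          a = NULL, b = NULL, c = NULL, d = NULL) {
  kind <- match.arg(kind)
  if (kind == "stevens_power") {
    stopifnot(is.numeric(a), is.finite(a), a > 0, is.numeric(b), is.finite(b))
    coef <- list(a = a, b = b)
  } else {
    stopifnot(is.numeric(c), is.finite(c), is.numeric(d), is.finite(d))
    coef <- list(c = c, d = d)
  }
  structure(list(kind = kind, coefficients = coef), class = "intensity_law")
}

#' @export
print.intensity_law <- function(x, ...) {
  cf <- x$coefficients
  if (x$kind == "stevens_power") {
    cat(sprintf("<intensity_law> Stevens power law: M(I) = %g * I^%g\n",
                cf$a, cf$b))
  } else {
    cat(sprintf("<intensity_law> Weber-Fechner log law: M(I) = %g + %g * log(I)\n",
                cf$c, cf$d))
  }
  invisible(x)
}

#' Evaluate an intensity law
#'
#' Maps fluence rates to photograviceptive numbers `M(I)`. Outputs that fall
#' below zero (possible for the Weber-Fechner form) are flagged invalid via
#' the `valid` attribute, not silently clamped.
#'
#' @param I Fluence rate(s), strictly positive (arbitrary units).
#' @param law An [intensity_law()].
#' @return Numeric vector of `M` values with a logical attribute `valid`.
#' @export
intensity_to_M <- function(I, law) {
  stopifnot(inherits(law, "intensity_law"))
  if (any(!is.finite(I)) || any(I <= 0)) {
    stop("fluence rate I must be finite and strictly positive")
  }
  cf <- law$coefficients
  M <- if (law$kind == "stevens_power") cf$a * I^cf$b else cf$c + cf$d * log(I)
  attr(M, "valid") <- M >= 0
  M
}

#' Invert an intensity law for the fluence rate
#'
#' Returns the fluence rate at which the law yields a target `M`. This is how
#' compensation experiments are emulated: tuning `I` until the organ holds
#' its initial tilt (`A_R = A0`) pins `M` at `A_P / A0 - 1`.
#'
#' @param law An [intensity_law()].
#' @param target_M Target photograviceptive number, > 0 and within the law's
#'   range. An infinite target (pure gravitropic alignment) is reported as an
#'   error for the power law only when unreachable (`b >= 0`).
#' @return Fluence rate `I` with `M(I) = target_M`.
#' @export
invert_law_for_intensity <- function(law, target_M) {
  stopifnot(inherits(law, "intensity_law"), is.numeric(target_M))
  if (any(!is.finite(target_M)) || any(target_M <= 0)) {
    stop("target M must be finite and strictly positive")
  }
  cf <- law$coefficients
  if (law$kind == "stevens_power") {
    if (cf$b == 0) stop("power law with zero exponent cannot be inverted")
    (target_M / cf$a)^(1 / cf$b)
  } else {
    if (cf$d == 0) stop("log law with zero slope cannot be inverted")
    exp((target_M - cf$c) / cf$d)
  }
}
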