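#' Sensitivities and geometry of a tropic organ
#'
#' Bundles the three perceptive sensitivities of the model family —
#' graviceptive `beta` (rad per rad per length per time), proprioceptive
#' `gamma` (1/time) and photoceptive `nu` (1/(length time)) — with the organ
#' geometry and the directions of the external fields.
#'
#' @param beta Graviceptive sensitivity, >= 0.
#' @param gamma Proprioceptive sensitivity, >= 0.
#' @param nu Photoceptive sensitivity, >= 0.
#' @param A0 Initial tilt of the (straight) organ from the vertical, radians.
#' @param A_P Direction of the collimated light beam, radians from vertical.
#' @param L Organ length, > 0.
#' @param L_gz Growth-zone length, in `(0, L]`; only the apical `L_gz` of the
#'   organ changes curvature. Defaults to `L` (whole organ responsive).
#' @param GSA Gravitropic set-point angle, radians (default 0,
#'   ortho-gravitropism). The `-beta * (A - GSA)` generalization is exposed
#'   but has not been validated against non-orthogravitropic organs.
#' @return An object of class `tropic_params`.
#' @examples
#' p <- tropic_params(beta = 2, gamma = 0.5, nu = 1, A0 = 0.5, A_P = pi / 2)
#' derived_numbers(p)
#' @export
tropic_params <- function(beta, gamma, nu = 0, A0 = 0, A_P = 0,
                          L = 1, L_gz = L, GSA = 0) {
  stopifnot(is.finite(beta), beta >= 0, is.finite(gamma), gamma >= 0,
            is.finite(nu), nu >= 0, is.finite(L), L > 0,
            is.finite(L_gz), L_gz > 0, L_gz <= L,
            is.finite(A0), is.finite(A_P), is.finite(GSA))
  structure(list(beta = beta, gamma = gamma, nu = nu, A0 = A0, A_P = A_P,
                 L = L, L_gz = L_gz, GSA = GSA),
            class = "tropic_params")
}

#' @export
print.tropic_params <- function(x, ...) {
  cat(sprintf(
    "<tropic_params> beta=%g gamma=%g nu=%g | A0=%g A_P=%g GSA=%g rad | L=%g L_gz=%g\n",
    x$beta, x$gamma, x$nu, x$A0, x$A_P, x$GSA, x$L, x$L_gz))
  invisible(x)
}

#' Dimensionless control numbers and derived scales
#'
#' Computes the quantities that control the dynamics and the steady-state
#' shape of the model family:
#' \describe{
#'   \item{B}{graviproprioceptive number, `beta * L_gz / gamma`;}
#'   \item{D}{photoproprioceptive number, `nu * L_gz / gamma`;}
#'   \item{M}{photograviceptive number, `beta / nu` (`Inf` when `nu = 0`;
#'     note `M * D = B` whenever `D > 0`);}
#'   \item{B_prime}{`B + D`, the single number driving the local
#'     photo-gravi-proprioceptive dynamics;}
#'   \item{A_R}{the photogravitropic set-point angle
#'     `A_P * nu / (nu + beta) = A_P / (1 + M)`, the direction the apex
#'     aligns with under the combined cues;}
#'   \item{T_c}{characteristic convergence time `1 / (gamma + nu * L_gz)`;}
#'   \item{L_c}{convergence length `L / B_prime`, the basal length over
#'     which curvature persists at steady state.}
#' }
#'
#' @param params A [tropic_params()].
#' @return A list of class `derived_numbers` with elements
#'   `B`, `D`, `M`, `B_prime`, `A_R`, `T_c`, `L_c`.
#' @export
derived_numbers <- function(params) {
  stopifnot(inherits(params, "tropic_params"))
  p <- params
  # gamma = 0 yields Inf markers for B and D (the no-steady-state limit)
  # rather than an error, so limit-case analyses can still query A_R and T_c
  B <- if (p$gamma > 0) p$beta * p$L_gz / p$gamma else if (p$beta > 0) Inf else 0
  D <- if (p$gamma > 0) p$nu * p$L_gz / p$gamma else if (p$nu > 0) Inf else 0
  M <- if (p$nu > 0) p$beta / p$nu else if (p$beta > 0) Inf else NaN
  if (p$beta + p$nu > 0) {
    A_R <- p$A_P * p$nu / (p$nu + p$beta)
  } else {
    stop("A_R is undefined when beta = nu = 0 (no directional cue)")
  }
  denom_t <- p$gamma + p$nu * p$L_gz
  T_c <- if (denom_t > 0) 1 / denom_t else Inf
  B_prime <- B + D
  L_c <- if (is.finite(B_prime) && B_prime > 0) p$L / B_prime else
    if (B_prime == 0) Inf else 0
  structure(list(B = B, D = D, M = M, B_prime = B_prime, A_R = A_R,
                 T_c = T_c, L_c = L_c),
            class = "derived_numbers")
}

#' @export
print.derived_numbers <- function(x, ...) {
  cat(sprintf(
    "<derived_numbers> B=%g D=%g M=%g B'=%g | A_R=%g rad | T_c=%g L_c=%g\n",
    x$B, x$D, x$M, x$B_prime, x$A_R, x$T_c, x$L_c))
  invisible(x)
}

#' Characteristic time, convergence length and steady tip angle
#'
#' Convenience summary of the scales governing convergence of the local
#' photo-gravi-proprioceptive dynamics: the characteristic time
#' `T_c = 1 / (gamma + nu * L_gz)`, the convergence length `L_c = L / (B + D)`
#' and the closed-form steady apical angle
#' `(A0 - A_R) * exp(-(B + D)) + A_R`. The flag `tip_near_AR` reports whether
#' `exp(-(B + D)) < 0.01`, i.e. whether the steady tip angle is
#' indistinguishable from the set-point angle `A_R` at experimental accuracy.
#'
#' @inheritParams derived_numbers
#' @return A list with `T_c`, `L_c`, `tip_limit` and `tip_near_AR`.
#' @export
characteristic_quantities <- function(params) {
  dn <- derived_numbers(params)
  if (!is.finite(dn$T_c) && params$gamma + params$nu * params$L_gz <= 0) {
    stop("characteristic time undefined: gamma and nu are both zero")
  }
  expBD <- exp(-dn$B_prime)
  list(T_c = dn$T_c, L_c = dn$L_c,
       tip_limit = (params$A0 - dn$A_R) * expBD + dn$A_R,
       tip_near_AR = is.finite(expBD) && expBD < 0.01)
}
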