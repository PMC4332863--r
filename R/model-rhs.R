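#' Model variants
#'
#' @description
#' Four linear variants describe the local curvature rate of change of a
#' tropically responding organ, differing in which cues are sensed and where
#' light is perceived:
#'
#' \describe{
#'   \item{`AC`}{graviproprioceptive:
#'     `dC/dt = -beta (A(s) - GSA) - gamma C(s)`;}
#'   \item{`AaC`}{apical photoproprioceptive:
#'     `dC/dt = -nu (A(L) - A_P) - gamma C(s)`;}
#'   \item{`ARC`}{local photo-gravi-proprioceptive:
#'     `dC/dt = -beta (A(s) - GSA) - nu (A(s) - A_P) - gamma C(s)`;}
#'   \item{`ARaC`}{apical-photoception photo-gravi-proprioceptive:
#'     `dC/dt = -beta (A(s) - GSA) - nu (A(L) - A_P) - gamma C(s)`.}
#' }
#'
#' The rate is zero outside the growth zone (`s < L - L_gz`). The sensing
#' terms are the first-order (small-angle) linearizations of the Lambert
#' cosine dependence on the angle between organ and field; the optional
#' `sine_law` mode keeps the full `sin(A - GSA)` / `sin(A - A_P)` dependence,
#' which matters for initial tilts beyond 90 degrees where the linear model
#' is documented to break down.
#'
#' @param variant One of `"AC"`, `"AaC"`, `"ARC"`, `"ARaC"`.
#' @param shape An [organ_shape()] on the params' length.
#' @param params A [tropic_params()].
#' @param sine_law Logical; use the full sine dependence instead of its
#'   small-angle linearization (default `FALSE`, as in the closed forms).
#' @param apical_angle Optional override for the perceived apical angle
#'   `A(L)`, used by the finite-propagation-time simulator; by default the
#'   instantaneous tip angle of `shape`.
#' @return Numeric vector: `dC/dt` at every grid node.
#' @examples
#' p <- tropic_params(beta = 2, gamma = 1, nu = 1, A0 = 0.3, A_P = pi / 2)
#' sh <- organ_shape(seq(0, 1, length.out = 11),
#'                   angle = rep(0.3, 11), curvature = rep(0, 11))
#' model_rhs("ARaC", sh, p)
#' @export
model_rhs <- function(variant, shape, params, sine_law = FALSE,
                      apical_angle = NULL) {
  variant <- check_variant(variant)
  stopifnot(inherits(shape, "organ_shape"), inherits(params, "tropic_params"))
  if (abs(shape$L - params$L) > 1e-9 * params$L) {
    stop("shape length does not match the parameter set's organ length L")
  }
  A <- shape$angle
  C <- shape$curvature
  if (is.null(apical_angle)) apical_angle <- A[length(A)]
  ang <- if (sine_law) function(x) sin(x) else function(x) x
  p <- params
  rate <- switch(variant,
    AC   = -p$beta * ang(A - p$GSA) - p$gamma * C,
    AaC  = -p$nu * ang(apical_angle - p$A_P) - p$gamma * C,
    ARC  = -p$beta * ang(A - p$GSA) - p$nu * ang(A - p$A_P) - p$gamma * C,
    ARaC = -p$beta * ang(A - p$GSA) - p$nu * ang(apical_angle - p$A_P) -
      p$gamma * C)
  rate * growth_zone_mask(shape$s, p)
}

check_variant <- function(variant) {
  if (!is.character(variant) || length(variant) != 1 ||
      !variant %in% c("AC", "AaC", "ARC", "ARaC")) {
    stop("unknown model variant; use one of \"AC\", \"AaC\", \"ARC\", \"ARaC\"")
  }
  variant
}

# 1 where the organ responds (apical growth zone, inclusive of its basal
# boundary so the whole organ is active when L_gz = L), 0 elsewhere
growth_zone_mask <- function(s, params) {
  as.numeric(s >= params$L - params$L_gz - 1e-12 * params$L)
}

#' Mirror a shape, kinematics or parameter set through the vertical
#'
#' The model family is equivariant under reflection through the gravity axis:
#' negating the angle and curvature fields together with the angular
#' parameters (`A0`, `A_P`, `GSA`) yields an equally valid trajectory, and
#' [model_rhs()] commutes with the transform. Applying it twice is the
#' identity.
#'
#' @param x An [organ_shape()], a [tropic_params()], or a `kinematics`
#'   object (see [simulate_tropism()]).
#' @return The mirrored object, same class as the input.
#' @export
symmetry_transform <- function(x) {
  if (inherits(x, "tropic_params")) {
    x$A0 <- -x$A0
    x$A_P <- -x$A_P
    x$GSA <- -x$GSA
    return(x)
  }
  if (inherits(x, "organ_shape")) {
    x$angle <- -x$angle
    x$curvature <- -x$curvature
    return(x)
  }
  if (inherits(x, "kinematics")) {
    x$A <- -x$A
    x$C <- -x$C
    x$params <- symmetry_transform(x$params)
    return(x)
  }
  stop("symmetry_transform: unsupported object of class ", class(x)[1])
}
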