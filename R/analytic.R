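#' Closed-form transient of the apical photoproprioceptive (AaC) model
#'
#' With apical photoception the curvature field is spatially uniform at all
#' times, so the organ is an arc of a circle and the dynamics admit a closed
#' form. For a straight organ tilted at `A0` under zenithal light
#' (`A_P = 0`):
#' `A(s, t) = A0 * (1 - (s/L) * k * (1 - exp(-(nu L + gamma) t)))` and
#' `C(t) = -(A0 / L) * k * (1 - exp(-(nu L + gamma) t))`, with
#' `k = 1 / (1 + gamma / (nu L)) = D / (1 + D)`. For a general light
#' direction the same form applies to the offset angle `A - A_P`.
#'
#' Requires the whole organ to be responsive (`L_gz = L`), the regime in
#' which the closed form is derived.
#'
#' @param params A [tropic_params()] (only `gamma`, `nu`, `A0`, `A_P`, `L`
#'   are used; `beta` must be 0 for the formula to be the exact solution).
#' @param s Arc-length positions (vector).
#' @param t Times (vector).
#' @return A list with matrices `angle` and `curvature`, of dimension
#'   `length(s)` by `length(t)`.
#' @export
aac_transient <- function(params, s, t) {
  p <- params
  stopifnot(inherits(p, "tropic_params"), all(s >= 0), all(s <= p$L + 1e-12),
            all(t >= 0))
  require_full_growth_zone(p)
  r <- p$nu * p$L + p$gamma
  if (r <= 0) stop("aac_transient requires gamma + nu * L > 0")
  k <- p$nu * p$L / r                      # D / (1 + D)
  amp <- (p$A0 - p$A_P) * k                # offset amplitude
  relax <- 1 - exp(-r * t)                 # length(t)
  angle <- p$A0 - outer(s / p$L, relax) * amp
  curvature <- matrix(rep(-amp / p$L * relax, each = length(s)),
                      nrow = length(s))
  list(angle = angle, curvature = curvature)
}

require_full_growth_zone <- function(p) {
  if (abs(p$L_gz - p$L) > 1e-12 * p$L) {
    stop("closed-form solutions assume a fully responsive organ (L_gz = L)")
  }
  invisible(p)
}

#' Closed-form steady-state shape of a model variant
#'
#' Steady states of the four variants (requiring `L_gz = L`):
#' \describe{
#'   \item{AC}{`A(s) = (A0 - GSA) exp(-beta s / gamma) + GSA` — no steady
#'     state when `gamma = 0` (the organ oscillates indefinitely);}
#'   \item{ARC}{`A(s) = (A0 - A_R) exp(-(beta + nu) s / gamma) + A_R`;}
#'   \item{AaC}{uniform curvature
#'     `C = -(A0 - A_P) D / ((1 + D) L)`, a linear angle profile with tip
#'     angle `(A0 + D A_P) / (1 + D)`; exists even at `gamma = 0`;}
#'   \item{ARaC}{`A(s) = A0' (e^{-Bs/L} - e^{-B} (1 - e^{-Bs/L}) /
#'     (M + 1 - e^{-B})) + A_R` with `A0' = A0 - A_R`, and curvature
#'     `C(s) = -A0' (B/L) e^{-Bs/L} (1 + e^{-B} / (M + 1 - e^{-B}))`.}
#' }
#' Here `A_R` generalizes to `(beta GSA + nu A_P) / (beta + nu)` when a
#' non-zero gravitropic set-point angle is used.
#'
#' @param variant Model variant.
#' @param params A [tropic_params()].
#' @param s_grid Arc-length grid for the returned shape; default 201 nodes.
#' @return An [organ_shape()].
#' @export
steady_state <- function(variant, params, s_grid = NULL) {
  variant <- check_variant(variant)
  p <- params
  stopifnot(inherits(p, "tropic_params"))
  require_full_growth_zone(p)
  if (is.null(s_grid)) s_grid <- seq(0, p$L, length.out = 201)
  check_grid(s_grid)
  s <- s_grid
  if (variant %in% c("AC", "ARC", "ARaC") && p$gamma <= 0) {
    stop("no steady state: with gamma = 0 the ", variant,
         " model oscillates indefinitely")
  }
  if (variant == "AC") {
    rate <- p$beta / p$gamma
    A <- (p$A0 - p$GSA) * exp(-rate * s) + p$GSA
    C <- -(p$A0 - p$GSA) * rate * exp(-rate * s)
    return(organ_shape(s, angle = A, curvature = C))
  }
  if (variant == "ARC") {
    if (p$beta + p$nu <= 0) stop("ARC steady state needs beta + nu > 0")
    A_R <- (p$beta * p$GSA + p$nu * p$A_P) / (p$beta + p$nu)
    rate <- (p$beta + p$nu) / p$gamma
    A <- (p$A0 - A_R) * exp(-rate * s) + A_R
    C <- -(p$A0 - A_R) * rate * exp(-rate * s)
    return(organ_shape(s, angle = A, curvature = C))
  }
  if (variant == "AaC") {
    r <- p$gamma + p$nu * p$L
    if (r <= 0 || p$nu <= 0) stop("AaC steady state needs nu > 0")
    cc <- -p$nu * (p$A0 - p$A_P) / r
    A <- p$A0 + cc * s
    C <- rep(cc, length(s))
    return(organ_shape(s, angle = A, curvature = C))
  }
  # ARaC
  if (p$beta + p$nu <= 0) stop("ARaC steady state needs beta + nu > 0")
  A_R <- (p$beta * p$GSA + p$nu * p$A_P) / (p$beta + p$nu)
  B <- p$beta * p$L / p$gamma
  M <- if (p$nu > 0) p$beta / p$nu else Inf
  A0p <- p$A0 - A_R
  if (B < 1e-9) {
    # proprioception-dominated limit: the apical photoproprioceptive shape
    D <- p$nu * p$L / p$gamma
    cc <- -(A0p / p$L) * D / (1 + D)
    A <- p$A0 + cc * s
    C <- rep(cc, length(s))
    return(organ_shape(s, angle = A, curvature = C))
  }
  eB <- exp(-B)
  es <- exp(-B * s / p$L)
  denom <- M + 1 - eB
  A <- A0p * (es - eB * (1 - es) / denom) + A_R
  C <- -A0p * (B / p$L) * es * (1 + eB / denom)
  organ_shape(s, angle = A, curvature = C)
}

#' Limit-case steady shapes of the apical photo-gravi-proprioceptive model
#'
#' The steady state of the `ARaC` model is controlled by the two numbers `B`
#' (graviception vs proprioception) and `M` (graviception vs photoception);
#' four limits organize its behavior:
#' \describe{
#'   \item{`B_inf`}{graviception dominates proprioception — no steady state
#'     (the organ oscillates indefinitely); returned as a marker, not an
#'     error;}
#'   \item{`B_zero`}{proprioception dominates — the arc-of-circle AaC steady
#'     shape with `A_R = A_P`;}
#'   \item{`M_inf`}{graviception dominates photoception — the pure
#'     graviproprioceptive profile `A(s) = A0 exp(-B s / L)`;}
#'   \item{`M_zero`}{photoception dominates — the tip aligns exactly with
#'     the light (`A(L) = A_P`) but the curvature distribution stays under
#'     graviproprioceptive control:
#'     `A(s) = A0' (e^{-Bs/L} - (1 - e^{-Bs/L}) / (e^B - 1)) + A_P`,
#'     `C(s) = -A0' (B/L) e^{-Bs/L} / (1 - e^{-B})`, `A0' = A0 - A_P`.}
#' }
#'
#' @param case One of `"B_inf"`, `"B_zero"`, `"M_inf"`, `"M_zero"`.
#' @param params A [tropic_params()].
#' @param s_grid Arc-length grid (default 201 nodes over `[0, L]`).
#' @return An [organ_shape()], or for `"B_inf"` a list with
#'   `status = "no_steady_state"`.
#' @export
limit_case_shape <- function(case = c("B_inf", "B_zero", "M_inf", "M_zero"),
                             params, s_grid = NULL) {
  case <- match.arg(case)
  p <- params
  stopifnot(inherits(p, "tropic_params"))
  require_full_growth_zone(p)
  if (is.null(s_grid)) s_grid <- seq(0, p$L, length.out = 201)
  check_grid(s_grid)
  s <- s_grid
  if (case == "B_inf") {
    return(list(status = "no_steady_state",
                reason = "graviception dominates proprioception: the organ oscillates indefinitely"))
  }
  if (case == "B_zero") {
    if (p$nu <= 0) stop("B_zero limit requires photoception (nu > 0)")
    pp <- p
    pp$beta <- 0
    return(steady_state("AaC", pp, s))
  }
  if (p$gamma <= 0) stop("limit shapes with gravisensing require gamma > 0")
  if (p$beta <= 0) {
    stop("the ", case, " limit keeps graviproprioceptive shape control ",
         "and requires beta > 0")
  }
  B <- p$beta * p$L / p$gamma
  if (case == "M_inf") {
    A <- (p$A0 - p$GSA) * exp(-B * s / p$L) + p$GSA
    C <- -(p$A0 - p$GSA) * (B / p$L) * exp(-B * s / p$L)
    return(organ_shape(s, angle = A, curvature = C))
  }
  # M_zero: photoception dominates, A_R = A_P, tip exactly at the light
  if (p$nu <= 0) {
    stop("M_zero limit contradicts nu = 0 (photoception must dominate)")
  }
  A0p <- p$A0 - p$A_P
  eB <- exp(-B)
  es <- exp(-B * s / p$L)
  A <- A0p * (es - (1 - es) * eB / (1 - eB)) + p$A_P
  C <- -A0p * (B / p$L) * es / (1 - eB)
  organ_shape(s, angle = A, curvature = C)
}
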