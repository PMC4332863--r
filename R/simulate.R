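#' Simulate tropic movement of a clamped, initially straight organ
#'
#' Integrates a model variant (see [model_rhs()]) in time by the method of
#' lines: the curvature field is the dynamical state, advanced with a
#' classical fixed-step RK4 scheme, and the angle field is recomputed from
#' the curvature at every stage by trapezoid integration from the clamped
#' base (`A(0, t) = A0`). The initial condition is a straight tilted organ,
#' `A(s, 0) = A0`, `C(s, 0) = 0`.
#'
#' Because the linearized models are linear time-invariant in the curvature
#' field, an exact matrix-exponential stepper (`method = "expm"`) is provided
#' as an independent cross-check of the RK4 integrator.
#'
#' @param variant Model variant, one of `"AC"`, `"AaC"`, `"ARC"`, `"ARaC"`.
#' @param params A [tropic_params()].
#' @param t_end End time of the simulation, > 0.
#' @param dt Time step; default `0.05 / (gamma + (beta + nu) * L_gz)`, a
#'   conservative fraction of the fastest relaxation scale. The step is
#'   shrunk slightly so that `t_end` is hit exactly.
#' @param n_nodes Number of arc-length grid nodes (default 201).
#' @param output_every Store every `output_every`-th step (plus the initial
#'   and final states). `NULL` (default) auto-thins to at most ~400 slices.
#' @param method `"rk4"` (default) or `"expm"` (exact linear stepper; not
#'   available with `sine_law` or a propagation delay).
#' @param sine_law Keep the full sine angular dependence (see [model_rhs()]).
#' @return A `kinematics` object: list with `t` (output times), `s` (grid),
#'   `A` and `C` (node-by-time matrices), `params`, `variant`, and solver
#'   metadata (`dt`, `method`, `T_B`, `sine_law`).
#' @examples
#' p <- tropic_params(beta = 0, gamma = 1, nu = 4, A0 = 0.5, A_P = 0)
#' kin <- simulate_tropism("AaC", p, t_end = 1)
#' tail(tip_angle_series(kin), 1)
#' @export
simulate_tropism <- function(variant, params, t_end, dt = NULL,
                             n_nodes = 201, output_every = NULL,
                             method = c("rk4", "expm"), sine_law = FALSE) {
  method <- match.arg(method)
  sim_engine(variant, params, t_end, dt = dt, n_nodes = n_nodes,
             output_every = output_every, method = method,
             sine_law = sine_law, T_B = 0)
}

#' Simulate apical-photoception variants with a finite signal-propagation time
#'
#' The apical models assume the basipetal signal carrying the tip orientation
#' is instantaneous. This variant relaxes that: the apical term at position
#' `s` and time `t` uses the tip angle `A(L, t - T_B * (L - s) / L)`, i.e.
#' the signal travels from apex to base in time `T_B` with a linear
#' apex-to-base delay profile, and contributes nothing before it first
#' arrives at `s`. With `T_B = 0` the trajectory is identical (bitwise, same
#' stepper) to [simulate_tropism()].
#'
#' @inheritParams simulate_tropism
#' @param variant `"AaC"` or `"ARaC"` (the variants with apical photoception).
#' @param T_B Apex-to-base propagation time, >= 0. Compare it to the movement
#'   time `T_c` (see [characteristic_quantities()]): for `T_B / T_c` well
#'   below 1 the instantaneous approximation is accurate.
#' @return A `kinematics` object (see [simulate_tropism()]).
#' @export
simulate_with_propagation <- function(variant, params, t_end, T_B,
                                      dt = NULL, n_nodes = 201,
                                      output_every = NULL, sine_law = FALSE) {
  variant <- check_variant(variant)
  if (!variant %in% c("AaC", "ARaC")) {
    stop("propagation delay applies to the apical-photoception variants ",
         "\"AaC\" and \"ARaC\" only")
  }
  if (!is.finite(T_B) || T_B < 0) stop("propagation time T_B must be >= 0")
  sim_engine(variant, params, t_end, dt = dt, n_nodes = n_nodes,
             output_every = output_every, method = "rk4",
             sine_law = sine_law, T_B = T_B)
}

# shared fixed-step engine; T_B = 0 reduces exactly to the instantaneous model
sim_engine <- function(variant, params, t_end, dt, n_nodes, output_every,
                       method, sine_law, T_B) {
  variant <- check_variant(variant)
  stopifnot(inherits(params, "tropic_params"), is.finite(t_end), t_end > 0)
  p <- params
  s <- seq(0, p$L, length.out = n_nodes)
  mask <- growth_zone_mask(s, p)
  rate_scale <- p$gamma + (p$beta + p$nu) * p$L_gz
  if (is.null(dt)) dt <- if (rate_scale > 0) 0.05 / rate_scale else t_end / 100
  n_steps <- max(1L, as.integer(ceiling(t_end / dt - 1e-9)))
  dt <- t_end / n_steps
  if (is.null(output_every)) output_every <- max(1L, ceiling(n_steps / 400))
  out_idx <- unique(c(seq(0L, n_steps, by = output_every), n_steps))

  if (method == "expm") {
    if (sine_law || T_B > 0) {
      stop("the matrix-exponential stepper handles the linear, ",
           "instantaneous-signal models only")
    }
    return(sim_expm(variant, p, s, mask, dt, n_steps, out_idx))
  }

  h <- diff(s)
  angles_of <- function(C) {
    p$A0 + c(0, cumsum(h * (C[-n_nodes] + C[-1]) / 2))
  }
  ang <- if (sine_law) function(x) sin(x) else function(x) x
  apical <- variant %in% c("AaC", "ARaC")
  tau <- T_B * (p$L - s) / p$L
  hist_t <- numeric(n_steps + 1L)
  hist_a <- numeric(n_steps + 1L)
  hist_a[1L] <- p$A0
  n_hist <- 1L

  # tip-angle signal perceived at each node at stage time `tq`; zero weight
  # before first arrival of the basipetal signal
  apex_signal <- function(tq, aL_stage) {
    if (T_B == 0) {
      return(list(a = aL_stage, w = 1))
    }
    q <- tq - tau
    a <- numeric(length(q))
    w <- as.numeric(q >= 0)
    tlast <- hist_t[n_hist]
    past <- q >= 0 & q <= tlast
    if (any(past)) {
      a[past] <- if (n_hist < 2L) hist_a[1L] else
        stats::approx(hist_t[seq_len(n_hist)], hist_a[seq_len(n_hist)],
                      xout = q[past], rule = 2, ties = "ordered")$y
    }
    ahead <- q > tlast
    if (any(ahead)) {
      # within the step being built: blend the last accepted tip angle with
      # the current stage estimate
      frac <- if (tq > tlast) (q[ahead] - tlast) / (tq - tlast) else 1
      a[ahead] <- hist_a[n_hist] + frac * (aL_stage - hist_a[n_hist])
    }
    list(a = a, w = w)
  }

  deriv <- function(C, tq) {
    A <- angles_of(C)
    aL <- A[n_nodes]
    rate <- -p$gamma * C
    if (variant %in% c("AC", "ARC", "ARaC")) {
      rate <- rate - p$beta * ang(A - p$GSA)
    }
    if (variant == "ARC") rate <- rate - p$nu * ang(A - p$A_P)
    if (apical) {
      sig <- apex_signal(tq, aL)
      rate <- rate - p$nu * ang(sig$a - p$A_P) * sig$w
    }
    rate * mask
  }

  C <- numeric(n_nodes)
  lim <- 1e4 * (abs(p$A0) + abs(p$A_P) + abs(p$GSA) + 1) *
    max(1, rate_scale) / p$L
  n_out <- length(out_idx)
  A_out <- matrix(NA_real_, n_nodes, n_out)
  C_out <- matrix(NA_real_, n_nodes, n_out)
  t_out <- out_idx * dt
  slot <- 1L
  if (out_idx[1L] == 0L) {
    A_out[, 1L] <- angles_of(C)
    C_out[, 1L] <- C
    slot <- 2L
  }
  for (k in seq_len(n_steps)) {
    t0 <- (k - 1L) * dt
    k1 <- deriv(C, t0)
    k2 <- deriv(C + dt / 2 * k1, t0 + dt / 2)
    k3 <- deriv(C + dt / 2 * k2, t0 + dt / 2)
    k4 <- deriv(C + dt * k3, t0 + dt)
    C <- C + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(C)) || max(abs(C)) > lim) {
      stop("numerical instability detected (curvature energy growth); ",
           "reduce the time step dt")
    }
    A <- angles_of(C)
    n_hist <- n_hist + 1L
    hist_t[n_hist] <- k * dt
    hist_a[n_hist] <- A[n_nodes]
    if (slot <= n_out && out_idx[slot] == k) {
      A_out[, slot] <- A
      C_out[, slot] <- C
      slot <- slot + 1L
    }
  }
  new_kinematics(t_out, s, A_out, C_out, p, variant,
                 dt = dt, method = "rk4", T_B = T_B, sine_law = sine_law)
}

# exact stepper for the linear time-invariant system: the curvature state
# obeys dC/dt = M C + b with A = A0 + W C (trapezoid weights W); one matrix
# exponential per output interval, propagated by repeated multiplication
sim_expm <- function(variant, p, s, mask, dt, n_steps, out_idx) {
  n <- length(s)
  h <- diff(s)
  W <- matrix(0, n, n)
  for (i in 2:n) {
    w <- numeric(n)
    hh <- h[seq_len(i - 1L)]
    w[seq_len(i - 1L)] <- w[seq_len(i - 1L)] + hh / 2
    w[2:i] <- w[2:i] + hh / 2
    W[i, ] <- w
  }
  eL <- W[n, , drop = FALSE]  # row mapping C to A(L) - A0
  one <- rep(1, n)
  Mm <- -p$gamma * diag(n)
  bb <- numeric(n)
  if (variant %in% c("AC", "ARC", "ARaC")) {
    Mm <- Mm - p$beta * W
    bb <- bb - p$beta * (p$A0 - p$GSA) * one
  }
  if (variant == "ARC") {
    Mm <- Mm - p$nu * W
    bb <- bb - p$nu * (p$A0 - p$A_P) * one
  }
  if (variant %in% c("AaC", "ARaC")) {
    Mm <- Mm - p$nu * one %*% eL
    bb <- bb - p$nu * (p$A0 - p$A_P) * one
  }
  Mm <- Mm * mask
  bb <- bb * mask
  G <- rbind(cbind(Mm, bb), 0)
  t_out <- out_idx * dt
  # uniform spacing except possibly the last interval
  state <- c(numeric(n), 1)
  n_out <- length(t_out)
  A_out <- matrix(NA_real_, n, n_out)
  C_out <- matrix(NA_real_, n, n_out)
  angles_of <- function(C) p$A0 + as.vector(W %*% C)
  prev_t <- 0
  E_cache <- list()
  for (j in seq_len(n_out)) {
    step <- t_out[j] - prev_t
    if (step > 0) {
      key <- sprintf("%.15g", step)
      if (is.null(E_cache[[key]])) {
        E_cache[[key]] <- as.matrix(Matrix::expm(G * step))
      }
      state <- as.vector(E_cache[[key]] %*% state)
      prev_t <- t_out[j]
    }
    C_out[, j] <- state[seq_len(n)]
    A_out[, j] <- angles_of(C_out[, j])
  }
  new_kinematics(t_out, s, A_out, C_out, p, variant,
                 dt = dt, method = "expm", T_B = 0, sine_law = FALSE)
}

new_kinematics <- function(t, s, A, C, params, variant, dt, method,
                           T_B = 0, sine_law = FALSE, seed = NULL,
                           noise_sigma = NULL, truth = NULL) {
  structure(list(t = t, s = s, A = A, C = C, params = params,
                 variant = variant, dt = dt, method = method, T_B = T_B,
                 sine_law = sine_law, seed = seed, noise_sigma = noise_sigma,
                 truth = truth),
            class = "kinematics")
}

#' @export
print.kinematics <- function(x, ...) {
  cat(sprintf(
    "<kinematics> %s model: %d nodes x %d times, t in [0, %g] (%s, dt = %g)\n",
    x$variant, length(x$s), length(x$t), max(x$t), x$method, x$dt))
  invisible(x)
}

# curvature-rate field of a stored time slice, reusing the model definitions
kin_slice_rate <- function(kin, j) {
  sh <- slice_shape(kin, j)
  model_rhs(kin$variant, sh, kin$params, sine_law = kin$sine_law)
}

#' Extract one time slice of a kinematics object as an organ shape
#'
#' @param kin A `kinematics` object.
#' @param j Time index (column), defaulting to the final slice.
#' @return An [organ_shape()].
#' @export
slice_shape <- function(kin, j = length(kin$t)) {
  structure(list(s = kin$s, angle = kin$A[, j], curvature = kin$C[, j],
                 L = kin$s[length(kin$s)]),
            class = "organ_shape")
}

#' Detect the steady state of a simulated trajectory
#'
#' Scans the stored time slices for the earliest time at which the curvature
#' rate of change is negligible:
#' `max_s |dC/dt| < rel_tol * (gamma + nu * L_gz) * max(|A0 - A_R|, eps)`.
#' The rate scale `gamma + nu * L_gz` reduces to the proprioceptive rate
#' `gamma` for the purely local models and keeps the criterion meaningful
#' for apical photoception with weak proprioception (`gamma -> 0`), where a
#' steady state genuinely exists.
#'
#' Non-convergence within the simulated window is a first-class result (the
#' graviception-dominated limit oscillates indefinitely), reported through
#' `converged = FALSE`, not an error.
#'
#' @param kin A `kinematics` object.
#' @param rel_tol Relative tolerance of the rate criterion (default 1e-3).
#' @return A list with `converged`, `t_steady` (`NA` if not converged),
#'   `shape` (the steady or final [organ_shape()]), `index` and `status`.
#' @export
detect_steady_state <- function(kin, rel_tol = 1e-3) {
  stopifnot(inherits(kin, "kinematics"))
  p <- kin$params
  A_R <- if (p$beta + p$nu > 0) {
    (p$beta * p$GSA + p$nu * p$A_P) / (p$beta + p$nu)
  } else {
    p$GSA
  }
  thr <- rel_tol * (p$gamma + p$nu * p$L_gz) * max(abs(p$A0 - A_R), 1e-8)
  for (j in seq_along(kin$t)) {
    if (max(abs(kin_slice_rate(kin, j))) < thr) {
      return(list(converged = TRUE, t_steady = kin$t[j],
                  shape = slice_shape(kin, j), index = j,
                  status = "converged"))
    }
  }
  list(converged = FALSE, t_steady = NA_real_,
       shape = slice_shape(kin, length(kin$t)), index = length(kin$t),
       status = "not_converged")
}

#' Apical (tip) angle time series
#'
#' @param kin A `kinematics` object.
#' @return A data frame with columns `t` and `tip_angle` (radians), the organ
#'   orientation at `s = L` at each stored time.
#' @export
tip_angle_series <- function(kin) {
  stopifnot(inherits(kin, "kinematics"))
  data.frame(t = kin$t, tip_angle = kin$A[nrow(kin$A), ])
}
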