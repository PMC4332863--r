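#' Specification of a synthetic photogravitropic-equilibrium experiment
#'
#' Describes the design of an emulated tilted-coleoptile equilibrium
#' experiment with known ground truth. The defaults mirror the classical
#' design the package is meant to analyze: initial tilts of 0, 10, 30, 90
#' and 120 degrees (the 120-degree rows exist to exercise the beyond-90
#' exclusion logic), light held perpendicular to the initial orientation
#' (`A_P = A0 + pi/2`), a fluence-rate grid spanning five decades, 15
#' replicates per condition, and Gaussian measurement noise on the tip
#' angle (where measurement error lives), not on `M`.
#'
#' Two protocols are supported: `PROT1` measures the equilibrium tip angle
#' over the full `A0 x I` grid; `PROT2` tunes the fluence rate per tilt so
#' that the organ holds its initial angle (`A_R = A0`), which pins
#' `M* = A_P / A0 - 1` and records the compensating intensity.
#'
#' @param protocol `"PROT1"` or `"PROT2"`.
#' @param A0 Initial tilt angles, radians.
#' @param I Fluence-rate grid (arbitrary units, > 0).
#' @param law True [intensity_law()] linking `I` to `M`.
#' @param sigma Gaussian noise s.d. on the measured tip angle, radians
#'   (default 2 degrees, a calibration choice for plausible goniometer
#'   error).
#' @param intensity_jitter Multiplicative log-normal jitter s.d. on the
#'   delivered intensity (default 0).
#' @param replicates Replicates per condition (default 15).
#' @param seed RNG seed recorded in every output.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(protocol = c("PROT1", "PROT2"),
                           A0 = c(0, 10, 30, 90, 120) * pi / 180,
                           I = 10^seq(-2, 3, length.out = 12),
                           law = intensity_law("stevens_power",
                                               a = 1, b = -0.4),
                           sigma = 2 * pi / 180,
                           intensity_jitter = 0,
                           replicates = 15,
                           seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(all(is.finite(A0)), all(I > 0), inherits(law, "intensity_law"),
            is.finite(sigma), sigma >= 0, intensity_jitter >= 0,
            replicates >= 1)
  structure(list(protocol = protocol, A0 = A0, I = I, law = law,
                 sigma = sigma, intensity_jitter = intensity_jitter,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a synthetic photogravitropic-equilibrium dataset
#'
#' For `PROT1`, each `(A0, I, replicate)` condition yields a record with
#' `A_P = A0 + pi/2`, true equilibrium tip angle `A_P / (1 + M(I))` and
#' observed tip angle `true + N(0, sigma^2)`. For `PROT2`, each tilt
#' `A0 != 0` yields replicates of the compensation experiment: the intensity
#' solving `M(I) = A_P / A0 - 1` is recorded together with a tip angle of
#' `A0` plus noise (tilts of zero are skipped with a warning — the
#' compensating intensity is infinite).
#'
#' @param spec A [generator_spec()].
#' @return A data frame with columns `protocol`, `A0`, `A_P`, `I`,
#'   `tip_angle`, `replicate` (angles in radians), carrying the generating
#'   spec (ground truth, seed included) as attribute `"truth"`.
#' @export
generate_pgea_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  rows <- list()
  if (spec$protocol == "PROT1") {
    grid <- expand.grid(rep = seq_len(spec$replicates), I = spec$I,
                        A0 = spec$A0)
    A_P <- grid$A0 + pi / 2
    I_del <- grid$I
    if (spec$intensity_jitter > 0) {
      I_del <- I_del * exp(stats::rnorm(nrow(grid), 0, spec$intensity_jitter))
    }
    M <- as.numeric(intensity_to_M(I_del, spec$law))
    tip_true <- A_P / (1 + M)
    tip_obs <- tip_true + stats::rnorm(nrow(grid), 0, spec$sigma)
    out <- data.frame(protocol = "PROT1", A0 = grid$A0, A_P = A_P,
                      I = I_del, tip_angle = tip_obs,
                      replicate = grid$rep, stringsAsFactors = FALSE)
  } else {
    A0 <- spec$A0
    if (any(A0 == 0)) {
      warning("PROT2: skipping A0 = 0 (compensating intensity is infinite)")
      A0 <- A0[A0 != 0]
    }
    grid <- expand.grid(rep = seq_len(spec$replicates), A0 = A0)
    A_P <- grid$A0 + pi / 2
    target <- A_P / grid$A0 - 1
    I_star <- invert_law_for_intensity(spec$law, target)
    tip_obs <- grid$A0 + stats::rnorm(nrow(grid), 0, spec$sigma)
    out <- data.frame(protocol = "PROT2", A0 = grid$A0, A_P = A_P,
                      I = I_star, tip_angle = tip_obs,
                      replicate = grid$rep, stringsAsFactors = FALSE)
  }
  attr(out, "truth") <- spec
  out
}

#' Simulate kinematics with added angle measurement noise
#'
#' Runs [simulate_tropism()] and corrupts the angle field with i.i.d.
#' Gaussian noise, recomputing the curvature field from the noisy angles —
#' the same operation a digitized time-lapse would undergo. With
#' `noise_sigma = 0` the result equals the clean simulation.
#'
#' @inheritParams simulate_tropism
#' @param noise_sigma Gaussian noise s.d. on the angle field, radians.
#' @param seed RNG seed, recorded in the output.
#' @param ... Passed to [simulate_tropism()].
#' @return A `kinematics` object with the truth parameters and seed attached
#'   (`$truth`, `$seed`, `$noise_sigma`).
#' @export
generate_noisy_kinematics <- function(variant, params, t_end, noise_sigma,
                                      seed = 1L, ...) {
  stopifnot(is.finite(noise_sigma), noise_sigma >= 0)
  kin <- simulate_tropism(variant, params, t_end, ...)
  truth <- list(params = params, variant = variant, dt = kin$dt)
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    kin$A <- kin$A + matrix(stats::rnorm(length(kin$A), 0, noise_sigma),
                            nrow = nrow(kin$A))
    for (j in seq_along(kin$t)) {
      kin$C[, j] <- angles_to_curvature(kin$A[, j], kin$s)
    }
  }
  kin$seed <- as.integer(seed)
  kin$noise_sigma <- noise_sigma
  kin$truth <- truth
  kin
}
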