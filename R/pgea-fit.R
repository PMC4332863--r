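#' Photograviceptive number from an equilibrium tip angle
#'
#' At photogravitropic equilibrium the tip aligns with the set-point angle
#' `A_R = A_P / (1 + M)`, so the balance number is recovered from a measured
#' equilibrium tip angle as `M = A_P / tip - 1`. A tip angle of exactly zero
#' (pure gravitropic alignment) yields an infinite-`M` marker (`Inf`), not an
#' error. Records are flagged invalid when `M < 0` (tip beyond the light
#' direction — measurement noise) or when tip and light direction have
#' opposite signs.
#'
#' @param A_P Light direction(s), radians from vertical.
#' @param tip_angle Measured equilibrium tip angle(s), radians.
#' @return A data frame with columns `M`, `valid` and `reason` (`""` when
#'   valid; `"infinite_M"`, `"negative_M"` or `"sign_mismatch"` otherwise —
#'   infinite `M` is a legitimate marker but cannot enter a log-space fit).
#' @export
M_from_equilibrium <- function(A_P, tip_angle) {
  stopifnot(is.numeric(A_P), is.numeric(tip_angle))
  n <- max(length(A_P), length(tip_angle))
  A_P <- rep_len(A_P, n)
  tip <- rep_len(tip_angle, n)
  M <- ifelse(tip == 0, Inf, A_P / tip - 1)
  reason <- character(n)
  reason[tip == 0] <- "infinite_M"
  bad_sign <- tip != 0 & tip * A_P <= 0
  reason[bad_sign] <- "sign_mismatch"
  neg <- tip != 0 & !bad_sign & M < 0
  reason[neg] <- "negative_M"
  data.frame(M = M, valid = reason == "", reason = reason,
             stringsAsFactors = FALSE)
}

# Orthogonal (total least squares, unit error-variance ratio) straight-line
# fit: minimizes summed squared perpendicular distances. Solved from the
# eigen-decomposition of the 2x2 second-moment matrix about the centroid.
# R^2 is reported as 1 - (perpendicular residual sum) / (total variance
# about the centroid), i.e. lambda_1 / (lambda_1 + lambda_2).
orthogonal_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  xm <- mean(x)
  ym <- mean(y)
  Sxx <- sum((x - xm)^2)
  Syy <- sum((y - ym)^2)
  Sxy <- sum((x - xm) * (y - ym))
  ev <- eigen(matrix(c(Sxx, Sxy, Sxy, Syy), 2, 2), symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (abs(v[1]) < 1e-12) stop("orthogonal fit degenerate: vertical line")
  slope <- v[2] / v[1]
  intercept <- ym - slope * xm
  resid_perp <- (y - intercept - slope * x) / sqrt(1 + slope^2)
  rss <- sum(resid_perp^2)
  tot <- Sxx + Syy
  list(slope = slope, intercept = intercept,
       rss_perp = rss,
       residual_rms = sqrt(rss / length(x)),
       r_squared = if (tot > 0) 1 - rss / tot else NA_real_)
}

ols_fit <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  resid <- fit$residuals
  Syy <- sum((y - mean(y))^2)
  list(slope = fit$coefficients[2], intercept = fit$coefficients[1],
       rss_perp = sum(resid^2 / (1 + fit$coefficients[2]^2)),
       residual_rms = sqrt(mean(resid^2)),
       r_squared = if (Syy > 0) 1 - sum(resid^2) / Syy else NA_real_)
}

# shared validity screen for equilibrium records; returns the M estimates
# plus a mask with reason codes (n_used + n_excluded = n_records)
pgea_validity <- function(data) {
  need <- c("A0", "A_P", "I", "tip_angle")
  if (!all(need %in% names(data))) {
    stop("PGEA data must have columns ", paste(need, collapse = ", "),
         " (radians; use read_pgea() for degree-based files)")
  }
  mm <- M_from_equilibrium(data$A_P, data$tip_angle)
  reason <- mm$reason
  over <- abs(data$A0) > pi / 2 + 1e-9
  reason[over] <- ifelse(reason[over] == "", "A0_beyond_90deg",
                         paste(reason[over], "A0_beyond_90deg", sep = "+"))
  bad_I <- !is.finite(data$I) | data$I <= 0
  reason[bad_I] <- ifelse(reason[bad_I] == "", "nonpositive_intensity",
                          paste(reason[bad_I], "nonpositive_intensity",
                                sep = "+"))
  zero_M <- reason == "" & mm$M == 0
  reason[zero_M] <- "zero_M"    # tip exactly at the light direction
  data.frame(M = mm$M, valid = reason == "", reason = reason,
             stringsAsFactors = FALSE)
}

#' Fit an intensity-response law to photogravitropic equilibrium data
#'
#' Converts each equilibrium record to a photograviceptive number
#' `M = A_P / tip - 1`, excludes invalid records (nonpositive `M`, initial
#' tilts beyond 90 degrees where the linearized model is documented to fail,
#' nonpositive intensities), transforms to the law's fit space — `(log I,
#' log M)` for the Stevens power law, `(log I, M)` for the Weber-Fechner log
#' law — and fits a straight line by orthogonal (total least squares)
#' regression with unit error-variance ratio. Ordinary least squares is
#' available for comparison.
#'
#' @param data A data frame of equilibrium records with columns `A0`, `A_P`,
#'   `I`, `tip_angle` (angles in radians), e.g. from
#'   [generate_pgea_dataset()] or [read_pgea()].
#' @param law `"stevens_power"` or `"weber_fechner_log"`.
#' @param method `"orthogonal"` (default) or `"ols"`.
#' @return An object of class `intensity_law_fit`: the fitted
#'   [intensity_law()], `slope` and `intercept` in the fit space (natural
#'   logs), `r_squared`, `residual_rms` (per-record root-mean-square
#'   perpendicular distance in the fit space), `n_used`, `n_excluded`, the
#'   per-record validity `mask`, and the `fit_space` tag (`"log-log"` or
#'   `"semi-log"`).
#' @export
fit_intensity_law <- function(data,
                              law = c("stevens_power", "weber_fechner_log"),
                              method = c("orthogonal", "ols")) {
  law <- match.arg(law)
  method <- match.arg(method)
  mask <- pgea_validity(data)
  use <- mask$valid
  if (law == "stevens_power") {
    # log M needs strictly positive, finite M
    use <- use & is.finite(mask$M) & mask$M > 0
  } else {
    use <- use & is.finite(mask$M)
  }
  if (sum(use) < 3) {
    stop("insufficient data: need at least 3 valid records, have ", sum(use))
  }
  x <- log(data$I[use])
  if (length(unique(signif(x, 12))) < 2) {
    stop("insufficient data: intensity must span more than a single value")
  }
  y <- if (law == "stevens_power") log(mask$M[use]) else mask$M[use]
  ft <- if (method == "orthogonal") orthogonal_fit(x, y) else ols_fit(x, y)
  coef <- if (law == "stevens_power") {
    intensity_law("stevens_power", a = exp(ft$intercept), b = ft$slope)
  } else {
    intensity_law("weber_fechner_log", c = ft$intercept, d = ft$slope)
  }
  structure(list(law = coef, kind = law, method = method,
                 slope = unname(ft$slope), intercept = unname(ft$intercept),
                 r_squared = ft$r_squared, residual_rms = ft$residual_rms,
                 rss_perp = ft$rss_perp,
                 n_used = sum(use), n_excluded = sum(!use),
                 mask = cbind(data.frame(used = use), mask),
                 fit_space = if (law == "stevens_power") "log-log"
                             else "semi-log"),
            class = "intensity_law_fit")
}

#' @export
print.intensity_law_fit <- function(x, ...) {
  cat(sprintf(
    "<intensity_law_fit> %s (%s, %s space)\n  slope = %.6g, intercept = %.6g, R^2 = %.4f\n  records: %d used, %d excluded\n",
    x$kind, x$method, x$fit_space, x$slope, x$intercept, x$r_squared,
    x$n_used, x$n_excluded))
  invisible(x)
}

#' Master-curve collapse of equilibrium data across initial tilts
#'
#' The model predicts that `M = A_P / tip - 1` depends on the fluence rate
#' only, not on the initial tilt `A0`: plotted against `I`, the groups of
#' records taken at different `A0` should collapse onto a single master
#' curve. This is tested by comparing per-`A0`-group orthogonal fits with a
#' pooled fit: the data are declared collapsed when the pooled per-record
#' residual is at most `threshold` times the mean grouped residual.
#'
#' @inheritParams fit_intensity_law
#' @param threshold Pooled-to-grouped residual ratio above which the verdict
#'   is "not collapsed" (default 1.2).
#' @return A list with the pooled fit, a per-group summary (slope, residual
#'   RMS, n), the between-group `slope_dispersion` (max minus min), the
#'   `residual_ratio`, the logical `collapsed` verdict, and `excluded`
#'   records with reason codes.
#' @export
master_curve_collapse <- function(data,
                                  law = c("stevens_power",
                                          "weber_fechner_log"),
                                  threshold = 1.2) {
  law <- match.arg(law)
  mask <- pgea_validity(data)
  groups <- split(seq_len(nrow(data)), signif(data$A0, 10))
  # groups with enough valid records for a line fit
  fits <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    sub <- data[idx, , drop = FALSE]
    ok <- tryCatch(fit_intensity_law(sub, law = law), error = function(e) NULL)
    if (!is.null(ok)) fits[[g]] <- ok
  }
  excluded <- cbind(data[!mask$valid, , drop = FALSE],
                    reason = mask$reason[!mask$valid])
  if (length(fits) < 1) stop("no A0 group has enough valid records")
  pooled <- fit_intensity_law(data, law = law)
  slopes <- vapply(fits, function(f) f$slope, numeric(1))
  group_rms <- vapply(fits, function(f) f$residual_rms, numeric(1))
  summary <- data.frame(A0 = as.numeric(names(fits)), slope = slopes,
                        residual_rms = group_rms,
                        n_used = vapply(fits, function(f) f$n_used,
                                        numeric(1)))
  if (length(fits) == 1) {
    return(list(pooled = pooled, groups = summary,
                slope_dispersion = 0, residual_ratio = 1,
                collapsed = TRUE, threshold = threshold,
                note = "single A0 group: trivially collapsed",
                excluded = excluded))
  }
  mean_rms <- mean(group_rms)
  ratio <- if (pooled$residual_rms == 0 && mean_rms == 0) 1
           else if (mean_rms == 0) Inf
           else pooled$residual_rms / mean_rms
  list(pooled = pooled, groups = summary,
       slope_dispersion = max(slopes) - min(slopes),
       residual_ratio = ratio,
       collapsed = is.finite(ratio) && ratio <= threshold,
       threshold = threshold,
       excluded = excluded)
}

#' Graviproprioceptive number from a dark steady-state shape
#'
#' In darkness the steady shape of a gravi-proprioceptive organ is the
#' exponential `A(s) = A0 exp(-B s / L)`, so the whole-organ shape measured
#' in a simple tilting experiment determines `B` by nonlinear least squares.
#' The amplitude is profiled out analytically (for fixed `B` the optimal
#' amplitude is a linear least-squares coefficient), leaving a 1-D
#' minimization over `B`; using the whole profile for the amplitude, rather
#' than the single measured basal node, keeps the estimate insensitive to
#' noise at the base.
#'
#' @param shape An [organ_shape()] of the dark steady state.
#' @param B_max Upper bound of the search interval (default 500).
#' @return A list with `B`, `A0` (fitted basal amplitude), `residual_norm`
#'   (RMS of angle residuals) and `note` (`""`, or a flat-profile /
#'   sign-consistency diagnostic).
#' @export
estimate_B_from_dark_shape <- function(shape, B_max = 500) {
  validate_organ_shape(shape)
  A0 <- shape$angle[1]
  s <- shape$s
  L <- shape$L
  note <- ""
  if (abs(A0) < 1e-10) {
    stop("basal angle is zero: B is unidentifiable from an untilted organ")
  }
  if (any(sign(shape$angle) == -sign(A0) &
          abs(shape$angle) > 0.05 * abs(A0))) {
    note <- "sign inconsistency: angle profile crosses zero appreciably"
  }
  amp <- function(B) {
    eb <- exp(-B * s / L)
    sum(shape$angle * eb) / sum(eb * eb)
  }
  sse <- function(B) {
    eb <- exp(-B * s / L)
    sum((shape$angle - amp(B) * eb)^2)
  }
  opt <- stats::optimize(sse, interval = c(0, B_max), tol = 1e-10)
  B_hat <- opt$minimum
  # optimize() never returns the boundary exactly; snap a flat profile to 0
  if (sse(0) <= opt$objective) B_hat <- 0
  if (B_hat < 1e-3 && note == "") {
    note <- "near-flat profile: B close to 0 is weakly identified"
  }
  list(B = B_hat, A0 = amp(B_hat),
       residual_norm = sqrt(sse(B_hat) / length(s)), note = note)
}

#' Photoproprioceptive number from B and M
#'
#' The three control numbers are linked by `M = B / D`, so `D = B / M`.
#' An infinite-`M` marker (pure gravitropic alignment) gives `D = 0`.
#'
#' @param B_estimate Graviproprioceptive number, >= 0.
#' @param M_estimate Photograviceptive number, > 0 or `Inf`.
#' @return `D = B / M` (`Inf` marker when `M = 0`).
#' @export
estimate_D <- function(B_estimate, M_estimate) {
  stopifnot(is.numeric(B_estimate), B_estimate >= 0, is.numeric(M_estimate),
            M_estimate >= 0)
  ifelse(M_estimate == 0, Inf, B_estimate / M_estimate)
}

#' Phenomenological photogravitropic equilibrium baseline
#'
#' The classical phenomenological description of the equilibrium tip angle,
#' `PGEA = k log(I / I0) - g sin(A0)`, with `I0` a light-sensing threshold.
#' It is provided purely as a comparison baseline: unlike the set-point-angle
#' model it predicts a dark-equilibrium angle that depends on `sin(A0)` and
#' a bright-light tip angle that grows without saturation, both inconsistent
#' with the limiting behavior of gravitropic and phototropic organs.
#'
#' @param I Fluence rate(s).
#' @param I0 Threshold fluence rate, > 0.
#' @param k Phototropic coefficient.
#' @param g Gravitropic coefficient.
#' @param A0 Initial tilt (radians).
#' @return A list with `angle` (`k log(I/I0) - g sin(A0)`) and
#'   `below_threshold` (logical; `TRUE` where `I < I0`).
#' @export
pgea_phenomenological <- function(I, I0, k, g, A0) {
  stopifnot(is.finite(I0), I0 > 0, all(is.finite(I)), all(I > 0))
  list(angle = k * log(I / I0) - g * sin(A0),
       below_threshold = I < I0)
}
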