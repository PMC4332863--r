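# Shared fixtures: parameter sets, shapes and small generators used across
# the test files. Everything is built in code; no data files.

grid01 <- function(n = 201, L = 1) seq(0, L, length.out = n)

# a parameter set with every sensing channel active
full_params <- function(beta = 1.5, gamma = 1, nu = 0.7, A0 = 0.6,
                        A_P = 1.1, L = 1, L_gz = L, GSA = 0) {
  tropic_params(beta = beta, gamma = gamma, nu = nu, A0 = A0, A_P = A_P,
                L = L, L_gz = L_gz, GSA = GSA)
}

# split a target B' = (beta + nu) L_gz / gamma across channels per variant
params_for_variant <- function(variant, B_prime, gamma = 1, A0 = 0.5,
                               A_P = 0.9, grav_frac = 0.6) {
  beta <- switch(variant, AC = B_prime, AaC = 0, grav_frac * B_prime) * gamma
  nu <- switch(variant, AC = 0, AaC = B_prime,
               (1 - grav_frac) * B_prime) * gamma
  tropic_params(beta = beta, gamma = gamma, nu = nu, A0 = A0, A_P = A_P)
}

# straight tilted shape on the unit grid
straight_shape <- function(A0, n = 201, L = 1) {
  organ_shape(grid01(n, L), angle = rep(A0, n), curvature = rep(0, n))
}

random_params <- function() {
  tropic_params(beta = stats::runif(1, 0.1, 5),
                gamma = stats::runif(1, 0.2, 3),
                nu = stats::runif(1, 0.1, 5),
                A0 = stats::runif(1, -1, 1),
                A_P = stats::runif(1, -1.5, 1.5))
}

# brute-force orthogonal line fit: exhaustive search over a (direction
# angle, signed offset) grid, minimizing summed squared perpendicular
# distances. Independent of the eigen-decomposition implementation.
brute_force_orthogonal <- function(x, y, n_theta = 721, n_offset = 401) {
  best <- list(ss = Inf)
  r_max <- max(sqrt((x - mean(x))^2 + (y - mean(y))^2)) + 1e-9
  for (theta in seq(-pi / 2 + 1e-6, pi / 2 - 1e-6,
                    length.out = n_theta)) {
    nx <- -sin(theta)
    ny <- cos(theta)
    proj <- nx * (x - mean(x)) + ny * (y - mean(y))
    for (r in seq(-r_max, r_max, length.out = n_offset)) {
      ss <- sum((proj - r)^2)
      if (ss < best$ss) best <- list(ss = ss, theta = theta, r = r)
    }
  }
  # line: points with n . (p - centroid) = r  =>  slope tan(theta)
  slope <- tan(best$theta)
  x0 <- mean(x) + best$r * -sin(best$theta)
  y0 <- mean(y) + best$r * cos(best$theta)
  list(slope = slope, intercept = y0 - slope * x0, ss = best$ss)
}
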