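#' Existence discriminant for the polarity model
#'
#' The stationary integro-differential model has a positive solution iff
#' `Lambda = knf/kpf - (1/alpha) * ((alpha-1)/alpha * sqrt(knf/d1) * rtot / |U_alpha|)^(alpha-1)`
#' is non-positive: `Lambda > 0` means no steady bell-shaped profile exists,
#' `Lambda = 0` a unique tangency solution, `Lambda < 0` two candidate
#' solutions (low and high peak).
#'
#' @param knf,kpf Negative/positive feedback rates (> 0).
#' @param constants A [rop_constants()] bundle.
#' @param ref Reference solution ([solve_reference()]); `NULL` uses a cached
#'   default at the constants' `alpha`.
#' @return The discriminant value (scalar).
#' @examples
#' discriminant(knf = 0.2, kpf = 0.3) # about -0.021: two roots
#' @export
discriminant <- function(knf, kpf, constants = rop_constants(), ref = NULL) {
  stopifnot(knf > 0, kpf > 0)
  ref <- resolve_reference(ref, constants)
  a <- constants$alpha
  knf / kpf -
    (1 / a) * ((a - 1) / a * sqrt(knf / constants$d1) *
                 constants$rtot / ref$mass)^(a - 1)
}

#' Solve the peak-scale calibration equation
#'
#' Given feedback rates, the spatial compression is `mu = sqrt(knf / d1)` and
#' the peak scale `lambda` solves
#' `knf/kpf - lambda^(alpha-1) + lambda^alpha * sqrt(d1/knf) * |U_alpha| / rtot = 0`.
#' The left-hand side decreases to a minimum at
#' `lambda* = (alpha-1)/alpha * mu * rtot / |U_alpha|` and increases beyond,
#' so roots are bracketed on `(0, lambda*)` and `(lambda*, lambda_max)`, where
#' `lambda_max = mu * rtot / |U_alpha|` is where the membrane mass
#' `lambda |U_alpha| / mu` would exhaust the free pool `rtot`. The number of
#' roots (0, 1, or 2) is decided by the sign of [discriminant()].
#'
#' @inheritParams discriminant
#' @param tangency_tol Absolute tolerance on the discriminant within which the
#'   tangency (single-root) case is declared.
#' @param root_tol Convergence tolerance passed to the bracketed root solver.
#' @return An object of class `solvability_report`: list with `discriminant`,
#'   `n_roots`, `roots` (increasing), `lam_star` (stationary point of the
#'   left-hand side), and `mu`.
#' @examples
#' solve_lambda(knf = 0.2, kpf = 0.3) # roots about 0.216 and 0.600
#' @export
solve_lambda <- function(knf, kpf, constants = rop_constants(), ref = NULL,
                         tangency_tol = 1e-9, root_tol = 1e-12) {
  stopifnot(knf > 0, kpf > 0)
  ref <- resolve_reference(ref, constants)
  a <- constants$alpha
  mu <- sqrt(knf / constants$d1)
  disc <- discriminant(knf, kpf, constants, ref)
  lam_star <- (a - 1) / a * mu * constants$rtot / ref$mass
  lam_max <- mu * constants$rtot / ref$mass
  lhs <- function(l) {
    knf / kpf - l^(a - 1) + l^a * sqrt(constants$d1 / knf) * ref$mass / constants$rtot
  }
  if (disc > tangency_tol) {
    roots <- numeric(0)
  } else if (abs(disc) <= tangency_tol) {
    roots <- lam_star
  } else {
    lo <- uniroot(lhs, c(.Machine$double.eps, lam_star), tol = root_tol)$root
    hi <- uniroot(lhs, c(lam_star, lam_max), tol = root_tol)$root
    roots <- c(lo, hi)
  }
  structure(
    list(discriminant = disc, n_roots = length(roots), roots = roots,
         lam_star = lam_star, mu = mu),
    class = "solvability_report")
}

#' @export
print.solvability_report <- function(x, ...) {
  cat("<solvability_report>\n")
  cat(sprintf("  discriminant = %.6g  (%d positive root%s)\n",
              x$discriminant, x$n_roots, if (x$n_roots == 1L) "" else "s"))
  if (x$n_roots > 0) {
    cat(sprintf("  lambda roots: %s   mu = %.6g\n",
                paste(sprintf("%.6g", x$roots), collapse = ", "), x$mu))
  }
  invisible(x)
}

#' Convert shape parameters to feedback rates
#'
#' Inverts the calibration: `knf = d1 * mu^2` and
#' `kpf = d1 * mu^2 / (lambda^(alpha-1) - lambda^alpha |U_alpha| / (mu rtot))`,
#' valid on the constraint set `mu * rtot - lambda * |U_alpha| > 0` (the
#' membrane cannot hold more ROP1 than the free pool provides).
#'
#' @param lam,mu Shape parameters: peak scale and spatial compression (> 0).
#' @inheritParams discriminant
#' @return Named list `knf`, `kpf`.
#' @examples
#' shape_to_rates(lam = 0.6, mu = 1) # knf about 0.2, kpf about 0.3
#' @export
shape_to_rates <- function(lam, mu, constants = rop_constants(), ref = NULL) {
  stopifnot(lam > 0, mu > 0)
  ref <- resolve_reference(ref, constants)
  a <- constants$alpha
  slack <- mu * constants$rtot - lam * ref$mass
  if (slack <= 0) {
    abort(sprintf(
      "shape violates the existence constraint mu*Rtot - lambda*|U_alpha| > 0 (got %.3g)",
      slack))
  }
  knf <- constants$d1 * mu^2
  denom <- lam^(a - 1) - lam^a * ref$mass / (mu * constants$rtot)
  list(knf = knf, kpf = knf / denom)
}

#' Evaluate a model profile
#'
#' The membrane concentration `R(x) = lambda * U_alpha(mu * x)`, evaluated by
#' cubic interpolation of the reference solution (zero outside the scaled
#' domain `|mu x| >= c`).
#'
#' @inheritParams shape_to_rates
#' @param x Positions (micrometres).
#' @param ref Reference solution; `NULL` uses the cached default.
#' @return Numeric vector of concentrations.
#' @examples
#' evaluate_profile(0.6, 1, x = 0) # peak about 0.9663
#' @export
evaluate_profile <- function(lam, mu, x, ref = NULL,
                             constants = rop_constants()) {
  stopifnot(lam >= 0, mu > 0)
  ref <- resolve_reference(ref, constants)
  lam * reference_profile(ref, mu * x)
}

#' Membrane fraction of active ROP1
#'
#' The fraction `r = lambda * |U_alpha| / (mu * rtot)` of the total free pool
#' residing on the membrane. Any shape arising from a valid steady state
#' satisfies `r^(alpha-1) * (1 - r) <= (alpha-1)^(alpha-1) / alpha^alpha`.
#'
#' @inheritParams shape_to_rates
#' @return Scalar fraction in (0, 1).
#' @export
membrane_fraction <- function(lam, mu, constants = rop_constants(), ref = NULL) {
  stopifnot(lam > 0, mu > 0)
  ref <- resolve_reference(ref, constants)
  r <- lam * ref$mass / (mu * constants$rtot)
  if (r >= 1) {
    abort(sprintf(
      "membrane mass lambda*|U_alpha|/mu = %.3g exceeds the free pool rtot = %.3g",
      lam * ref$mass / mu, constants$rtot))
  }
  r
}

#' Rescale feedback rates under intensity renormalization
#'
#' Dividing intensities by a constant `r0` leaves the negative-feedback rate
#' unchanged and multiplies the positive-feedback rate by `r0^(alpha-1)`:
#' fits on rescaled data are comparable after this shift.
#'
#' @param knf,kpf Feedback rates.
#' @param alpha Superlinearity exponent.
#' @param r0 Positive normalization constant the data were divided by.
#' @return Named list `knf`, `kpf` on the rescaled intensity scale.
#' @examples
#' rescale_rates(0.2, 0.3, alpha = 1.2, r0 = 2)
#' @export
rescale_rates <- function(knf, kpf, alpha = 1.2, r0) {
  stopifnot(r0 > 0, alpha > 1, knf > 0, kpf > 0)
  list(knf = knf, kpf = kpf * r0^(alpha - 1))
}
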