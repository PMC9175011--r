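#' Project a symmetric matrix to the positive-semidefinite cone
#'
#' Eigen-decomposes the symmetrized input and clips negative eigenvalues to
#' zero. Used on the noise-bias-corrected population covariance, which can
#' lose definiteness when the correction is of the same order as the raw
#' between-tube scatter. Idempotent on matrices that are already PSD.
#'
#' @param m A symmetric matrix.
#' @return List with `matrix` (the projection) and `eigenvalues` (before
#'   clipping).
#' @export
psd_project <- function(m) {
  sym <- (m + t(m)) / 2
  e <- eigen(sym, symmetric = TRUE)
  proj <- e$vectors %*% diag(pmax(e$values, 0), nrow = length(e$values)) %*%
    t(e$vectors)
  dimnames(proj) <- dimnames(sym)
  list(matrix = (proj + t(proj)) / 2, eigenvalues = e$values)
}

#' Fit the polarity model to a population of tubes
#'
#' Constrained method-of-moments estimation for the mixed model in which
#' each tube has its own shape `theta_i = (lambda_i, mu_i)` drawn from a
#' population with mean `theta0` and covariance `Sigma0`:
#'
#' 1. each tube is fitted by [fit_tube()] (tubes whose fit fails are dropped
#'    with a warning, never silently);
#' 2. `theta0` is the unweighted mean of the per-tube estimates;
#' 3. the noise variance is pooled, `sigma^2 = sum RSS_i / sum (n_i - 2)`;
#' 4. the raw `Sigma0` is the sample covariance of the per-tube estimates
#'    (divisor `m - 1`) minus the estimation-noise bias
#'    `sigma^2 * mean(T_i^{-1})` with `T_i = J_i' J_i` the per-tube
#'    curvature;
#' 5. if the corrected matrix is not positive semidefinite its negative
#'    eigenvalues are clipped to zero ([psd_project()]);
#' 6. `theta0` is converted to population feedback rates, with delta-method
#'    confidence intervals propagated through the covariance of the mean
#'    (sample covariance of the per-tube estimates divided by `m`).
#'
#' @param data Long data frame with columns `tube_id`, `x`, `y`.
#' @param constants,ref Model constants and reference solution.
#' @param conf.level Confidence level for the intervals.
#' @param ... Passed to [fit_tube()].
#'
#' @return An object of class `population_fit`: `theta0` (named vector),
#'   `Sigma0` (projected), `Sigma0_raw`, `eigenvalues_raw`, `sigma`,
#'   `rates0`, `cov_theta0`, `ci_shape`, `ci_rates`, `rho_shape`,
#'   `rho_rates`, `per_tube` (list of `tube_fit`), `m`, `dropped`.
#' @examples
#' pop <- simulate_population(m = 4, step = 0.6, seed = 2)
#' fit <- fit_population(pop$tubes)
#' tidy(fit)
#' @export
fit_population <- function(data, constants = rop_constants(), ref = NULL,
                           conf.level = 0.95, ...) {
  ref <- resolve_reference(ref, constants)
  stopifnot(is.data.frame(data), all(c("tube_id", "x", "y") %in% names(data)))
  split_tubes <- split(data, factor(data$tube_id,
                                    levels = unique(data$tube_id)))
  if (length(split_tubes) < 2) abort("fit_population needs at least 2 tubes")
  fits <- purrr::map(split_tubes, function(d) {
    tryCatch(fit_tube(d, constants = constants, ref = ref, ...),
             error = function(e) {
               warn(sprintf("dropping tube %s: %s", d$tube_id[1],
                            conditionMessage(e)))
               NULL
             })
  })
  dropped <- names(fits)[purrr::map_lgl(fits, is.null)]
  fits <- purrr::compact(fits)
  m <- length(fits)
  if (m < 2) abort("fewer than 2 tubes could be fitted")

  theta_mat <- t(vapply(fits, function(f) c(lambda = f$lambda, mu = f$mu),
                        numeric(2)))
  theta0 <- colMeans(theta_mat)
  sigma2 <- sum(vapply(fits, `[[`, numeric(1), "rss")) /
    sum(vapply(fits, function(f) f$n - 2, numeric(1)))

  raw_cov <- cov(theta_mat) # divisor m - 1
  # estimation-noise bias: each theta_i is measured with covariance
  # sigma^2 T_i^{-1}, T_i = J_i' J_i at the per-tube estimate
  Tinv <- purrr::map(fits, function(f) {
    J <- shape_jacobian(f$lambda, f$mu, f$data$x, ref)
    solve(crossprod(J))
  })
  bias <- sigma2 * Reduce(`+`, Tinv) / m
  Sigma0_raw <- raw_cov - bias
  dimnames(Sigma0_raw) <- dimnames(raw_cov)
  proj <- psd_project(Sigma0_raw)
  Sigma0 <- proj$matrix

  rates0 <- shape_to_rates(theta0[["lambda"]], theta0[["mu"]], constants, ref)
  # simple-mean CLT: the mean's covariance is the scatter of the per-tube
  # estimates (which already includes their estimation noise) over m
  cov_theta0 <- raw_cov / m
  dm <- delta_method_rates(theta0, cov_theta0, constants, ref,
                           conf.level = conf.level)
  z <- qnorm(1 - (1 - conf.level) / 2)
  se_shape <- sqrt(diag(cov_theta0))
  ci_shape <- tibble(
    term = c("lambda", "mu"),
    estimate = unname(theta0),
    std.error = unname(se_shape),
    conf.low = unname(theta0 - z * se_shape),
    conf.high = unname(theta0 + z * se_shape))
  rho_shape <- if (all(diag(Sigma0) > 0)) {
    Sigma0[1, 2] / sqrt(Sigma0[1, 1] * Sigma0[2, 2])
  } else NA_real_

  structure(
    list(theta0 = theta0, Sigma0 = Sigma0, Sigma0_raw = Sigma0_raw,
         eigenvalues_raw = proj$eigenvalues, sigma = sqrt(sigma2),
         rates0 = c(knf = rates0$knf, kpf = rates0$kpf),
         cov_theta0 = cov_theta0, ci_shape = ci_shape, ci_rates = dm$ci,
         rho_shape = rho_shape, rho_rates = dm$rho,
         per_tube = fits, m = m, dropped = dropped,
         constants = constants, conf.level = conf.level,
         ref_hash = reference_hash(ref),
         ref_meta = list(alpha = ref$alpha, c = ref$c, n_mesh = ref$n_mesh,
                         mass = ref$mass, peak = ref$peak)),
    class = "population_fit")
}

#' Delta-method inference for the population feedback rates
#'
#' Propagates the asymptotic covariance of the population mean shape
#' `theta0 = (lambda0, mu0)` through the shape-to-rates map using a
#' central-finite-difference Jacobian, yielding confidence intervals for
#' `knf0`, `kpf0` and the implied correlation between them.
#'
#' @param theta0 Named vector `c(lambda = , mu = )`, strictly inside the
#'   constraint set.
#' @param cov_theta0 2x2 covariance of `theta0` (order lambda, mu).
#' @param constants,ref Model constants and reference solution.
#' @param conf.level Confidence level.
#' @return List with `ci` (tibble: term, estimate, std.error, conf.low,
#'   conf.high), `cov_rates` and `rho` (the rate correlation).
#' @export
delta_method_rates <- function(theta0, cov_theta0,
                               constants = rop_constants(), ref = NULL,
                               conf.level = 0.95) {
  ref <- resolve_reference(ref, constants)
  lam <- theta0[["lambda"]]
  mu <- theta0[["mu"]]
  if (mu * constants$rtot - lam * ref$mass <= 0) {
    abort("boundary case not supported: theta0 is not strictly inside the constraint set")
  }
  rates <- shape_to_rates(lam, mu, constants, ref)
  J <- rates_jacobian(lam, mu, constants, ref$mass)
  cov_rates <- J %*% cov_theta0 %*% t(J)
  cov_rates <- (cov_rates + t(cov_rates)) / 2
  se <- sqrt(pmax(diag(cov_rates), 0))
  z <- qnorm(1 - (1 - conf.level) / 2)
  est <- c(knf = rates$knf, kpf = rates$kpf)
  rho <- if (all(se > 0)) cov_rates[1, 2] / prod(se) else NA_real_
  list(
    ci = tibble(term = names(est), estimate = unname(est),
                std.error = unname(se),
                conf.low = unname(est - z * se),
                conf.high = unname(est + z * se)),
    cov_rates = cov_rates, rho = rho)
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("<population_fit> %d tubes%s\n", x$m,
              if (length(x$dropped)) sprintf(" (%d dropped)", length(x$dropped)) else ""))
  cat(sprintf("  theta0: lambda = %.4f  mu = %.4f   sigma = %.4f\n",
              x$theta0[["lambda"]], x$theta0[["mu"]], x$sigma))
  cat(sprintf("  rates0: knf = %.4f  kpf = %.4f   rho(knf,kpf) = %.3f\n",
              x$rates0[["knf"]], x$rates0[["kpf"]], x$rho_rates))
  cat(sprintf("  Sigma0: sd_lambda = %.4f  sd_mu = %.4f  rho = %.3f\n",
              sqrt(x$Sigma0[1, 1]), sqrt(x$Sigma0[2, 2]), x$rho_shape))
  invisible(x)
}

#' @exportS3Method
tidy.population_fit <- function(x, ...) {
  dplyr::bind_rows(x$ci_shape, x$ci_rates)
}

#' @exportS3Method
glance.population_fit <- function(x, ...) {
  tibble(m = x$m, n_obs = sum(vapply(x$per_tube, `[[`, numeric(1), "n")),
         sigma = x$sigma,
         sd_lambda = sqrt(x$Sigma0[1, 1]), sd_mu = sqrt(x$Sigma0[2, 2]),
         rho_shape = x$rho_shape, rho_rates = x$rho_rates,
         n_dropped = length(x$dropped))
}

#' Per-tube estimates from a population fit
#'
#' @param x A `population_fit`.
#' @return Tibble with one row per fitted tube: `tube_id`, `lambda`, `mu`,
#'   `knf`, `kpf`, `sigma`, `n`, `on_boundary`.
#' @export
per_tube_estimates <- function(x) {
  stopifnot(inherits(x, "population_fit"))
  purrr::map_dfr(x$per_tube, function(f) {
    tibble(tube_id = f$tube_id, lambda = f$lambda, mu = f$mu,
           knf = f$knf, kpf = f$kpf, sigma = f$sigma, n = f$n,
           on_boundary = f$on_boundary)
  })
}
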