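#' Simulate one tube's intensity profile
#'
#' Draws `y_j = lambda * U_alpha(mu * x_j) + eps_j` with i.i.d. Gaussian noise
#' on a uniform grid over `[-halfwidth, halfwidth]` (or at uniformly random
#' positions). The step sizes 0.6, 0.3, 0.1 give the standard design sizes
#' n = 51, 101, 301 on the default domain.
#'
#' @param lam,mu True shape parameters.
#' @param sigma Noise standard deviation (>= 0).
#' @param step Grid step in micrometres (ignored when `n` is given with
#'   `design = "uniform"`).
#' @param halfwidth Half-width of the sampling window (default 15).
#' @param tube_id Label for the tube.
#' @param design `"grid"` for the uniform grid, `"uniform"` for random
#'   uniform positions (then `n` must be given).
#' @param n Number of random positions when `design = "uniform"`.
#' @param constants,ref Model constants and reference solution.
#' @param seed Optional integer; when given, output is reproducible and the
#'   caller's RNG state is untouched.
#'
#' @return A tibble with columns `tube_id`, `x`, `y`.
#' @examples
#' tube <- simulate_tube(lam = 0.6, mu = 1, sigma = 0.2, step = 0.1, seed = 1)
#' nrow(tube) # 301
#' @export
simulate_tube <- function(lam = 0.6, mu = 1, sigma = 0.2, step = 0.1,
                          halfwidth = 15, tube_id = "T1",
                          design = c("grid", "uniform"), n = NULL,
                          constants = rop_constants(), ref = NULL,
                          seed = NULL) {
  design <- match.arg(design)
  stopifnot(sigma >= 0, step > 0, halfwidth > 0)
  ref <- resolve_reference(ref, constants)
  with_optional_seed(seed, {
    x <- if (design == "grid") {
      seq(-halfwidth, halfwidth, by = step)
    } else {
      stopifnot(!is.null(n), n >= 1)
      sort(runif(n, -halfwidth, halfwidth))
    }
    truth <- evaluate_profile(lam, mu, x, ref = ref, constants = constants)
    tibble(tube_id = tube_id, x = x, y = truth + rnorm(length(x), 0, sigma))
  })
}

#' Default population covariance of (lambda, mu)
#'
#' The standard simulation design: SDs 0.06 for both shape parameters with
#' correlation 0.8.
#'
#' @param sd_lambda,sd_mu Population standard deviations.
#' @param rho Correlation between lambda and mu.
#' @return A 2x2 matrix with dimnames `c("lambda", "mu")`.
#' @export
population_sigma <- function(sd_lambda = 0.06, sd_mu = 0.06, rho = 0.8) {
  stopifnot(sd_lambda >= 0, sd_mu >= 0, abs(rho) <= 1)
  m <- matrix(c(sd_lambda^2, rho * sd_lambda * sd_mu,
                rho * sd_lambda * sd_mu, sd_mu^2), 2, 2)
  dimnames(m) <- list(c("lambda", "mu"), c("lambda", "mu"))
  m
}

#' Simulate a population of tubes
#'
#' Per-tube shape parameters `(lambda_i, mu_i)` are drawn from a bivariate
#' normal with mean `theta0` and covariance `Sigma`, truncated by rejection to
#' the constraint set `{lambda, mu > 0, mu * rtot - lambda * |U_alpha| > 0}`;
#' each tube is then observed through [simulate_tube()].
#'
#' @param m Number of tubes.
#' @param theta0 Named vector `c(lambda = , mu = )`, the population mean.
#' @param Sigma 2x2 population covariance (order lambda, mu); default
#'   [population_sigma()].
#' @param sigma Measurement noise SD.
#' @inheritParams simulate_tube
#' @return A list with `tubes` (long tibble `tube_id`, `x`, `y`) and `params`
#'   (tibble `tube_id`, `lambda`, `mu` of the true per-tube parameters).
#' @examples
#' pop <- simulate_population(m = 3, step = 0.6, seed = 1)
#' pop$params
#' @export
simulate_population <- function(m = 50, theta0 = c(lambda = 0.6, mu = 1),
                                Sigma = population_sigma(), sigma = 0.2,
                                step = 0.1, halfwidth = 15,
                                constants = rop_constants(), ref = NULL,
                                seed = NULL) {
  stopifnot(m >= 1, all(theta0 > 0))
  ref <- resolve_reference(ref, constants)
  sl <- theta0[["mu"]] * constants$rtot - theta0[["lambda"]] * ref$mass
  if (sl <= 0) abort("population mean theta0 must lie strictly inside the constraint set")
  with_optional_seed(seed, {
    params <- draw_truncated_shapes(m, theta0, Sigma, constants, ref)
    tubes <- purrr::map2(seq_len(m), params, function(i, th) {
      simulate_tube(lam = th[1], mu = th[2], sigma = sigma, step = step,
                    halfwidth = halfwidth, tube_id = sprintf("T%02d", i),
                    constants = constants, ref = ref)
    })
    list(
      tubes = dplyr::bind_rows(tubes),
      params = tibble(
        tube_id = sprintf("T%02d", seq_len(m)),
        lambda = purrr::map_dbl(params, 1),
        mu = purrr::map_dbl(params, 2))
    )
  })
}

# rejection sampler for the truncated bivariate normal on the constraint set
draw_truncated_shapes <- function(m, theta0, Sigma, constants, ref) {
  mean_vec <- c(theta0[["lambda"]], theta0[["mu"]])
  out <- vector("list", m)
  filled <- 0L
  drawn <- 0L
  while (filled < m) {
    batch <- max(2L * (m - filled), 16L)
    prop <- MASS::mvrnorm(batch, mu = mean_vec, Sigma = Sigma)
    if (batch == 1L) prop <- matrix(prop, nrow = 1L)
    drawn <- drawn + batch
    ok <- prop[, 1] > 0 & prop[, 2] > 0 &
      prop[, 2] * constants$rtot - prop[, 1] * ref$mass > 0
    keep <- which(ok)
    for (k in keep) {
      if (filled >= m) break
      filled <- filled + 1L
      out[[filled]] <- prop[k, ]
    }
    if (drawn >= 100L * m && filled < drawn / 100L) {
      abort("population design infeasible: truncation acceptance rate below 1%")
    }
  }
  out
}

#' Simulate a raw tube-by-position intensity matrix
#'
#' Emulates unprocessed line-scan exports for the preprocessing stage: tubes
#' on a common reference grid (by default 173 points at step 0.1205 um,
#' centred on the tip), each with a positive baseline offset (so raw profiles
#' do not vanish at the boundaries), sparse outliers, Gaussian noise, and
#' missing-at-random entries. The baseline and outlier settings are synthetic
#' fixtures chosen to look like raw microscopy exports; they are not
#' measured quantities.
#'
#' @param m Number of tubes (default 12).
#' @param n_grid Number of grid positions (default 173).
#' @param grid_step Grid step in micrometres (default 0.1205).
#' @param theta0,Sigma,sigma Population design as in [simulate_population()].
#' @param baseline_range Per-tube baseline offset, drawn uniformly from this
#'   range times the tube's true peak.
#' @param outlier_rate Fraction of cells replaced by outliers.
#' @param outlier_size Outlier magnitude in units of `sigma`.
#' @param missing_frac Fraction of cells set missing at random (default 0.25).
#' @inheritParams simulate_tube
#' @return A list: `observed` (matrix with `NA` for missing), `complete`
#'   (same matrix before masking), `truth` (noise-free profiles plus
#'   baseline), `params` (per-tube tibble with `lambda`, `mu`, `baseline`),
#'   and `grid` (the common positions, also stored as the matrices'
#'   `"grid"` attribute).
#' @export
simulate_raw_matrix <- function(m = 12, n_grid = 173, grid_step = 0.1205,
                                theta0 = c(lambda = 0.6, mu = 1),
                                Sigma = population_sigma(), sigma = 0.2,
                                baseline_range = c(0.1, 0.3),
                                outlier_rate = 0.01, outlier_size = 5,
                                missing_frac = 0.25,
                                constants = rop_constants(), ref = NULL,
                                seed = NULL) {
  stopifnot(m >= 2, n_grid >= 3, grid_step > 0,
            missing_frac >= 0, missing_frac < 1)
  ref <- resolve_reference(ref, constants)
  grid <- (seq_len(n_grid) - (n_grid + 1) / 2) * grid_step
  with_optional_seed(seed, {
    params <- draw_truncated_shapes(m, theta0, Sigma, constants, ref)
    lam <- purrr::map_dbl(params, 1)
    mu <- purrr::map_dbl(params, 2)
    baseline <- runif(m, baseline_range[1], baseline_range[2]) *
      (lam * ref$peak)
    truth <- t(vapply(seq_len(m), function(i) {
      baseline[i] + evaluate_profile(lam[i], mu[i], grid, ref = ref,
                                     constants = constants)
    }, numeric(n_grid)))
    complete <- truth + matrix(rnorm(m * n_grid, 0, sigma), m, n_grid)
    n_out <- round(outlier_rate * m * n_grid)
    if (n_out > 0) {
      idx <- sample.int(m * n_grid, n_out)
      complete[idx] <- complete[idx] +
        sample(c(-1, 1), n_out, replace = TRUE) * outlier_size * sigma
    }
    observed <- complete
    n_miss <- round(missing_frac * m * n_grid)
    if (n_miss > 0) observed[sample.int(m * n_grid, n_miss)] <- NA_real_
    ids <- sprintf("T%02d", seq_len(m))
    dimnames(observed) <- dimnames(complete) <- dimnames(truth) <-
      list(ids, sprintf("%.4f", grid))
    attr(observed, "grid") <- attr(complete, "grid") <- attr(truth, "grid") <- grid
    list(observed = observed, complete = complete, truth = truth,
         params = tibble(tube_id = ids, lambda = lam, mu = mu,
                         baseline = baseline),
         grid = grid)
  })
}

#' @importFrom stats rnorm runif
NULL
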