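test_that("raw initial values recover the truth on noiseless data", {
  ref <- test_ref()
  tube <- simulate_tube(lam = 0.6, mu = 1, sigma = 0, step = 0.1, ref = ref)
  st <- initial_shape(tube, wt_constants(), ref)
  expect_equal(st[["lambda"]], 0.6, tolerance = 1e-6) # x = 0 is on the grid
  expect_equal(st[["mu"]], 1, tolerance = 0.02) # Riemann-sum accuracy
})

test_that("identity configuration: data equal to the reference curve", {
  ref <- test_ref()
  dat <- tibble::tibble(x = ref$grid, y = ref$values)
  st <- initial_shape(dat, wt_constants(), ref)
  expect_equal(st[["lambda"]], 1, tolerance = 1e-8)
  expect_equal(st[["mu"]], 1, tolerance = 0.02)
})

test_that("initial lambda scales with the peak observation", {
  ref <- test_ref()
  tube <- simulate_tube(lam = 0.6, mu = 1, sigma = 0, step = 0.3, ref = ref)
  st1 <- initial_shape(tube, wt_constants(), ref)
  tube$y <- 2 * tube$y
  st2 <- initial_shape(tube, wt_constants(), ref)
  expect_equal(st2[["lambda"]], 2 * st1[["lambda"]], tolerance = 1e-10)
})

test_that("pathological noise falls back to mu = 1 with a warning", {
  ref <- test_ref()
  dat <- tibble::tibble(x = seq(-15, 15, by = 2), y = c(rep(-1, 15), 0.5))
  dat <- dat[order(dat$x), ]
  expect_warning(st <- initial_shape(dat, wt_constants(), ref), "falling back")
})

test_that("noiseless fits recover the shape exactly", {
  ref <- test_ref()
  for (pars in list(c(0.6, 1), c(0.4, 0.8), c(0.7, 1.2))) {
    tube <- simulate_tube(lam = pars[1], mu = pars[2], sigma = 0,
                          step = 0.3, ref = ref)
    fit <- fit_tube(tube, ref = ref)
    expect_equal(fit$lambda, pars[1], tolerance = 1e-6)
    expect_equal(fit$mu, pars[2], tolerance = 1e-6)
    expect_lt(fit$rss, 1e-12)
    expect_false(fit$on_boundary)
  }
})

test_that("optimizer matches a brute-force grid search on a tiny instance", {
  ref <- test_ref()
  x7 <- seq(-12, 12, length.out = 7)
  y7 <- evaluate_profile(0.55, 1.1, x7, ref = ref)
  dat <- tibble::tibble(x = x7, y = y7)
  fit <- fit_tube(dat, ref = ref)
  # two-stage exhaustive search: coarse 0.01 over [0.1, 2]^2, then 1e-3
  rss_grid <- function(lams, mus) {
    sapply(mus, function(m) {
      u <- reference_profile(ref, m * x7)
      sapply(lams, function(l) sum((y7 - l * u)^2))
    }) # lams x mus
  }
  lams <- seq(0.1, 2, by = 0.01)
  mus <- seq(0.1, 2, by = 0.01)
  g <- rss_grid(lams, mus)
  ix <- arrayInd(which.min(g), dim(g))
  lams2 <- seq(lams[ix[1]] - 0.02, lams[ix[1]] + 0.02, by = 1e-3)
  mus2 <- seq(mus[ix[2]] - 0.02, mus[ix[2]] + 0.02, by = 1e-3)
  g2 <- rss_grid(lams2, mus2)
  ix2 <- arrayInd(which.min(g2), dim(g2))
  expect_equal(fit$lambda, lams2[ix2[1]], tolerance = 2e-3)
  expect_equal(fit$mu, mus2[ix2[2]], tolerance = 2e-3)
})

test_that("fitted RSS never exceeds the RSS at the initial values", {
  ref <- test_ref()
  consts <- wt_constants()
  for (seed in 1:5) {
    tube <- simulate_tube(lam = 0.6, mu = 1, sigma = 0.4, step = 0.3,
                          seed = seed, ref = ref)
    fit <- fit_tube(tube, ref = ref)
    st <- initial_shape(tube, consts, ref)
    rss0 <- sum((tube$y - evaluate_profile(st[["lambda"]], st[["mu"]],
                                           tube$x, ref = ref))^2)
    expect_lte(fit$rss, rss0 + 1e-10)
  }
})

test_that("every fit satisfies the existence constraint", {
  ref <- test_ref()
  consts <- wt_constants()
  for (seed in 1:8) {
    tube <- simulate_tube(lam = 0.6, mu = 1, sigma = 0.4, step = 0.6,
                          seed = 100 + seed, ref = ref)
    fit <- fit_tube(tube, ref = ref)
    expect_gt(fit$lambda, 0)
    expect_gt(fit$mu, 0)
    expect_gte(fit$mu * consts$rtot - fit$lambda * ref$mass, 0)
  }
})

test_that("scaling intensities scales lambda and leaves mu invariant", {
  ref <- test_ref()
  tube <- simulate_tube(lam = 0.6, mu = 1, sigma = 0.2, step = 0.3,
                        seed = 21, ref = ref)
  fit1 <- fit_tube(tube, ref = ref)
  tube2 <- tube
  tube2$y <- 3 * tube$y
  fit2 <- fit_tube(tube2, ref = ref)
  expect_equal(fit2$lambda, 3 * fit1$lambda, tolerance = 1e-5)
  expect_equal(fit2$mu, fit1$mu, tolerance = 1e-5)
})

test_that("sigma estimate uses the n - 2 divisor", {
  ref <- test_ref()
  tube <- simulate_tube(sigma = 0.2, step = 0.3, seed = 4, ref = ref)
  fit <- fit_tube(tube, ref = ref)
  expect_equal(fit$sigma, sqrt(fit$rss / (fit$n - 2)), tolerance = 1e-12)
})

test_that("asymptotic covariance: zero at sigma = 0, shrinking in n", {
  ref <- test_ref()
  tube0 <- simulate_tube(sigma = 0, step = 0.3, ref = ref)
  fit0 <- fit_tube(tube0, ref = ref)
  expect_equal(max(abs(shape_covariance(fit0))), 0, tolerance = 1e-12)
  se_for <- function(step, seed) {
    tube <- simulate_tube(sigma = 0.2, step = step, seed = seed, ref = ref)
    sqrt(diag(shape_covariance(fit_tube(tube, ref = ref))))
  }
  se51 <- se_for(0.6, 31)
  se301 <- se_for(0.1, 31)
  expect_true(all(se301 < se51))
  # covariance is symmetric positive semidefinite
  tube <- simulate_tube(sigma = 0.2, step = 0.3, seed = 5, ref = ref)
  cv <- shape_covariance(fit_tube(tube, ref = ref))
  expect_identical(cv, t(cv))
  expect_true(all(eigen(cv, symmetric = TRUE)$values >= -1e-15))
})

test_that("input validation catches short, non-finite and off-membrane data", {
  ref <- test_ref()
  expect_error(fit_tube(tibble::tibble(x = 1:3, y = 1:3), ref = ref),
               "at least 5")
  expect_error(
    fit_tube(tibble::tibble(x = c(0, 1, 2, 3, NA), y = rep(1, 5)), ref = ref),
    "finite")
  expect_error(
    fit_tube(tibble::tibble(x = c(0, 1, 2, 3, 99), y = rep(1, 5)), ref = ref),
    "outside the membrane")
})

test_that("tidy and glance expose the estimates as tibbles", {
  ref <- test_ref()
  tube <- simulate_tube(sigma = 0.2, step = 0.3, seed = 12, ref = ref)
  fit <- fit_tube(tube, ref = ref)
  td <- tidy(fit)
  expect_identical(td$term, c("lambda", "mu", "knf", "kpf"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
})
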