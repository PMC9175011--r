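test_that("discriminant matches independent arithmetic at the wild-type rates", {
  ref <- test_ref()
  # knf/kpf - (1/alpha) * ((alpha-1)/alpha * sqrt(knf/D1) * Rtot/|U|)^(alpha-1)
  # with the closed-form oracle mass, by direct arithmetic
  expected <- 0.2 / 0.3 - (1 / 1.2) * ((0.2 / 1.2) * 1 * 30 / oracle_mass)^0.2
  got <- discriminant(0.2, 0.3, wt_constants(), ref)
  expect_equal(got, expected, tolerance = 1e-3)
  expect_lt(got, 0) # two-root regime
})

test_that("discriminant sign limits behave as the model predicts", {
  ref <- test_ref()
  consts <- wt_constants()
  # knf/kpf -> 0 keeps only the negative second term
  expect_lt(discriminant(1e-6, 10, consts, ref), 0)
  # large knf/kpf forbids any positive solution
  expect_gt(discriminant(0.5, 0.01, consts, ref), 0)
})

test_that("lambda roots satisfy the calibration equation to 1e-8", {
  ref <- test_ref()
  consts <- wt_constants()
  lhs <- function(l, knf, kpf) {
    knf / kpf - l^0.2 + l^1.2 * sqrt(consts$d1 / knf) * ref$mass / consts$rtot
  }
  for (knf in c(0.1, 0.2, 0.3)) {
    for (kpf in c(0.25, 0.3, 0.4)) {
      rep <- solve_lambda(knf, kpf, consts, ref)
      for (r in rep$roots) expect_lt(abs(lhs(r, knf, kpf)), 1e-8)
      expect_equal(rep$mu, sqrt(knf / consts$d1))
    }
  }
})

test_that("wild-type rates give the canonical roots", {
  rep <- solve_lambda(0.2, 0.3, wt_constants(), test_ref())
  expect_identical(rep$n_roots, 2L)
  expect_equal(rep$roots[2], 0.6, tolerance = 0.005 / 0.6)
  # independent oracle for the smaller root: bisection on the equation
  # written out with the closed-form mass
  f <- function(l) 0.2 / 0.3 - l^0.2 + l^1.2 * oracle_mass / 30
  lam_star <- (0.2 / 1.2) * 30 / oracle_mass
  small <- bisect(f, 1e-8, lam_star)
  expect_equal(rep$roots[1], small, tolerance = 1e-3)
  expect_equal(small, 0.216, tolerance = 0.005)
})

test_that("tangency case returns the single stationary root", {
  ref <- test_ref()
  consts <- wt_constants()
  # pick knf, then choose kpf so the discriminant is exactly zero
  knf <- 0.2
  term <- (1 / 1.2) * ((0.2 / 1.2) * sqrt(knf / consts$d1) *
                         consts$rtot / ref$mass)^0.2
  kpf <- knf / term
  rep <- solve_lambda(knf, kpf, consts, ref)
  expect_identical(rep$n_roots, 1L)
  expect_equal(rep$roots, rep$lam_star, tolerance = 1e-9)
  expect_equal(rep$lam_star,
               (0.2 / 1.2) * sqrt(knf / consts$d1) * consts$rtot / ref$mass)
})

test_that("no-solution regime reports zero roots without error", {
  rep <- solve_lambda(0.5, 0.01, wt_constants(), test_ref())
  expect_identical(rep$n_roots, 0L)
  expect_length(rep$roots, 0)
  expect_gt(rep$discriminant, 0)
})

test_that("root count always agrees with the discriminant sign", {
  ref <- test_ref()
  consts <- wt_constants()
  ks <- seq(0.05, 0.5, length.out = 10)
  for (knf in ks) {
    for (kpf in ks) {
      rep <- solve_lambda(knf, kpf, consts, ref)
      if (rep$discriminant > 1e-9) expect_identical(rep$n_roots, 0L)
      else if (rep$discriminant < -1e-9) expect_identical(rep$n_roots, 2L)
      else expect_identical(rep$n_roots, 1L)
    }
  }
})

test_that("profile evaluation matches the canonical scale and boundary", {
  ref <- test_ref()
  expect_equal(evaluate_profile(0.6, 1, 0, ref = ref), 0.9663,
               tolerance = 0.001 / 0.9663)
  expect_equal(evaluate_profile(0.6, 1, c(-15, 15), ref = ref), c(0, 0))
  expect_equal(evaluate_profile(0, 1, seq(-5, 5), ref = ref), rep(0, 11))
  # linear in lambda, compression in mu
  x <- c(-3, 0.5, 7)
  expect_equal(evaluate_profile(1.2, 1, x, ref = ref),
               2 * evaluate_profile(0.6, 1, x, ref = ref))
  expect_equal(evaluate_profile(0.6, 2, x, ref = ref),
               evaluate_profile(0.6, 1, 2 * x, ref = ref))
})

test_that("shape-to-rates inverts the calibration for both roots", {
  ref <- test_ref()
  consts <- wt_constants()
  r <- shape_to_rates(0.6, 1, consts, ref)
  expect_equal(r$knf, 0.2, tolerance = 1e-6)
  expect_equal(r$kpf, 0.3, tolerance = 1e-3)
  grid <- seq(0.08, 0.45, length.out = 6)
  for (knf in grid) {
    for (kpf in grid) {
      rep <- solve_lambda(knf, kpf, consts, ref)
      for (root in rep$roots) {
        back <- shape_to_rates(root, rep$mu, consts, ref)
        expect_equal(back$knf, knf, tolerance = 1e-6)
        expect_equal(back$kpf, kpf, tolerance = 1e-6)
      }
    }
  }
})

test_that("no-depletion limit of the positive-feedback rate", {
  ref <- test_ref()
  big <- rop_constants(alpha = 1.2, d1 = 0.2, rtot = 1e9, l0 = 15)
  r <- shape_to_rates(0.6, 1, big, ref)
  expect_equal(r$kpf, 0.2 / 0.6^0.2, tolerance = 1e-6)
})

test_that("constraint violations fail loudly, naming the constraint", {
  ref <- test_ref()
  consts <- wt_constants()
  # lambda large enough that the membrane mass would exceed rtot
  expect_error(shape_to_rates(3, 1, consts, ref), "mu\\*Rtot - lambda")
  expect_error(membrane_fraction(3, 1, consts, ref), "exceeds the free pool")
})

test_that("membrane fraction and its existence bound", {
  ref <- test_ref()
  consts <- wt_constants()
  r <- membrane_fraction(0.6, 1, consts, ref)
  expect_equal(r, 0.6 * oracle_mass / 30, tolerance = 1e-3)
  expect_equal(r, 0.262, tolerance = 0.002)
  # bound (alpha-1)^(alpha-1)/alpha^alpha at alpha = 1.2
  bound <- 0.2^0.2 / 1.2^1.2
  expect_equal(bound, 0.5824, tolerance = 1e-3)
  # every shape produced by the calibration satisfies it
  for (kpf in c(0.25, 0.3, 0.4)) {
    rep <- solve_lambda(0.2, kpf, consts, ref)
    for (root in rep$roots) {
      rr <- membrane_fraction(root, rep$mu, consts, ref)
      expect_lte(rr^0.2 * (1 - rr), bound + 1e-9)
      # mass bound: membrane content below the free pool
      expect_lt(root * ref$mass / rep$mu, consts$rtot)
    }
  }
})

test_that("rate rescaling follows the renormalization relation", {
  expect_equal(rescale_rates(0.2, 0.3, 1.2, r0 = 1), list(knf = 0.2, kpf = 0.3))
  out <- rescale_rates(0.2, 0.3, 1.2, r0 = 2)
  expect_equal(out$knf, 0.2)
  expect_equal(out$kpf, 0.3 * 2^0.2, tolerance = 1e-12)
  expect_equal(out$kpf, 0.3446, tolerance = 1e-4)
  # the ratio transforms by 1/r0^(alpha-1)
  expect_equal(out$knf / out$kpf, (0.2 / 0.3) / 2^0.2, tolerance = 1e-12)
})
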