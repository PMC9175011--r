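# shared fixtures: one reference solve reused by every test file
test_ref <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- solve_reference(alpha = 1.2, c = 15)
    ref
  }
})

wt_constants <- function() rop_constants(alpha = 1.2, d1 = 0.2, rtot = 30, l0 = 15)

# closed-form infinite-domain mass |U_alpha| for alpha = 1.2:
# peak * (2/(alpha-1)) * integral of sech^10 = 1.1^5 * 10 * 256/315
oracle_mass <- 1.1^5 * 10 * 256 / 315

# independent bisection root-finder used as an oracle against solve_lambda
bisect <- function(f, lo, hi, tol = 1e-10) {
  flo <- f(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else hi <- mid
  }
  (lo + hi) / 2
}
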