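#' Model constants for the ROP1 polarity model
#'
#' Bundles the fixed mechanistic constants of the stationary
#' integro-differential model: the superlinearity exponent of the positive
#' feedback, the lateral diffusion coefficient, the membrane half-length and
#' the total free ROP1 pool. These are treated as known throughout; only the
#' feedback rates (equivalently the shape parameters) are estimated.
#'
#' The defaults are the wild-type Arabidopsis working values used in all
#' examples and simulations: `alpha = 1.2`, `d1 = 0.2`, `rtot = 30`,
#' `l0 = 15`. Positions are in micrometres; intensities are on the
#' boundary-normalized scale, so all constants are in those working units.
#'
#' @param alpha Superlinearity exponent of the positive feedback
#'   (dimensionless, must exceed 1).
#' @param d1 Lateral diffusion coefficient (working units).
#' @param rtot Total free ROP1 in the cell (intensity x micrometre units).
#' @param l0 Membrane half-length in micrometres; the membrane is
#'   `[-l0, l0]` with the apical tip at 0.
#'
#' @return An object of class `rop_constants` (a named list).
#' @examples
#' rop_constants()
#' rop_constants(alpha = 1.5, rtot = 40)
#' @export
rop_constants <- function(alpha = 1.2, d1 = 0.2, rtot = 30, l0 = 15) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(d1), length(d1) == 1L, is.finite(d1),
            is.numeric(rtot), length(rtot) == 1L, is.finite(rtot),
            is.numeric(l0), length(l0) == 1L, is.finite(l0))
  if (alpha <= 1) abort("`alpha` must be > 1 (superlinear positive feedback).")
  if (d1 <= 0) abort("`d1` must be positive.")
  if (rtot <= 0) abort("`rtot` must be positive.")
  if (l0 <= 0) abort("`l0` must be positive.")
  structure(list(alpha = alpha, d1 = d1, rtot = rtot, l0 = l0),
            class = "rop_constants")
}

#' @export
print.rop_constants <- function(x, ...) {
  cat("<rop_constants>\n")
  cat(sprintf("  alpha = %g   d1 = %g   rtot = %g   l0 = %g um\n",
              x$alpha, x$d1, x$rtot, x$l0))
  invisible(x)
}

# run code under a temporary seed when one is supplied, else as-is
with_optional_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
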