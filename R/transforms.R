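#' BSP / effect-site concentration transforms
#'
#' The burst suppression probability (BSP) is tied to a dimensionless
#' measure of effect-site (brain) anesthetic concentration by a monotone
#' hyperbolic transform mapping `[0, Inf)` onto `[0, 1)`. Two families are
#' provided: the rectangular hyperbola `p = x / (1 + x)` (default) and
#' `p = tanh(x)`. Both are strictly increasing with `p(0) = 0`, so the BSP
#' and the effect-site concentration are interchangeable control targets.
#'
#' @param x_e Nonnegative effect-site concentration (vectorized).
#' @param p BSP value(s) in `[0, 1)`.
#' @param transform Transform family, `"hyperbolic_ratio"` or `"tanh"`.
#' @return `bsp_from_conc()` returns probabilities in `[0, 1)`;
#'   `conc_from_bsp()` returns nonnegative concentrations. The two are
#'   exact inverses.
#' @examples
#' bsp_from_conc(1)        # 0.5
#' conc_from_bsp(0.9)      # 9
#' @export
bsp_from_conc <- function(x_e, transform = c("hyperbolic_ratio", "tanh")) {
  transform <- match.arg(transform)
  if (any(!is.finite(x_e)) || any(x_e < 0)) {
    stop("`x_e` must be finite and nonnegative.", call. = FALSE)
  }
  bsp_transform(transform)$g(x_e)
}

#' @rdname bsp_from_conc
#' @export
conc_from_bsp <- function(p, transform = c("hyperbolic_ratio", "tanh")) {
  transform <- match.arg(transform)
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1)) {
    stop("`p` must lie in [0, 1).", call. = FALSE)
  }
  bsp_transform(transform)$ginv(p)
}

# Internal transform family: g maps concentration to BSP; dg/d2g are first
# and second derivatives in x, used by the Laplace update's chain rule.
bsp_transform <- function(name) {
  switch(name,
    hyperbolic_ratio = list(
      name = "hyperbolic_ratio",
      g    = function(x) x / (1 + x),
      ginv = function(p) p / (1 - p),
      dg   = function(x) 1 / (1 + x)^2,
      d2g  = function(x) -2 / (1 + x)^3
    ),
    tanh = list(
      name = "tanh",
      g    = function(x) tanh(x),
      ginv = function(p) atanh(p),
      dg   = function(x) 1 / cosh(x)^2,
      d2g  = function(x) -2 * tanh(x) / cosh(x)^2
    ),
    stop("Unknown transform `", name, "`.", call. = FALSE)
  )
}
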