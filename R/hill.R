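#' Normalized Hill activation shape
#'
#' A Hill sigmoid `f(x) = beta * x^n / (k^n + x^n)` rescaled so that it
#' passes through the three anchor points `f(0) = 0`, `f(ec50) = 1/2` and
#' `f(1) = 1`. The anchor constraints have the closed-form solution
#' `beta = (ec50^n - 1) / (2 * ec50^n - 1)` and `k = (beta - 1)^(1/n)`,
#' which exists exactly when `0 < ec50 < 1` and `ec50^n < 1/2`.
#'
#' @param n Hill coefficient (> 0); steepness of the sigmoid.
#' @param ec50 input activity giving half-maximal activation, in (0, 1).
#' @return object of class `HillShape`: list with `n`, `ec50`, `beta`, `k`.
#' @examples
#' s <- hillShape(1.4, 0.5)
#' hillAct(0.5, s)  # 0.5 by construction
#' @export
hillShape <- function(n = 1.4, ec50 = 0.5) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("normalized Hill parameterization requires n > 0")
  if (!is.numeric(ec50) || length(ec50) != 1L || !is.finite(ec50) ||
      ec50 <= 0 || ec50 >= 1)
    stop("normalized Hill parameterization requires 0 < ec50 < 1")
  e <- ec50^n
  if (e >= 0.5)
    stop("normalized Hill parameterization requires ec50^n < 1/2 ",
         "(got ec50^n = ", signif(e, 6L), ")")
  beta <- (e - 1) / (2 * e - 1)
  k <- (beta - 1)^(1 / n)
  structure(list(n = n, ec50 = ec50, beta = beta, k = k),
            class = "HillShape")
}

#' @export
print.HillShape <- function(x, ...) {
  cat(sprintf("HillShape: n=%g, ec50=%g, beta=%.6g, k=%.6g\n",
              x$n, x$ec50, x$beta, x$k))
  invisible(x)
}

#' Normalized Hill activation
#'
#' Evaluates the activation sigmoid of a [hillShape()] at input activity
#' `x`, clamping `x` into `[0, 1]` first and the result into `[0, 1]`
#' (guards against inputs from species with `ymax > 1`). Monotone
#' nondecreasing in `x`, with `f(0) = 0`, `f(ec50) = 1/2`, `f(1) = 1`.
#'
#' @param x input activity, numeric vector with entries `>= 0`.
#' @param shape a `HillShape`.
#' @return activation values in `[0, 1]`, same length as `x`.
#' @export
hillAct <- function(x, shape) {
  if (!inherits(shape, "HillShape")) stop("shape must be a HillShape")
  if (any(!is.finite(x)) || any(x < 0))
    stop("activation input must be finite and >= 0")
  x <- pmin(x, 1)
  xn <- x^shape$n
  pmin(pmax(shape$beta * xn / (shape$k^shape$n + xn), 0), 1)
}

#' Normalized Hill inhibition
#'
#' The inhibition branch: `1 - hillAct(x, shape)`. Equals 1 when the
#' repressor is absent and 0 when it is fully active.
#'
#' @inheritParams hillAct
#' @return inhibition values in `[0, 1]`.
#' @export
hillInhib <- function(x, shape) 1 - hillAct(x, shape)
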