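#' Regulation function parameters
#'
#' Bundle the five kinetic parameters of the titration/Hill regulation
#' function: `k0` (basal synthesis rate, RFU/min), `k1` (maximal minus basal
#' rate, RFU/min), `n` (Hill exponent, >= 1), `theta` (activation threshold,
#' RFU) and `K` (sigma/anti-sigma dissociation constant, RFU).
#'
#' @param k0,k1,n,theta,K numeric scalars; all non-negative, `n >= 1`.
#' @return An object of class `"regulation_params"`, a named numeric vector.
#' @examples
#' regulation_params(0.22, 6.6, 1.38, 6252, 47467)
#' @export
regulation_params <- function(k0, k1, n, theta, K) {
  p <- c(k0 = k0, k1 = k1, n = n, theta = theta, K = K)
  if (anyNA(p) || any(p < 0))
    stop("regulation parameters must be non-negative")
  if (n < 1)
    stop("Hill exponent n must be >= 1")
  structure(p, class = "regulation_params")
}

as_regulation_params <- function(x) {
  if (inherits(x, "regulation_params")) return(x)
  x <- unlist(x)
  if (length(x) != 5L)
    stop("expected 5 regulation parameters (k0, k1, n, theta, K)")
  if (is.null(names(x)) || !all(c("k0", "k1", "n", "theta", "K") %in% names(x)))
    names(x) <- c("k0", "k1", "n", "theta", "K")
  regulation_params(x[["k0"]], x[["k1"]], x[["n"]], x[["theta"]], x[["K"]])
}

#' @export
print.regulation_params <- function(x, ...) {
  cat("Regulation function parameters (k0, k1, n, theta, K):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Free sigma-factor concentration under anti-sigma titration
#'
#' Computes the concentration of free FliA from total FliA (`pA`), total
#' FlgM (`pM`) and the FliA-FlgM dissociation constant `K`, under the
#' quasi-equilibrium assumption for the association/dissociation reaction:
#' \deqn{p_{A,free} = \frac{1}{2}\left(-(K + p_M - p_A) +
#'   \sqrt{(K + p_M - p_A)^2 + 4 K p_A}\right).}
#'
#' When `K + pM - pA` is large and positive the textbook form suffers
#' catastrophic cancellation; the conjugate form
#' `2*K*pA / (b + sqrt(b^2 + 4*K*pA))` is used there instead.
#'
#' @param pA total FliA concentration (RFU), vectorised.
#' @param pM total FlgM concentration (RFU), vectorised.
#' @param K dissociation constant (RFU).
#' @return Free FliA concentration, same length as the inputs;
#'   always in `[0, pA]`.
#' @examples
#' free_fliA(2, 1, 1)  # sqrt(2)
#' @export
free_fliA <- function(pA, pM, K) {
  if (anyNA(c(pA, pM, K)) || any(pA < 0) || any(pM < 0) || any(K < 0))
    stop("pA, pM and K must be non-negative")
  b <- K + pM - pA
  disc <- sqrt(b^2 + 4 * K * pA)
  out <- ifelse(b > 0,
                ifelse(b + disc > 0, 2 * K * pA / (b + disc), 0),
                0.5 * (-b + disc))
  pmin(pmax(out, 0), pA)
}

#' Hill regulation function of promoter activity
#'
#' The promoter activity as a Hill function of the free activator
#' concentration: `f = k0 + k1 * x^n / (theta^n + x^n)`.
#' The degenerate corner `theta = 0, x = 0` is defined by continuity along
#' `x -> 0` as `f = k0`.
#'
#' @param pA_free free FliA concentration (RFU), vectorised.
#' @param params a [regulation_params] object (or coercible).
#' @return Promoter activity in RFU/min, bounded in `[k0, k0 + k1]`.
#' @export
hill_activity <- function(pA_free, params) {
  params <- as_regulation_params(params)
  if (any(pA_free < 0)) stop("pA_free must be non-negative")
  k0 <- params[["k0"]]; k1 <- params[["k1"]]
  n <- params[["n"]]; theta <- params[["theta"]]
  # ratio written as 1/(1 + (theta/x)^n) to avoid overflow for large x^n
  h <- ifelse(pA_free > 0, 1 / (1 + (theta / pA_free)^n), 0)
  k0 + k1 * h
}

#' Regulation function with global physiological effects
#'
#' Multiplies the Hill regulation function by the measured activity of a
#' constitutive promoter, which reads out the activity of the gene
#' expression machinery: `f = f_const * (k0 + k1 * x^n/(theta^n + x^n))`.
#'
#' @param f_const constitutive promoter activity (RFU/min), vectorised.
#' @inheritParams hill_activity
#' @return Promoter activity in RFU/min.
#' @export
global_activity <- function(f_const, pA_free, params) {
  if (any(f_const < 0)) stop("f_const must be non-negative")
  f_const * hill_activity(pA_free, params)
}

#' Regulation function with rescaled global physiological effects
#'
#' Rescales the variation of the constitutive promoter activity around its
#' temporal mean across all conditions by a strength factor `alpha`:
#' `f = (alpha*(f_const - f_const_mean) + f_const_mean) * hill(x)`.
#' `alpha = 0` removes the time variation of global effects, `alpha = 1`
#' recovers [global_activity], and the upper bound 1.25 keeps the prefactor
#' non-negative for realistic constitutive profiles.
#'
#' @param f_const constitutive promoter activity (RFU/min), vectorised.
#' @param f_const_mean temporal mean of `f_const` pooled over all conditions.
#' @param alpha strength of global effects, in `[0, 1.25]`.
#' @inheritParams hill_activity
#' @return Promoter activity in RFU/min.
#' @export
alpha_activity <- function(f_const, f_const_mean, pA_free, params, alpha) {
  if (alpha < 0 || alpha > 1.25)
    stop("alpha must lie in [0, 1.25]")
  pre <- alpha * (f_const - f_const_mean) + f_const_mean
  if (any(pre < 0))
    stop("rescaled global prefactor is negative; alpha exceeds the bound ",
         "that keeps promoter activity non-negative")
  pre * hill_activity(pA_free, params)
}
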