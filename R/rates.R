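#' Fraction of activated priming catalyst
#'
#' Probability that the priming catalyst has bound its full complement of
#' `n` Ca2+ ions, assuming instantaneous equilibrium binding to `n`
#' independent, identical sites: `g(ca) = (ca / (K_D + ca))^n`. For
#' cooperativity one, `g(K_D) = 0.5` exactly.
#'
#' @param ca Free Ca2+ concentration(s), uM (vectorised, >= 0).
#' @param K_D Per-site dissociation constant, uM (> 0).
#' @param n Cooperativity, integer >= 1.
#' @return Activated fraction in \[0, 1\], same length as `ca`.
#' @examples
#' catalyst_activation(100, K_D = 100, n = 1) # 0.5
#' @export
catalyst_activation <- function(ca, K_D, n = 1) {
  if (!is.numeric(ca) || any(!is.finite(ca)) || any(ca < 0))
    abort("`ca` must be finite and >= 0.")
  if (!is.numeric(K_D) || length(K_D) != 1L || !is.finite(K_D) || K_D <= 0)
    abort("`K_D` must be a single positive number.")
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    abort("`n` must be an integer >= 1.")
  (ca / (K_D + ca))^n
}

#' Overall priming rate constants at a given Ca2+ level
#'
#' The NRP-RRP priming step runs along two routes: a slow uncatalysed one
#' (`k20`, `k_minus20`) and a fast catalysed one whose contribution is
#' weighted by the activated-catalyst fraction `g(ca)`:
#' `k2 = k20 + k2cat*g`, `k_minus2 = k_minus20 + k_minus2cat*g`. Because
#' `k_minus2cat` is derived from the thermodynamic constraint, the ratio
#' `k2/k_minus2` equals `k20/k_minus20` at every Ca2+ concentration: the
#' catalyst speeds the transition without moving the equilibrium.
#'
#' @param ca Free Ca2+ concentration(s), uM (vectorised).
#' @param params An [spm_params()] object (or the `catalyst` component of a
#'   PPM+cat parameter set).
#' @return A tibble with columns `ca`, `g`, `k2`, `k_minus2` (rates in 1/s).
#' @examples
#' priming_rates(0.5, spm_params()) # k2 = 0.12, k_minus2 = 0.10
#' @export
priming_rates <- function(ca, params) {
  g <- catalyst_activation(ca, params$K_D, params$n)
  tibble::tibble(
    ca = ca, g = g,
    k2 = params$k20 + params$k2cat * g,
    k_minus2 = params$k_minus20 + params$k_minus2cat * g
  )
}

#' Ca2+-dependent recruitment flux from the Depot
#'
#' Michaelis-Menten recruitment of vesicles from the (infinite) Depot Pool
#' into the first primed pool: `k1(ca) = k1Max * ca / (K_M + ca)`, in fF/s.
#' The Depot is assumed large enough that release never depletes it, so the
#' flux depends on Ca2+ only.
#'
#' @param ca Free Ca2+ concentration(s), uM (vectorised, >= 0).
#' @param params A `pool_params` object carrying `k1Max` and `K_M`.
#' @return Recruitment flux in fF/s, same length as `ca`.
#' @examples
#' recruitment_rate(2.3, spm_params()) # half-saturation: 27.5 fF/s
#' @export
recruitment_rate <- function(ca, params) {
  if (!is.numeric(ca) || any(!is.finite(ca)) || any(ca < 0))
    abort("`ca` must be finite and >= 0.")
  params$k1Max * ca / (params$K_M + ca)
}
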