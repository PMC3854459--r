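#' @rdname spm_rhs
#' @export
spm_state <- function(NRP = 0, RRP = 0, RRPCa = 0, RRPCa2 = 0, RRPCa3 = 0, F = 0) {
  c(NRP = NRP, RRP = RRP, RRPCa = RRPCa, RRPCa2 = RRPCa2, RRPCa3 = RRPCa3, F = F)
}

#' @rdname ppm_rhs
#' @export
ppm_state <- function(SRP = 0, SRPCa = 0, SRPCa2 = 0, SRPCa3 = 0,
                      RRP = 0, RRPCa = 0, RRPCa2 = 0, RRPCa3 = 0,
                      Fs = 0, Fr = 0) {
  c(SRP = SRP, SRPCa = SRPCa, SRPCa2 = SRPCa2, SRPCa3 = SRPCa3,
    RRP = RRP, RRPCa = RRPCa, RRPCa2 = RRPCa2, RRPCa3 = RRPCa3,
    Fs = Fs, Fr = Fr)
}

spm_state_names <- c("NRP", "RRP", "RRPCa", "RRPCa2", "RRPCa3", "F")
ppm_state_names <- c("SRP", "SRPCa", "SRPCa2", "SRPCa3",
                     "RRP", "RRPCa", "RRPCa2", "RRPCa3", "Fs", "Fr")

# effective priming rates of a PPM (fixed or catalyst-driven)
ppm_priming <- function(ca, params) {
  if (!is.null(params$catalyst)) {
    pr <- priming_rates(ca, params$catalyst)
    list(k2 = pr$k2, k_minus2 = pr$k_minus2)
  } else {
    list(k2 = params$k2, k_minus2 = params$k_minus2)
  }
}

#' SPM kinetic equations
#'
#' Right-hand side of the Sequential Pool Model at a fixed Ca2+ level.
#' Pools are carried in fF (capacitance proxy for vesicle number). The
#' fusion sensor is a three-identical-site scheme with statistical
#' factors: forward rates `3*k3*ca`, `2*k3*ca`, `k3*ca` and backward rates
#' `k_minus3`, `2*k_minus3`, `3*k_minus3`; the triply bound state fuses at
#' `k4` into the absorbing state `F`.
#'
#' Variant behaviour: under `unclamped_syt_null`, the final fusion barrier
#' is absent and every RRP sensor state fuses at total rate `k4`
#' irrespective of Ca2+ (the Ca2+-binding cascade is retained; the triply
#' bound state is not double-counted). Under `destabilized_syt_null`, the
#' reverse priming rate (both components) is multiplied by the variant's
#' factor.
#'
#' @param state Named numeric vector as produced by [spm_state()].
#' @param ca Free Ca2+ concentration, uM.
#' @param params An [spm_params()] object.
#' @param variant An [spm_variant()] (or mode string), default wild type.
#' @return Named vector of time derivatives (fF/s), same names as `state`.
#' @export
spm_rhs <- function(state, ca, params, variant = spm_variant("wt")) {
  variant <- as_spm_variant(variant)
  k1 <- recruitment_rate(ca, params)
  pr <- priming_rates(ca, params)
  k2 <- pr$k2
  km2 <- pr$k_minus2
  if (variant$mode == "destabilized_syt_null") km2 <- km2 * variant$factor
  b <- params$k3 * ca
  u <- params$k_minus3
  k4 <- params$k4
  unclamp <- if (variant$mode == "unclamped_syt_null") k4 else 0

  N <- state[["NRP"]]; R <- state[["RRP"]]
  C1 <- state[["RRPCa"]]; C2 <- state[["RRPCa2"]]; C3 <- state[["RRPCa3"]]

  c(NRP    = k1 - (params$k_minus1 + k2) * N + km2 * R,
    RRP    = k2 * N - (km2 + 3 * b + unclamp) * R + u * C1,
    RRPCa  = 3 * b * R - (u + 2 * b + unclamp) * C1 + 2 * u * C2,
    RRPCa2 = 2 * b * C1 - (2 * u + b + unclamp) * C2 + 3 * u * C3,
    RRPCa3 = b * C2 - (3 * u + k4) * C3,
    F      = k4 * C3 + unclamp * (R + C1 + C2))
}

#' PPM kinetic equations
#'
#' Right-hand side of the Parallel Pool Model at a fixed Ca2+ level. The
#' Depot feeds the SRP through the shared Michaelis-Menten recruitment
#' step; SRP and RRP interconvert between their Ca2+-free states at
#' (`k2`, `k_minus2`) — or at catalyst-derived rates for PPM+cat — and each
#' pool carries its own three-identical-site Ca2+ sensor. Fusion fluxes
#' accumulate separately into `Fs` (slow pathway, from SRPCa3 at `k4s`)
#' and `Fr` (fast pathway, from RRPCa3 at `k4r`).
#'
#' @param state Named numeric vector as produced by [ppm_state()].
#' @param ca Free Ca2+ concentration, uM.
#' @param params A [ppm_params()] object.
#' @return Named vector of time derivatives (fF/s), same names as `state`.
#' @export
ppm_rhs <- function(state, ca, params) {
  k1 <- recruitment_rate(ca, params)
  pr <- ppm_priming(ca, params)
  k2 <- pr$k2; km2 <- pr$k_minus2
  bs <- params$k3s * ca; us <- params$k_minus3s
  br <- params$k3r * ca; ur <- params$k_minus3r

  S <- state[["SRP"]]; S1 <- state[["SRPCa"]]
  S2 <- state[["SRPCa2"]]; S3 <- state[["SRPCa3"]]
  R <- state[["RRP"]]; R1 <- state[["RRPCa"]]
  R2 <- state[["RRPCa2"]]; R3 <- state[["RRPCa3"]]

  c(SRP    = k1 - (params$k_minus1 + k2 + 3 * bs) * S + km2 * R + us * S1,
    SRPCa  = 3 * bs * S - (us + 2 * bs) * S1 + 2 * us * S2,
    SRPCa2 = 2 * bs * S1 - (2 * us + bs) * S2 + 3 * us * S3,
    SRPCa3 = bs * S2 - (3 * us + params$k4s) * S3,
    RRP    = k2 * S - (km2 + 3 * br) * R + ur * R1,
    RRPCa  = 3 * br * R - (ur + 2 * br) * R1 + 2 * ur * R2,
    RRPCa2 = 2 * br * R1 - (2 * ur + br) * R2 + 3 * ur * R3,
    RRPCa3 = br * R2 - (3 * ur + params$k4r) * R3,
    Fs     = params$k4s * S3,
    Fr     = params$k4r * R3)
}

#' Analytic resting steady state of the SPM
#'
#' Solves the linear balance of the five pre-fusion pools (NRP, RRP and
#' the three Ca2+-bound RRP states) at a fixed Ca2+ concentration, with the
#' fused state absorbing. At rest this defines the initial condition of
#' every simulation; the steady fusion flux is the model's spontaneous
#' release rate.
#'
#' @inheritParams spm_rhs
#' @return A list with `pools` (named vector, fF; `F` excluded) and
#'   `fusion_flux` (fF/s), of class `"pool_steady_state"`.
#' @examples
#' spm_steady_state(0.5, spm_params())$fusion_flux # ~1.7 fF/s
#' @export
spm_steady_state <- function(ca, params, variant = spm_variant("wt")) {
  variant <- as_spm_variant(variant)
  k1 <- recruitment_rate(ca, params)
  pr <- priming_rates(ca, params)
  k2 <- pr$k2
  km2 <- pr$k_minus2
  if (variant$mode == "destabilized_syt_null") km2 <- km2 * variant$factor
  b <- params$k3 * ca
  u <- params$k_minus3
  k4 <- params$k4
  unclamp <- if (variant$mode == "unclamped_syt_null") k4 else 0

  A <- matrix(0, 5, 5)
  A[1, ] <- c(-(params$k_minus1 + k2), km2, 0, 0, 0)
  A[2, ] <- c(k2, -(km2 + 3 * b + unclamp), u, 0, 0)
  A[3, ] <- c(0, 3 * b, -(u + 2 * b + unclamp), 2 * u, 0)
  A[4, ] <- c(0, 0, 2 * b, -(2 * u + b + unclamp), 3 * u)
  A[5, ] <- c(0, 0, 0, b, -(3 * u + k4))
  x <- tryCatch(solve(A, c(-k1, 0, 0, 0, 0)),
                error = function(e) abort("Steady-state balance system is singular."))
  pools <- setNames(x, spm_state_names[1:5])
  flux <- k4 * pools[["RRPCa3"]] +
    unclamp * (pools[["RRP"]] + pools[["RRPCa"]] + pools[["RRPCa2"]])
  structure(list(pools = pools, fusion_flux = flux), class = "pool_steady_state")
}

#' Analytic resting steady state of the PPM
#'
#' Linear balance of the eight pre-fusion pools of the Parallel Pool Model
#' at fixed Ca2+, with both fused states absorbing.
#'
#' @inheritParams ppm_rhs
#' @return A list with `pools` (named vector, fF), `fusion_flux` (total,
#'   fF/s), `flux_slow` and `flux_fast`, of class `"pool_steady_state"`.
#' @export
ppm_steady_state <- function(ca, params) {
  k1 <- recruitment_rate(ca, params)
  pr <- ppm_priming(ca, params)
  k2 <- pr$k2; km2 <- pr$k_minus2
  bs <- params$k3s * ca; us <- params$k_minus3s
  br <- params$k3r * ca; ur <- params$k_minus3r

  A <- matrix(0, 8, 8)
  A[1, ] <- c(-(params$k_minus1 + k2 + 3 * bs), us, 0, 0, km2, 0, 0, 0)
  A[2, ] <- c(3 * bs, -(us + 2 * bs), 2 * us, 0, 0, 0, 0, 0)
  A[3, ] <- c(0, 2 * bs, -(2 * us + bs), 3 * us, 0, 0, 0, 0)
  A[4, ] <- c(0, 0, bs, -(3 * us + params$k4s), 0, 0, 0, 0)
  A[5, ] <- c(k2, 0, 0, 0, -(km2 + 3 * br), ur, 0, 0)
  A[6, ] <- c(0, 0, 0, 0, 3 * br, -(ur + 2 * br), 2 * ur, 0)
  A[7, ] <- c(0, 0, 0, 0, 0, 2 * br, -(2 * ur + br), 3 * ur)
  A[8, ] <- c(0, 0, 0, 0, 0, 0, br, -(3 * ur + params$k4r))
  x <- tryCatch(solve(A, c(-k1, rep(0, 7))),
                error = function(e) abort("Steady-state balance system is singular."))
  pools <- setNames(x, ppm_state_names[1:8])
  flux_slow <- params$k4s * pools[["SRPCa3"]]
  flux_fast <- params$k4r * pools[["RRPCa3"]]
  structure(list(pools = pools, fusion_flux = flux_slow + flux_fast,
                 flux_slow = flux_slow, flux_fast = flux_fast),
            class = "pool_steady_state")
}

#' @export
print.pool_steady_state <- function(x, ...) {
  cat("<resting steady state>\n")
  print(round(x$pools, 4))
  cat("fusion flux:", format(x$fusion_flux, digits = 4), "fF/s\n")
  invisible(x)
}
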