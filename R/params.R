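#' Sequential Pool Model parameters
#'
#' Construct the parameter set of the Sequential Pool Model (SPM) of
#' chromaffin-cell secretion: Michaelis-Menten Ca2+-dependent recruitment
#' from an infinite Depot into the Non-Releasable Pool (NRP), reversible
#' priming into the Readily-Releasable Pool (RRP) accelerated by a
#' Ca2+-dependent catalyst, and a three-site cooperative Ca2+ sensor gating
#' final fusion. Defaults are the published chromaffin-cell values
#' (preset `"spm_table1"`).
#'
#' The catalyst accelerates forward and reverse priming identically, so the
#' reverse catalysed ceiling is never a free parameter: it is derived from
#' the thermodynamic constraint `k_minus2cat = k2cat * k_minus20 / k20`,
#' which guarantees that the NRP:RRP equilibrium ratio `k2/k_minus2 =
#' k20/k_minus20` is independent of Ca2+.
#'
#' @param k1Max Recruitment ceiling, fF/s.
#' @param K_M Recruitment Michaelis constant, uM.
#' @param k_minus1 NRP-to-Depot unpriming rate, 1/s.
#' @param k20 Uncatalysed priming rate, 1/s (must be > 0).
#' @param k2cat Catalysed priming ceiling, 1/s.
#' @param k_minus20 Uncatalysed unpriming rate, 1/s.
#' @param K_D Catalyst Ca2+ dissociation constant, uM.
#' @param n Catalyst Ca2+ cooperativity (integer >= 1).
#' @param k3 Sensor per-site Ca2+ on-rate, 1/(s*uM).
#' @param k_minus3 Sensor per-site off-rate, 1/s.
#' @param k4 Final fusion rate, 1/s.
#'
#' @return An object of class `c("spm_params", "pool_params")`: a named list
#'   of the rates above plus the derived `k_minus2cat`.
#' @examples
#' p <- spm_params()
#' p$k_minus2cat # 20 * 0.017 / 0.021
#' @export
spm_params <- function(k1Max = 55, K_M = 2.3, k_minus1 = 0.05,
                       k20 = 0.021, k2cat = 20, k_minus20 = 0.017,
                       K_D = 100, n = 1,
                       k3 = 4.4, k_minus3 = 56, k4 = 1450) {
  p <- list(k1Max = k1Max, K_M = K_M, k_minus1 = k_minus1,
            k20 = k20, k2cat = k2cat, k_minus20 = k_minus20,
            K_D = K_D, n = n, k3 = k3, k_minus3 = k_minus3, k4 = k4)
  validate_spm_params(p)
  p$k_minus2cat <- k2cat * k_minus20 / k20
  structure(p, class = c("spm_params", "pool_params"))
}

validate_spm_params <- function(p) {
  num <- c("k1Max", "K_M", "k_minus1", "k20", "k2cat", "k_minus20",
           "K_D", "n", "k3", "k_minus3", "k4")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      abort(sprintf("SPM parameter `%s` must be a single finite nonnegative number.", nm))
  }
  if (p$K_M <= 0) abort("`K_M` must be > 0.")
  if (p$K_D <= 0) abort("`K_D` must be > 0.")
  if (p$k20 <= 0) abort("`k20` must be > 0 (k_minus2cat = k2cat*k_minus20/k20 is otherwise undefined).")
  if (p$n < 1 || p$n != round(p$n)) abort("Catalyst cooperativity `n` must be an integer >= 1.")
  invisible(p)
}

#' Parallel Pool Model parameters
#'
#' Construct the parameter set of the classical Parallel Pool Model (PPM):
#' Ca2+-dependent recruitment from the Depot into the Slowly-Releasable
#' Pool (SRP), a Ca2+-independent SRP-RRP interconversion, and two
#' parallel three-site Ca2+ sensors driving fusion from the SRP (slow
#' pathway) and the RRP (fast pathway). Defaults are the published
#' chromaffin-cell values (preset `"ppm_table2"`).
#'
#' Supplying `catalyst` turns the model into the PPM+cat hybrid: the fixed
#' `k2`/`k_minus2` interconversion is replaced by the same Ca2+-dependent
#' catalyst rate law used in the SPM, with `k_minus2cat` again derived from
#' the thermodynamic constraint.
#'
#' @param k1Max,K_M,k_minus1 Recruitment parameters as in [spm_params()].
#' @param k2 SRP-to-RRP rate, 1/s.
#' @param k_minus2 RRP-to-SRP rate, 1/s.
#' @param k3s,k_minus3s,k4s Slow-sensor per-site on/off rates and fusion rate.
#' @param k3r,k_minus3r,k4r Fast-sensor per-site on/off rates and fusion rate.
#' @param catalyst Optional named list with elements `k20`, `k2cat`,
#'   `k_minus20`, `K_D`, `n`. When present, `k2`/`k_minus2` are ignored and
#'   the priming step follows the catalyst rate law (PPM+cat).
#'
#' @return An object of class `c("ppm_params", "pool_params")`.
#' @examples
#' preset_params("ppm_table2")
#' preset_params("ppm_cat")$catalyst
#' @export
ppm_params <- function(k1Max = 55, K_M = 2.3, k_minus1 = 0.05,
                       k2 = 0.12, k_minus2 = 0.1,
                       k3s = 0.5, k_minus3s = 4, k4s = 20,
                       k3r = 4.4, k_minus3r = 56, k4r = 1450,
                       catalyst = NULL) {
  p <- list(k1Max = k1Max, K_M = K_M, k_minus1 = k_minus1,
            k2 = k2, k_minus2 = k_minus2,
            k3s = k3s, k_minus3s = k_minus3s, k4s = k4s,
            k3r = k3r, k_minus3r = k_minus3r, k4r = k4r)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      abort(sprintf("PPM parameter `%s` must be a single finite nonnegative number.", nm))
  }
  if (p$K_M <= 0) abort("`K_M` must be > 0.")
  if (!is.null(catalyst)) {
    need <- c("k20", "k2cat", "k_minus20", "K_D", "n")
    missing <- setdiff(need, names(catalyst))
    if (length(missing))
      abort(paste0("PPM catalyst is missing: ", paste(missing, collapse = ", ")))
    cat_p <- catalyst[need]
    validate_spm_params(c(cat_p, list(k1Max = 0, K_M = 1, k_minus1 = 0,
                                      k3 = 0, k_minus3 = 0, k4 = 0)))
    cat_p$k_minus2cat <- cat_p$k2cat * cat_p$k_minus20 / cat_p$k20
    p$catalyst <- cat_p
  }
  structure(p, class = c("ppm_params", "pool_params"))
}

#' Built-in parameter presets
#'
#' Named parameter sets for chromaffin cells: `"spm_table1"` (the SPM
#' defaults), `"ppm_table2"` (the PPM defaults), and `"ppm_cat"` (the PPM
#' with the SPM's catalyst grafted onto the SRP-to-RRP step; the hybrid's
#' own published rate adjustments are not available, so the SPM catalyst
#' values serve as configurable defaults).
#'
#' @param name One of `"spm_table1"`, `"ppm_table2"`, `"ppm_cat"`.
#' @return A `pool_params` object.
#' @export
preset_params <- function(name = c("spm_table1", "ppm_table2", "ppm_cat")) {
  name <- match.arg(name)
  switch(name,
    spm_table1 = spm_params(),
    ppm_table2 = ppm_params(),
    ppm_cat = {
      s <- spm_params()
      ppm_params(catalyst = s[c("k20", "k2cat", "k_minus20", "K_D", "n")])
    })
}

#' Model variants of the SPM
#'
#' Perturbations of the wild-type SPM used to emulate synaptotagmin-1
#' deletion. `"unclamped_syt_null"` removes the final fusion barrier so
#' that every RRP sensor state fuses Ca2+-independently at the maximal
#' rate `k4`; `"destabilized_syt_null"` raises the free energy of the RRP
#' by multiplying the reverse priming rate (both its uncatalysed and
#' catalysed components) by `factor`.
#'
#' @param mode `"wt"`, `"unclamped_syt_null"` or `"destabilized_syt_null"`.
#' @param factor Multiplier on `k_minus2` for the destabilized variant
#'   (default 10).
#' @return An object of class `"spm_variant"`.
#' @export
spm_variant <- function(mode = c("wt", "unclamped_syt_null", "destabilized_syt_null"),
                        factor = 10) {
  mode <- match.arg(mode)
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    abort("`factor` must be a single positive number.")
  structure(list(mode = mode, factor = factor), class = "spm_variant")
}

as_spm_variant <- function(variant) {
  if (inherits(variant, "spm_variant")) return(variant)
  if (is.character(variant)) return(spm_variant(variant))
  abort("`variant` must be an `spm_variant` or a mode string.")
}

#' @export
print.pool_params <- function(x, ...) {
  kind <- if (inherits(x, "spm_params")) "Sequential Pool Model (SPM)"
          else if (!is.null(x$catalyst)) "Parallel Pool Model + catalyst (PPM+cat)"
          else "Parallel Pool Model (PPM)"
  cat("<", kind, " parameters>\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a parameter set into a two-column tibble
#'
#' @param x A `pool_params` object.
#' @param ... Unused.
#' @return A tibble with columns `parameter` and `value`.
#' @method tidy pool_params
#' @export
tidy.pool_params <- function(x, ...) {
  flat <- x
  if (!is.null(flat$catalyst)) {
    cat_p <- flat$catalyst
    flat$catalyst <- NULL
    names(cat_p) <- paste0("cat_", names(cat_p))
    flat <- c(flat, cat_p)
  }
  tibble::tibble(parameter = names(flat), value = unlist(flat, use.names = FALSE))
}
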