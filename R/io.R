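#' Write / read a trace as CSV
#'
#' Traces are stored with unit-suffixed headers: `t_s`, `ca_uM`, one
#' column per pool (fF), `dCm_fF` (and `influx_fF` when present). Reading
#' restores the in-memory column names; the round trip is exact at double
#' precision.
#'
#' @param trace A `pool_trace` (or any data frame with `t`, `dCm`).
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` a
#'   tibble with columns `t`, `ca`, pools, `dCm`.
#' @export
write_trace <- function(trace, path) {
  out <- trace
  nm <- names(out)
  nm[nm == "t"] <- "t_s"
  nm[nm == "ca"] <- "ca_uM"
  nm[nm == "dCm"] <- "dCm_fF"
  nm[nm == "influx"] <- "influx_fF"
  names(out) <- nm
  readr::write_csv(as.data.frame(out), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0)
    abort(sprintf("Malformed trace CSV: first problem at line %d (%s).",
                  probs$row[1], probs$expected[1]))
  nm <- names(df)
  nm[nm == "t_s"] <- "t"
  nm[nm == "ca_uM"] <- "ca"
  nm[nm == "dCm_fF"] <- "dCm"
  nm[nm == "influx_fF"] <- "influx"
  names(df) <- nm
  if (!all(c("t", "dCm") %in% names(df)))
    abort("Trace CSV must contain columns `t_s` and `dCm_fF`.")
  tibble::as_tibble(df)
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration describing one simulation run:
#' which model and preset, parameter overrides, the Ca2+ protocol, solver
#' settings, and optional fixture-noise settings. Unknown keys are
#' rejected; overrides are validated through the parameter constructors,
#' so invariant violations (e.g. a negative rate) fail loudly.
#'
#' Recognised top-level keys: `model` (`spm`/`ppm`/`ppm_cat`), `preset`,
#' `params` (name-value overrides), `variant`, `factor`, `protocol`
#' (list of segment maps), `t_span`, `solver` ([solver_settings()]
#' fields), `noise` (`sd`, `seed`), `out_dir`.
#'
#' @param path Path to a YAML/JSON file.
#' @return A list of class `"run_config"` with resolved `params`
#'   (`pool_params`), `protocol` (`ca_protocol`), `settings`, `variant`,
#'   `model`, `t_span`, `noise`, `out_dir`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("model", "preset", "params", "variant", "factor", "protocol",
             "t_span", "solver", "noise", "out_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    abort(paste0("Unknown configuration keys: ", paste(bad, collapse = ", ")))

  model <- raw$model %||% "spm"
  if (!model %in% c("spm", "ppm", "ppm_cat"))
    abort("`model` must be one of: spm, ppm, ppm_cat.")
  preset <- raw$preset %||% switch(model, spm = "spm_table1",
                                   ppm = "ppm_table2", ppm_cat = "ppm_cat")
  base <- preset_params(preset)

  params <- base
  if (!is.null(raw$params)) {
    ctor <- if (inherits(base, "spm_params")) spm_params else ppm_params
    ctor_args <- setdiff(names(formals(ctor)), "catalyst")
    bad_par <- setdiff(names(raw$params), c(ctor_args, "catalyst"))
    if (length(bad_par))
      abort(paste0("Unknown parameter overrides: ", paste(bad_par, collapse = ", ")))
    keep <- base[intersect(names(base), ctor_args)]
    args <- modifyList(keep, raw$params[setdiff(names(raw$params), "catalyst")])
    if (!is.null(base$catalyst) || !is.null(raw$params$catalyst))
      args$catalyst <- modifyList(base$catalyst %||% list(),
                                  raw$params$catalyst %||% list())
    params <- do.call(ctor, args)
  }

  protocol <- if (!is.null(raw$protocol))
    ca_protocol(dplyr::bind_rows(lapply(raw$protocol, tibble::as_tibble)))
  else ca_step_protocol()

  settings <- do.call(solver_settings, raw$solver %||% list())
  variant <- spm_variant(raw$variant %||% "wt", factor = raw$factor %||% 10)
  t_span <- raw$t_span %||% c(protocol$t_start[1], max(protocol$t_start) + 5.1)
  if (length(t_span) != 2L) abort("`t_span` must have two elements.")

  noise <- raw$noise %||% list(sd = 0, seed = 1L)
  if (!all(names(noise) %in% c("sd", "seed")))
    abort("`noise` accepts only `sd` and `seed`.")
  noise$sd <- noise$sd %||% 0
  noise$seed <- noise$seed %||% 1L
  if (noise$sd < 0) abort("`noise$sd` must be >= 0.")

  structure(list(model = model, preset = preset, params = params,
                 variant = variant, protocol = protocol,
                 t_span = as.numeric(t_span), settings = settings,
                 noise = noise, out_dir = raw$out_dir %||% "."),
            class = "run_config")
}

#' Write a run configuration back to YAML
#'
#' @param config A `"run_config"` (or plain list of the raw keys).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  raw <- list(
    model = config$model, preset = config$preset,
    variant = config$variant$mode, factor = config$variant$factor,
    protocol = apply(as.data.frame(config$protocol), 1, function(r) {
      seg <- list(t_start = as.numeric(r[["t_start"]]), kind = r[["kind"]],
                  level = as.numeric(r[["level"]]))
      if (!is.na(r[["tau"]])) seg$tau <- as.numeric(r[["tau"]])
      if (!is.na(r[["target"]])) seg$target <- as.numeric(r[["target"]])
      seg
    }),
    t_span = config$t_span,
    solver = unclass(config$settings),
    noise = config$noise,
    out_dir = config$out_dir)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Generate a synthetic noisy capacitance trace
#'
#' Integrates a model over a protocol and adds seeded Gaussian noise to
#' the cumulative capacitance only (the measurement-noise model of a
#' capacitance recording; pool series stay clean). Deterministic per
#' seed; `noise_sd = 0` returns the clean trace.
#'
#' @inheritParams integrate_model
#' @param noise_sd Noise standard deviation, fF.
#' @param seed Integer seed.
#' @return A `pool_trace` tibble with noisy `dCm`.
#' @export
generate_fixture <- function(params = NULL, protocol, noise_sd = 0, seed = 1L,
                             t_span = NULL, model = "spm",
                             variant = spm_variant("wt"),
                             settings = solver_settings()) {
  if (is.null(t_span))
    t_span <- c(protocol$t_start[1], max(protocol$t_start) + 5.1)
  trace <- integrate_model(model, params, protocol, t_span,
                           variant = variant, settings = settings)
  trace$dCm <- trace$dCm + local_rnorm(seed, nrow(trace), sd = noise_sd)
  trace
}

`%||%` <- function(a, b) if (is.null(a)) b else a
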