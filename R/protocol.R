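#' Piecewise intracellular Ca2+ protocols
#'
#' A stimulation protocol is an ordered set of segments, each starting at
#' `t_start` (s) and describing `[Ca2+]_i` (uM) until the next segment:
#' `"constant"` and `"step_to"` hold `level`; `"exp_relax"` relaxes
#' exponentially from `level` toward `target` with time constant `tau`.
#' Evaluation is right-continuous: at a segment boundary the new segment's
#' value applies.
#'
#' @param segments A data frame with columns `t_start`, `kind`, `level` and
#'   optionally `tau`, `target`.
#' @return A tibble of class `"ca_protocol"`.
#' @seealso [ca_step_protocol()], [ca_at()]
#' @export
ca_protocol <- function(segments) {
  segments <- tibble::as_tibble(segments)
  for (col in c("tau", "target")) if (!col %in% names(segments)) segments[[col]] <- NA_real_
  need <- c("t_start", "kind", "level", "tau", "target")
  missing <- setdiff(need, names(segments))
  if (length(missing))
    abort(paste0("Protocol segments are missing columns: ", paste(missing, collapse = ", ")))
  segments <- segments[need]
  if (nrow(segments) < 1L) abort("A protocol needs at least one segment.")
  if (is.unsorted(segments$t_start, strictly = TRUE))
    abort("Segment `t_start` values must be strictly increasing.")
  if (!all(segments$kind %in% c("constant", "step_to", "exp_relax")))
    abort("Segment `kind` must be one of: constant, step_to, exp_relax.")
  if (any(!is.finite(segments$level) | segments$level < 0))
    abort("Segment `level` must be finite and >= 0.")
  relax <- segments$kind == "exp_relax"
  if (any(relax & (!is.finite(segments$tau) | segments$tau <= 0)))
    abort("exp_relax segments need `tau` > 0.")
  if (any(relax & (!is.finite(segments$target) | segments$target < 0)))
    abort("exp_relax segments need `target` >= 0.")
  class(segments) <- c("ca_protocol", class(segments))
  segments
}

#' Step protocol between two Ca2+ levels
#'
#' The canonical uncaging-flash drive: hold `pre` uM from `t0`, then step
#' instantaneously to `post` uM at `t_step` (e.g. 0.5 to 25 uM at 0.5 s).
#'
#' @param pre,post Ca2+ levels before and after the step, uM.
#' @param t_step Step time, s.
#' @param t0 Protocol start time, s (default 0).
#' @return A `ca_protocol`.
#' @export
ca_step_protocol <- function(pre = 0.5, post = 25, t_step = 0.5, t0 = 0) {
  ca_protocol(tibble::tibble(
    t_start = c(t0, t_step),
    kind = c("constant", "step_to"),
    level = c(pre, post)))
}

#' Evaluate a Ca2+ protocol
#'
#' @param protocol A [ca_protocol()].
#' @param t Time(s) in s; must not precede the first segment start.
#' @return `[Ca2+]_i` in uM at each `t`.
#' @examples
#' ca_at(ca_step_protocol(), c(0.49, 0.5)) # 0.5 then 25 (right-continuous)
#' @export
ca_at <- function(protocol, t) {
  if (!inherits(protocol, "ca_protocol")) protocol <- ca_protocol(protocol)
  if (any(t < protocol$t_start[1]))
    abort(sprintf("Time %g s precedes the protocol start (%g s).",
                  min(t), protocol$t_start[1]))
  idx <- findInterval(t, protocol$t_start)  # right-continuous
  lvl <- protocol$level[idx]
  relax <- protocol$kind[idx] == "exp_relax"
  if (any(relax)) {
    tau <- protocol$tau[idx[relax]]
    tgt <- protocol$target[idx[relax]]
    dt <- t[relax] - protocol$t_start[idx[relax]]
    lvl[relax] <- tgt + (protocol$level[idx[relax]] - tgt) * exp(-dt / tau)
  }
  lvl
}
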