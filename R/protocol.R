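#' Multi-echo FLASH acquisition protocol
#'
#' Describes the three RF- and gradient-spoiled multi-echo 3D FLASH scans
#' of an MPM session: a T1-weighted scan (high flip angle), a PD-weighted
#' scan (low flip angle) and an MT-weighted scan (low flip angle preceded
#' by an off-resonance MT saturation pulse). All three share one TR; the
#' MT-weighted echo train is shorter so the MT pulse fits into the same
#' TR.
#'
#' The default echo grid starts at 2.30 ms and steps by 2.314 ms, placing
#' the sixth echo at 13.87 ms; PDw/T1w acquire 8 echoes and MTw 6. The MT
#' pulse metadata (duration, off-resonance offset, nominal pulse flip) is
#' carried for provenance but the pulse itself is not simulated
#' mechanistically.
#'
#' @param flip_deg named numeric vector of nominal excitation flip angles
#'   in degrees for weightings `T1w`, `PDw`, `MTw`.
#' @param tr_ms repetition time in ms, shared by all weightings.
#' @param te_first_ms first echo time in ms.
#' @param te_step_ms echo spacing in ms.
#' @param n_echoes named integer vector of echo counts per weighting.
#' @param mt_pulse list with `duration_ms`, `offset_khz`, `flip_deg`
#'   describing the MT saturation pulse (metadata only).
#' @return an object of class `mpm_protocol`: a list with one element per
#'   weighting (`flip_deg`, `tr_ms`, `te_ms`) plus `mt_pulse`.
#' @examples
#' p <- mpm_protocol()
#' p$T1w$flip_deg   # 21
#' p$MTw$te_ms      # 6 echoes, last at 13.87 ms
#' @export
mpm_protocol <- function(flip_deg = c(T1w = 21, PDw = 6, MTw = 6),
                         tr_ms = 25.0,
                         te_first_ms = 2.30,
                         te_step_ms = 2.314,
                         n_echoes = c(T1w = 8L, PDw = 8L, MTw = 6L),
                         mt_pulse = list(duration_ms = 4, offset_khz = 2,
                                         flip_deg = 220)) {
  w_names <- c("T1w", "PDw", "MTw")
  if (!all(w_names %in% names(flip_deg)) || !all(w_names %in% names(n_echoes)))
    stopf("flip_deg and n_echoes must be named with %s",
          paste(w_names, collapse = ", "))
  check_number(tr_ms, "tr_ms", lower = 1e-6)
  proto <- lapply(w_names, function(w) {
    te <- te_first_ms + (seq_len(n_echoes[[w]]) - 1) * te_step_ms
    list(flip_deg = unname(flip_deg[[w]]), tr_ms = tr_ms, te_ms = te)
  })
  names(proto) <- w_names
  proto$mt_pulse <- mt_pulse
  class(proto) <- "mpm_protocol"
  validate_protocol(proto)
  proto
}

validate_protocol <- function(proto) {
  for (w in protocol_weightings(proto)) {
    p <- proto[[w]]
    if (p$flip_deg <= 0 || p$flip_deg >= 90)
      stopf("%s: flip angle must be in (0, 90) degrees", w)
    if (length(p$te_ms) < 1L || any(diff(p$te_ms) <= 0))
      stopf("%s: echo times must be strictly increasing", w)
    if (any(p$te_ms >= p$tr_ms))
      stopf("%s: all echo times must be shorter than TR (%g ms)", w, p$tr_ms)
  }
  invisible(proto)
}

protocol_weightings <- function(proto)
  intersect(c("T1w", "PDw", "MTw"), names(proto))

#' @export
print.mpm_protocol <- function(x, ...) {
  cat("Multi-echo FLASH MPM protocol\n")
  for (w in protocol_weightings(x)) {
    p <- x[[w]]
    cat(sprintf("  %s: flip %g deg, TR %g ms, %d echoes (%.2f..%.2f ms)\n",
                w, p$flip_deg, p$tr_ms, length(p$te_ms),
                min(p$te_ms), max(p$te_ms)))
  }
  if (!is.null(x$mt_pulse))
    cat(sprintf("  MT pulse: %g ms Gaussian, %g kHz off-resonance, %g deg\n",
                x$mt_pulse$duration_ms, x$mt_pulse$offset_khz,
                x$mt_pulse$flip_deg))
  invisible(x)
}
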