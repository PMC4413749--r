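#' Sound exposure level
#'
#' Cumulative sound energy over a time interval, referenced to 1 second:
#' `SEL = 10*log10( sum(p^2 * dt) / (p_ref^2 * 1 s) )` in dB re p_ref^2 s.
#' For a stationary signal of level SPL over T seconds,
#' `SEL = SPL + 10*log10(T)`.
#'
#' @param p A [pressure_series()].
#' @param t0,t1 Interval in offset seconds (`0 <= t0 < t1 <= duration`);
#'   default the whole series.
#' @return SEL in dB re p_ref^2 s.
#' @export
#' @examples
#' p <- synth_white_noise(60, duration = 10, sample_rate = 2000, seed = 1)
#' sel(p) - spl_rms(p) # ~ 10*log10(10) = 10 dB
sel <- function(p, t0 = 0, t1 = duration(p)) {
  stopifnot(inherits(p, "pressure_series"))
  if (!(is_scalar_number(t0) && is_scalar_number(t1) && t1 > t0)) {
    abort("Need a non-degenerate interval with t0 < t1.")
  }
  idx <- window_indices(p, t0, t1)
  x <- p$pressure[idx]
  e <- sum(x^2) / p$sample_rate
  if (e <= 0) abort("SEL is undefined for a zero-energy interval.")
  10 * log10(e / p$p_ref^2)
}
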