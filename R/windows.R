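#' Analysis window coefficients and normalization constants
#'
#' Returns the periodic (DFT-even) taper of length `n` together with the two
#' constants needed to calibrate spectra: the coherent gain `sum(w)/n`
#' (amplitude scaling of an in-bin tone) and the equivalent noise bandwidth
#' `n * sum(w^2) / sum(w)^2` in bins (the width of the ideal rectangular
#' filter passing the same noise power). For large `n` the Hann window tends
#' to coherent gain 0.5 and noise bandwidth 1.5 bins; the rectangular window
#' has gain 1 and bandwidth exactly 1 bin.
#'
#' @param window `"hann"`, `"hamming"` or `"rectangular"`.
#' @param n Window length in samples (>= 2).
#' @return A list with `w` (length-`n` coefficients), `coherent_gain` and
#'   `enbw_bins`.
#' @export
#' @examples
#' wc <- window_coefficients("hann", 1024)
#' wc$coherent_gain # 0.5
#' wc$enbw_bins     # ~1.5
window_coefficients <- function(window = c("hann", "hamming", "rectangular"),
                                n) {
  if (!is.character(window) || length(window) != 1L ||
      !window %in% c("hann", "hamming", "rectangular")) {
    abort(sprintf(
      "Unknown window kind %s; use \"hann\", \"hamming\" or \"rectangular\".",
      deparse(window[1L])
    ))
  }
  if (!is_scalar_number(n) || n < 2) abort("`n` must be an integer >= 2.")
  n <- as.integer(n)
  k <- seq_len(n) - 1L
  w <- switch(window,
    hann = 0.5 - 0.5 * cos(2 * pi * k / n),
    hamming = 0.54 - 0.46 * cos(2 * pi * k / n),
    rectangular = rep(1, n)
  )
  list(
    window = window,
    w = w,
    coherent_gain = sum(w) / n,
    enbw_bins = n * sum(w^2) / sum(w)^2
  )
}
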