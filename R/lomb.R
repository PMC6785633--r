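#' Lomb-Scargle periodogram with analytic peak significance
#'
#' Classical normalized periodogram (with the phase-invariant tau offset,
#' variance-normalized as in Horne & Baliunas) evaluated on a frequency grid
#' covering the requested period range. The grid is oversampled by `oversampling`
#' relative to the independent-frequency spacing `1/T` (T = series span) to
#' refine the location of the peak. The best period is the argmax of power;
#' its significance is the standard extreme-value tail
#' `p = 1 - (1 - exp(-z))^M` with `z` the peak power and `M` the number of
#' independent frequencies inside the scanned range,
#' `M = floor((f_hi - f_lo) * T) + 1`. Oversampled grid points are strongly
#' correlated, so M deliberately does not grow with `oversampling`. A constant
#' series has zero power everywhere and p = 1.
#'
#' @param values numeric series (>= 4 finite values).
#' @param times_h sampling times in hours (even or uneven).
#' @param period_range numeric length-2, periods in hours to scan
#'   (default 12-48 h).
#' @param oversampling frequency-grid oversampling factor (default 10).
#' @return List with `p`, `period`, `z` (peak power), `M`, and `power`
#'   (tibble of `freq`, `period`, `power`).
#' @examples
#' t <- seq(0, 30, by = 6)
#' lomb_scargle(cos(2 * pi * t / 24), t)
#' @export
lomb_scargle <- function(values, times_h, period_range = c(12, 48),
                         oversampling = 10) {
  if (length(values) != length(times_h)) {
    stop("values and times_h must have the same length", call. = FALSE)
  }
  if (length(values) < 4 || any(!is.finite(values))) {
    stop("lomb_scargle requires >= 4 finite values", call. = FALSE)
  }
  if (period_range[1] <= 0 || period_range[2] <= period_range[1]) {
    stop("invalid period_range", call. = FALSE)
  }
  span <- diff(range(times_h))
  f_lo <- 1 / period_range[2]
  f_hi <- 1 / period_range[1]
  freqs <- seq(f_lo, f_hi, by = 1 / (oversampling * span))
  M <- max(1L, floor((f_hi - f_lo) * span) + 1L)

  xc <- values - mean(values)
  s2 <- sum(xc^2) / (length(values) - 1)
  if (s2 == 0) {
    power <- tibble::tibble(freq = freqs, period = 1 / freqs,
                            power = rep(0, length(freqs)))
    return(list(p = 1, period = NA_real_, z = 0, M = M, power = power))
  }
  pw <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * times_h)), sum(cos(2 * w * times_h))) / (2 * w)
    ct <- cos(w * (times_h - tau))
    st <- sin(w * (times_h - tau))
    cc <- sum(ct^2)
    ss <- sum(st^2)
    term_c <- if (cc > 1e-12) sum(xc * ct)^2 / cc else 0
    term_s <- if (ss > 1e-12) sum(xc * st)^2 / ss else 0
    (term_c + term_s) / (2 * s2)
  }, numeric(1))

  i <- which.max(pw)
  z <- pw[i]
  # p = 1 - (1 - exp(-z))^M, computed on the log scale for stability
  p <- if (z <= 0) 1 else -expm1(M * log1p(-exp(-z)))
  p <- min(max(p, 0), 1)
  list(p = p, period = 1 / freqs[i], z = z, M = M,
       power = tibble::tibble(freq = freqs, period = 1 / freqs, power = pw))
}
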