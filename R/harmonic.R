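#' Cosinor (harmonic) regression at a fixed 24-hour period
#'
#' Ordinary least squares of
#' `y = m + a*cos(2*pi*t/24) + b*sin(2*pi*t/24)`.
#' The amplitude `A = sqrt(a^2 + b^2)` is half the peak-to-trough difference
#' on the log2 scale; the phase `phi = (24/2pi) * atan2(b, a) mod 24` is the
#' peak time in hours; the p-value is the F-test of the two rhythm
#' coefficients against the intercept-only model, with (2, n - 3) degrees of
#' freedom. Because the response is log2 expression, the linear-scale
#' peak-to-trough fold change is `2^(2A)`.
#'
#' @param times sampling times in hours (taken mod 24).
#' @param values log2 expression, same length.
#' @return list of class `harmonic_fit`: `n`, `mesor`, `coef_cos`,
#'   `coef_sin`, `amplitude`, `phase`, `p_value`, `log2_ptt` (= 2A) and
#'   `fc_ptt` (= 2^(2A)).
#' @examples
#' t <- seq(0, 22, by = 2)
#' fit_harmonic(t, 5 + cos(2 * pi * t / 24))
#' @export
fit_harmonic <- function(times, values) {
  stopifnot(length(times) == length(values))
  keep <- is.finite(times) & is.finite(values)
  times <- times[keep] %% 24
  values <- values[keep]
  n <- length(values)
  if (n < 4) stop("harmonic fit requires n >= 4")
  if (length(unique(round(times, 9))) < 2)
    stop("harmonic fit not estimable: all times equal (mod 24)")
  w <- 2 * pi * times / 24
  X <- cbind(1, cos(w), sin(w))
  fit <- lm.fit(X, values)
  if (fit$rank < 3) stop("harmonic fit not estimable: singular design")
  cf <- fit$coefficients
  rss <- sum(fit$residuals^2)
  tss <- sum((values - mean(values))^2)
  amplitude <- sqrt(cf[2]^2 + cf[3]^2)
  phase <- (atan2(cf[3], cf[2]) * 24 / (2 * pi)) %% 24
  if (phase >= 24) phase <- 0
  if (tss <= .Machine$double.eps * n) {        # constant response
    fstat <- 0; p <- 1
  } else {
    fstat <- ((tss - rss) / 2) / (rss / (n - 3))
    p <- pf(fstat, 2, n - 3, lower.tail = FALSE)
  }
  structure(list(n = n, mesor = unname(cf[1]),
                 coef_cos = unname(cf[2]), coef_sin = unname(cf[3]),
                 amplitude = unname(amplitude), phase = unname(phase),
                 f_stat = unname(fstat), p_value = unname(p),
                 log2_ptt = unname(2 * amplitude),
                 fc_ptt = unname(2^(2 * amplitude))),
            class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf(
    "<harmonic_fit> n=%d mesor=%.3f A=%.3f phase=%.2fh fc(ptt)=%.2f p=%.3g\n",
    x$n, x$mesor, x$amplitude, x$phase, x$fc_ptt, x$p_value))
  invisible(x)
}

#' Classify a cosinor fit as rhythmic
#'
#' A gene is called rhythmic in a group when the fit's p-value is at most
#' `p_max` and the peak-to-trough fold change is at least `fc_min`; ties at
#' either threshold pass.
#'
#' @param fit a [fit_harmonic()] result.
#' @param p_max p-value ceiling (default 1e-4).
#' @param fc_min peak-to-trough fold-change floor (default 1.5).
#' @return logical.
#' @export
is_rhythmic <- function(fit, p_max = 1e-4, fc_min = 1.5) {
  stopifnot(inherits(fit, "harmonic_fit"))
  fit$p_value <= p_max && fit$fc_ptt >= fc_min
}

#' Circular distance between two peak phases
#'
#' @param phi1,phi2 phases in hours, `[0, 24)`.
#' @return hours in `[0, 12]`.
#' @examples
#' phase_difference(23, 1)  # 2
#' @export
phase_difference <- function(phi1, phi2) {
  d <- abs(phi1 - phi2) %% 24
  min(d, 24 - d)
}
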