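# Scalar summaries of PRC shape: peak-to-baseline ratio, sigmoid fit of its
# rate dependence, and the peak-location time transform.

#' Peak-to-baseline ratio of a PRC
#'
#' Concise shape summary contrasting the extrema of largest absolute value in
#' the early (\eqn{\varphi \in [0, 0.5]}) and late (\eqn{[0.5, 1]}) halves of
#' the curve:
#' \deqn{r = \frac{|m_l - m_e|}{|m_l| + |m_e|}.}
#' `r = 0` for a flat (phase-independent) curve, and `r = 1` whenever the two
#' extrema have opposite signs, as in type-II PRCs. The ratio is invariant to
#' positive rescaling of the curve, hence to the charge normalisation.
#' The point at `phi = 0.5` belongs to both halves; an exact tie between the
#' halves is resolved to the late one.
#'
#' @param curve A `smoothed_prc` (or any data frame with `phi`, `z` covering
#'   \[0, 1\]).
#' @return A one-row tibble: `m_e`, `m_l` (1/pC), `phi_e`, `phi_l`, `r`,
#'   `flat` (TRUE when the curve is identically zero, in which case `r = 0`
#'   with a warning).
#' @export
peak_to_baseline <- function(curve) {
  stopifnot(all(c("phi", "z") %in% names(curve)))
  early <- curve[curve$phi <= 0.5, ]
  late <- curve[curve$phi >= 0.5, ]
  if (nrow(early) == 0 || nrow(late) == 0) {
    abort("curve must cover both halves of [0, 1]",
          class = "prcclamp_error_curve")
  }
  ie <- which.max(abs(early$z))
  il <- which.max(abs(late$z))
  m_e <- early$z[ie]
  m_l <- late$z[il]
  if (abs(m_l) + abs(m_e) == 0) {
    warn("curve is identically zero; peak-to-baseline ratio undefined, returning 0")
    r <- 0
    flat <- TRUE
  } else {
    r <- abs(m_l - m_e) / (abs(m_l) + abs(m_e))
    flat <- FALSE
  }
  tibble(m_e = m_e, m_l = m_l,
         phi_e = early$phi[ie], phi_l = late$phi[il],
         r = r, flat = flat)
}

#' Sigmoid fit of the rate dependence of the peak-to-baseline ratio
#'
#' Fits the two-parameter logistic
#' \deqn{r(F) = \left(1 + e^{-(F - a)/b}\right)^{-1}}
#' to (firing rate, r) pairs by unweighted least squares. `a` is the midpoint
#' rate (Hz) at which r = 0.5 and `b` the slope scale (Hz). The optimisation
#' is deterministic: a Levenberg-Marquardt fit is started from every point of
#' a fixed grid of initial values and the best solution is kept.
#'
#' @param rates_hz Firing rates, Hz (>= 3 points spanning >= 20 Hz).
#' @param r_values Peak-to-baseline ratios at those rates.
#' @return A `sigmoid_fit` object (list with `a`, `b`, `rss`, `n`, `data`).
#' @export
fit_sigmoid <- function(rates_hz, r_values) {
  stopifnot(length(rates_hz) == length(r_values))
  if (length(rates_hz) < 3 || diff(range(rates_hz)) < 20) {
    abort("need >= 3 points spanning >= 20 Hz", class = "prcclamp_error_fit")
  }
  if (diff(range(r_values)) < sqrt(.Machine$double.eps)) {
    abort("all r values equal; sigmoid parameters are unidentifiable",
          class = "prcclamp_error_fit")
  }
  dat <- data.frame(f = as.double(rates_hz), r = as.double(r_values))
  a0 <- seq(min(dat$f), max(dat$f), length.out = 5)
  b0 <- c(5, 10, 20, 40, 80)
  best <- NULL
  for (a in a0) for (b in b0) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ 1 / (1 + exp(-(f - a) / b)),
        data = dat, start = list(a = a, b = b),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        cf <- coef(fit)
        best <- list(a = unname(cf["a"]), b = unname(cf["b"]), rss = rss)
      }
    }
  }
  if (is.null(best)) abort("sigmoid fit failed from every start",
                           class = "prcclamp_error_fit")
  structure(
    list(a = best$a, b = best$b, rss = best$rss, n = nrow(dat),
         data = as_tibble(dat)),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> r(F) = 1/(1 + exp(-(F - a)/b))\n"))
  cat(sprintf("  a = %.3f Hz (midpoint), b = %.3f Hz (slope scale), rss = %.4g, n = %d\n",
              x$a, x$b, x$rss, x$n))
  invisible(x)
}

#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble(a = x$a, b = x$b, rss = x$rss, n = x$n)
}

#' @export
augment.sigmoid_fit <- function(x, ...) {
  d <- x$data
  d$.fitted <- predict_sigmoid(x, d$f)
  d$.resid <- d$r - d$.fitted
  d
}

predict_sigmoid <- function(fit, f) 1 / (1 + exp(-(f - fit$a) / fit$b))

#' Location of the PRC peak, in phase and in time
#'
#' The global maximum of the smoothed PRC, reported both as a phase
#' `phi_peak` and as a time relative to the AP following the stimulus,
#' \deqn{\tau_{peak} = (\varphi_{peak} - 1) \cdot \langle ISI\rangle \le 0.}
#' A plateau maximum (several grid points within numerical tolerance of the
#' maximum) is resolved to its midpoint, with a warning. The transform is
#' exactly invertible given the mean ISI, so a rate-independent time-to-spike
#' preference appears as `tau_peak` constant across rates.
#'
#' @param curve A `smoothed_prc` (columns `phi`, `z`).
#' @param mean_isi_s Mean ISI, seconds; defaults to the curve's provenance
#'   attribute.
#' @return A one-row tibble: `phi_peak`, `tau_peak_s`, `z_peak`.
#' @export
peak_time <- function(curve, mean_isi_s = NULL) {
  stopifnot(all(c("phi", "z") %in% names(curve)))
  if (is.null(mean_isi_s)) mean_isi_s <- attr(curve, "mean_isi_s", exact = TRUE)
  if (is.null(mean_isi_s)) {
    abort("mean_isi_s not supplied and absent from the curve",
          class = "prcclamp_error_curve")
  }
  zmax <- max(curve$z)
  at <- which(curve$z >= zmax - 1e-12 * max(1, abs(zmax)))
  if (length(at) > 1) {
    warn("plateau maximum; reporting the plateau midpoint")
    phi_peak <- mean(range(curve$phi[at]))
  } else {
    phi_peak <- curve$phi[at]
  }
  tibble(phi_peak = phi_peak,
         tau_peak_s = (phi_peak - 1) * mean_isi_s,
         z_peak = zmax)
}
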