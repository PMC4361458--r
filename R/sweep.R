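# End-to-end rate sweep: closed-loop session -> corrected direct PRC ->
# smoothing -> shape metrics at each target rate, then the sigmoid fit of
# r(F).

#' Run a firing-rate sweep
#'
#' For each target rate (visited in a shuffled order, so slow drifts cannot
#' masquerade as rate dependence): run a closed-loop frequency-clamp session,
#' estimate the corrected direct PRC, smooth it, and compute the shape
#' metrics; finally fit the sigmoid r(F). The neuron can be a fixed
#' simulator or a factory `rate_hz -> neuron` (e.g. built on
#' [prc_rate_family()]) so the ground-truth PRC may itself depend on the
#' rate.
#'
#' @param f_targets_hz Target rates, Hz (>= 2).
#' @param neuron A simulator object, or a function `rate_hz -> simulator`.
#' @param n_pulses Perturbations per session.
#' @param pulse_amplitude_pA,pulse_duration_s Pulse template.
#' @param seed Integer seed; each session uses `seed + <rate index>`.
#' @param shuffle Visit the rates in a shuffled order (default TRUE).
#' @param out_dir Optional directory: per-rate session archives and the
#'   summary CSV are written there.
#' @param ... Passed to [pid_config()].
#' @return A `rate_sweep` list: `summary` (one row per rate: `f_target_hz`,
#'   `rate_hz`, `r`, `m_e`, `m_l`, `phi_peak`, `tau_peak_ms`, `n_trials`,
#'   `n_samples`, `cv`), `fit` (a `sigmoid_fit`, or NULL if degenerate),
#'   `prcs` (list of `smoothed_prc`).
#' @export
run_rate_sweep <- function(f_targets_hz, neuron, n_pulses = 400,
                           pulse_amplitude_pA = 100, pulse_duration_s = 5e-4,
                           seed = 1, shuffle = TRUE, out_dir = NULL, ...) {
  stopifnot(length(f_targets_hz) >= 2)
  order_idx <- seq_along(f_targets_hz)
  if (shuffle) {
    set.seed(seed)
    order_idx <- sample(order_idx)
  }
  rows <- vector("list", length(f_targets_hz))
  prcs <- vector("list", length(f_targets_hz))
  names(prcs) <- paste0("f", f_targets_hz)
  for (pos in seq_along(order_idx)) {
    i <- order_idx[pos]
    f_t <- f_targets_hz[i]
    nrn <- if (is.function(neuron)) neuron(f_t) else neuron
    session <- run_closed_loop_session(
      nrn, pid_config(f_target = f_t, ...), sobol_scheduler(),
      pulse_amplitude_pA = pulse_amplitude_pA,
      pulse_duration_s = pulse_duration_s,
      n_pulses = n_pulses, seed = seed + i)
    curve <- session_prc(session)
    pb <- peak_to_baseline(curve)
    pk <- peak_time(curve)
    g <- glance.clamp_session(session)
    rows[[i]] <- tibble(
      f_target_hz = f_t,
      rate_hz = g$rate_hz,
      r = pb$r, m_e = pb$m_e, m_l = pb$m_l,
      phi_peak = pk$phi_peak, tau_peak_ms = 1e3 * pk$tau_peak_s,
      n_trials = g$n_pulses, n_samples = attr(curve, "n_samples"),
      cv = g$cv_unperturbed
    )
    prcs[[i]] <- curve
    if (!is.null(out_dir)) {
      write_session(session, file.path(out_dir, sprintf("rate_%03.0f", f_t)))
      write_prc_csv(curve, file.path(out_dir, sprintf("prc_%03.0f.csv", f_t)))
    }
  }
  summary <- dplyr::arrange(dplyr::bind_rows(rows), .data$f_target_hz)
  fit <- tryCatch(fit_sigmoid(summary$rate_hz, summary$r),
                  error = function(e) NULL)
  if (!is.null(out_dir)) {
    readr::write_csv(summary, file.path(out_dir, "summary.csv"))
  }
  structure(list(summary = summary, fit = fit, prcs = prcs),
            class = "rate_sweep")
}

#' @export
print.rate_sweep <- function(x, ...) {
  cat(sprintf("<rate_sweep> %d target rates\n", nrow(x$summary)))
  print(x$summary)
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' @export
tidy.rate_sweep <- function(x, ...) x$summary

#' @export
glance.rate_sweep <- function(x, ...) {
  if (is.null(x$fit)) {
    tibble(n_rates = nrow(x$summary), a = NA_real_, b = NA_real_,
           rss = NA_real_)
  } else {
    tibble(n_rates = nrow(x$summary), a = x$fit$a, b = x$fit$b,
           rss = x$fit$rss)
  }
}
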