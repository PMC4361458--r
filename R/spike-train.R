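# Spike trains, spike detection, ISI statistics and the online rate estimator.
# Internal units: seconds, Hz, pA, pC.

#' Construct a spike train
#'
#' A spike train is a tibble with one row per action potential (AP), holding
#' the AP peak time in seconds and a source label. Times must be strictly
#' increasing so that all inter-spike intervals (ISIs) are positive.
#'
#' @param spike_times Numeric vector of AP peak times, seconds, strictly
#'   increasing.
#' @param source_id Label of the generating cell / simulator (recycled).
#'
#' @return A tibble of class `spike_train` with columns `time_s` and
#'   `source_id`.
#' @export
#' @examples
#' spike_train(c(0.01, 0.03, 0.05))
spike_train <- function(spike_times, source_id = "cell") {
  spike_times <- as.double(spike_times)
  if (anyNA(spike_times) || any(!is.finite(spike_times))) {
    abort("spike times must be finite", class = "prcclamp_error_spikes")
  }
  if (is.unsorted(spike_times, strictly = TRUE)) {
    abort("spike times must be strictly increasing",
          class = "prcclamp_error_spikes")
  }
  out <- tibble(time_s = spike_times, source_id = as.character(source_id))
  class(out) <- c("spike_train", class(out))
  out
}

#' @export
print.spike_train <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<spike_train> %d spikes", n))
  if (n >= 2) {
    span <- diff(range(x$time_s))
    cat(sprintf(", %.3g s, mean rate %.3g Hz", span, (n - 1) / span))
  }
  cat("\n")
  NextMethod()
}

spike_times <- function(train) {
  if (inherits(train, "spike_train") || is.data.frame(train)) train$time_s
  else as.double(train)
}

#' Detect spikes in a voltage trace
#'
#' Finds positive threshold crossings and reports, for each crossing, the time
#' of the local maximum of the suprathreshold segment (the AP peak). Crossings
#' closer than `refractory` to the previous accepted spike are discarded,
#' which prevents double-detection of a single AP.
#'
#' @param trace A data frame with columns `time_s` and `v_mV` (uniformly
#'   sampled membrane potential), e.g. as returned by the simulators.
#' @param threshold Detection threshold, mV.
#' @param refractory Minimum separation between detected spikes, seconds.
#' @param source_id Label for the returned train.
#'
#' @return A [spike_train()]. A threshold above the trace maximum yields an
#'   empty train (not an error).
#' @export
detect_spikes <- function(trace, threshold = -20, refractory = 1e-3,
                          source_id = "detected") {
  stopifnot(is.data.frame(trace), all(c("time_s", "v_mV") %in% names(trace)))
  if (nrow(trace) == 0) {
    abort("empty voltage trace", class = "prcclamp_error_trace")
  }
  if (refractory < 0) abort("refractory must be >= 0")
  v <- trace$v_mV
  if (any(!is.finite(v))) abort("voltage trace contains non-finite values")
  above <- v >= threshold
  # rising edges: below -> above
  up <- which(!above[-length(above)] & above[-1]) + 1L
  if (above[1]) up <- c(1L, up)
  if (length(up) == 0) return(spike_train(numeric(0), source_id))
  down <- which(above[-length(above)] & !above[-1])
  peaks <- vapply(up, function(i) {
    j <- down[down >= i][1]
    if (is.na(j)) j <- length(v)
    i + which.max(v[i:j]) - 1L
  }, integer(1))
  t_peak <- trace$time_s[peaks]
  keep <- logical(length(t_peak))
  last <- -Inf
  for (k in seq_along(t_peak)) {
    if (t_peak[k] - last >= refractory) {
      keep[k] <- TRUE
      last <- t_peak[k]
    }
  }
  spike_train(t_peak[keep], source_id)
}

#' Inter-spike interval statistics
#'
#' Mean ISI, coefficient of variation and firing rate over the non-excluded
#' ISIs of a train. ISI `k` is the interval between spikes `k` and `k + 1`.
#' In perturbation experiments the ISIs containing a pulse (and, optionally,
#' the one immediately after) are excluded so that the mean reflects the
#' unperturbed firing period; see [unperturbed_isi_indices()].
#'
#' @param train A [spike_train()] or numeric vector of spike times.
#' @param exclude Integer indices of ISIs to drop before computing the
#'   statistics.
#'
#' @return A one-row tibble: `mean_isi_s`, `cv`, `rate_hz`, `n_isi`.
#' @export
isi_stats <- function(train, exclude = integer(0)) {
  ts <- spike_times(train)
  isi <- diff(ts)
  if (length(exclude)) isi <- isi[-exclude]
  if (length(isi) < 1 || length(ts) < 2) {
    abort("need at least 2 usable spikes", class = "prcclamp_error_spikes")
  }
  m <- mean(isi)
  tibble(
    mean_isi_s = m,
    # population SD: the CV of the ISI *distribution*
    cv = sqrt(mean((isi - m)^2)) / m,
    rate_hz = 1 / m,
    n_isi = length(isi)
  )
}

#' Indices of unperturbed ISIs
#'
#' Given spike times and pulse times, returns the indices of ISIs that
#' neither contain a pulse nor immediately follow an ISI that does. The mean
#' over these ISIs is the unperturbed-period estimate used for phase
#' assignment; including perturbed ISIs would bias the measured phase shifts
#' toward zero.
#'
#' @param train Spike train or numeric times.
#' @param pulse_times Numeric vector of perturbation onset times, seconds.
#' @return Integer vector of usable ISI indices.
#' @export
unperturbed_isi_indices <- function(train, pulse_times) {
  ts <- spike_times(train)
  n_isi <- length(ts) - 1L
  if (n_isi < 1) return(integer(0))
  hit <- findInterval(pulse_times, ts)
  hit <- hit[hit >= 1L & hit <= n_isi]
  bad <- unique(c(hit, hit + 1L))
  setdiff(seq_len(n_isi), bad[bad <= n_isi])
}

#' Online instantaneous firing-rate estimate
#'
#' Exponentially weighted rate estimator updated once per AP:
#' \deqn{\tilde F_k = ISI_k^{-1} (1 - e^{-ISI_k/\tau}) +
#'       \tilde F_{k-1} e^{-ISI_k/\tau}}
#' with timescale `tau` (default 1 s). The update is a convex combination of
#' the latest inverse ISI and the previous estimate, so for constant ISIs it
#' converges monotonically to the true rate. The closed-loop controller
#' initialises the estimate at its target rate to avoid start-up transients.
#'
#' @param f_hat Previous estimate, Hz (initialise at the target rate).
#' @param isi_k Latest inter-spike interval, seconds (> 0).
#' @param tau Estimator timescale, seconds.
#' @return Updated estimate, Hz.
#' @export
update_rate_estimate <- function(f_hat, isi_k, tau = 1) {
  if (!is.finite(isi_k) || isi_k <= 0) {
    abort("isi_k must be > 0", class = "prcclamp_error_rate")
  }
  stopifnot(tau > 0, f_hat >= 0)
  w <- exp(-isi_k / tau)
  (1 - w) / isi_k + f_hat * w
}
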