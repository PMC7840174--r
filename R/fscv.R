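#' Simulate a series of stimulated dopamine transients
#'
#' Emulates the oxidation-potential current recorded with fast-scan
#' cyclic voltammetry around repeated stimulations: each sweep holds one
#' release transient with double-exponential shape (normalized so its
#' noise-free peak equals the programmed amplitude), geometric
#' per-stimulation rundown, and a multiplicative drug effect from a
#' given stimulation onward. Stimulations are spaced uniformly (120 s
#' electrical / 180 s optical by convention).
#'
#' @param n_stims number of stimulations.
#' @param peak_nA noise-free peak of the first stimulation (nA).
#' @param rise_tau_s,decay_tau_s transient shape time constants (s, > 0).
#' @param noise_sd_nA SD of Gaussian amplitude noise added to each
#'   stimulation's realized peak (release variability between
#'   stimulations, the variance component that matters for
#'   percent-of-baseline summaries).
#' @param rundown_per_stim fractional amplitude loss per stimulation in
#'   `[0, 1)`: stimulation k (1-based) has true peak
#'   `peak_nA * (1 - rundown_per_stim)^(k-1)`.
#' @param drug_start_idx first stimulation index (1-based) at which the
#'   drug is present; `NULL` for none.
#' @param drug_scale multiplicative drug effect on the true peak (> 0).
#' @param offset_nA constant background offset added to every sample
#'   (removed by [background_subtract()]).
#' @param stim_interval_s inter-stimulation interval.
#' @param pre_stim_window_s seconds of pre-stimulation data kept per
#'   sweep (background window, default 1 s).
#' @param sweep_s post-stimulation seconds per sweep.
#' @param sample_hz sweep sampling rate.
#' @param seed integer seed.
#' @return object of class `transient_series`: `t` (sweep time, 0 =
#'   stimulation), `current` (matrix, time x stimulation, nA),
#'   `stim_times`, `true_peaks_nA` (realized per-stimulation peaks,
#'   amplitude noise included), `pre_stim_window_s`.
#' @export
simulate_transients <- function(n_stims = 10, peak_nA = 1,
                                rise_tau_s = 0.1, decay_tau_s = 0.5,
                                noise_sd_nA = 0, rundown_per_stim = 0,
                                drug_start_idx = NULL, drug_scale = 1,
                                offset_nA = 0, stim_interval_s = 120,
                                pre_stim_window_s = 1, sweep_s = 3,
                                sample_hz = 100, seed = NULL) {
  if (rise_tau_s <= 0 || decay_tau_s <= 0)
    abort_clampresp("time constants must be > 0", "spec_error")
  if (rundown_per_stim < 0 || rundown_per_stim >= 1)
    abort_clampresp("rundown_per_stim must lie in [0, 1)", "spec_error")
  if (drug_scale <= 0) abort_clampresp("drug_scale must be > 0", "spec_error")
  if (pre_stim_window_s >= stim_interval_s)
    abort_clampresp("pre_stim_window_s must be shorter than the stimulation interval",
                    "spec_error")
  t <- seq(-pre_stim_window_s, sweep_s, by = 1 / sample_hz)
  shape <- ifelse(t > 0, (1 - exp(-t / rise_tau_s)) * exp(-t / decay_tau_s), 0)
  shape <- shape / max(shape)   # programmed peak is exact on the grid
  k <- seq_len(n_stims)
  peaks <- peak_nA * (1 - rundown_per_stim)^(k - 1)
  if (!is.null(drug_start_idx))
    peaks[k >= drug_start_idx] <- peaks[k >= drug_start_idx] * drug_scale
  if (noise_sd_nA > 0)
    peaks <- peaks + with_seed_if(seed, stats::rnorm(n_stims, 0, noise_sd_nA))
  cur <- outer(shape, peaks) + offset_nA
  structure(list(t = t, current = cur,
                 stim_times = (k - 1) * stim_interval_s,
                 true_peaks_nA = peaks,
                 pre_stim_window_s = pre_stim_window_s),
            class = "transient_series")
}

#' Subtract the pre-stimulation background from each sweep
#'
#' Removes the mean current over the `pre_stim_window` seconds before
#' stimulation from every sweep, so the corrected pre-stimulation mean
#' is 0.
#'
#' @param series a [simulate_transients()] result, or a list with `t`
#'   and a `current` matrix (time x stimulation).
#' @param pre_stim_window_s background window length (s); default the
#'   series' own.
#' @return the series with `current` background-corrected.
#' @export
background_subtract <- function(series, pre_stim_window_s = NULL) {
  w <- pre_stim_window_s %||% series$pre_stim_window_s
  pre <- series$t < 0 & series$t >= -w
  if (!any(pre))
    abort_clampresp("no samples in the pre-stimulation window", "window_error")
  bg <- colMeans(series$current[pre, , drop = FALSE])
  series$current <- sweep(series$current, 2L, bg)
  series
}

#' Peak transient amplitude per stimulation
#'
#' @param series a background-corrected series.
#' @param search_window_s two-element window (s, relative to
#'   stimulation) searched for the maximum.
#' @return numeric vector of peak amplitudes (nA), one per stimulation.
#' @export
peak_amplitude <- function(series, search_window_s = c(0, 2)) {
  win <- series$t >= search_window_s[1L] & series$t <= search_window_s[2L]
  if (!any(win))
    abort_clampresp("search window contains no samples", "window_error")
  apply(series$current[win, , drop = FALSE], 2L, max)
}

#' Percent-of-baseline drug effect on transient peaks
#'
#' @param peaks per-stimulation peak amplitudes.
#' @param baseline_idxs,drug_idxs index sets (non-empty) of baseline and
#'   drug-phase stimulations.
#' @param condition label for the effect row.
#' @return object of class `fscv_effect`: `condition`,
#'   `baseline_mean_nA`, `drug_mean_nA`, `percent_of_baseline`.
#' @export
percent_of_baseline <- function(peaks, baseline_idxs, drug_idxs,
                                condition = "") {
  if (length(baseline_idxs) == 0L || length(drug_idxs) == 0L)
    abort_clampresp("baseline and drug index sets must be non-empty", "window_error")
  b <- mean(peaks[baseline_idxs])
  d <- mean(peaks[drug_idxs])
  if (b <= 0)
    abort_clampresp("baseline mean peak must be > 0", "domain_error")
  structure(list(condition = condition, baseline_mean_nA = b,
                 drug_mean_nA = d, percent_of_baseline = 100 * d / b),
            class = "fscv_effect")
}

#' @export
print.fscv_effect <- function(x, ...) {
  cat(sprintf("<fscv_effect> %s: baseline %.3g nA, drug %.3g nA, %.1f%% of baseline\n",
              x$condition, x$baseline_mean_nA, x$drug_mean_nA,
              x$percent_of_baseline))
  invisible(x)
}

#' Quantify a transient series end to end
#'
#' Chains [background_subtract()], [peak_amplitude()] and
#' [percent_of_baseline()].
#'
#' @param series a [simulate_transients()]-shaped series.
#' @param baseline_idxs,drug_idxs stimulation index sets.
#' @param condition label.
#' @param search_window_s peak search window.
#' @return an `fscv_effect`.
#' @export
fscv_quantify <- function(series, baseline_idxs, drug_idxs, condition = "",
                          search_window_s = c(0, 2)) {
  corrected <- background_subtract(series)
  peaks <- peak_amplitude(corrected, search_window_s)
  percent_of_baseline(peaks, baseline_idxs, drug_idxs, condition)
}
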