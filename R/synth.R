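#' Parameters for one synthetic holding-current trace
#'
#' Defaults emulate a stable whole-cell voltage-clamp recording at
#' V_clamp = -60 mV: a holding current of a few tens of pA, iid Gaussian
#' sample noise, optional linear drift, and a drug response with
#' minutes-scale exponential onset and washout.
#'
#' @param baseline_pA baseline holding current.
#' @param noise_sd_pA per-sample Gaussian noise SD (>= 0).
#' @param drift_pA_per_min linear drift slope (0 = stable).
#' @param amp_pA signed response amplitude: > 0 outward, < 0 inward, 0 no
#'   response. May be a vector, recycled over epochs.
#' @param tau_on_s,tau_off_s onset and washout time constants (s, > 0).
#' @param recovery_frac fraction of the response that washes out in
#'   `[0, 1]`; 1 = full recovery to baseline.
#' @param sample_hz sampling rate.
#' @param ar1 optional AR(1) coefficient in `[0, 1)` for temporally
#'   correlated noise (stress-tests the classifier against slow wander);
#'   0 gives iid noise. Stationary marginal SD stays `noise_sd_pA`.
#' @param seed integer seed; identical (params, epochs, seed) give a
#'   bit-identical trace. `NULL` draws from the ambient RNG stream.
#' @return a list of class `synth_params`.
#' @export
synth_params <- function(baseline_pA = 40, noise_sd_pA = 2,
                         drift_pA_per_min = 0, amp_pA = 0,
                         tau_on_s = 30, tau_off_s = 60,
                         recovery_frac = 1, sample_hz = 10,
                         ar1 = 0, seed = NULL) {
  if (noise_sd_pA < 0) abort_clampresp("noise_sd_pA must be >= 0", "spec_error")
  if (tau_on_s <= 0 || tau_off_s <= 0)
    abort_clampresp("tau_on_s and tau_off_s must be > 0", "spec_error")
  if (recovery_frac < 0 || recovery_frac > 1)
    abort_clampresp("recovery_frac must lie in [0, 1]", "spec_error")
  if (ar1 < 0 || ar1 >= 1) abort_clampresp("ar1 must lie in [0, 1)", "spec_error")
  structure(list(baseline_pA = baseline_pA, noise_sd_pA = noise_sd_pA,
                 drift_pA_per_min = drift_pA_per_min, amp_pA = amp_pA,
                 tau_on_s = tau_on_s, tau_off_s = tau_off_s,
                 recovery_frac = recovery_frac, sample_hz = sample_hz,
                 ar1 = ar1, seed = seed),
            class = "synth_params")
}

# Response kernel for one epoch: rises as 1 - exp(-(t - t_on)/tau_on)
# during application, then relaxes toward (1 - recovery_frac) * g(t_off)
# with time constant tau_off.
response_kernel <- function(time, t_on, t_off, tau_on, tau_off, recovery_frac) {
  g <- numeric(length(time))
  during <- time >= t_on & time < t_off
  g[during] <- 1 - exp(-(time[during] - t_on) / tau_on)
  g_off <- 1 - exp(-(t_off - t_on) / tau_on)
  after <- time >= t_off
  g[after] <- g_off * ((1 - recovery_frac) +
                         recovery_frac * exp(-(time[after] - t_off) / tau_off))
  g
}

# Mean of the onset kernel over a window [a, b] seconds after t_on
# (both within the application); closed form used as the oracle for the
# plateau effect a window-mean classifier should report.
#' Expected window-mean of the response kernel during application
#'
#' @param a,b window start/end in seconds after drug onset (within the
#'   application).
#' @param tau_on onset time constant (s).
#' @return mean of `1 - exp(-t/tau_on)` over `[a, b]`.
#' @export
kernel_window_mean <- function(a, b, tau_on) {
  1 - tau_on / (b - a) * (exp(-a / tau_on) - exp(-b / tau_on))
}

#' Simulate one holding-current trace
#'
#' `current(t) = baseline + drift * t + sum_e amp_e * g_e(t) + noise(t)`
#' with the epoch kernel `g_e` of [response_kernel()].
#'
#' @param params a [synth_params()].
#' @param epochs data frame of [drug_epoch()] rows (non-overlapping).
#' @param duration_s total duration; default runs 300 s past the last
#'   epoch offset.
#' @param cell_id,meta,v_clamp passed to [ihold_trace()].
#' @return an [ihold_trace()].
#' @export
simulate_trace <- function(params, epochs, duration_s = NULL,
                           cell_id = "sim", meta = cell_meta(),
                           v_clamp = -60) {
  stopifnot(inherits(params, "synth_params"))
  epochs <- validate_epochs(epochs)
  duration_s <- duration_s %||% (max(epochs$t_off_s) + 300)
  n <- round(duration_s * params$sample_hz)
  time <- (seq_len(n) - 1L) / params$sample_hz
  cur <- params$baseline_pA + params$drift_pA_per_min * time / 60
  amps <- rep(params$amp_pA, length.out = nrow(epochs))
  for (e in seq_len(nrow(epochs))) {
    if (amps[e] != 0)
      cur <- cur + amps[e] *
        response_kernel(time, epochs$t_on_s[e], epochs$t_off_s[e],
                        params$tau_on_s, params$tau_off_s,
                        params$recovery_frac)
  }
  noise <- with_seed_if(params$seed, {
    if (params$noise_sd_pA == 0) {
      numeric(n)
    } else if (params$ar1 == 0) {
      stats::rnorm(n, 0, params$noise_sd_pA)
    } else {
      w <- stats::rnorm(n, 0, params$noise_sd_pA * sqrt(1 - params$ar1^2))
      as.numeric(stats::filter(w, params$ar1, method = "recursive"))
    }
  })
  ihold_trace(cell_id, time, cur + noise, v_clamp = v_clamp,
              epochs = epochs, meta = meta)
}

#' Specification of a simulated cohort
#'
#' Mixture of response classes plus concentration dependence and
#' desensitization, mirroring the structure of an agonist-response
#' population study: a majority of outward responders, a minority of
#' inward responders seen only at low concentrations, and non-responders.
#' Class default probabilities follow a 44/15/27-of-86 split; saturating
#' amplitudes default to 20 +/- 10 pA outward and -16 +/- 8 pA inward;
#' concentration scaling is a Hill factor with EC50 8 nM; a prior
#' application at >= 100 nM multiplies later response amplitudes by
#' `desens_frac` (default 0.14).
#'
#' @param n_cells number of cells.
#' @param p_outward,p_inward,p_none class probabilities, sum to 1 within
#'   1e-9.
#' @param amp_mean_out,amp_sd_out saturating outward amplitude mean/SD
#'   (pA); draws are truncated to be positive.
#' @param amp_mean_in,amp_sd_in saturating inward amplitude mean/SD
#'   (negative mean); draws truncated negative.
#' @param ec50_nM,hill_n Hill scaling `c^n / (c^n + EC50^n)` applied to
#'   the cell amplitude at each epoch concentration.
#' @param inward_max_conc_nM inward responses occur only at
#'   concentrations <= this (above it an inward cell contributes 0).
#' @param desens_threshold_nM,desens_frac epochs after a first
#'   application at concentration >= the threshold have their amplitude
#'   multiplied by `desens_frac`.
#' @param seed integer seed for reproducible cohorts.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cells = 86,
                        p_outward = 44 / 86, p_inward = 15 / 86,
                        p_none = 27 / 86,
                        amp_mean_out = 20, amp_sd_out = 10,
                        amp_mean_in = -16, amp_sd_in = 8,
                        ec50_nM = 8, hill_n = 1,
                        inward_max_conc_nM = 100,
                        desens_threshold_nM = 100, desens_frac = 0.14,
                        seed = NULL) {
  p <- c(p_outward, p_inward, p_none)
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9)
    abort_clampresp("class probabilities must lie in [0,1] and sum to 1", "spec_error")
  if (desens_frac < 0 || desens_frac > 1)
    abort_clampresp("desens_frac must lie in [0, 1]", "spec_error")
  structure(list(n_cells = as.integer(n_cells), p_outward = p_outward,
                 p_inward = p_inward, p_none = p_none,
                 amp_mean_out = amp_mean_out, amp_sd_out = amp_sd_out,
                 amp_mean_in = amp_mean_in, amp_sd_in = amp_sd_in,
                 ec50_nM = ec50_nM, hill_n = hill_n,
                 inward_max_conc_nM = inward_max_conc_nM,
                 desens_threshold_nM = desens_threshold_nM,
                 desens_frac = desens_frac, seed = seed),
            class = "cohort_spec")
}

#' Hill occupancy factor
#'
#' @param conc_nM concentration(s) in nM.
#' @param ec50_nM half-maximal concentration.
#' @param hill_n Hill coefficient.
#' @return `conc^n / (conc^n + ec50^n)`.
#' @export
hill_factor <- function(conc_nM, ec50_nM, hill_n = 1) {
  conc_nM^hill_n / (conc_nM^hill_n + ec50_nM^hill_n)
}

rnorm_trunc <- function(mean, sd, sign) {
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (sign * x > 0) return(x)
  }
  sign * abs(mean)
}

#' Simulate a labeled cohort of traces
#'
#' Each cell draws a response class from the mixture, a saturating
#' amplitude for that class, and realizes per-epoch amplitudes as
#' `amp * hill_factor(conc)` with inward suppression above
#' `inward_max_conc_nM` and desensitization after a first application at
#' `>= desens_threshold_nM`.
#'
#' @param spec a [cohort_spec()].
#' @param protocol data frame of [drug_epoch()] rows applied to every
#'   cell.
#' @param params per-cell [synth_params()] defaults (`amp_pA` and `seed`
#'   are overridden per cell).
#' @param duration_s passed to [simulate_trace()].
#' @return list with `traces` (list of [ihold_trace()]) and `truth`, a
#'   data frame (cell_id, epoch, conc_nM, class, true_amp_pA) recording
#'   the generative ground truth.
#' @export
simulate_cohort <- function(spec, protocol, params = synth_params(),
                            duration_s = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  protocol <- validate_epochs(protocol)
  n_ep <- nrow(protocol)
  hill <- hill_factor(protocol$conc_nM, spec$ec50_nM, spec$hill_n)
  # desensitized epochs: any strictly earlier epoch at >= threshold
  desens <- vapply(seq_len(n_ep), function(e)
    e > 1L && any(protocol$conc_nM[seq_len(e - 1L)] >= spec$desens_threshold_nM),
    logical(1))
  draws <- with_seed_if(spec$seed, {
    cls <- sample(c("outward", "inward", "none"), spec$n_cells, replace = TRUE,
                  prob = c(spec$p_outward, spec$p_inward, spec$p_none))
    amp <- vapply(cls, function(cl) switch(cl,
      outward = rnorm_trunc(spec$amp_mean_out, spec$amp_sd_out, +1),
      inward = rnorm_trunc(spec$amp_mean_in, spec$amp_sd_in, -1),
      none = 0), numeric(1))
    list(cls = cls, amp = amp)
  })
  traces <- vector("list", spec$n_cells)
  truth <- vector("list", spec$n_cells)
  for (i in seq_len(spec$n_cells)) {
    amps <- draws$amp[i] * hill
    if (draws$cls[i] == "inward")
      amps[protocol$conc_nM > spec$inward_max_conc_nM] <- 0
    amps[desens] <- amps[desens] * spec$desens_frac
    p_i <- params
    p_i$amp_pA <- amps
    p_i$seed <- derive_seed(spec$seed, i)
    id <- sprintf("cell%04d", i)
    traces[[i]] <- simulate_trace(p_i, protocol, duration_s = duration_s,
                                  cell_id = id,
                                  meta = cell_meta(region = "VTA"))
    truth[[i]] <- data.frame(cell_id = id, epoch = seq_len(n_ep),
                             conc_nM = protocol$conc_nM,
                             class = draws$cls[i], true_amp_pA = amps,
                             stringsAsFactors = FALSE)
  }
  list(traces = traces, truth = do.call(rbind, truth))
}
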