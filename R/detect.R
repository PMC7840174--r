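#' Detection configuration
#'
#' Tunables of the window-based classifier: 30-s bins, the last eight
#' binned pre-drug points versus the last eight binned points during
#' application (a 4-min window each), two-sided alpha 0.05, and an
#' optional secondary magnitude criterion (`min_effect_pA`, e.g. 1.5 pA;
#' default 0 = off).
#'
#' @param bin_width_s bin width in seconds.
#' @param n_baseline_bins,n_drug_bins bins per comparison window (>= 2).
#' @param alpha significance level in (0, 1).
#' @param min_effect_pA minimum |effect| to call a response (pA).
#' @param welch use Welch's unequal-variance t test instead of the
#'   default pooled-variance Student test.
#' @return a list of class `detection_config`.
#' @export
detection_config <- function(bin_width_s = 30, n_baseline_bins = 8,
                             n_drug_bins = 8, alpha = 0.05,
                             min_effect_pA = 0, welch = FALSE) {
  if (n_baseline_bins < 2 || n_drug_bins < 2)
    abort_clampresp("window bin counts must be >= 2", "spec_error")
  if (alpha <= 0 || alpha >= 1)
    abort_clampresp("alpha must lie in (0, 1)", "spec_error")
  structure(list(bin_width_s = bin_width_s,
                 n_baseline_bins = as.integer(n_baseline_bins),
                 n_drug_bins = as.integer(n_drug_bins), alpha = alpha,
                 min_effect_pA = min_effect_pA, welch = isTRUE(welch)),
            class = "detection_config")
}

#' Bin a trace into fixed-width means
#'
#' Bin `k` covers `[t0 + (k-1)*w, t0 + k*w)`; its value is the arithmetic
#' mean of all samples in that interval. A trailing partial bin is
#' discarded (`floor(duration / w)` bins).
#'
#' @param trace an [ihold_trace()].
#' @param bin_width_s bin width (s); trace duration must be at least two
#'   bins.
#' @return an object of class `binned_trace` with `bin_times` (bin start
#'   times), `bin_means` (pA), and the source epochs/metadata.
#' @export
bin_trace <- function(trace, bin_width_s = 30) {
  stopifnot(inherits(trace, "ihold_trace"))
  dt <- (trace$time[length(trace$time)] - trace$time[1L]) /
    (length(trace$time) - 1L)
  duration <- length(trace$time) * dt
  n_bins <- floor(duration / bin_width_s + 1e-9)
  if (n_bins < 2L)
    abort_clampresp("trace shorter than two bins", "window_error")
  idx <- floor((trace$time - trace$time[1L]) / bin_width_s + 1e-9) + 1L
  keep <- idx <= n_bins
  means <- as.numeric(rowsum(trace$current[keep], idx[keep])) /
    tabulate(idx[keep], n_bins)
  structure(list(cell_id = trace$cell_id,
                 bin_width_s = bin_width_s,
                 bin_times = trace$time[1L] + (seq_len(n_bins) - 1L) * bin_width_s,
                 bin_means = means,
                 epochs = trace$epochs, meta = trace$meta),
            class = "binned_trace")
}

resolve_epoch <- function(binned, epoch) {
  if (is.numeric(epoch) && length(epoch) == 1L) {
    if (epoch < 1 || epoch > nrow(binned$epochs))
      abort_clampresp("epoch index out of range", "epoch_error")
    binned$epochs[epoch, , drop = FALSE]
  } else {
    epoch
  }
}

# Bin-index windows used by the classifier: last n_base bins starting
# strictly before t_on, last n_drug bins starting within [t_on, t_off).
classifier_windows <- function(binned, epoch, cfg) {
  starts <- binned$bin_times
  base_idx <- which(starts < epoch$t_on_s)
  if (length(base_idx) < cfg$n_baseline_bins)
    abort_clampresp("fewer baseline bins than the configured window", "window_error")
  base_idx <- utils::tail(base_idx, cfg$n_baseline_bins)
  drug_idx <- which(starts >= epoch$t_on_s & starts < epoch$t_off_s)
  if (length(drug_idx) < 2L)
    abort_clampresp("fewer than two bins within the drug application", "window_error")
  truncated <- length(drug_idx) < cfg$n_drug_bins
  drug_idx <- utils::tail(drug_idx, min(length(drug_idx), cfg$n_drug_bins))
  list(base = base_idx, drug = drug_idx, truncated = truncated)
}

#' Classify the response to one drug application
#'
#' Student's two-sample t test (pooled variance by default) between the
#' last `n_baseline_bins` pre-drug bin means and the last `n_drug_bins`
#' bin means during application. The effect size is the drug-window mean
#' minus the baseline-window mean. Direction is `"none"` when
#' `p >= alpha` or `|effect| < min_effect_pA`, otherwise the sign of the
#' effect (`"outward"` for positive). Short (e.g. 2-min pressure) epochs
#' with fewer than `n_drug_bins` full bins use all available drug bins
#' (>= 2) and are flagged `truncated`.
#'
#' @param binned a [bin_trace()] result.
#' @param epoch an epoch row of `binned$epochs`, or its index.
#' @param cfg a [detection_config()].
#' @return an object of class `response_call`: `p_value`, `direction`,
#'   `effect_pA`, window index ranges, `truncated`, plus cell id,
#'   concentration and metadata for cohort summaries.
#' @export
classify_response <- function(binned, epoch, cfg = detection_config()) {
  stopifnot(inherits(binned, "binned_trace"))
  epoch <- resolve_epoch(binned, epoch)
  w <- classifier_windows(binned, epoch, cfg)
  base <- binned$bin_means[w$base]
  drug <- binned$bin_means[w$drug]
  tt <- t_test(drug, base, welch = cfg$welch)
  effect <- mean(drug) - mean(base)
  direction <- if (tt$p >= cfg$alpha || abs(effect) < cfg$min_effect_pA) {
    "none"
  } else if (effect > 0) "outward" else "inward"
  structure(list(cell_id = binned$cell_id, drug = epoch$drug,
                 conc_nM = epoch$conc_nM, delivery = epoch$delivery,
                 p_value = tt$p, direction = direction, effect_pA = effect,
                 baseline_window = range(w$base), drug_window = range(w$drug),
                 truncated = w$truncated, meta = binned$meta),
            class = "response_call")
}

#' @export
print.response_call <- function(x, ...) {
  cat(sprintf("<response_call> %s %s %g nM (%s): %s, effect %.2f pA, p = %.3g%s\n",
              x$cell_id, x$drug, x$conc_nM, x$delivery, x$direction,
              x$effect_pA, x$p_value,
              if (x$truncated) " [truncated drug window]" else ""))
  invisible(x)
}

#' Classify every epoch of a trace
#'
#' @param trace an [ihold_trace()].
#' @param cfg a [detection_config()].
#' @return a list of [classify_response()] calls, one per epoch.
#' @export
classify_trace <- function(trace, cfg = detection_config()) {
  binned <- bin_trace(trace, cfg$bin_width_s)
  lapply(seq_len(nrow(trace$epochs)), function(e)
    classify_response(binned, e, cfg))
}

#' Sliding-window validation of a classification
#'
#' Compares every 4-min (=`n_baseline_bins`-bin) window, advancing one
#' bin at a time from the first bin through the last full window, against
#' the fixed baseline window (the bins immediately preceding drug onset)
#' with Student's t test; p values are Bonferroni-corrected over the
#' number of windows tested for this cell. A well-behaved drug response
#' shows one contiguous run of significant windows overlapping the
#' application; significance during washout suggests drift.
#'
#' @param binned a [bin_trace()] result.
#' @param epoch epoch row or index (fixes the baseline window).
#' @param cfg a [detection_config()].
#' @return an object of class `sliding_window_result`: `window_starts`
#'   (first bin index of each window), `raw_p`, `corrected_p`,
#'   `significant`, `max_consecutive`, `onset_bin`, and
#'   `washout_present` (FALSE flags a degraded result with no
#'   post-application bins).
#' @export
sliding_window <- function(binned, epoch, cfg = detection_config()) {
  stopifnot(inherits(binned, "binned_trace"))
  epoch <- resolve_epoch(binned, epoch)
  w <- classifier_windows(binned, epoch, cfg)
  base <- binned$bin_means[w$base]
  width <- cfg$n_baseline_bins
  n_bins <- length(binned$bin_means)
  starts <- seq_len(n_bins - width + 1L)
  raw_p <- vapply(starts, function(s) {
    t_test(binned$bin_means[s:(s + width - 1L)], base, welch = cfg$welch)$p
  }, numeric(1))
  corrected <- bonferroni(raw_p)
  sig <- corrected < cfg$alpha
  onset_bin <- which(binned$bin_times >= epoch$t_on_s)[1L]
  structure(list(cell_id = binned$cell_id, window_starts = starts,
                 raw_p = raw_p, corrected_p = corrected, significant = sig,
                 max_consecutive = max_true_run(sig),
                 onset_bin = onset_bin, baseline_start = w$base[1L],
                 washout_present = any(binned$bin_times >= epoch$t_off_s)),
            class = "sliding_window_result")
}

#' Proportion of cells significant per onset-aligned window
#'
#' Aligns each cell's sliding-window result to its drug-onset bin and
#' reports, for each aligned window start, the fraction of cells whose
#' window was significant after correction.
#'
#' @param results list of [sliding_window()] results sharing bin width
#'   and epoch alignment.
#' @return data frame with `offset_bins` (window start relative to the
#'   onset bin), `prop_significant`, and `n_cells` contributing at that
#'   offset. Empty input gives an empty data frame.
#' @export
window_histogram <- function(results) {
  if (length(results) == 0L)
    return(data.frame(offset_bins = integer(0),
                      prop_significant = numeric(0), n_cells = integer(0)))
  per <- lapply(results, function(r)
    data.frame(offset_bins = r$window_starts - r$onset_bin,
               significant = r$significant))
  all <- do.call(rbind, per)
  agg <- aggregate(significant ~ offset_bins, data = all,
                   FUN = function(x) c(mean(x), length(x)))
  data.frame(offset_bins = agg$offset_bins,
             prop_significant = agg$significant[, 1L],
             n_cells = as.integer(agg$significant[, 2L]))
}

#' Desensitization ratio of two responses in the same cell
#'
#' Signed ratio of the second response's effect size to the first's;
#' 1 means no desensitization, 0 a fully abolished second response.
#'
#' @param call1,call2 [classify_response()] calls for the first and
#'   second applications in one cell.
#' @return `effect2 / effect1`.
#' @export
desensitization_ratio <- function(call1, call2) {
  if (call1$cell_id != call2$cell_id)
    abort_clampresp("calls are from different cells", "domain_error")
  if (call1$effect_pA == 0)
    abort_clampresp("first response effect is zero; ratio undefined", "domain_error")
  call2$effect_pA / call1$effect_pA
}

#' Bind response calls into a data frame
#'
#' @param calls list of [classify_response()] calls.
#' @return data frame with one row per call (cell id, drug,
#'   concentration, delivery, p, effect, direction, truncated flag, and
#'   metadata columns).
#' @export
bind_calls <- function(calls) {
  do.call(rbind, lapply(calls, function(cl)
    data.frame(cell_id = cl$cell_id, drug = cl$drug, conc_nM = cl$conc_nM,
               delivery = cl$delivery, p_value = cl$p_value,
               effect_pA = cl$effect_pA, direction = cl$direction,
               truncated = cl$truncated, region = cl$meta$region,
               th_status = cl$meta$th_status, projection = cl$meta$projection,
               stringsAsFactors = FALSE)))
}

sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_

summarize_one <- function(df, digits) {
  n_out <- sum(df$direction == "outward")
  n_in <- sum(df$direction == "inward")
  n_resp <- n_out + n_in
  n_tot <- nrow(df)
  pct <- function(num, den) if (den > 0) round(100 * num / den, digits) else NA_real_
  out_eff <- df$effect_pA[df$direction == "outward"]
  in_eff <- df$effect_pA[df$direction == "inward"]
  data.frame(n_total = n_tot, n_responsive = n_resp,
             n_outward = n_out, n_inward = n_in,
             pct_responsive = pct(n_resp, n_tot),
             pct_outward_all = pct(n_out, n_tot),
             pct_inward_all = pct(n_in, n_tot),
             pct_outward_responsive = pct(n_out, n_resp),
             pct_inward_responsive = pct(n_in, n_resp),
             mean_effect_outward = if (n_out) mean(out_eff) else NA_real_,
             sem_effect_outward = if (n_out) sem(out_eff) else NA_real_,
             mean_effect_inward = if (n_in) mean(in_eff) else NA_real_,
             sem_effect_inward = if (n_in) sem(in_eff) else NA_real_)
}

#' Cohort summary of response calls
#'
#' Counts and percentages of responsive / outward / inward cells, plus
#' mean +/- SEM of effect sizes by direction, optionally grouped by
#' metadata or concentration columns.
#'
#' @param calls list of [classify_response()] calls or a [bind_calls()]
#'   data frame.
#' @param keys character vector of grouping columns (e.g. `"conc_nM"`,
#'   `"region"`, `"th_status"`, `"projection"`); empty = one overall row.
#' @param digits rounding for percentage columns (default whole
#'   percent).
#' @return data frame of class `cohort_summary`, one row per group.
#' @export
summarize_cohort <- function(calls, keys = character(), digits = 0) {
  df <- if (is.data.frame(calls)) calls else bind_calls(calls)
  if (is.null(df) || nrow(df) == 0L) {
    res <- summarize_one(data.frame(direction = character(0),
                                    effect_pA = numeric(0)), digits)
  } else if (length(keys) == 0L) {
    res <- summarize_one(df, digits)
  } else {
    groups <- split(df, df[keys], drop = TRUE)
    res <- do.call(rbind, lapply(groups, function(g)
      cbind(g[1L, keys, drop = FALSE], summarize_one(g, digits))))
    rownames(res) <- NULL
  }
  class(res) <- c("cohort_summary", "data.frame")
  res
}
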