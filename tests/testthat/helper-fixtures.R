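# Shared fixtures: a standard bath epoch (5-min baseline, 6-min
# application) and parameter builders used across test files.

std_epoch <- function(conc_nM = 10, t_on = 300, t_off = 660,
                      delivery = "bath") {
  drug_epoch("N/OFQ", conc_nM, t_on, t_off, delivery)
}

null_params <- function(...) {
  synth_params(amp_pA = 0, noise_sd_pA = 2, ...)
}

# Noise-free step trace: 40 pA baseline, +step during the epoch.
step_trace <- function(step_pA = 15, epoch = std_epoch(),
                       duration_s = 960, hz = 10) {
  t <- (seq_len(duration_s * hz) - 1) / hz
  cur <- rep(40, length(t))
  cur[t >= epoch$t_on_s & t < epoch$t_off_s] <- 40 + step_pA
  ihold_trace("step", t, cur, epochs = epoch)
}

random_trace <- function() {
  n <- sample(50:300, 1)
  hz <- sample(c(1, 5, 10), 1)
  t <- (seq_len(n) - 1) / hz
  ihold_trace(cell_id = paste0("c", sample(1e6, 1)),
              time = t, current = rnorm(n, 40, 2),
              v_clamp = -60,
              epochs = drug_epoch("N/OFQ", sample(c(10, 100, 1000), 1),
                                  t_on_s = t[5], t_off_s = t[n - 5],
                                  delivery = sample(c("bath", "pressure"), 1)),
              meta = cell_meta(region = sample(c("VTA", "SNc"), 1),
                               th_status = sample(c("positive", "negative",
                                                    "unknown"), 1)))
}

# Constructed response-call table for cohort summaries.
calls_fixture <- function(n_out, n_in, n_none, projection = "unknown") {
  n <- n_out + n_in + n_none
  data.frame(cell_id = sprintf("c%03d", seq_len(n)),
             drug = "N/OFQ", conc_nM = 10, delivery = "bath",
             p_value = c(rep(0.01, n_out + n_in), rep(0.5, n_none)),
             effect_pA = c(rep(10, n_out), rep(-10, n_in), rep(0.1, n_none)),
             direction = c(rep("outward", n_out), rep("inward", n_in),
                           rep("none", n_none)),
             truncated = FALSE, region = "VTA", th_status = "unknown",
             projection = projection, stringsAsFactors = FALSE)
}
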