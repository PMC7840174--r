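REGIONS <- c("VTA", "SNc", "other")
TH_STATUS <- c("positive", "negative", "unknown")
PROJECTIONS <- c("mPFC", "pACC", "NAc", "unknown")
DELIVERY <- c("bath", "pressure")

#' Cell metadata
#'
#' Metadata attached to one recorded neuron: anatomical region, tyrosine
#' hydroxylase (TH) immunoreactivity (the dopaminergic marker), and the
#' retrogradely identified projection target.
#'
#' @param region one of `"VTA"`, `"SNc"`, `"other"`.
#' @param th_status one of `"positive"`, `"negative"`, `"unknown"`.
#' @param projection one of `"mPFC"`, `"pACC"`, `"NAc"`, `"unknown"`.
#' @param notes free text.
#' @return a list of class `cell_meta`.
#' @export
cell_meta <- function(region = "other", th_status = "unknown",
                      projection = "unknown", notes = "") {
  region <- match.arg(region, REGIONS)
  th_status <- match.arg(th_status, TH_STATUS)
  projection <- match.arg(projection, PROJECTIONS)
  structure(list(region = region, th_status = th_status,
                 projection = projection, notes = as.character(notes)),
            class = "cell_meta")
}

#' Drug-application epoch
#'
#' One drug application: agonist identity, concentration, on/off times and
#' delivery route. Bath perfusion epochs are typically 5-7 min; pressure
#' ejection epochs about 2 min; any positive duration is accepted.
#'
#' @param drug drug name, e.g. `"N/OFQ"`.
#' @param conc_nM concentration in nM, must be > 0.
#' @param t_on_s,t_off_s application start/end in seconds from recording
#'   start; `t_off_s > t_on_s`.
#' @param delivery `"bath"` or `"pressure"`.
#' @return a one-row data frame; bind rows to build a protocol.
#' @export
drug_epoch <- function(drug, conc_nM, t_on_s, t_off_s, delivery = "bath") {
  delivery <- match.arg(delivery, DELIVERY)
  if (!is_scalar_number(conc_nM) || conc_nM <= 0)
    abort_clampresp("epoch concentration must be a positive number (nM)", "epoch_error")
  if (!is_scalar_number(t_on_s) || !is_scalar_number(t_off_s) || t_off_s <= t_on_s)
    abort_clampresp("epoch must satisfy t_off_s > t_on_s", "epoch_error")
  data.frame(drug = as.character(drug), conc_nM = conc_nM,
             t_on_s = t_on_s, t_off_s = t_off_s, delivery = delivery,
             stringsAsFactors = FALSE)
}

validate_epochs <- function(epochs, t_min = NULL, t_max = NULL) {
  need <- c("drug", "conc_nM", "t_on_s", "t_off_s", "delivery")
  if (!is.data.frame(epochs) || !all(need %in% names(epochs)))
    abort_clampresp("epochs must be a data frame with columns drug, conc_nM, t_on_s, t_off_s, delivery",
                    "epoch_error")
  if (nrow(epochs) == 0L) return(epochs)
  if (any(epochs$conc_nM <= 0))
    abort_clampresp("epoch concentrations must be > 0 nM", "epoch_error")
  if (any(epochs$t_off_s <= epochs$t_on_s))
    abort_clampresp("every epoch needs t_off_s > t_on_s", "epoch_error")
  if (!all(epochs$delivery %in% DELIVERY))
    abort_clampresp("epoch delivery must be 'bath' or 'pressure'", "epoch_error")
  o <- order(epochs$t_on_s)
  epochs <- epochs[o, , drop = FALSE]
  if (nrow(epochs) > 1L &&
      any(epochs$t_on_s[-1L] < epochs$t_off_s[-nrow(epochs)]))
    abort_clampresp("epochs overlap", "epoch_error")
  if (!is.null(t_min) &&
      (any(epochs$t_on_s < t_min) || any(epochs$t_off_s > t_max)))
    abort_clampresp("epoch lies outside the recorded time range", "epoch_error")
  rownames(epochs) <- NULL
  epochs
}

#' Holding-current trace
#'
#' Container for one cell's voltage-clamp holding-current recording:
#' uniformly sampled time (s) and current (pA) vectors, the clamp potential,
#' the drug-application epochs, and cell metadata. Sign convention: a
#' positive change in holding current is an outward (inhibitory, at
#' -60 mV) current; negative is inward.
#'
#' @param cell_id identifier string.
#' @param time seconds from recording start; strictly increasing, uniform
#'   step (constant to within 1e-6 s).
#' @param current holding current in pA, same length as `time`.
#' @param v_clamp clamp potential in mV (default -60).
#' @param epochs data frame of [drug_epoch()] rows; must lie within the
#'   recorded time range and must not overlap.
#' @param meta a [cell_meta()].
#' @return an object of class `ihold_trace`.
#' @export
ihold_trace <- function(cell_id, time, current, v_clamp = -60,
                        epochs = drug_epoch("none", 1, 0, 1)[0, ],
                        meta = cell_meta()) {
  time <- as.numeric(time)
  current <- as.numeric(current)
  if (length(time) != length(current) || length(time) < 2L)
    abort_clampresp("time and current must have equal length >= 2", "format_error")
  step <- (time[length(time)] - time[1L]) / (length(time) - 1L)
  if (step <= 0 || max(abs(diff(time) - step)) > 1e-6)
    abort_clampresp("sampling step is not uniform to within 1e-6 s", "sampling_error")
  epochs <- validate_epochs(epochs, t_min = time[1L], t_max = time[length(time)])
  if (!inherits(meta, "cell_meta")) meta <- do.call(cell_meta, as.list(meta))
  structure(list(cell_id = as.character(cell_id), time = time,
                 current = current, v_clamp = as.numeric(v_clamp),
                 epochs = epochs, meta = meta),
            class = "ihold_trace")
}

#' @export
print.ihold_trace <- function(x, ...) {
  dt <- x$time[2L] - x$time[1L]
  cat(sprintf("<ihold_trace> %s: %d samples @ %.3g Hz, %.1f s, V_clamp %g mV\n",
              x$cell_id, length(x$time), 1 / dt, diff(range(x$time)) + dt,
              x$v_clamp))
  cat(sprintf("  region %s, TH %s, projection %s; %d epoch(s)\n",
              x$meta$region, x$meta$th_status, x$meta$projection,
              nrow(x$epochs)))
  invisible(x)
}

guess_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE) && !grepl("\t", first, fixed = TRUE)) "," else "\t"
}

#' Read a trace from delimited text plus a JSON sidecar
#'
#' The data file is a two-column delimited table (TSV or CSV) with header
#' columns `time_s` and `current_pA`. The sidecar is JSON holding
#' `cell_id`, `v_clamp_mV`, `epochs` (array of objects with `drug`,
#' `conc_nM`, `t_on_s`, `t_off_s`, `delivery`) and `meta` (`region`,
#' `th_status`, `projection`, `notes`).
#'
#' @param path_data path to the delimited time/current table.
#' @param path_meta path to the JSON sidecar.
#' @return a validated [ihold_trace()].
#' @export
read_trace <- function(path_data, path_meta) {
  tab <- utils::read.table(path_data, header = TRUE, sep = guess_sep(path_data),
                           stringsAsFactors = FALSE)
  if (!all(c("time_s", "current_pA") %in% names(tab)))
    abort_clampresp("data table must have columns time_s and current_pA", "format_error")
  side <- jsonlite::fromJSON(path_meta, simplifyDataFrame = TRUE)
  if (is.null(side$epochs) || (is.data.frame(side$epochs) && nrow(side$epochs) == 0L))
    abort_clampresp("sidecar has no epochs entry", "epoch_error")
  meta <- side$meta %||% list()
  ihold_trace(cell_id = side$cell_id %||% sub("\\.[^.]*$", "", basename(path_data)),
              time = tab$time_s, current = tab$current_pA,
              v_clamp = side$v_clamp_mV %||% -60,
              epochs = as.data.frame(side$epochs),
              meta = cell_meta(region = meta$region %||% "other",
                               th_status = meta$th_status %||% "unknown",
                               projection = meta$projection %||% "unknown",
                               notes = meta$notes %||% ""))
}

#' Write a trace to delimited text plus a JSON sidecar
#'
#' Inverse of [read_trace()]; numeric columns are written with 17
#' significant digits so that read-after-write reproduces the trace
#' exactly.
#'
#' @param trace an [ihold_trace()].
#' @param path_data,path_meta output paths.
#' @return invisibly, `trace`.
#' @export
write_trace <- function(trace, path_data, path_meta) {
  stopifnot(inherits(trace, "ihold_trace"))
  tab <- data.frame(time_s = sprintf("%.17g", trace$time),
                    current_pA = sprintf("%.17g", trace$current))
  utils::write.table(tab, path_data, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- list(cell_id = trace$cell_id, v_clamp_mV = trace$v_clamp,
               epochs = trace$epochs, meta = unclass(trace$meta))
  jsonlite::write_json(side, path_meta, auto_unbox = TRUE, digits = NA)
  invisible(trace)
}

#' Write keyed records as a tab-delimited summary table
#'
#' @param records a data frame, or a list of named lists sharing one key
#'   set (the first record fixes the column order). An empty list writes a
#'   header-only file when `columns` is supplied, otherwise an empty file.
#' @param path output path.
#' @param columns optional character vector fixing the header for empty
#'   input.
#' @return invisibly, the data frame written.
#' @export
write_summary <- function(records, path, columns = NULL) {
  if (is.data.frame(records)) {
    df <- records
  } else if (length(records) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(columns)),
                                 columns))
  } else {
    keys <- names(records[[1L]])
    same <- vapply(records, function(r) setequal(names(r), keys), logical(1))
    if (is.null(keys) || any(!same))
      abort_clampresp("records do not share a common key set", "schema_error")
    df <- do.call(rbind, lapply(records, function(r)
      as.data.frame(r[keys], stringsAsFactors = FALSE)))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
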