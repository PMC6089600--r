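# Plain-text I/O for decay histograms and IRFs: CSV of (bin_index, count)
# or (bin_index, weight) plus a JSON sidecar carrying the time base, ADC
# ratio, seed and ground truth.

#' Write a decay histogram as CSV plus JSON sidecar
#'
#' @param hist a [decay_histogram()].
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @export
write_decay_csv <- function(hist, path) {
  utils::write.csv(data.frame(bin_index = seq_len(hist$n_bins) - 1L,
                              count = hist$counts),
                   path, row.names = FALSE)
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  meta <- list(bin_width_ns = hist$bin_width, adc_ratio = hist$adc_ratio,
               irf_weights = hist$irf$weights, truth = strip(hist$truth))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a decay histogram written by [write_decay_csv()]
#'
#' @param path CSV path with its `<path>.json` sidecar alongside.
#' @return a [decay_histogram()].
#' @export
read_decay_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  irf <- flim_irf(meta$irf_weights, meta$bin_width_ns)
  decay_histogram(d$count, meta$bin_width_ns, meta$adc_ratio, irf,
                  truth = meta$truth)
}

#' Write an FCS curve as CSV
#' @param curve an [fcs_curve()].
#' @param path CSV path.
#' @export
write_fcs_csv <- function(curve, path) {
  utils::write.csv(data.frame(lag_s = curve$lags, G = curve$G),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an FCS curve from CSV
#' @param path CSV with columns `lag_s`, `G`.
#' @param count_rate,background_rate optional detector rates, s^-1.
#' @export
read_fcs_csv <- function(path, count_rate = NA_real_, background_rate = 0) {
  d <- utils::read.csv(path)
  fcs_curve(d$lag_s, d$G, count_rate, background_rate)
}
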