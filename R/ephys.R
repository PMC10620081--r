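# Envelope-analysis pipeline for depth-electrode recordings: Butterworth
# filtering, Hilbert-envelope extraction, epoch-wise modulation metrics,
# contact normalization, depth gradients and interpolated maps.

# Analytic signal x + i*H(x) via the FFT (frequency-domain one-sided
# doubling). Used for envelope extraction; no Hilbert primitive exists in
# the imported signal stack.
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty trace")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Butterworth bandpass filter
#'
#' First-order Butterworth bandpass (0.5-5 kHz for TI recordings, 1-40 Hz
#' for conventional tACS), optionally applied forward-reverse for zero
#' phase distortion.
#'
#' @param trace numeric signal vector.
#' @param fs sampling rate, samples/s.
#' @param lo,hi band edges, Hz; `0 < lo < hi < fs/2`.
#' @param order filter order (default 1).
#' @param zero_phase apply forward-reverse (`signal::filtfilt`) when
#'   TRUE (default), else causal single-pass filtering.
#' @return filtered trace.
#' @export
bandpass <- function(trace, fs, lo, hi, order = 1L, zero_phase = TRUE) {
  if (!(lo > 0 && lo < hi && hi < fs / 2)) stop("invalid band: need 0 < lo < hi < fs/2")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  if (zero_phase) signal::filtfilt(bf, trace) else
    as.numeric(signal::filter(bf, trace))
}

#' Amplitude envelope of a trace
#'
#' Magnitude of the analytic (Hilbert) signal, smoothed with a
#' first-order Butterworth low-pass filter.
#'
#' @param trace bandpassed signal.
#' @param fs sampling rate, samples/s.
#' @param lp_cutoff low-pass cutoff, Hz (default 500).
#' @param zero_phase forward-reverse filtering (default TRUE).
#' @return envelope trace (same length).
#' @export
envelope <- function(trace, fs, lp_cutoff = 500, zero_phase = TRUE) {
  if (length(trace) == 0L) stop("empty trace")
  if (lp_cutoff >= fs / 2) stop("lp_cutoff must be below the Nyquist frequency")
  env <- Mod(analytic_signal(trace))
  bf <- signal::butter(1, lp_cutoff / (fs / 2), type = "low")
  if (zero_phase) signal::filtfilt(bf, env) else
    as.numeric(signal::filter(bf, env))
}

#' Epoch-wise envelope-modulation metrics for one contact
#'
#' Splits the trace into `n_epochs` epochs of `epoch_len` seconds and
#' computes, per epoch, the envelope maximum/minimum and the filtered
#' signal maximum. Reported metrics:
#' \itemize{
#'   \item `modulation_amplitude`: mean over epochs of
#'     (env max - env min)/2, mV — the mean half-difference between the
#'     envelope waveform maxima and minima;
#'   \item `absolute_amplitude`: median over epochs of the per-epoch
#'     signal maxima, mV;
#'   \item `modulation_ratio`: by default the envelope depth
#'     (env max - env min)/env max averaged over epochs (1 for equal
#'     two-tone contributions, 0 for an unmodulated tone); the literal
#'     half-difference reading, which saturates at 0.5, is available via
#'     `ratio_mode = "half_difference"`.
#' }
#' The first and last 100 ms of the trace are excluded from the extrema
#' to avoid filter edge transients.
#'
#' @param trace bandpassed signal, mV.
#' @param fs sampling rate, samples/s.
#' @param epoch_len epoch length, s.
#' @param n_epochs number of epochs (trace must cover them).
#' @param lp_cutoff envelope low-pass cutoff, Hz.
#' @param zero_phase forward-reverse filtering flag.
#' @param ratio_mode `"depth"` or `"half_difference"`.
#' @param edge_exclude leading/trailing exclusion, s.
#' @return list with `modulation_amplitude`, `absolute_amplitude`,
#'   `modulation_ratio`.
#' @export
modulation_metrics <- function(trace, fs, epoch_len = 1, n_epochs = 25,
                               lp_cutoff = 500, zero_phase = TRUE,
                               ratio_mode = c("depth", "half_difference"),
                               edge_exclude = 0.1) {
  ratio_mode <- match.arg(ratio_mode)
  n <- length(trace)
  need <- round(n_epochs * epoch_len * fs)
  if (n < need) stop("trace too short for the requested epochs")
  env <- envelope(trace, fs, lp_cutoff, zero_phase)
  keep_lo <- floor(edge_exclude * fs)
  keep_hi <- n - floor(edge_exclude * fs)
  ep_len_s <- round(epoch_len * fs)
  emax <- emin <- smax <- numeric(n_epochs)
  for (e in seq_len(n_epochs)) {
    i0 <- (e - 1L) * ep_len_s + 1L
    i1 <- min(e * ep_len_s, n)
    sel <- max(i0, keep_lo + 1L):min(i1, keep_hi)
    emax[e] <- max(env[sel])
    emin[e] <- min(env[sel])
    smax[e] <- max(trace[sel])
  }
  ratio <- ifelse(emax > 0,
                  switch(ratio_mode,
                         depth = (emax - emin) / emax,
                         half_difference = (emax - emin) / 2 / emax),
                  0)
  list(modulation_amplitude = mean((emax - emin) / 2),
       absolute_amplitude = median(smax),
       modulation_ratio = mean(ratio))
}

#' Normalize per-contact metrics to their maximum across contacts
#'
#' @param metrics data.frame with numeric metric columns (e.g.
#'   `modulation_amplitude`, `absolute_amplitude`).
#' @param columns which columns to normalize.
#' @return the data.frame with added `normalized_<column>` columns whose
#'   maximum is exactly 1.
#' @export
normalize_across_contacts <- function(metrics,
                                      columns = c("modulation_amplitude",
                                                  "absolute_amplitude")) {
  for (cl in columns) {
    v <- metrics[[cl]]
    if (is.null(v)) stop(sprintf("column %s absent", cl))
    mx <- max(v)
    if (mx == 0) stop(sprintf("all-zero metric vector: %s", cl))
    metrics[[paste0("normalized_", cl)]] <- v / mx
  }
  metrics
}

#' Field estimates from a contact depth profile
#'
#' First spatial derivative of per-contact amplitudes along the electrode
#' shaft: `|delta value| / delta depth` per neighboring contact pair.
#' With values in mV and depths in mm the result is directly in V/m.
#'
#' @param contact_values per-contact amplitudes, mV.
#' @param contact_depths strictly increasing depths, mm.
#' @return data.frame with `mid_depth_mm` (interval midpoints) and
#'   `field_Vm`.
#' @export
depth_profile <- function(contact_values, contact_depths) {
  if (length(contact_values) != length(contact_depths))
    stop("values and depths must have the same length")
  if (length(contact_depths) < 2L) stop("need at least 2 contacts")
  dd <- diff(contact_depths)
  if (any(dd <= 0)) stop("contact depths must be strictly increasing")
  data.frame(mid_depth_mm = contact_depths[-length(contact_depths)] + dd / 2,
             field_Vm = abs(diff(contact_values)) / dd)
}

# 3-point moving average with shrinking windows at the ends
moving_average3 <- function(v) {
  n <- length(v)
  vapply(seq_len(n),
         function(i) mean(v[max(1L, i - 1L):min(n, i + 1L)]), 0)
}

#' Interpolated 2D amplitude map across electrodes
#'
#' Applies a 3-point moving average along each electrode's contacts, then
#' linearly interpolates the electrode-by-contact values onto a regular
#' `nrow x ncol` grid (100 x 151 by default): rows span the electrode
#' position axis, columns the contact depth axis.
#'
#' @param values matrix, contacts x electrodes.
#' @param contact_depths per-contact depths, mm.
#' @param electrode_positions per-electrode coordinate, mm.
#' @param grid_dim output grid size, `c(rows, cols)`.
#' @return `grid_dim` matrix of interpolated amplitudes.
#' @export
interpolate_map <- function(values, contact_depths, electrode_positions,
                            grid_dim = c(100L, 151L)) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("need at least 2 contacts per electrode")
  if (ncol(values) < 2L) stop("need at least 2 electrodes")
  if (nrow(values) != length(contact_depths) ||
      ncol(values) != length(electrode_positions))
    stop("dimension mismatch between values, depths and positions")
  sm <- apply(values, 2, moving_average3)
  dq <- seq(min(contact_depths), max(contact_depths), length.out = grid_dim[2])
  by_depth <- apply(sm, 2, function(col)
    approx(contact_depths, col, xout = dq)$y)     # cols x electrodes
  pq <- seq(min(electrode_positions), max(electrode_positions),
            length.out = grid_dim[1])
  out <- t(apply(by_depth, 1, function(row)
    approx(electrode_positions, row, xout = pq)$y))  # cols x rows
  t(out)  # rows x cols
}

#' Full envelope-analysis pipeline for a recording
#'
#' Per contact: bandpass (0.5-5 kHz for `band = "ti"`, 1-40 Hz for
#' `band = "tacs"`) -> Hilbert envelope -> epoch-wise modulation metrics;
#' then normalization across contacts and depth-gradient field estimates.
#'
#' @param rec a [synth_recording()] (or compatible) recording, data in mV.
#' @param band `"ti"` or `"tacs"`.
#' @param epoch_len,n_epochs epoching parameters (25 x 1 s by default).
#' @param zero_phase forward-reverse filtering flag.
#' @param ratio_mode see [modulation_metrics()].
#' @param lp_cutoff envelope low-pass cutoff, Hz.
#' @return Object of class `ti_metrics`: list with `contacts` (data.frame
#'   of per-contact metrics and normalized values), `profile_modulation`
#'   and `profile_absolute` (depth-gradient data.frames, V/m), and `band`.
#' @export
analyze_recording <- function(rec, band = c("ti", "tacs"),
                              epoch_len = 1, n_epochs = 25,
                              zero_phase = TRUE,
                              ratio_mode = c("depth", "half_difference"),
                              lp_cutoff = 500) {
  band <- match.arg(band)
  ratio_mode <- match.arg(ratio_mode)
  edges <- if (band == "ti") c(500, 5000) else c(1, 40)
  n_c <- nrow(rec$data)
  rows <- lapply(seq_len(n_c), function(k) {
    tr <- bandpass(rec$data[k, ], rec$fs, edges[1], edges[2],
                   zero_phase = zero_phase)
    mm <- modulation_metrics(tr, rec$fs, epoch_len, n_epochs,
                             lp_cutoff = lp_cutoff, zero_phase = zero_phase,
                             ratio_mode = ratio_mode)
    data.frame(contact = k, depth_mm = rec$contact_depths[k],
               modulation_amplitude = mm$modulation_amplitude,
               absolute_amplitude = mm$absolute_amplitude,
               modulation_ratio = mm$modulation_ratio)
  })
  contacts <- normalize_across_contacts(do.call(rbind, rows))
  structure(list(
    contacts = contacts,
    profile_modulation = depth_profile(contacts$modulation_amplitude,
                                       contacts$depth_mm),
    profile_absolute = depth_profile(contacts$absolute_amplitude,
                                     contacts$depth_mm),
    band = band
  ), class = "ti_metrics")
}

#' @export
print.ti_metrics <- function(x, ...) {
  cat(sprintf("ti_metrics (%s band): %d contacts\n", x$band, nrow(x$contacts)))
  print(x$contacts, digits = 4, row.names = FALSE)
  invisible(x)
}
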