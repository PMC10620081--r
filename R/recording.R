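#' Synthesize a two-tone multichannel recording
#'
#' Emulates a depth-electrode recording during temporal-interference
#' stimulation: each contact sees the superposition of two kHz sinusoids
#' with contact-specific amplitudes plus additive white Gaussian noise,
#'
#'   data[k](t) = A1[k] sin(2 pi f1 t) + A2[k] sin(2 pi f2 t) + N(0, sd).
#'
#' @param contact_depths contact depths along the shaft, mm, strictly
#'   increasing.
#' @param A1_profile,A2_profile per-contact amplitudes of the two
#'   carriers, mV.
#' @param f1,f2 carrier frequencies, Hz.
#' @param fs sampling rate, samples/s; must exceed twice the highest
#'   carrier.
#' @param duration trace length, s.
#' @param noise_sd Gaussian noise s.d., mV.
#' @param seed RNG seed for the noise; fixed seed gives identical data.
#' @return Object of class `ti_recording`: list with `data`
#'   (contacts x samples, mV), `fs`, `contact_depths`, `f1`, `f2`.
#' @examples
#' rec <- synth_recording(c(10, 20), c(1, 1), c(1, 0.5), 2005, 2000,
#'                        fs = 30000, duration = 1, noise_sd = 0)
#' dim(rec$data)
#' @export
synth_recording <- function(contact_depths, A1_profile, A2_profile,
                            f1 = 2005, f2 = 2000, fs = 30000,
                            duration = 25, noise_sd = 0, seed = NULL) {
  n_c <- length(contact_depths)
  if (length(A1_profile) != n_c || length(A2_profile) != n_c)
    stop("amplitude profiles must match the number of contacts")
  if (any(diff(contact_depths) <= 0))
    stop("contact depths must be strictly increasing")
  if (fs <= 2 * max(f1, f2))
    stop("sampling rate must exceed twice the highest carrier frequency")
  if (duration <= 0) stop("duration must be > 0")
  n_s <- round(fs * duration)
  t <- (seq_len(n_s) - 1) / fs
  s1 <- sin(2 * pi * f1 * t)
  s2 <- sin(2 * pi * f2 * t)
  data <- outer(A1_profile, s1) + outer(A2_profile, s2)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    data <- data + matrix(rnorm(n_c * n_s, sd = noise_sd), n_c, n_s)
  }
  structure(list(data = data, fs = fs,
                 contact_depths = as.numeric(contact_depths),
                 f1 = f1, f2 = f2),
            class = "ti_recording")
}

#' @export
print.ti_recording <- function(x, ...) {
  cat(sprintf("ti_recording: %d contacts x %d samples @ %g kS/s (%.3g s), carriers %g/%g Hz\n",
              nrow(x$data), ncol(x$data), x$fs / 1000,
              ncol(x$data) / x$fs, x$f1, x$f2))
  invisible(x)
}

#' Write / read a recording as CSV
#'
#' Plain-text interchange: one row per contact, a `depth_mm` column first,
#' sampling rate and carriers in `#`-prefixed header lines.
#'
#' @param rec a `ti_recording`; `path` file path.
#' @return `read_recording_csv` returns a `ti_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g f1=%g f2=%g", rec$fs, rec$f1, rec$f2), con)
  df <- data.frame(depth_mm = rec$contact_depths, rec$data)
  utils::write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1]]
  vals <- setNames(as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  m <- as.matrix(utils::read.table(path, sep = ",", skip = 1L))
  structure(list(data = unname(m[, -1, drop = FALSE]), fs = vals[["fs"]],
                 contact_depths = unname(m[, 1]),
                 f1 = vals[["f1"]], f2 = vals[["f2"]]),
            class = "ti_recording")
}
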