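# Phase linearity measurement (PLM) connectivity.
#
# The PLM between two signals is the fraction of spectral power of the
# interferometric signal z(t) = exp(i * dphi(t)) lying within +-B of zero
# frequency, with dphi the instantaneous phase difference: values near 1
# mean the phase difference evolves (almost) linearly, i.e. the signals
# are phase-synchronized up to a constant frequency offset smaller than B.

#' Canonical frequency bands
#'
#' The five canonical bands used throughout: delta (0.5-4 Hz), theta
#' (4-8 Hz), alpha (8-13 Hz), beta (13-30 Hz), gamma (30-48 Hz).
#'
#' @return data.frame with columns \code{name}, \code{f_lo}, \code{f_hi}.
#' @export
canonical_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             f_lo = c(0.5, 4, 8, 13, 30),
             f_hi = c(4, 8, 13, 30, 48),
             stringsAsFactors = FALSE)
}

band_definition <- function(band) {
  if (is.character(band)) {
    b <- canonical_bands()
    row <- b[b$name == band, ]
    if (nrow(row) != 1) stop("unknown band '", band, "'")
    return(list(name = row$name, f_lo = row$f_lo, f_hi = row$f_hi))
  }
  stopifnot(is.list(band), band$f_lo > 0, band$f_lo < band$f_hi)
  band
}

#' PLM estimator parameters
#'
#' @param B half-bandwidth in Hz of the near-zero integration window; the
#'   full window 2B defaults to 1 Hz.
#' @param dc_policy \code{"exclude"} (default) drops the exact 0 Hz bin
#'   from numerator and denominator, so a constant phase difference (the
#'   signature of volume conduction / a shared source) scores 0;
#'   \code{"include"} keeps it, matching the literal integral.
#' @param min_epoch_s minimum admissible epoch duration in seconds.
#' @param pad_factor integer zero-padding factor for the spectrum (1 = no
#'   padding; the plain finite-T transform).
#' @return object of class \code{plm_params}.
#' @export
plm_params <- function(B = 0.5, dc_policy = c("exclude", "include"),
                       min_epoch_s = 4, pad_factor = 1) {
  dc_policy <- match.arg(dc_policy)
  stopifnot(B > 0, min_epoch_s > 0, pad_factor >= 1)
  structure(list(B = B, dc_policy = dc_policy, min_epoch_s = min_epoch_s,
                 pad_factor = as.integer(pad_factor)),
            class = "plm_params")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order Butterworth band-pass design applied forward and backward
#' (zero phase distortion); output length equals input length.
#'
#' @param x numeric signal.
#' @param band band name or list with \code{f_lo}, \code{f_hi} (Hz).
#' @param fs sampling rate (Hz).
#' @param order filter design order (default 4).
#' @return filtered signal.
#' @export
bandpass <- function(x, band, fs, order = 4) {
  band <- band_definition(band)
  if (band$f_hi >= fs / 2) {
    stop("band upper edge ", band$f_hi, " Hz is at or above Nyquist (fs = ",
         fs, " Hz)")
  }
  if (length(x) < 3 * 3 * order) stop("signal too short to filter")
  flt <- signal::butter(order, c(band$f_lo, band$f_hi) / (fs / 2),
                        type = "pass")
  as.numeric(signal::filtfilt(flt, x))
}

#' Instantaneous phase via the analytic signal
#'
#' Computes the analytic signal by single-sided spectrum reconstruction
#' (FFT, doubling of positive frequencies, inverse FFT) and returns its
#' argument, wrapped to (-pi, pi].
#'
#' @param x real band-limited signal (non-constant).
#' @return phase in radians, same length as \code{x}.
#' @export
instantaneous_phase <- function(x) {
  n <- length(x)
  if (n < 2 || diff(range(x)) == 0) {
    stop("instantaneous phase undefined for constant input")
  }
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  xa <- fft(X * h, inverse = TRUE) / n
  Arg(xa)
}

# Signed FFT bin frequencies for a length-n transform at rate fs.
.fft_freqs <- function(n, fs) {
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k * fs / n
}

# Core PLM computation on a matrix of interferometric signals (columns).
.plm_from_z <- function(Z_cols, fs, params) {
  n <- nrow(Z_cols)
  n_pad <- n * params$pad_factor
  if (n_pad > n) {
    Z_cols <- rbind(Z_cols,
                    matrix(0 + 0i, n_pad - n, ncol(Z_cols)))
  }
  spec <- stats::mvfft(Z_cols)
  pow <- Re(spec * Conj(spec))
  # Parseval consistency check: |z| = 1 so total two-sided power must equal
  # n_fft * n_samples for every pair (within numerical tolerance)
  tot <- colSums(pow)
  expected <- n_pad * n
  if (any(abs(tot - expected) > 1e-6 * expected)) {
    stop("internal error: Parseval consistency violated in PLM computation")
  }
  f <- .fft_freqs(n_pad, fs)
  near <- abs(f) <= params$B + 1e-12
  if (params$dc_policy == "exclude") {
    keep <- seq_len(n_pad) != 1L
    num <- colSums(pow[near & keep, , drop = FALSE])
    den <- colSums(pow[keep, , drop = FALSE])
  } else {
    num <- colSums(pow[near, , drop = FALSE])
    den <- tot
  }
  out <- ifelse(den <= expected * 1e-12, 0, num / pmax(den, .Machine$double.xmin))
  pmin(pmax(out, 0), 1)
}

#' PLM between two phase series
#'
#' @param x_phase,y_phase instantaneous phase series (radians), equal
#'   length.
#' @param fs sampling rate (Hz).
#' @param params \code{\link{plm_params}}.
#' @return scalar in [0, 1].
#' @export
plm_pair <- function(x_phase, y_phase, fs, params = plm_params()) {
  if (length(x_phase) != length(y_phase)) {
    stop("phase series must have equal length")
  }
  if (length(x_phase) / fs < params$min_epoch_s) {
    stop("segment shorter than min_epoch_s = ", params$min_epoch_s, " s")
  }
  z <- exp(1i * (x_phase - y_phase))
  as.numeric(.plm_from_z(matrix(z, ncol = 1), fs, params))
}

#' PLM adjacency matrix of an epoched recording
#'
#' Band-filters every channel, extracts instantaneous phases, computes the
#' PLM for every unordered channel pair within each epoch, and averages
#' across epochs. Epochs shorter than \code{min_epoch_s} are rejected with
#' a warning; if none remain an error is thrown.
#'
#' @param rec an \code{\link{epoched_recording}}.
#' @param band band name or definition.
#' @param params \code{\link{plm_params}}.
#' @return object of class \code{connectivity_matrix}: list with
#'   \code{band}, \code{roi_labels} and the symmetric \code{values} matrix
#'   (diagonal 0).
#' @export
plm_matrix <- function(rec, band, params = plm_params()) {
  mats <- plm_epoch_matrices(rec, band, params)
  values <- Reduce(`+`, lapply(mats, `[[`, "values")) / length(mats)
  structure(list(band = mats[[1]]$band, roi_labels = rec$roi_labels,
                 values = values),
            class = "connectivity_matrix")
}

#' Per-epoch PLM matrices of a recording
#'
#' As \code{\link{plm_matrix}} but without the final epoch average: one
#' \code{connectivity_matrix} per admissible epoch, e.g. for building one
#' spanning tree per epoch.
#'
#' @inheritParams plm_matrix
#' @return list of \code{connectivity_matrix} objects.
#' @export
plm_epoch_matrices <- function(rec, band, params = plm_params()) {
  stopifnot(inherits(rec, "epoched_recording"))
  band <- band_definition(band)
  ok <- vapply(rec$epochs, function(ep) ncol(ep) / rec$fs >= params$min_epoch_s,
               logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " epoch(s) shorter than ", params$min_epoch_s,
            " s rejected")
  }
  epochs <- rec$epochs[ok]
  if (!length(epochs)) stop("no epoch of sufficient duration")
  n_nodes <- length(rec$roi_labels)
  pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  lapply(epochs, function(ep) {
    phases <- apply(ep, 1, function(ch) {
      instantaneous_phase(bandpass(ch, band, rec$fs))
    })  # n_samples x n_nodes
    # interferometric signals for all pairs, in memory-bounded chunks
    vals <- numeric(nrow(pairs))
    chunk <- 512L
    for (start in seq(1, nrow(pairs), by = chunk)) {
      idx <- start:min(start + chunk - 1L, nrow(pairs))
      Z <- exp(1i * (phases[, pairs[idx, 2], drop = FALSE] -
                       phases[, pairs[idx, 1], drop = FALSE]))
      vals[idx] <- .plm_from_z(Z, rec$fs, params)
    }
    values <- matrix(0, n_nodes, n_nodes,
                     dimnames = list(rec$roi_labels, rec$roi_labels))
    values[pairs] <- vals
    values <- values + t(values)
    structure(list(band = band$name, roi_labels = rec$roi_labels,
                   values = values),
              class = "connectivity_matrix")
  })
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix (%s band): %d x %d PLM weights, mean %.3f\n",
              x$band, nrow(x$values), ncol(x$values),
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}
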