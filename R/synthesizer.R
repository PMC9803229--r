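# Forward synthesis of bidirectional multichannel axial-transmission signals.
#
# Each emitter-receiver trace is built in the frequency domain: the pulse
# spectrum is propagated through a modal transfer function (one term per
# guided-mode wavenumber root at that frequency, amplitude-tapered), plus a
# non-dispersive head-wave (first arriving signal) term, then inverse-FFT'd
# back to time. Probe tilt enters as a direction-antisymmetric path-length
# gradient - exactly the bias the bidirectional design is meant to cancel.

#' Probe geometry and acquisition settings
#'
#' Linear array with one block of receivers surrounded by two transmitter
#' blocks (bidirectional axial transmission layout): 24 receivers at 0.8 mm
#' pitch between two groups of 5 transmitters at 1 mm pitch, 1 MHz wideband
#' excitation.
#'
#' @param n_receivers Number of receive elements.
#' @param n_transmitters_per_side Transmit elements in each outer block.
#' @param receiver_pitch Receive pitch, mm.
#' @param transmitter_pitch Transmit pitch, mm.
#' @param gap_tx_rx Gap between the innermost transmitter and the nearest
#'   receiver, mm.
#' @param sampling_rate Sampling rate, Hz (must exceed 4x the pulse centre
#'   frequency).
#' @param record_length Record length, samples.
#' @param pulse_center_frequency Pulse centre frequency, Hz.
#' @return An object of class \code{probe_geometry}.
#' @export
probe_geometry <- function(n_receivers = 24, n_transmitters_per_side = 5,
                           receiver_pitch = 0.8, transmitter_pitch = 1.0,
                           gap_tx_rx = 2.0, sampling_rate = 20e6,
                           record_length = 2000,
                           pulse_center_frequency = 1e6) {
  if (!.is_count(n_receivers) || !.is_count(n_transmitters_per_side) ||
      !.is_count(record_length))
    .bdat_stop("element counts and record length must be positive integers",
               "bdat_usage_error")
  if (receiver_pitch <= 0 || transmitter_pitch <= 0 || gap_tx_rx <= 0)
    .bdat_stop("pitches and gap must be > 0 (mm)", "bdat_usage_error")
  if (sampling_rate <= 4 * pulse_center_frequency)
    .bdat_stop("sampling_rate must exceed 4x pulse_center_frequency",
               "bdat_usage_error")
  structure(list(n_receivers = n_receivers,
                 n_transmitters_per_side = n_transmitters_per_side,
                 receiver_pitch = receiver_pitch,
                 transmitter_pitch = transmitter_pitch,
                 gap_tx_rx = gap_tx_rx,
                 sampling_rate = sampling_rate,
                 record_length = record_length,
                 pulse_center_frequency = pulse_center_frequency),
            class = "probe_geometry")
}

#' Receiver positions along the array, m (origin at first receiver)
#' @param geometry A \code{probe_geometry}.
#' @return Numeric vector, length \code{n_receivers}.
#' @export
receiver_positions <- function(geometry) {
  (seq_len(geometry$n_receivers) - 1) * geometry$receiver_pitch * 1e-3
}

# emitter -> receiver distances (m), rows = emitters, cols = receivers;
# identical for both directions by mirror symmetry of the layout
.tx_rx_distances <- function(geometry) {
  xr <- receiver_positions(geometry)
  dtx <- geometry$gap_tx_rx * 1e-3 +
    (seq_len(geometry$n_transmitters_per_side) - 1) *
    geometry$transmitter_pitch * 1e-3
  outer(dtx, xr, function(d, x) d + x)
}

#' Gaussian-modulated excitation pulse
#'
#' Unit-peak cosine carrier with a Gaussian envelope whose -6 dB spectral
#' full width equals \code{fractional_bandwidth * center_frequency}.
#'
#' @param center_frequency Carrier frequency, Hz.
#' @param fractional_bandwidth -6 dB fractional bandwidth in (0, 2).
#' @param sampling_rate Sampling rate, Hz.
#' @param n_samples Length of the returned waveform (default: enough to hold
#'   the envelope).
#' @return List with \code{t} (s), \code{x} (amplitude), \code{center_time}.
#' @export
synthesize_pulse <- function(center_frequency, fractional_bandwidth = 0.6,
                             sampling_rate = 20e6, n_samples = NULL) {
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 2)
    .bdat_stop("fractional_bandwidth must lie in (0, 2)", "bdat_usage_error")
  if (sampling_rate <= 4 * center_frequency)
    .bdat_stop("sampling_rate must exceed 4x center_frequency",
               "bdat_usage_error")
  sigma <- sqrt(2 * log(2)) / (pi * fractional_bandwidth * center_frequency)
  t0 <- 4 * sigma
  if (is.null(n_samples)) n_samples <- ceiling(8 * sigma * sampling_rate)
  t <- (seq_len(n_samples) - 1) / sampling_rate
  x <- cos(2 * pi * center_frequency * (t - t0)) * exp(-(t - t0)^2 / (2 * sigma^2))
  list(t = t, x = x, center_time = t0, sigma = sigma)
}

# positive-frequency pulse spectrum on the FFT bins of a record
.pulse_spectrum <- function(geometry, fractional_bandwidth = 0.6) {
  n <- geometry$record_length
  fs <- geometry$sampling_rate
  f0 <- geometry$pulse_center_frequency
  sigma <- sqrt(2 * log(2)) / (pi * fractional_bandwidth * f0)
  t0 <- 4 * sigma
  f <- (0:(n %/% 2)) * fs / n
  # analytic spectrum of the Gaussian-modulated cosine (positive lobe)
  amp <- exp(-2 * pi^2 * sigma^2 * (f - f0)^2)
  list(f = f, spec = amp * exp(-2i * pi * f * t0), sigma = sigma, t0 = t0)
}

# hermitian-symmetric inverse FFT of positive-frequency spectra;
# S: matrix n_pos x n_traces -> real matrix record_length x n_traces
.irfft <- function(S, n) {
  npos <- nrow(S)
  full <- matrix(0i, n, ncol(S))
  full[seq_len(npos), ] <- S
  if (n %% 2 == 0) full[npos, ] <- Re(full[npos, ])  # Nyquist bin real
  idx <- 2:(if (n %% 2 == 0) npos - 1L else npos)   # mirror all but DC/Nyquist
  full[n - idx + 2L, ] <- Conj(full[idx, , drop = FALSE])
  Re(stats::mvfft(full, inverse = TRUE)) / n
}

#' Simulate one bidirectional acquisition
#'
#' Generates the full set of forward (left transmitters) and backward (right
#' transmitters) traces for a plate model: a superposition of the traced
#' guided modes plus a first-arriving head wave at the effective axial bulk
#' longitudinal velocity, with optional probe tilt (direction-antisymmetric
#' path-length gradient), a common soft-tissue delay, and seeded Gaussian
#' noise. Amplitudes are normalized so the strongest noise-free sample is 1.
#'
#' @param model A \code{\link{plate_model}}.
#' @param geometry A \code{\link{probe_geometry}}.
#' @param fractional_bandwidth Pulse -6 dB fractional bandwidth.
#' @param mode_amplitude Weighting rule for guided-mode amplitudes: a function
#'   of the wavenumber vector. The default is a \code{1/sqrt(k)} taper with a
#'   smooth roll-off below ~300 rad/m, so that modes switch on continuously at
#'   their cutoff (a hard 1/sqrt(k) jump at cutoff rings non-causally across
#'   the whole record).
#' @param fas_velocity Head-wave velocity, m/s, or \code{"auto"} for the
#'   effective axial longitudinal velocity sqrt(c_axial_eff / rho_eff).
#' @param fas_amplitude Head-wave amplitude relative to unit mode weight.
#' @param noise_rms Gaussian noise RMS relative to the noise-free peak.
#' @param tilt Probe tilt, mrad; scales path lengths by (1 +- tilt*1e-3)
#'   with opposite signs in the two directions.
#' @param soft_tissue_delay Common propagation delay, microseconds.
#' @param seed Integer seed for the noise (NULL = use current RNG state).
#' @return An object of class \code{array_signals}: list with \code{signals}
#'   (list \code{forward}, \code{backward}; arrays emitter x receiver x time),
#'   \code{geometry} and \code{provenance} (truth record).
#' @export
simulate_array_signals <- function(model, geometry = probe_geometry(),
                                   fractional_bandwidth = 0.6,
                                   mode_amplitude = function(k)
                                     (1 - exp(-(k / 300)^2)) / sqrt(k),
                                   fas_velocity = "auto",
                                   fas_amplitude = 0.2,
                                   noise_rms = 0, tilt = 0,
                                   soft_tissue_delay = 0, seed = NULL) {
  stopifnot(inherits(model, "plate_model"), inherits(geometry, "probe_geometry"))
  eff <- effective_properties(model)
  if (identical(fas_velocity, "auto"))
    fas_velocity <- sqrt(eff$c33 * 1e9 / eff$rho)
  ps <- .pulse_spectrum(geometry, fractional_bandwidth)
  band <- which(abs(ps$spec) >= 0.01 * max(abs(ps$spec)) & ps$f > 0)
  if (!length(band))
    .bdat_stop("empty pulse band", "bdat_simulation_error")
  fb <- ps$f[band]
  # guided-mode wavenumber roots on the band frequencies
  kmax <- 2 * pi * max(fb) / 600   # slower than any mode of interest
  curves <- trace_dispersion_curves(model, fb, k_max = kmax, k_min = 20)
  if (!length(curves$branches))
    .bdat_stop("no guided-mode branch inside the pulse band",
               "bdat_simulation_error")
  # per band frequency: vector of mode wavenumbers
  kroots <- vector("list", length(fb))
  for (b in curves$branches) {
    idx <- match(b$f, fb)
    for (i in seq_along(idx)) kroots[[idx[i]]] <- c(kroots[[idx[i]]], b$k[i])
  }
  dist0 <- .tx_rx_distances(geometry)
  n <- geometry$record_length
  tau <- soft_tissue_delay * 1e-6
  tilt_rad <- tilt * 1e-3
  dirsign <- c(forward = +1, backward = -1)
  signals <- list()
  for (dname in names(dirsign)) {
    # backward emitters sit on the far side: distance to receiver r equals the
    # forward distance to the mirror receiver (reversal in receiver order)
    d <- if (dname == "forward") dist0 else dist0[, rev(seq_len(ncol(dist0))), drop = FALSE]
    d <- d * (1 + dirsign[[dname]] * tilt_rad)
    S <- matrix(0i, length(ps$f), length(d))
    for (j in seq_along(fb)) {
      kv <- kroots[[j]]
      tr <- rep(0i, length(d))
      if (length(kv)) {
        a <- mode_amplitude(kv)
        # e^{-ikx}: delay phase convention matching the forward FFT analysis
        tr <- as.vector(exp(-1i * outer(as.vector(d), kv)) %*% a)
      }
      tr <- tr + fas_amplitude * exp(-2i * pi * fb[j] * as.vector(d) / fas_velocity)
      S[band[j], ] <- ps$spec[band[j]] * exp(-2i * pi * fb[j] * tau) * tr
    }
    x <- .irfft(S, n)
    signals[[dname]] <- array(t(x), dim = c(nrow(d), ncol(d), n))
  }
  peak <- max(abs(signals$forward), abs(signals$backward))
  if (peak == 0) .bdat_stop("degenerate zero signal set", "bdat_simulation_error")
  signals <- lapply(signals, function(a) a / peak)
  if (noise_rms > 0) {
    signals <- .with_seed(seed, lapply(signals, function(a)
      a + array(stats::rnorm(length(a), sd = noise_rms), dim = dim(a))))
  }
  structure(list(signals = signals, geometry = geometry,
                 provenance = list(model = unclass(model), tilt = tilt,
                                   soft_tissue_delay = soft_tissue_delay,
                                   noise_rms = noise_rms, seed = seed,
                                   fas_velocity = fas_velocity,
                                   fas_amplitude = fas_amplitude,
                                   fractional_bandwidth = fractional_bandwidth)),
            class = "array_signals")
}

#' @export
print.array_signals <- function(x, ...) {
  d <- dim(x$signals$forward)
  cat(sprintf("<array_signals> %d emitters x %d receivers x %d samples per direction\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Simulate a full measurement protocol
#'
#' Reproduces the clinical acquisition protocol: \code{n_series} probe
#' placements (each with its own small repositioning jitter in tilt and
#' soft-tissue delay) times \code{n_acquisitions} repeated acquisitions per
#' placement (fresh noise each time). Default protocol: four series of ten
#' acquisitions.
#'
#' @param model A \code{\link{plate_model}}.
#' @param geometry A \code{\link{probe_geometry}}.
#' @param n_series Number of series (probe repositionings).
#' @param n_acquisitions Acquisitions per series.
#' @param jitter_tilt_sd SD of the per-series tilt perturbation, mrad.
#' @param jitter_delay_sd SD of the per-series soft-tissue-delay
#'   perturbation, microseconds.
#' @param noise_rms Per-acquisition noise RMS relative to peak.
#' @param seed Integer seed; the whole protocol is deterministic given it.
#' @param ... Further arguments passed to \code{simulate_array_signals}.
#' @return List of length \code{n_series}; each element a list of
#'   \code{array_signals} of length \code{n_acquisitions}.
#' @export
acquisition_series <- function(model, geometry = probe_geometry(),
                               n_series = 4, n_acquisitions = 10,
                               jitter_tilt_sd = 1, jitter_delay_sd = 0.1,
                               noise_rms = 0.01, seed = 1, ...) {
  if (!.is_count(n_series) || !.is_count(n_acquisitions))
    .bdat_stop("protocol counts must be >= 1", "bdat_usage_error")
  .with_seed(seed, {
    lapply(seq_len(n_series), function(s) {
      tilt_s <- stats::rnorm(1, 0, jitter_tilt_sd)
      delay_s <- abs(stats::rnorm(1, 0.5, jitter_delay_sd))
      lapply(seq_len(n_acquisitions), function(a)
        simulate_array_signals(model, geometry, tilt = tilt_s,
                               soft_tissue_delay = delay_s,
                               noise_rms = noise_rms,
                               seed = stats::runif(1, 1, 2^30), ...))
    })
  })
}

#' Write an acquisition to the "bdat-sig-1" signal container
#'
#' Versioned single-file container holding both direction blocks
#' (emitter x receiver x time arrays), the probe geometry and the provenance
#' record. Round-trips bit-identically.
#'
#' @param signals An \code{array_signals} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_signals <- function(signals, path) {
  stopifnot(inherits(signals, "array_signals"))
  saveRDS(list(format = "bdat-sig-1",
               signals = signals$signals,
               geometry = unclass(signals$geometry),
               provenance = signals$provenance),
          path)
  invisible(path)
}

#' Read a "bdat-sig-1" signal container
#' @param path File path written by \code{\link{write_signals}}.
#' @return An \code{array_signals} object.
#' @export
read_signals <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    .bdat_stop(paste0("cannot parse signal container: ", conditionMessage(e)),
               "bdat_parse_error"))
  if (!identical(obj$format, "bdat-sig-1"))
    .bdat_stop("unknown signal container version (expected bdat-sig-1)",
               "bdat_parse_error")
  structure(list(signals = obj$signals,
                 geometry = structure(obj$geometry, class = "probe_geometry"),
                 provenance = obj$provenance),
            class = "array_signals")
}
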