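# From time signals to the SVD-based guided-wave spectrum (Norm function).
#
# Per frequency, the emitter x receiver response matrix is decomposed by SVD;
# the reception singular vectors spanning the signal subspace form the basis
# onto which unit-norm (optionally attenuated) plane waves are projected.
# The squared projection, in [0, 1], is the Norm image; its ridges are the
# experimental guided-mode branches.

.tukey_window <- function(n, alpha = 0.25) {
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Frequency-domain response matrices of an acquisition
#'
#' Applies a Tukey window to every trace, FFTs, and keeps the frequency bins
#' inside \code{band} (default: the -20 dB band of the aggregate magnitude
#' spectrum; \code{"full"} keeps every non-negative bin).
#'
#' @param signals An \code{array_signals} object.
#' @param band \code{NULL} (auto), \code{"full"}, or \code{c(f_lo, f_hi)} Hz.
#' @param tukey_alpha Taper fraction of the Tukey window.
#' @param band_db Threshold (dB below peak) for the automatic band.
#' @return Class \code{response_spectrum}: list with \code{f} (Hz),
#'   \code{spectra} (per direction, complex arrays emitter x receiver x freq),
#'   \code{geometry}.
#' @export
response_spectrum <- function(signals, band = NULL, tukey_alpha = 0.25,
                              band_db = 20) {
  stopifnot(inherits(signals, "array_signals"))
  g <- signals$geometry
  n <- dim(signals$signals$forward)[3]
  if (!is.null(band) && !identical(band, "full")) {
    if (length(band) != 2 || band[1] < 0 || band[2] <= band[1])
      .bdat_stop("band must be c(f_lo, f_hi) with 0 <= f_lo < f_hi",
                 "bdat_usage_error")
  }
  w <- .tukey_window(n, tukey_alpha)
  f_all <- (0:(n %/% 2)) * g$sampling_rate / n
  spectra <- lapply(signals$signals, function(a) {
    d <- dim(a)
    m <- matrix(aperm(a, c(3, 1, 2)), nrow = d[3]) * w
    X <- stats::mvfft(m)[seq_along(f_all), , drop = FALSE]
    array(t(X), dim = c(d[1], d[2], length(f_all)))
  })
  keep <- seq_along(f_all)
  if (identical(band, "full")) {
    # keep everything
  } else if (is.null(band)) {
    mag <- sqrt(Mod(spectra$forward)^2 + Mod(spectra$backward)^2)
    agg <- apply(mag, 3, sum)
    keep <- which(agg >= max(agg) * 10^(-band_db / 20) & f_all > 0)
    keep <- seq(min(keep), max(keep))  # contiguous band
  } else {
    keep <- which(f_all >= band[1] & f_all <= band[2])
    if (!length(keep)) .bdat_stop("band outside record", "bdat_usage_error")
  }
  structure(list(f = f_all[keep],
                 spectra = lapply(spectra, function(a) a[, , keep, drop = FALSE]),
                 geometry = g),
            class = "response_spectrum")
}

#' Per-frequency reception singular-vector basis
#'
#' SVD of each direction's response matrix at each frequency; singular
#' vectors are kept while their singular value is within \code{keep_db} of
#' the largest, up to \code{keep_max} vectors.
#'
#' @param spectrum A \code{response_spectrum}.
#' @param keep_db Dynamic-range cut for kept singular values, dB.
#' @param keep_max Maximum number of kept singular vectors per frequency.
#' @param decimate_to If the band holds more frequency bins than this, keep
#'   an evenly spaced subset (the image does not need every FFT bin).
#' @return Class \code{svd_basis}: list with \code{f}, per direction a list
#'   of n_receivers x r complex matrices, \code{n_kept}, \code{geometry}.
#' @export
signal_subspace <- function(spectrum, keep_db = 20, keep_max = 5,
                            decimate_to = 64) {
  stopifnot(inherits(spectrum, "response_spectrum"))
  f <- spectrum$f
  idx <- seq_along(f)
  if (length(f) > decimate_to)
    idx <- unique(round(seq(1, length(f), length.out = decimate_to)))
  basis <- list()
  n_kept <- list()
  for (dname in names(spectrum$spectra)) {
    arr <- spectrum$spectra[[dname]]
    vs <- vector("list", length(idx))
    nk <- integer(length(idx))
    for (j in seq_along(idx)) {
      M <- matrix(arr[, , idx[j]], nrow = dim(arr)[1])
      if (all(Mod(M) == 0)) { vs[j] <- list(NULL); next }
      sv <- svd(M, nu = 0)
      r <- which(sv$d >= sv$d[1] * 10^(-keep_db / 20))
      r <- seq_len(min(length(r), keep_max, nrow(M)))
      vs[[j]] <- sv$v[, r, drop = FALSE]
      nk[j] <- length(r)
    }
    basis[[dname]] <- vs
    n_kept[[dname]] <- nk
  }
  structure(list(f = f[idx], basis = basis, n_kept = n_kept,
                 geometry = spectrum$geometry),
            class = "svd_basis")
}

# Unit-norm (optionally attenuated) plane-wave test vectors at the receiver
# positions; k may be a vector -> matrix n_rx x length(k). sign = +1 for
# propagation toward increasing receiver position, -1 for the reverse.
# The reception singular vectors span the conjugated row space of the
# response matrix, so a mode travelling forward with phase exp(-i k x)
# appears in the basis as exp(+i k x): the forward test vector carries the
# positive exponent (and the attenuated amplitude grows along +x so that it
# decays along the actual propagation path after conjugation).
.steering_matrix <- function(x_r, k, sign = 1, k_imag = 0) {
  E <- exp(sign * outer(x_r, 1i * k - k_imag))
  sweep(E, 2, sqrt(colSums(Mod(E)^2)), "/")
}

# squared projection of steering vectors onto kept singular vectors
# V: n_rx x r (possibly NULL), E: n_rx x nk -> numeric nk in [0,1]
.proj_values <- function(V, E) {
  if (is.null(V)) return(numeric(ncol(E)))
  colSums(Mod(crossprod(Conj(V), E))^2)
}

#' The Norm function: SVD-based f-k spectrum image
#'
#' Each pixel is the squared projection of a unit-normalized plane wave
#' exp(-i k x) (optionally attenuated via an imaginary wavenumber part) onto
#' the reception singular vectors kept at that frequency. Values lie in
#' [0, 1]; ridges follow the guided-mode dispersion branches. The two
#' directions are processed independently with direction-matched steering
#' vectors; the combined image is their pointwise mean.
#'
#' @param x A \code{response_spectrum} or a precomputed \code{svd_basis}.
#' @param k_grid Positive increasing wavenumber grid, rad/m.
#' @param attenuation_k_imag Imaginary wavenumber of the test wave, rad/m
#'   (0 = plain plane wave).
#' @param ... Passed to \code{\link{signal_subspace}} when \code{x} is a
#'   \code{response_spectrum}.
#' @return Class \code{norm_image}: list with \code{f}, \code{k},
#'   \code{values} (list \code{forward}, \code{backward}, \code{combined};
#'   matrices n_f x n_k), \code{n_kept}, and the \code{svd_basis} used.
#' @export
norm_image <- function(x, k_grid = seq(200, 6000, by = 10),
                       attenuation_k_imag = 0, ...) {
  if (inherits(x, "response_spectrum")) x <- signal_subspace(x, ...)
  stopifnot(inherits(x, "svd_basis"))
  if (any(k_grid <= 0) || is.unsorted(k_grid, strictly = TRUE))
    .bdat_stop("k_grid must be positive increasing", "bdat_usage_error")
  x_r <- receiver_positions(x$geometry)
  nf <- length(x$f)
  dirsign <- c(forward = 1, backward = -1)
  values <- list()
  for (dname in names(x$basis)) {
    E <- .steering_matrix(x_r, k_grid, dirsign[[dname]], attenuation_k_imag)
    img <- matrix(0, nf, length(k_grid))
    for (j in seq_len(nf)) img[j, ] <- .proj_values(x$basis[[dname]][[j]], E)
    values[[dname]] <- img
  }
  values$combined <- (values$forward + values$backward) / 2
  if (all(values$combined == 0))
    warning("all-zero signals: empty Norm image")
  structure(list(f = x$f, k = k_grid, values = values, n_kept = x$n_kept,
                 basis = x), class = "norm_image")
}

#' Extract experimental branch points from a Norm image
#'
#' Per-frequency local maxima above \code{threshold}, linked across
#' frequency into tracks by nearest-wavenumber continuity. Deterministic.
#'
#' @param image A \code{norm_image}.
#' @param threshold Minimum pixel value for a maximum to count.
#' @param direction Which image to use: "combined", "forward" or "backward".
#' @return Class \code{branch_points}: list of tracks, each
#'   \code{list(f, k, value)}, ordered by appearance.
#' @export
extract_branches <- function(image, threshold = 0.4,
                             direction = c("combined", "forward", "backward")) {
  stopifnot(inherits(image, "norm_image"))
  direction <- match.arg(direction)
  v <- image$values[[direction]]
  kg <- image$k
  maxima <- vector("list", nrow(v))
  vals <- vector("list", nrow(v))
  for (j in seq_len(nrow(v))) {
    row <- v[j, ]
    n <- length(row)
    loc <- which(row >= threshold &
                   row >= c(-Inf, row[-n]) & row > c(row[-1], -Inf))
    maxima[[j]] <- kg[loc]
    vals[[j]] <- row[loc]
  }
  dk <- if (length(kg) > 1) kg[2] - kg[1] else 1
  tracks <- .track_branches(image$f, maxima, k_step = 3 * dk)
  # attach values back to track points
  out <- lapply(tracks, function(tr) {
    val <- vapply(seq_along(tr$f), function(i) {
      j <- match(tr$f[i], image$f)
      vals[[j]][match(tr$k[i], maxima[[j]])]
    }, numeric(1))
    list(f = tr$f, k = tr$k, value = val)
  })
  structure(out, class = "branch_points")
}

#' Export a Norm image as a text grid plus JSON axes sidecar
#'
#' @param image A \code{norm_image}.
#' @param path Base path; writes \code{<path>.tsv} (matrix, rows = f) and
#'   \code{<path>.json} (axes and units).
#' @return Base path, invisibly.
#' @export
write_norm_image <- function(image, path) {
  stopifnot(inherits(image, "norm_image"))
  utils::write.table(image$values$combined, paste0(path, ".tsv"),
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  jsonlite::write_json(list(format = "bdat-norm-1",
                            f_hz = image$f, k_rad_per_m = image$k,
                            value = "squared projection, unitless in [0,1]"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a Norm image (f-k guided-wave spectrum)
#'
#' @param x A \code{norm_image}.
#' @param direction Which image to draw.
#' @param curves Optional \code{dispersion_curves} overlay.
#' @param ... Passed to \code{graphics::image}.
#' @export
plot.norm_image <- function(x, direction = "combined", curves = NULL, ...) {
  graphics::image(x$f / 1e6, x$k, x$values[[direction]],
                  xlab = "frequency (MHz)", ylab = "wavenumber (rad/m)",
                  useRaster = TRUE, ...)
  if (!is.null(curves))
    for (b in curves$branches)
      graphics::lines(b$f / 1e6, b$k, col = "white", lwd = 1.2)
  invisible(x)
}
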