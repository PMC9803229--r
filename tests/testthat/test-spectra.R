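test_that("spectrum of a pure sinusoid peaks at its frequency bin", {
  g <- probe_geometry(n_receivers = 4, n_transmitters_per_side = 1,
                      record_length = 1000)
  tt <- (0:999) / g$sampling_rate
  a <- array(rep(sin(2 * pi * 1e6 * tt), each = 4), c(1, 4, 1000))
  sig <- structure(list(signals = list(forward = a, backward = a),
                        geometry = g, provenance = list()),
                   class = "array_signals")
  sp <- response_spectrum(sig, band = "full", tukey_alpha = 0)
  mag <- abs(sp$spectra$forward[1, 1, ])
  expect_equal(sp$f[which.max(mag)], 1e6)
})

test_that("the response spectrum is linear and satisfies Parseval", {
  g <- probe_geometry(n_receivers = 3, n_transmitters_per_side = 1,
                      record_length = 512)
  mk <- function(seed) {
    a <- withr::with_seed(seed, array(rnorm(3 * 512), c(1, 3, 512)))
    structure(list(signals = list(forward = a, backward = a), geometry = g,
                   provenance = list()), class = "array_signals")
  }
  s1 <- mk(1); s2 <- mk(2)
  s12 <- s1
  s12$signals <- list(forward = s1$signals$forward + s2$signals$forward,
                      backward = s1$signals$backward + s2$signals$backward)
  f1 <- response_spectrum(s1, band = "full")
  f2 <- response_spectrum(s2, band = "full")
  f12 <- response_spectrum(s12, band = "full")
  expect_equal(f12$spectra$forward, f1$spectra$forward + f2$spectra$forward,
               tolerance = 1e-12)
  # Parseval on one windowed trace: sum x_w^2 = (1/N) sum |X|^2 over all bins
  w <- bdatr:::.tukey_window(512, 0.25)
  xw <- s1$signals$forward[1, 2, ] * w
  X <- f1$spectra$forward[1, 2, ]
  n <- 512
  e_freq <- (abs(X[1])^2 + 2 * sum(abs(X[2:(n / 2)])^2) +
               abs(X[n / 2 + 1])^2) / n
  expect_equal(sum(xw^2), e_freq, tolerance = 1e-6)
})

test_that("a single plane wave projects to 1 at its wavenumber, small elsewhere", {
  k0 <- 2000
  sig <- plane_wave_signals(k0)
  sp <- response_spectrum(sig, band = c(0.9e6, 1.1e6))
  ni <- norm_image(sp, k_grid = seq(200, 4000, by = 10))
  j <- which.min(abs(ni$f - 1e6))
  for (dir in c("forward", "backward", "combined")) {
    row <- ni$values[[dir]][j, ]
    expect_equal(ni$k[which.max(row)], k0, tolerance = 10 / k0)
    expect_gt(max(row), 0.95)
    # away from the main lobe: below the peak-sidelobe bound of the aperture
    far <- abs(ni$k - k0) > 2 * 2 * pi / (23 * 0.8e-3)
    expect_lt(max(row[far]), 0.3)
  }
})

test_that("projections are exactly zero for vectors orthogonal to the basis", {
  x_r <- receiver_positions(probe_geometry())
  E <- bdatr:::.steering_matrix(x_r, c(1000, 2000), 1)
  # project a random vector onto the orthocomplement of span(E)
  Q <- qr.Q(qr(E))
  perp <- diag(24) - Q %*% Conj(t(Q))
  vperp <- perp %*% rnorm(24)
  vperp <- vperp / sqrt(sum(Mod(vperp)^2))
  expect_lt(max(bdatr:::.proj_values(vperp, E)), 1e-20)
})

test_that("Norm values are bounded in [0,1] and invariant to global scaling", {
  sig <- noise_signals(sd = 1)
  sp <- response_spectrum(sig, band = c(0.5e6, 1.5e6))
  ni <- norm_image(sp, k_grid = seq(200, 4000, by = 20))
  for (dir in names(ni$values)) {
    expect_gte(min(ni$values[[dir]]), 0)
    expect_lte(max(ni$values[[dir]]), 1 + 1e-12)
  }
  sig2 <- sig
  sig2$signals <- lapply(sig$signals, function(a) 17.3 * a)
  ni2 <- norm_image(response_spectrum(sig2, band = c(0.5e6, 1.5e6)),
                    k_grid = seq(200, 4000, by = 20))
  expect_equal(ni2$values$combined, ni$values$combined, tolerance = 1e-10)
})

test_that("kept singular vectors are orthonormal to 1e-10", {
  sb <- nf_basis()
  for (dname in names(sb$basis)) {
    for (V in sb$basis[[dname]]) {
      if (is.null(V)) next
      G <- Conj(t(V)) %*% V
      expect_lt(max(abs(G - diag(ncol(V)))), 1e-10)
    }
  }
})

test_that("two modes separated by the aperture resolution are resolved", {
  g <- probe_geometry()
  aperture <- (g$n_receivers - 1) * g$receiver_pitch * 1e-3
  dk <- 2 * pi / aperture
  k1 <- 2000; k2 <- k1 + dk
  n <- g$record_length
  tt <- (0:(n - 1)) / g$sampling_rate
  x_r <- receiver_positions(g)
  a <- array(0, c(g$n_transmitters_per_side, g$n_receivers, n))
  for (e in seq_len(dim(a)[1])) for (r in seq_len(dim(a)[2]))
    a[e, r, ] <- cos(2 * pi * 1e6 * tt - k1 * x_r[r] + e) +
      cos(2 * pi * 1e6 * tt - k2 * x_r[r] + 2 * e)
  sig <- structure(list(signals = list(forward = a, backward = a),
                        geometry = g, provenance = list()),
                   class = "array_signals")
  ni <- norm_image(response_spectrum(sig, band = c(0.95e6, 1.05e6)),
                   k_grid = seq(1500, 2900, by = 5))
  j <- which.min(abs(ni$f - 1e6))
  row <- ni$values$forward[j, ]
  loc <- which(row > 0.4 & row >= c(-Inf, row[-length(row)]) &
                 row > c(row[-1], -Inf))
  km <- ni$k[loc]
  expect_true(any(abs(km - k1) < dk / 4))
  expect_true(any(abs(km - k2) < dk / 4))
})

test_that("branch extraction finds and separates constructed ridges", {
  one <- extract_branches(ridge_image(), threshold = 0.4)
  expect_length(one, 1)
  expect_length(one[[1]]$f, 20)

  two <- extract_branches(
    ridge_image(ridges = list(function(f) 800 + f / 1e3,
                              function(f) 2300 + f / 2e3)), threshold = 0.4)
  expect_length(two, 2)
  # no switching: each track stays on its own ridge (tracks are ordered by
  # descending wavenumber at first appearance, so the upper ridge comes first)
  expect_true(all(abs(two[[1]]$k - (2300 + two[[1]]$f / 2e3)) < 40))
  expect_true(all(abs(two[[2]]$k - (800 + two[[2]]$f / 1e3)) < 40))

  none <- extract_branches(ridge_image(amplitude = 0.2), threshold = 0.4)
  expect_length(none, 0)
})

test_that("noise-free ridge maxima lie on the model dispersion branches", {
  ni <- nf_image()
  pm <- nf_plate()
  cs <- trace_dispersion_curves(pm, ni$f, k_max = 6200, k_min = 20)
  g <- probe_geometry()
  half_res <- pi / ((g$n_receivers - 1) * g$receiver_pitch * 1e-3)
  ok <- tot <- 0
  for (j in seq_along(ni$f)) {
    row <- ni$values$combined[j, ]
    n <- length(row)
    loc <- which(row >= 0.4 & row >= c(-Inf, row[-n]) & row > c(row[-1], -Inf))
    if (!length(loc)) next
    tot <- tot + 1
    ks <- unlist(lapply(cs$branches, function(b) {
      i <- match(ni$f[j], b$f)
      if (!is.na(i)) b$k[i]
    }))
    if (all(vapply(ni$k[loc], function(k0) min(abs(ks - k0)) <= half_res,
                   logical(1)))) ok <- ok + 1
  }
  expect_gte(ok / tot, 0.9)
})

test_that("all-zero signals give an empty image with a warning", {
  g <- probe_geometry(n_receivers = 4, n_transmitters_per_side = 1,
                      record_length = 256)
  a <- array(0, c(1, 4, 256))
  sig <- structure(list(signals = list(forward = a, backward = a),
                        geometry = g, provenance = list()),
                   class = "array_signals")
  sp <- response_spectrum(sig, band = "full")
  expect_warning(ni <- norm_image(sp, k_grid = seq(100, 1000, by = 50)),
                 "all-zero")
  expect_true(all(ni$values$combined == 0))
  expect_length(extract_branches(ni), 0)
})

test_that("norm image exports a text grid with a JSON sidecar", {
  ni <- ridge_image()
  base <- tempfile()
  write_norm_image(ni, base)
  m <- as.matrix(utils::read.table(paste0(base, ".tsv")))
  expect_equal(dim(m), dim(ni$values$combined))
  ax <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(ax$f_hz, ni$f)
  unlink(paste0(base, c(".tsv", ".json")))
})
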