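# shared fixtures, built in code and cached per test file

# isotropic-limit constants (c11 = c33, c13 = c11 - 2 c55) used wherever a
# classical Rayleigh-Lamb oracle is the reference
iso_plate <- function(thickness = 2, porosity = 0) {
  plate_model(thickness, porosity, c11 = 29.4, c13 = 14.8, c33 = 29.4,
              c55 = 7.3, rho_matrix = 1850)
}

nf_plate <- function() plate_model(2.7, 0.10)

# classical Rayleigh-Lamb secular functions for an isotropic plate
# (independent textbook oracle, real-valued via complex sqrt)
rayleigh_lamb <- function(h, cL, cT, f, k, family) {
  om <- 2 * pi * f
  p <- sqrt(as.complex(om^2 / cL^2 - k^2))
  q <- sqrt(as.complex(om^2 / cT^2 - k^2))
  hh <- h / 2
  # column scaling as in any stable implementation; zeros unchanged
  sp <- exp(-abs(Im(p)) * hh); sq <- exp(-abs(Im(q)) * hh)
  if (family == "symmetric") {
    # (q^2-k^2)^2 cos(p hh) sin(q hh)/q + 4 k^2 p sin(p hh) cos(q hh)
    v <- (q^2 - k^2)^2 * cos(p * hh) * sp * .rl_sinq(q, hh) * sq +
      4 * k^2 * .rl_qsin(p, hh) * sp * cos(q * hh) * sq
  } else {
    # x p: 4 k^2 p^2 q sin(q hh) cos(p hh) + (q^2-k^2)^2 p sin(p hh) cos(q hh)
    v <- 4 * k^2 * p^2 * .rl_qsin(q, hh) * sq * cos(p * hh) * sp +
      (q^2 - k^2)^2 * .rl_qsin(p, hh) * sp * cos(q * hh) * sq
  }
  Re(v)
}
.rl_sinq <- function(q, a) ifelse(Mod(q) * a < 1e-12, a + 0i, sin(q * a) / q)
.rl_qsin <- function(q, a) q * sin(q * a)

# isotropic Rayleigh-wave velocity (root of the Rayleigh equation)
rayleigh_velocity <- function(cL, cT) {
  stats::uniroot(function(v)
    (2 - (v / cT)^2)^2 - 4 * sqrt(1 - (v / cL)^2) * sqrt(1 - (v / cT)^2),
    c(0.5 * cT, 0.9999 * cT), tol = 1e-10)$root
}

# brute-force root scan of the boundary determinant at one frequency
scan_roots_bruteforce <- function(model, f, k_max, family, k_step) {
  ks <- seq(k_step * 1e-3 + 1, k_max, by = k_step)
  d <- dispersion_determinant(model, f, ks, family)
  sc <- which(d[-length(d)] * d[-1] < 0 | d[-length(d)] == 0)
  vapply(sc, function(i)
    stats::uniroot(function(k) dispersion_determinant(model, f, k, family),
                   c(ks[i], ks[i + 1]), tol = 1e-8)$root, numeric(1))
}

# cached heavy objects, built once per test run
.test_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

nf_signals <- function() cached("nf_signals", simulate_array_signals(nf_plate()))
nf_basis <- function() cached("nf_basis",
                              signal_subspace(response_spectrum(nf_signals())))
nf_image <- function() cached("nf_image",
                              norm_image(response_spectrum(nf_signals())))

# plane-wave acquisition: one nondispersive wave exp(i(k0 x - w t)) across
# the receivers, direction-consistent for forward and backward blocks
plane_wave_signals <- function(k0 = 2000, geometry = probe_geometry(),
                               f0 = geometry$pulse_center_frequency) {
  n <- geometry$record_length
  fs <- geometry$sampling_rate
  tt <- (0:(n - 1)) / fs
  x_r <- receiver_positions(geometry)
  ne <- geometry$n_transmitters_per_side
  mk <- function(xsign) {
    a <- array(0, c(ne, length(x_r), n))
    for (e in seq_len(ne)) for (r in seq_along(x_r))
      a[e, r, ] <- cos(2 * pi * f0 * tt - xsign * k0 * x_r[r] + 0.3 * e)
    a
  }
  structure(list(signals = list(forward = mk(1), backward = mk(-1)),
                 geometry = geometry,
                 provenance = list(kind = "plane-wave fixture", k0 = k0)),
            class = "array_signals")
}

# white-noise acquisition (no structure at all)
noise_signals <- function(geometry = probe_geometry(), sd = 0.02, seed = 99) {
  ne <- geometry$n_transmitters_per_side
  nr <- geometry$n_receivers
  n <- geometry$record_length
  withr::with_seed(seed, structure(
    list(signals = list(forward = array(rnorm(ne * nr * n, sd = sd), c(ne, nr, n)),
                        backward = array(rnorm(ne * nr * n, sd = sd), c(ne, nr, n))),
         geometry = geometry, provenance = list(kind = "noise fixture")),
    class = "array_signals"))
}

# synthetic norm_image with prescribed gaussian ridges (for branch tracking)
ridge_image <- function(f = seq(5e5, 1e6, length.out = 20),
                        k = seq(200, 4000, by = 20),
                        ridges = list(function(ff) 1000 + ff / 1e3),
                        width = 60, amplitude = 0.9) {
  v <- matrix(0, length(f), length(k))
  for (rfun in ridges)
    for (j in seq_along(f))
      v[j, ] <- pmax(v[j, ], amplitude * exp(-(k - rfun(f[j]))^2 / (2 * width^2)))
  structure(list(f = f, k = k,
                 values = list(forward = v, backward = v, combined = v),
                 n_kept = NULL, basis = NULL),
            class = "norm_image")
}

# null cohort: two groups drawn from the same marginals (no effect)
null_cohort <- function(n_per_group = 100, seed = 1) {
  m <- bdatr:::.group_marginals()
  synthesize_cohort(cohort_spec(n = c(NF = n_per_group, NVF = n_per_group),
                                marginals = list(NF = m$NF, NVF = m$NF),
                                failure_rule = FALSE), seed = seed)
}
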