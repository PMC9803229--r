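test_that("effective properties follow the porosity power law and density mixing", {
  pm0 <- plate_model(2.7, 0)
  e0 <- effective_properties(pm0)
  expect_equal(e0$c55, pm0$c55)
  expect_equal(e0$c11, pm0$c11)
  expect_equal(e0$rho, pm0$rho_matrix)

  pm1 <- plate_model(2.7, 1)
  e1 <- effective_properties(pm1)
  expect_equal(e1$c11 + e1$c13 + e1$c33 + e1$c55, 0)
  expect_equal(e1$rho, pm1$rho_fluid)

  e10 <- effective_properties(plate_model(2.7, 0.10, q = 2))
  expect_equal(e10$c55, 7.3 * 0.81)   # 5.913 GPa, closed form
  expect_equal(e10$rho, 1850 * 0.9 + 1000 * 0.1)
})

test_that("plate model rejects invalid parameters", {
  expect_error(plate_model(-1, 0.1), class = "bdat_domain_error")
  expect_error(plate_model(2.7, 1.2), class = "bdat_domain_error")
  expect_error(plate_model(2.7, 0.1, c55 = -3), class = "bdat_domain_error")
  # c11*c33 - c13^2 <= 0
  expect_error(plate_model(2.7, 0.1, c11 = 5, c33 = 5, c13 = 15),
               class = "bdat_model_error")
  expect_error(plate_model(2.7, 0.1, q = 0.5), class = "bdat_domain_error")
})

test_that("isotropic limit reproduces the classical Rayleigh-Lamb sign pattern", {
  pm <- iso_plate()
  eff <- effective_properties(pm)
  cL <- sqrt(eff$c11 * 1e9 / eff$rho)
  cT <- sqrt(eff$c55 * 1e9 / eff$rho)
  fg <- seq(2e5, 1.4e6, length.out = 20)
  kg <- seq(100, 5000, length.out = 20)
  for (fam in c("symmetric", "antisymmetric")) {
    ours <- outer(fg, kg, function(f, k) dispersion_determinant(pm, f, k, fam))
    oracle <- outer(fg, kg, function(f, k)
      rayleigh_lamb(pm$thickness * 1e-3, cL, cT, f, k, fam))
    # identical sign-change structure along every frequency row
    for (i in seq_along(fg)) {
      sc_ours <- which(diff(sign(ours[i, ])) != 0)
      sc_oracle <- which(diff(sign(oracle[i, ])) != 0)
      expect_equal(sc_ours, sc_oracle,
                   info = sprintf("family %s, f = %g", fam, fg[i]))
    }
  }
})

test_that("determinant vanishes on traced branch points", {
  pm <- nf_plate()
  cs <- trace_dispersion_curves(pm, seq(4e5, 1.2e6, length.out = 9),
                                k_max = 6000, k_min = 20)
  for (b in cs$branches) {
    fam <- if (startsWith(b$label, "A")) "antisymmetric" else "symmetric"
    for (i in seq_along(b$f)) {
      d0 <- abs(dispersion_determinant(pm, b$f[i], b$k[i], fam))
      # local determinant scale from a nearby off-root evaluation
      dref <- abs(dispersion_determinant(pm, b$f[i], b$k[i] * 1.02 + 5, fam))
      expect_lt(d0, 1e-6 * max(dref, 1))
    }
  }
})

test_that("traced roots match an exhaustive fine sign-change scan", {
  pm <- nf_plate()
  fg <- seq(4e5, 1.3e6, length.out = 10)
  cs <- trace_dispersion_curves(pm, fg, k_max = 6000, k_min = 20)
  h <- pm$thickness * 1e-3
  matched <- total_traced <- total_brute <- 0
  for (j in seq_along(fg)) {
    traced <- sort(unlist(lapply(cs$branches, function(b) {
      i <- match(fg[j], b$f)
      if (!is.na(i)) b$k[i]
    })))
    for (fam in c("antisymmetric", "symmetric")) {
      brute <- scan_roots_bruteforce(pm, fg[j], 6000, fam,
                                     k_step = pi / (160 * h))
      total_brute <- total_brute + length(brute)
      matched <- matched + sum(vapply(brute, function(k0)
        any(abs(traced - k0) < 1), logical(1)))
    }
    total_traced <- total_traced + length(traced)
  }
  # >= 99% of brute-force roots found by the tracer (and no inflation)
  expect_gte(matched / total_brute, 0.99)
  expect_lte(total_traced, total_brute + 1)
})

test_that("sign-change count at fixed frequency equals traced root count", {
  pm <- nf_plate()
  f0 <- 9e5
  h <- pm$thickness * 1e-3
  cs <- trace_dispersion_curves(pm, c(f0 - 1, f0, f0 + 1), k_max = 6000,
                                k_min = 20)
  n_traced <- sum(vapply(cs$branches, function(b) f0 %in% b$f, logical(1)))
  n_scan <- 0
  for (fam in c("antisymmetric", "symmetric")) {
    ks <- seq(20, 6000, by = pi / (80 * h))
    d <- dispersion_determinant(pm, f0, ks, fam)
    n_scan <- n_scan + sum(d[-length(d)] * d[-1] < 0)
  }
  expect_equal(n_traced, n_scan)
})

test_that("A0 obeys the thin-plate sqrt(f) law in the asymptotic regime", {
  pm <- iso_plate(thickness = 2)
  fg <- seq(1e3, 8e3, length.out = 10)
  cs <- trace_dispersion_curves(pm, fg, k_max = 3000, k_min = 0.5,
                                k_step = pi / (200 * 0.002))
  a0 <- Filter(function(b) b$label == "A0", cs$branches)[[1]]
  v <- phase_velocity(a0, a0$f)
  slope <- unname(coef(lm(log(v) ~ log(a0$f)))[2])
  expect_equal(slope, 0.5, tolerance = 0.04)   # 0.5 +- 0.02 absolute
  expect_lt(abs(slope - 0.5), 0.02)
})

test_that("A0 and S0 converge to the Rayleigh velocity at high f*h", {
  pm <- iso_plate(thickness = 2)
  eff <- effective_properties(pm)
  vray <- rayleigh_velocity(sqrt(eff$c11 * 1e9 / eff$rho),
                            sqrt(eff$c55 * 1e9 / eff$rho))
  # f*h = 10 MHz*mm: f = 5 MHz on the 2 mm plate
  cs <- trace_dispersion_curves(pm, seq(4.6e6, 5e6, length.out = 5),
                                k_max = 25000)
  for (lbl in c("A0", "S0")) {
    b <- Filter(function(x) x$label == lbl, cs$branches)[[1]]
    expect_equal(phase_velocity(b, 5e6), vray, tolerance = 0.01)
  }
})

test_that("increasing porosity strictly decreases phase velocities", {
  f0 <- 6e5
  v_last <- Inf
  for (po in c(0, 0.05, 0.1, 0.15, 0.2)) {
    cs <- trace_dispersion_curves(plate_model(2.7, po),
                                  c(f0 * 0.99, f0, f0 * 1.01), k_max = 6000,
                                  k_min = 20)
    a0 <- Filter(function(b) b$label == "A0", cs$branches)[[1]]
    v <- phase_velocity(a0, f0)
    expect_lt(v, v_last)
    v_last <- v
  }
})

test_that("dispersion depends on f and h only through f*h", {
  c1 <- trace_dispersion_curves(plate_model(2, 0.1), c(8e5), k_max = 8000,
                                k_min = 20)
  c2 <- trace_dispersion_curves(plate_model(4, 0.1), c(4e5), k_max = 4000,
                                k_min = 10)
  k1 <- sort(unlist(lapply(c1$branches, function(b) b$k)))
  k2 <- sort(unlist(lapply(c2$branches, function(b) b$k)))
  expect_equal(length(k1), length(k2))
  expect_equal(k1, 2 * k2, tolerance = 1e-4)
})

test_that("phase_velocity interpolates and matches a direct root", {
  # definitional case: f = 1 MHz, k = 2*pi*1000 -> 1000 m/s
  b <- list(label = "X", f = c(9e5, 1e6, 1.1e6),
            k = c(2 * pi * 900, 2 * pi * 1000, 2 * pi * 1100))
  expect_equal(phase_velocity(b, 1e6), 1000)
  # interpolation stays between neighbor velocities
  v_mid <- phase_velocity(b, 9.5e5)
  v_nb <- 2 * pi * c(9e5, 1e6) / c(2 * pi * 900, 2 * pi * 1000)
  expect_gte(v_mid, min(v_nb)); expect_lte(v_mid, max(v_nb))
  expect_error(phase_velocity(b, 2e6), class = "bdat_range_error")

  # interpolated A0 velocity agrees with a bisection root recomputed at
  # exactly 0.5 MHz
  pm <- nf_plate()
  cs <- trace_dispersion_curves(pm, seq(4.6e5, 5.4e5, length.out = 5),
                                k_max = 6000, k_min = 20)
  a0 <- Filter(function(b) b$label == "A0", cs$branches)[[1]]
  k_root <- scan_roots_bruteforce(pm, 5e5, 6000, "antisymmetric",
                                  k_step = pi / (40 * 0.0027))
  v_root <- 2 * pi * 5e5 / max(k_root)   # A0 = largest-k antisymmetric root
  expect_equal(phase_velocity(a0, 5e5), v_root, tolerance = 1e-3)
})

test_that("usage errors are raised for bad tracer inputs", {
  pm <- nf_plate()
  expect_error(trace_dispersion_curves(pm, numeric(0), k_max = 100),
               class = "bdat_usage_error")
  expect_error(trace_dispersion_curves(pm, c(2e5, 1e5), k_max = 100),
               class = "bdat_usage_error")
  expect_error(trace_dispersion_curves(pm, 1e5, k_max = -5),
               class = "bdat_usage_error")
  expect_error(dispersion_determinant(pm, -1, 100, "symmetric"),
               class = "bdat_usage_error")
})

test_that("dispersion curves survive a JSON round trip", {
  pm <- nf_plate()
  cs <- trace_dispersion_curves(pm, seq(5e5, 8e5, length.out = 4),
                                k_max = 5000, k_min = 20)
  path <- tempfile(fileext = ".json")
  write_dispersion_json(cs, path)
  cs2 <- read_dispersion_json(path)
  expect_equal(length(cs2$branches), length(cs$branches))
  for (i in seq_along(cs$branches)) {
    expect_identical(cs2$branches[[i]]$label, cs$branches[[i]]$label)
    expect_equal(cs2$branches[[i]]$k, cs$branches[[i]]$k)
  }
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "other"), bad, auto_unbox = TRUE)
  expect_error(read_dispersion_json(bad), class = "bdat_parse_error")
  unlink(c(path, bad))
})

test_that("master dimensionless table agrees with the direct tracer", {
  pm <- plate_model(3.1, 0.07)
  fg <- seq(5e5, 1.2e6, length.out = 8)
  direct <- trace_dispersion_curves(pm, fg, k_max = 6000, k_min = 20)
  fast <- bdatr:::.model_branches_fast(pm, fg)
  a0_d <- Filter(function(b) b$label == "A0", direct$branches)[[1]]
  a0_f <- fast[[which.max(vapply(fast, function(b)
    max(b$k[b$f == fg[1]], 0), numeric(1)))]]
  common <- intersect(a0_d$f, a0_f$f)
  kd <- a0_d$k[match(common, a0_d$f)]
  kf <- a0_f$k[match(common, a0_f$f)]
  expect_equal(kd, kf, tolerance = 1e-4)
})
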