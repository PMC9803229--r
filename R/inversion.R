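# The Proj function and the measurement protocol.
#
# Proj(Ct.Th, Ct.Po): for a candidate plate, every traced model branch point
# (f, k_n(f; Th, Po)) inside the measured window is projected onto the
# reception singular vectors at f (same basis as the Norm image); the pixel
# is the average squared projection over branch points and directions. The
# estimate is the (Th, Po) maximizer, refined off-grid by direct search.

# stack the i-th kept singular vector of every frequency into one matrix
# (n_rx x n_f, zero column where fewer vectors were kept)
.stack_basis <- function(vs, n_rx, max_r) {
  nf <- length(vs)
  out <- vector("list", max_r)
  for (i in seq_len(max_r)) {
    Vi <- matrix(0i, n_rx, nf)
    for (j in seq_len(nf)) {
      V <- vs[[j]]
      if (!is.null(V) && ncol(V) >= i) Vi[, j] <- V[, i]
    }
    out[[i]] <- Conj(Vi)
  }
  out
}

# average squared projection of the model branch points of `model` onto the
# stacked basis; returns scalar in [0,1] (0 when no branch point in window).
# The candidate wavefield holds the guided-mode branches plus, optionally,
# the first-arrival lateral-wave line at the effective axial longitudinal
# velocity - the same non-dispersive component the synthesizer emits, so the
# forward and inverse models stay consistent.
# per-pixel sums: s = mean over directions of sum(v^gamma) over branch
# points, n = number of branch points in the window
.proj_point_sums <- function(model, stacked, f, x_r, k_window, master,
                             head_wave = TRUE, gamma = 2) {
  br <- .model_branches_fast(model, f, master)
  if (head_wave) {
    eff <- effective_properties(model)
    v_l <- sqrt(eff$c33 * 1e9 / eff$rho)
    br <- c(br, list(list(label = "FAS", f = f, k = 2 * pi * f / v_l)))
  }
  if (!length(br)) return(list(s = 0, n = 0L))
  fidx <- kk <- numeric(0)
  for (b in br) {
    keep <- b$k >= k_window[1] & b$k <= k_window[2]
    if (any(keep)) {
      fidx <- c(fidx, match(b$f[keep], f))
      kk <- c(kk, b$k[keep])
    }
  }
  if (!length(kk)) return(list(s = 0, n = 0L))
  total <- 0
  for (dname in names(stacked)) {
    sgn <- if (dname == "forward") 1 else -1
    E <- exp(sgn * 1i * outer(x_r, kk))
    E <- sweep(E, 2, sqrt(colSums(Mod(E)^2)), "/")
    v <- 0
    for (Vi in stacked[[dname]])
      v <- v + Mod(colSums(Vi[, fidx, drop = FALSE] * E))^2
    total <- total + sum(v^gamma)
  }
  list(s = total / length(stacked), n = length(kk))
}

# Pixel objective: power mean of the squared point projections with a
# completeness floor. A plain mean lets a displaced candidate whose few
# branches all graze strong ridges outscore the truth, whose average is
# diluted by modes under-represented in the rank-limited subspace; gamma = 2
# rewards points squarely on ridges. Dividing by max(n, n_ref) instead of n
# keeps a candidate that explains only a small subset of the measured
# wavefield (a very thin plate carrying one mode) from scoring high on that
# subset alone.
.proj_objective <- function(model, stacked, f, x_r, k_window, master,
                            head_wave = TRUE, gamma = 2, n_ref = 0) {
  ps <- .proj_point_sums(model, stacked, f, x_r, k_window, master,
                         head_wave, gamma)
  if (ps$n == 0L) return(0)
  (ps$s / max(ps$n, n_ref))^(1 / gamma)
}

#' Proj model-fit surface over the (Ct.Th, Ct.Po) plane
#'
#' @param basis A \code{svd_basis} (or a \code{norm_image}, whose basis is
#'   reused).
#' @param th_grid Candidate cortical thickness grid, mm.
#' @param po_grid Candidate cortical porosity grid, percent.
#' @param template A \code{plate_model} supplying the matrix constants
#'   (its thickness/porosity are ignored).
#' @param k_window Wavenumber window of the measurement, rad/m.
#' @param head_wave Include the first-arrival lateral-wave line (at the
#'   effective axial longitudinal velocity) among the candidate model
#'   branches, matching the synthesizer's wavefield.
#' @return Class \code{proj_map}: list with \code{th_grid}, \code{po_grid},
#'   \code{values} (matrix th x po in [0,1]), \code{argmax}
#'   (named c(ct_th, ct_po)), \code{max_value}, and the ingredients needed to
#'   re-evaluate the objective off-grid.
#' @export
proj_map <- function(basis, th_grid = seq(0.5, 5, by = 0.05),
                     po_grid = seq(0, 25, by = 0.5),
                     template = plate_model(1, 0),
                     k_window = c(300, 6000), head_wave = TRUE) {
  if (inherits(basis, "norm_image")) basis <- basis$basis
  stopifnot(inherits(basis, "svd_basis"))
  if (!length(th_grid) || !length(po_grid))
    .bdat_stop("empty parameter grid", "bdat_usage_error")
  x_r <- receiver_positions(basis$geometry)
  n_rx <- length(x_r)
  max_r <- max(unlist(basis$n_kept), 1)
  stacked <- lapply(basis$basis, .stack_basis, n_rx = n_rx, max_r = max_r)
  master <- .master_curves(template)
  sums <- npts <- matrix(NA_real_, length(th_grid), length(po_grid))
  for (it in seq_along(th_grid)) {
    for (ip in seq_along(po_grid)) {
      m <- plate_model(th_grid[it], po_grid[ip] / 100,
                       c11 = template$c11, c13 = template$c13,
                       c33 = template$c33, c55 = template$c55,
                       rho_matrix = template$rho_matrix,
                       rho_fluid = template$rho_fluid, q = template$q)
      ps <- tryCatch(
        .proj_point_sums(m, stacked, basis$f, x_r, k_window, master,
                         head_wave),
        error = function(e) NULL)      # pixel flagged invalid, not fatal
      if (!is.null(ps)) { sums[it, ip] <- ps$s; npts[it, ip] <- ps$n }
    }
  }
  # completeness floor: half the richest candidate's branch-point count
  n_ref <- 0.5 * max(npts, na.rm = TRUE)
  vals <- (sums / pmax(npts, n_ref))^(1 / 2)
  vals[!is.na(npts) & npts == 0] <- 0
  imax <- which(vals == max(vals, na.rm = TRUE), arr.ind = TRUE)[1, ]
  structure(list(th_grid = th_grid, po_grid = po_grid, values = vals,
                 argmax = c(ct_th = th_grid[imax[1]], ct_po = po_grid[imax[2]]),
                 max_value = max(vals, na.rm = TRUE),
                 template = template, k_window = k_window,
                 head_wave = head_wave, n_ref = n_ref,
                 basis_f = basis$f, x_r = x_r, stacked = stacked,
                 master = master),
            class = "proj_map")
}

#' @export
print.proj_map <- function(x, ...) {
  cat(sprintf("<proj_map> %d x %d grid, max %.3f at Ct.Th = %.2f mm, Ct.Po = %.1f %%\n",
              length(x$th_grid), length(x$po_grid), x$max_value,
              x$argmax["ct_th"], x$argmax["ct_po"]))
  invisible(x)
}

#' Off-grid refinement of the Proj maximum
#'
#' Nelder-Mead ascent of the Proj objective from the grid argmax, clipped to
#' the grid ranges. Never returns a point with a lower objective than the
#' grid maximum.
#'
#' @param map A \code{proj_map}.
#' @param objective Optional re-evaluator \code{function(ct_th, ct_po)}
#'   returning the objective value; by default the map's own Proj objective
#'   is re-evaluated off-grid.
#' @param tol_th,tol_po Convergence tolerances, mm and percentage points.
#' @param maxit Iteration cap; on non-convergence the grid argmax is
#'   returned with \code{converged = FALSE}.
#' @return List with \code{ct_th}, \code{ct_po}, \code{value},
#'   \code{converged}.
#' @export
refine_maximum <- function(map, objective = NULL, tol_th = 1e-3,
                           tol_po = 1e-2, maxit = 200) {
  stopifnot(inherits(map, "proj_map"))
  tpl <- map$template
  lims <- list(th = range(map$th_grid), po = range(map$po_grid))
  if (is.null(objective)) {
    objective <- function(ct_th, ct_po) {
      m <- plate_model(ct_th, ct_po / 100, c11 = tpl$c11, c13 = tpl$c13,
                       c33 = tpl$c33, c55 = tpl$c55,
                       rho_matrix = tpl$rho_matrix,
                       rho_fluid = tpl$rho_fluid, q = tpl$q)
      .proj_objective(m, map$stacked, map$basis_f, map$x_r, map$k_window,
                      map$master, isTRUE(map$head_wave),
                      n_ref = if (is.null(map$n_ref)) 0 else map$n_ref)
    }
  }
  obj <- function(p) {
    if (p[1] < lims$th[1] || p[1] > lims$th[2] ||
        p[2] < lims$po[1] || p[2] > lims$po[2]) return(1e6)
    -objective(p[1], p[2])
  }
  p0 <- as.numeric(map$argmax)
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit,
                                     reltol = 1e-9,
                                     parscale = c(tol_th * 50, tol_po * 50)))
  if (-opt$value >= map$max_value) {
    list(ct_th = opt$par[1], ct_po = opt$par[2], value = -opt$value,
         converged = opt$convergence == 0)
  } else {
    warning("refinement did not improve on the grid maximum")
    list(ct_th = p0[1], ct_po = p0[2], value = map$max_value,
         converged = FALSE)
  }
}

# analytic-signal envelopes of a trace matrix (time x traces)
.envelope <- function(x) {
  n <- nrow(x)
  X <- stats::mvfft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::mvfft(X * h, inverse = TRUE) / n)
}

# first threshold crossing of an envelope, linearly interpolated (samples)
.first_crossing <- function(env, thr) {
  i <- which(env >= thr)[1]
  if (is.na(i) || i == 1L) return(NA_real_)
  (i - 2) + (thr - env[i - 1]) / (env[i] - env[i - 1])
}

#' First-arriving-signal velocity (VFAS)
#'
#' Per direction, the first arrival at each receiver is picked as the first
#' crossing of the trace envelope above \code{threshold_factor} times the
#' pre-arrival noise RMS, floored at 10 percent of the emitter's peak
#' envelope (the floor keeps the pick on the head-wave onset, above the
#' leading tail of the fastest guided mode, and makes noise-free records
#' well-defined); arrival time is regressed on receiver position (robust
#' M-estimator, one velocity per emitter, median over emitters). The
#' bidirectional combination is the harmonic mean 2 V1 V2 / (V1 + V2),
#' cancelling tilt-induced biases to first order.
#'
#' @param signals An \code{array_signals}.
#' @param threshold_factor Multiple of the pre-arrival noise RMS.
#' @param v_upper Upper bound on physical arrival speed, m/s (defines the
#'   pre-arrival window).
#' @param min_receivers Minimum detectable arrivals per direction.
#' @param v_bounds Plausible first-arrival velocity window, m/s; fits outside
#'   it (noise-dominated picks) count as failures.
#' @return Class \code{velocity_estimate}: \code{v_forward},
#'   \code{v_backward}, \code{v_combined} (m/s), \code{r2}, \code{failed}.
#' @export
estimate_vfas <- function(signals, threshold_factor = 5, v_upper = 6000,
                          min_receivers = 3, v_bounds = c(1000, 8000)) {
  stopifnot(inherits(signals, "array_signals"))
  g <- signals$geometry
  fs <- g$sampling_rate
  x_r <- receiver_positions(g)
  dist0 <- .tx_rx_distances(g)
  v_dir <- r2_dir <- c(forward = NA_real_, backward = NA_real_)
  n_det <- c(forward = 0L, backward = 0L)
  for (dname in names(signals$signals)) {
    a <- signals$signals[[dname]]
    ne <- dim(a)[1]; nr <- dim(a)[2]; n <- dim(a)[3]
    # backward waves travel toward decreasing position: distance grows as
    # max(x) - x
    xr_d <- if (dname == "forward") x_r else max(x_r) - x_r
    vel <- r2 <- rep(NA_real_, ne)
    ndet_e <- integer(ne)
    for (e in seq_len(ne)) {
      tr <- t(matrix(a[e, , ], nrow = nr))      # time x receivers
      env <- .envelope(tr)
      # one threshold per emitter: per-receiver thresholds would put the
      # crossing at a different envelope offset on every trace and bias the
      # slope; pooled pre-arrival noise keeps the offset common
      noise <- stats::median(vapply(seq_len(nr), function(r) {
        d <- dist0[e, if (dname == "forward") r else nr - r + 1L]
        npre <- max(8L, floor(d / v_upper * fs))
        stats::sd(tr[seq_len(min(npre, n)), r])
      }, numeric(1)))
      thr <- max(threshold_factor * noise, 0.1 * max(env))
      t_arr <- rep(NA_real_, nr)
      for (r in seq_len(nr)) {
        cross <- .first_crossing(env[, r], thr)
        if (!is.na(cross)) t_arr[r] <- cross / fs
      }
      ok <- !is.na(t_arr)
      ndet_e[e] <- sum(ok)
      if (sum(ok) >= min_receivers) {
        fit <- tryCatch(MASS::rlm(t_arr[ok] ~ xr_d[ok], maxit = 50),
                        error = function(e) NULL,
                        warning = function(w) NULL)
        if (is.null(fit)) fit <- stats::lm(t_arr[ok] ~ xr_d[ok])
        sl <- stats::coef(fit)[2]
        if (is.finite(sl) && sl > 0 &&
            1 / sl >= v_bounds[1] && 1 / sl <= v_bounds[2]) {
          vel[e] <- 1 / sl
          tt <- t_arr[ok]
          r2[e] <- 1 - sum(stats::residuals(fit)^2) /
            max(sum((tt - mean(tt))^2), 1e-30)
        }
      }
    }
    n_det[dname] <- max(ndet_e)
    if (any(is.finite(vel))) {
      v_dir[dname] <- stats::median(vel, na.rm = TRUE)
      r2_dir[dname] <- stats::median(r2, na.rm = TRUE)
    }
  }
  failed <- any(!is.finite(v_dir)) || any(n_det < min_receivers)
  v_comb <- if (failed) NA_real_ else
    2 * v_dir[["forward"]] * v_dir[["backward"]] /
      (v_dir[["forward"]] + v_dir[["backward"]])
  structure(list(v_forward = v_dir[["forward"]],
                 v_backward = v_dir[["backward"]],
                 v_combined = v_comb, r2 = unname(r2_dir),
                 n_detected = n_det, failed = failed, method = "vfas"),
            class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  if (x$failed) cat(sprintf("<velocity_estimate:%s> failed\n", x$method))
  else cat(sprintf("<velocity_estimate:%s> V1 = %.0f, V2 = %.0f, combined = %.0f m/s\n",
                   x$method, x$v_forward, x$v_backward, x$v_combined))
  invisible(x)
}

# lowest-velocity usable track of one branch-point set; returns median phase
# velocity over the band or NA. v_range is the physical prior on A0 phase
# velocities in cortical bone: it rejects the fast head-wave line and slow
# noise ghosts.
.a0_velocity <- function(branches, band, min_points = 3,
                         v_range = c(800, 3000)) {
  best <- NA_real_
  for (tr in branches) {
    sel <- tr$f >= band[1] & tr$f <= band[2]
    if (sum(sel) < min_points) next
    v <- stats::median(2 * pi * tr$f[sel] / tr$k[sel])
    if (v < v_range[1] || v > v_range[2]) next
    if (is.na(best) || v < best) best <- v
  }
  best
}

#' Phase velocity of the fundamental antisymmetric (A0) mode
#'
#' The A0 track is identified as the lowest-phase-velocity track among the
#' extracted branch points; VA0 is the median phase velocity 2 pi f / k over
#' the track restricted to \code{band}. With per-direction branch sets the
#' bidirectional combination is the same harmonic mean as for VFAS.
#'
#' @param branches A \code{branch_points} set, or
#'   \code{list(forward = , backward = )} of two sets.
#' @param band Frequency band, Hz.
#' @param curves Optional \code{dispersion_curves}; unused for identification
#'   but reported in the provenance when given.
#' @param min_points Minimum in-band track points.
#' @param v_range Plausible A0 phase-velocity window, m/s; tracks whose
#'   median velocity falls outside (e.g. the fast first-arrival line) are
#'   not A0 candidates.
#' @return A \code{velocity_estimate} (method "va0").
#' @export
estimate_va0 <- function(branches, band = c(0.4e6, 0.8e6), curves = NULL,
                         min_points = 3, v_range = c(800, 3000)) {
  if (inherits(branches, "branch_points"))
    branches <- list(forward = branches, backward = branches)
  v1 <- .a0_velocity(branches$forward, band, min_points, v_range)
  v2 <- .a0_velocity(branches$backward, band, min_points, v_range)
  failed <- is.na(v1) || is.na(v2)
  structure(list(v_forward = v1, v_backward = v2,
                 v_combined = if (failed) NA_real_ else 2 * v1 * v2 / (v1 + v2),
                 r2 = NA_real_, n_detected = NULL,
                 failed = failed, method = "va0"),
            class = "velocity_estimate")
}

# coherent mean of response spectra (same geometry/band assumed)
.average_spectra <- function(specs) {
  out <- specs[[1]]
  for (dname in names(out$spectra)) {
    acc <- out$spectra[[dname]]
    for (s in specs[-1]) acc <- acc + s$spectra[[dname]]
    out$spectra[[dname]] <- acc / length(specs)
  }
  out
}

#' Run the full measurement protocol on acquired series
#'
#' Per acquisition, VFAS and VA0 are attempted; a series succeeds when both
#' velocities are obtained in at least half of its acquisitions (the probe is
#' otherwise considered misaligned). Per successful series, velocities are
#' the within-series medians and one inversion is run on the coherently
#' averaged response spectra. Final parameters are the means over successful
#' series; the measurement fails with fewer than two successful series.
#'
#' @param series List of series, each a list of \code{array_signals}
#'   (as returned by \code{\link{acquisition_series}}).
#' @param th_grid,po_grid Inversion grids (mm, percent).
#' @param k_grid Wavenumber grid for the Norm image, rad/m.
#' @param va0_band VA0 estimation band, Hz.
#' @param branch_threshold Norm-image maxima threshold.
#' @param template \code{plate_model} carrying the matrix constants.
#' @param refine Refine the per-series grid maximum off-grid?
#' @param qc_min_value Minimum Proj maximum for a series inversion to count.
#' @return Class \code{bdat_estimate}: \code{vfas}, \code{va0}, \code{ct_th},
#'   \code{ct_po} , \code{ratio} (%/mm), \code{series_success},
#'   \code{series_values}, \code{failed}, \code{provenance}.
#' @export
run_measurement_protocol <- function(series,
                                     th_grid = seq(1.0, 4.5, by = 0.1),
                                     po_grid = seq(0, 25, by = 1),
                                     k_grid = seq(200, 6000, by = 10),
                                     va0_band = c(0.4e6, 0.8e6),
                                     branch_threshold = 0.4,
                                     template = plate_model(1, 0),
                                     refine = TRUE,
                                     qc_min_value = 0.5) {
  if (!length(series)) .bdat_stop("need at least one series", "bdat_usage_error")
  n_series <- length(series)
  series_success <- logical(n_series)
  vals <- data.frame(series = seq_len(n_series), vfas = NA_real_,
                     va0 = NA_real_, ct_th = NA_real_, ct_po = NA_real_,
                     n_success = 0L)
  for (s in seq_len(n_series)) {
    acqs <- series[[s]]
    vfas_a <- va0_a <- rep(NA_real_, length(acqs))
    specs <- vector("list", length(acqs))
    band_s <- NULL   # common band within the series so spectra can be averaged
    for (a in seq_along(acqs)) {
      vf <- estimate_vfas(acqs[[a]])
      sp <- if (is.null(band_s)) response_spectrum(acqs[[a]]) else
        response_spectrum(acqs[[a]], band = band_s)
      if (is.null(band_s)) band_s <- range(sp$f)
      specs[[a]] <- sp
      ni <- norm_image(sp, k_grid = k_grid)
      va <- estimate_va0(list(
        forward = extract_branches(ni, branch_threshold, "forward"),
        backward = extract_branches(ni, branch_threshold, "backward")),
        band = va0_band)
      if (!vf$failed) vfas_a[a] <- vf$v_combined
      if (!va$failed) va0_a[a] <- va$v_combined
    }
    ok <- !is.na(vfas_a) & !is.na(va0_a)
    vals$n_success[s] <- sum(ok)
    if (sum(ok) >= length(acqs) / 2) {
      series_success[s] <- TRUE
      vals$vfas[s] <- stats::median(vfas_a[ok])
      vals$va0[s] <- stats::median(va0_a[ok])
      basis <- signal_subspace(.average_spectra(specs[ok]))
      pm <- proj_map(basis, th_grid, po_grid, template = template,
                     k_window = range(k_grid))
      est <- if (refine) refine_maximum(pm) else
        list(ct_th = pm$argmax[["ct_th"]], ct_po = pm$argmax[["ct_po"]],
             value = pm$max_value)
      if (est$value >= qc_min_value) {
        vals$ct_th[s] <- est$ct_th
        vals$ct_po[s] <- est$ct_po
      } else {
        series_success[s] <- FALSE
      }
    }
  }
  used <- series_success & !is.na(vals$ct_th)
  failed <- sum(used) < 2
  out <- list(
    vfas = if (failed) NA_real_ else mean(vals$vfas[used]),
    va0 = if (failed) NA_real_ else mean(vals$va0[used]),
    ct_th = if (failed) NA_real_ else mean(vals$ct_th[used]),
    ct_po = if (failed) NA_real_ else mean(vals$ct_po[used]),
    series_success = series_success,
    series_values = vals,
    failed = failed,
    provenance = list(n_series = n_series,
                      n_acquisitions = lengths(series)))
  out$ratio <- if (failed) NA_real_ else out$ct_po / out$ct_th
  structure(out, class = "bdat_estimate")
}

#' @export
print.bdat_estimate <- function(x, ...) {
  if (x$failed) {
    cat("<bdat_estimate> FAILED (fewer than two successful series)\n")
  } else {
    cat(sprintf(
      "<bdat_estimate> VFAS = %.0f m/s, VA0 = %.0f m/s, Ct.Th = %.2f mm, Ct.Po = %.1f %%, Ct.Po/Ct.Th = %.2f\n",
      x$vfas, x$va0, x$ct_th, x$ct_po, x$ratio))
  }
  cat(sprintf("  series success: %s\n",
              paste(ifelse(x$series_success, "ok", "fail"), collapse = " ")))
  invisible(x)
}

#' Write a BDAT estimate to JSON
#' @param estimate A \code{bdat_estimate}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_estimate_json <- function(estimate, path) {
  stopifnot(inherits(estimate, "bdat_estimate"))
  obj <- list(format = "bdat-estimate-1",
              units = list(vfas = "m/s", va0 = "m/s", ct_th = "mm",
                           ct_po = "%", ratio = "%/mm"),
              vfas = estimate$vfas, va0 = estimate$va0,
              ct_th = estimate$ct_th, ct_po = estimate$ct_po,
              ratio = estimate$ratio, failed = estimate$failed,
              series_success = estimate$series_success,
              provenance = estimate$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
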