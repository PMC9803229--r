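# Guided-mode dispersion of a traction-free, transversely isotropic plate.
#
# Coordinates: x = propagation (bone axis, TI symmetry axis "3"),
# z = thickness. Partial waves u ~ exp(i(kx - wt)) f(qz) with q^2 the roots
# of the Christoffel quartic; symmetric / antisymmetric families separate and
# each yields a 2x2 traction-free boundary determinant. All internal units SI
# (m, Pa, rad/s, rad/m); the user-facing plate_model carries mm and GPa.

# sin(q*a)/q, entire in q^2 (-> a as q -> 0)
.sinq <- function(q, a) {
  out <- sin(q * a) / q
  tiny <- Mod(q) * a < 1e-12
  if (any(tiny)) out[tiny] <- a + 0i
  out
}

# Boundary-condition determinant, vectorized over (omega, k).
# eff: effective constants in Pa + rho; h in m.
.disp_det <- function(eff, h, omega, k, family) {
  c11 <- eff$c11; c13 <- eff$c13; c33 <- eff$c33; c55 <- eff$c55
  rho <- eff$rho
  X <- c33 * k^2 - rho * omega^2
  Y <- c55 * k^2 - rho * omega^2
  A <- c55 * c11
  B <- X * c11 + Y * c55 - (c13 + c55)^2 * k^2
  CC <- X * Y
  disc <- B^2 - 4 * A * CC
  sq <- sqrt(as.complex(disc))
  q1s <- (-B + sq) / (2 * A)
  q2s <- (-B - sq) / (2 * A)
  q1 <- sqrt(q1s)
  q2 <- sqrt(q2s)
  P1 <- X + c55 * q1s
  P2 <- X + c55 * q2s
  d1 <- k^2 * c13 * (c13 + c55) - c11 * P1
  d2 <- k^2 * c13 * (c13 + c55) - c11 * P2
  hh <- h / 2
  # per-partial-wave scaling bounds cosh/sinh growth of evanescent waves;
  # positive factors leave the root set unchanged
  s1 <- exp(-abs(Im(q1)) * hh)
  s2 <- exp(-abs(Im(q2)) * hh)
  if (family == "symmetric") {
    t1 <- c55 * (P1 / (c13 + c55) - q1s)
    t2 <- c55 * (P2 / (c13 + c55) - q2s)
    D <- d1 * (cos(q1 * hh) * s1) * t2 * (.sinq(q2, hh) * s2) -
         d2 * (cos(q2 * hh) * s2) * t1 * (.sinq(q1, hh) * s1)
  } else {
    t1 <- c55 * (q1s - P1 / (c13 + c55))
    t2 <- c55 * (q2s - P2 / (c13 + c55))
    D <- d1 * (q1 * sin(q1 * hh) * s1) * t2 * (cos(q2 * hh) * s2) -
         d2 * (q2 * sin(q2 * hh) * s2) * t1 * (cos(q1 * hh) * s1)
  }
  # D is T(q1^2) - T(q2^2) for an analytic T with real coefficients: dividing
  # by (q1^2 - q2^2) makes the result real both for real and for
  # complex-conjugate root pairs, and regularizes near-degenerate roots
  den <- q1s - q2s
  out <- Re(D / den)
  bad <- !is.finite(out)
  if (any(bad)) {
    kk <- k
    if (length(kk) == 1L) kk <- rep(kk, length(out))
    oo <- omega
    if (length(oo) == 1L) oo <- rep(oo, length(out))
    out[bad] <- Recall(eff, h, oo[bad] * (1 + 1e-7), kk[bad], family)
  }
  out
}

#' Traction-free plate boundary determinant
#'
#' Scaled secular function of the guided-mode problem: it is continuous in
#' (frequency, wavenumber), real, and vanishes exactly on the dispersion
#' branches of the chosen symmetry family. Used by the root tracer and
#' available directly for diagnostics.
#'
#' @param model A \code{\link{plate_model}}.
#' @param frequency Frequency in Hz (> 0); vectorized.
#' @param wavenumber Wavenumber in rad/m (>= 0); vectorized.
#' @param family \code{"symmetric"} or \code{"antisymmetric"}.
#' @return Real numeric vector of determinant values (arbitrary scale).
#' @export
dispersion_determinant <- function(model, frequency, wavenumber,
                                   family = c("symmetric", "antisymmetric")) {
  stopifnot(inherits(model, "plate_model"))
  family <- match.arg(family)
  if (any(frequency <= 0)) .bdat_stop("frequency must be > 0", "bdat_usage_error")
  if (any(wavenumber < 0)) .bdat_stop("wavenumber must be >= 0", "bdat_usage_error")
  eff <- effective_properties(model)
  eff <- list(c11 = eff$c11 * 1e9, c13 = eff$c13 * 1e9,
              c33 = eff$c33 * 1e9, c55 = eff$c55 * 1e9, rho = eff$rho)
  .disp_det(eff, model$thickness * 1e-3, 2 * pi * frequency, wavenumber, family)
}

# Link per-frequency roots into branches by continuity. Roots are matched to
# linear-in-f predictions of active branches (gate a few scan steps wide);
# unmatched roots open new branches, branches may skip up to two frequencies
# (near-degenerate root pairs at avoided crossings can escape one scan cell).
# Branches are labelled by cutoff order: first frequency of appearance, ties
# broken by descending wavenumber (lowest phase velocity first), so index 1
# is the fundamental mode.
.track_branches <- function(f_grid, roots, k_step, max_skip = 4L) {
  brs <- list()   # each: f, k, jlast (index of last matched frequency)
  for (j in seq_along(f_grid)) {
    fj <- f_grid[j]
    r <- roots[[j]]
    used <- logical(length(r))
    if (length(brs) && length(r)) {
      act <- which(vapply(brs, function(b) j - b$jlast <= max_skip + 1L,
                          logical(1)))
      if (length(act)) {
        pred <- gate <- numeric(length(act))
        for (ii in seq_along(act)) {
          b <- brs[[act[ii]]]
          np <- length(b$f)
          if (np >= 2L) {
            slope <- (b$k[np] - b$k[np - 1L]) / (b$f[np] - b$f[np - 1L])
            pred[ii] <- b$k[np] + slope * (fj - b$f[np])
          } else {
            # single point: extrapolate at constant phase velocity (k ~ f)
            pred[ii] <- b$k[np] * fj / b$f[np]
          }
          gate[ii] <- 5 * k_step * (j - b$jlast) + 0.03 * abs(pred[ii])
        }
        for (ii in order(-pred)) {
          cand <- which(!used)
          if (!length(cand)) break
          dk <- abs(r[cand] - pred[ii])
          m <- which.min(dk)
          if (dk[m] <= gate[ii]) {
            bi <- act[ii]
            brs[[bi]]$f <- c(brs[[bi]]$f, fj)
            brs[[bi]]$k <- c(brs[[bi]]$k, r[cand[m]])
            brs[[bi]]$jlast <- j
            if (sum(dk <= gate[ii]) > 1L) brs[[bi]]$ambiguous <- TRUE
            used[cand[m]] <- TRUE
          }
        }
      }
    }
    for (kk in r[!used])
      brs[[length(brs) + 1L]] <- list(f = fj, k = kk, jlast = j,
                                      ambiguous = FALSE)
  }
  if (!length(brs)) return(list())
  ord <- order(vapply(brs, function(b) b$f[1], numeric(1)),
               -vapply(brs, function(b) b$k[1], numeric(1)))
  lapply(brs[ord], function(b)
    list(f = b$f, k = b$k, ambiguous = isTRUE(b$ambiguous)))
}

# vectorized bisection; lo/hi/omega are parallel vectors, fn(omega, k)
.bisect_roots <- function(fn, omega, lo, hi, tol_rel = 1e-9, maxit = 80) {
  flo <- fn(omega, lo)
  for (it in seq_len(maxit)) {
    mid <- 0.5 * (lo + hi)
    fm <- fn(omega, mid)
    left <- (flo * fm) <= 0
    hi[left] <- mid[left]
    lo[!left] <- mid[!left]
    flo[!left] <- fm[!left]
    if (all((hi - lo) <= tol_rel * pmax(abs(mid), 1))) break
  }
  0.5 * (lo + hi)
}

# all roots of one family on (k_min, k_max], per frequency; returns a list
# of wavenumber vectors (sorted ascending), one per frequency
.family_roots <- function(eff, h, f_grid, k_max, k_step, k_min, family,
                          tol_rel = 1e-9, refine_factor = 8L) {
  omega <- 2 * pi * f_grid
  ks <- seq(max(k_min, k_step * 1e-3), k_max, by = k_step)
  if (length(ks) < 2) return(rep(list(numeric(0)), length(f_grid)))
  grid <- .disp_det(eff, h, rep(omega, each = length(ks)),
                    rep(ks, times = length(omega)), family)
  dim(grid) <- c(length(ks), length(omega))
  blo <- bhi <- bom <- bfi <- NULL
  add_brackets <- function(kv, d, j) {
    sc <- which(d[-length(d)] * d[-1] < 0 | d[-length(d)] == 0)
    if (length(sc)) {
      blo <<- c(blo, kv[sc]); bhi <<- c(bhi, kv[sc + 1])
      bom <<- c(bom, rep(omega[j], length(sc)))
      bfi <<- c(bfi, rep(j, length(sc)))
    }
    length(sc) > 0
  }
  nk <- length(ks)
  for (j in seq_along(omega)) {
    d <- grid[, j]
    add_brackets(ks, d, j)
    # near-degenerate root pairs (avoided crossings) dip toward zero without
    # changing sign on the coarse grid: re-scan those cells finer
    if (nk >= 3) {
      ad <- abs(d)
      cand <- which(ad[2:(nk - 1)] < ad[1:(nk - 2)] &
                      ad[2:(nk - 1)] < ad[3:nk]) + 1L
      cand <- cand[d[cand - 1L] * d[cand] > 0 & d[cand] * d[cand + 1L] > 0]
      for (i in cand) {
        kf <- seq(ks[i - 1L], ks[i + 1L],
                  length.out = 2L * refine_factor + 1L)
        df <- .disp_det(eff, h, omega[j], kf, family)
        add_brackets(kf, df, j)
      }
    }
  }
  out <- rep(list(numeric(0)), length(f_grid))
  if (is.null(blo)) return(out)
  roots <- .bisect_roots(function(om, k) .disp_det(eff, h, om, k, family),
                         bom, blo, bhi, tol_rel = tol_rel)
  for (j in unique(bfi)) out[[j]] <- sort(roots[bfi == j])
  out
}

#' Trace guided-mode dispersion curves
#'
#' Finds, for every frequency of \code{f_grid}, all wavenumber roots of the
#' symmetric and antisymmetric boundary determinants in \code{(k_min, k_max]}
#' by sign-change bracketing plus bisection (relative tolerance
#' \code{1e-6}), and links them across frequency into labelled branches.
#' Within a family, branches of a free plate do not cross, so the n-th
#' largest wavenumber at each frequency belongs to the n-th mode; A0 is the
#' antisymmetric branch with the lowest phase velocity (largest k) at the
#' lowest frequency, S0 its symmetric counterpart.
#'
#' @param model A \code{\link{plate_model}}.
#' @param f_grid Increasing vector of frequencies, Hz.
#' @param k_max Upper wavenumber bound, rad/m.
#' @param k_min Lower wavenumber bound, rad/m (roots below are ignored).
#' @param k_step Scan step for sign-change bracketing; default
#'   \code{pi / (20 * h)} with h the plate thickness.
#' @return An object of class \code{dispersion_curves}: list with
#'   \code{model}, \code{branches} (each \code{list(label, f, k)}),
#'   \code{f_range}, \code{k_range}.
#' @export
trace_dispersion_curves <- function(model, f_grid, k_max, k_min = 1,
                                    k_step = NULL) {
  stopifnot(inherits(model, "plate_model"))
  if (length(f_grid) < 1) .bdat_stop("empty f_grid", "bdat_usage_error")
  if (is.unsorted(f_grid, strictly = TRUE))
    .bdat_stop("f_grid must be strictly increasing", "bdat_usage_error")
  if (!.is_num1(k_max) || k_max <= 0)
    .bdat_stop("k_max must be > 0", "bdat_usage_error")
  h <- model$thickness * 1e-3
  if (is.null(k_step)) k_step <- pi / (20 * h)
  eff0 <- effective_properties(model)
  eff <- list(c11 = eff0$c11 * 1e9, c13 = eff0$c13 * 1e9,
              c33 = eff0$c33 * 1e9, c55 = eff0$c55 * 1e9, rho = eff0$rho)
  fams <- c(antisymmetric = "A", symmetric = "S")
  branches <- list()
  for (fam in names(fams)) {
    roots <- .family_roots(eff, h, f_grid, k_max, k_step, k_min, fam)
    tracked <- .track_branches(f_grid, roots, k_step)
    for (n in seq_along(tracked)) {
      b <- tracked[[n]]
      branches[[length(branches) + 1L]] <-
        list(label = paste0(fams[[fam]], n - 1L), f = b$f, k = b$k,
             ambiguous = b$ambiguous)
    }
  }
  structure(list(model = model, branches = branches,
                 f_range = range(f_grid), k_range = c(k_min, k_max)),
            class = "dispersion_curves")
}

#' @export
print.dispersion_curves <- function(x, ...) {
  cat(sprintf("<dispersion_curves> %d branches, f in [%.3g, %.3g] Hz\n",
              length(x$branches), x$f_range[1], x$f_range[2]))
  for (b in x$branches)
    cat(sprintf("  %-3s %3d points, k in [%.4g, %.4g] rad/m\n",
                b$label, length(b$f), min(b$k), max(b$k)))
  invisible(x)
}

#' Phase velocity on a dispersion branch
#'
#' Linearly interpolates the branch wavenumber at \code{frequency} and
#' returns v = 2*pi*f / k (m/s).
#'
#' @param branch One element of \code{dispersion_curves$branches}.
#' @param frequency Frequency in Hz; must lie inside the branch support.
#' @return Phase velocity, m/s (vectorized over \code{frequency}).
#' @export
phase_velocity <- function(branch, frequency) {
  if (any(frequency < min(branch$f) | frequency > max(branch$f)))
    .bdat_stop("frequency outside branch support", "bdat_range_error")
  if (length(branch$f) == 1L) {
    k <- rep(branch$k, length(frequency))
  } else {
    k <- .interp(branch$f, branch$k, frequency)
  }
  2 * pi * frequency / k
}

# ---- dimensionless master curves ------------------------------------------
#
# Because every stiffness constant scales by the same porosity factor, the
# dimensionless dispersion relation K(Omega) (K = k*h, Omega = omega*h/v55)
# depends only on the matrix stiffness ratios. One master trace per matrix
# material therefore serves every (thickness, porosity) pixel of the Proj
# search; per-pixel curves are recovered by interpolation. Validated against
# trace_dispersion_curves in the test suite.

.master_key <- function(model) {
  paste("master", model$c11, model$c13, model$c33, model$c55,
        model$rho_matrix, sep = "|")
}

.master_curves <- function(model, Omega_max = 32, K_max = 30,
                           n_omega = 320) {
  key <- paste(.master_key(model), Omega_max, K_max, n_omega, sep = "|")
  if (!is.null(.bdatr_cache[[key]])) return(.bdatr_cache[[key]])
  v55 <- sqrt(model$c55 * 1e9 / model$rho_matrix)
  h <- 1e-3
  # graded grid: dense at low Omega where A0 varies fastest
  Om <- seq(sqrt(0.05), sqrt(Omega_max), length.out = n_omega)^2
  f_grid <- Om * v55 / (2 * pi * h)
  ref <- plate_model(thickness = 1, porosity = 0,
                     c11 = model$c11, c13 = model$c13, c33 = model$c33,
                     c55 = model$c55, rho_matrix = model$rho_matrix,
                     rho_fluid = model$rho_fluid, q = model$q)
  cs <- trace_dispersion_curves(ref, f_grid, k_max = K_max / h,
                                k_min = 0.01 / h)
  master <- lapply(cs$branches, function(b)
    list(label = b$label, Om = 2 * pi * b$f * h / v55, K = b$k * h))
  .bdatr_cache[[key]] <- master
  master
}

# branch wavenumbers k_n(f) for arbitrary (thickness, porosity) via the
# master table; returns list of list(label, f, k) on the requested freqs
.model_branches_fast <- function(model, freqs, master = NULL) {
  if (is.null(master)) master <- .master_curves(model)
  eff <- effective_properties(model)
  v55 <- sqrt(eff$c55 * 1e9 / eff$rho)
  h <- model$thickness * 1e-3
  Om <- 2 * pi * freqs * h / v55
  out <- list()
  for (b in master) {
    if (length(b$Om) < 2) next   # spurious single-point track
    K <- stats::approx(b$Om, b$K, xout = Om, rule = 1, ties = "ordered")$y
    keep <- !is.na(K)
    if (any(keep))
      out[[length(out) + 1L]] <- list(label = b$label, f = freqs[keep],
                                      k = K[keep] / h)
  }
  out
}

#' Serialize dispersion curves to JSON
#'
#' Layout: \code{\{units, model, branches: [\{label, f, k\}]\}} with f in Hz,
#' k in rad/m, thickness in mm, stiffness in GPa.
#'
#' @param curves A \code{dispersion_curves} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_dispersion_json <- function(curves, path) {
  stopifnot(inherits(curves, "dispersion_curves"))
  obj <- list(
    format = "bdat-dispersion-1",
    units = list(f = "Hz", k = "rad/m", thickness = "mm", stiffness = "GPa"),
    model = unclass(curves$model),
    f_range = curves$f_range, k_range = curves$k_range,
    branches = lapply(curves$branches, function(b)
      list(label = b$label, f = b$f, k = b$k)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read dispersion curves written by \code{write_dispersion_json}
#' @param path File path.
#' @return A \code{dispersion_curves} object.
#' @export
read_dispersion_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(obj$format) || !identical(obj$format, "bdat-dispersion-1"))
    .bdat_stop("not a bdat-dispersion-1 file", "bdat_parse_error")
  m <- obj$model
  model <- plate_model(m$thickness, m$porosity, m$c11, m$c13, m$c33, m$c55,
                       m$rho_matrix, m$rho_fluid, m$q)
  structure(list(model = model,
                 branches = lapply(obj$branches, function(b)
                   list(label = b$label, f = as.numeric(b$f),
                        k = as.numeric(b$k))),
                 f_range = as.numeric(obj$f_range),
                 k_range = as.numeric(obj$k_range)),
            class = "dispersion_curves")
}
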