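#' Porosity-parametrized cortical bone plate model
#'
#' A free (traction-free) plate of thickness \code{thickness} whose material
#' is a transversely isotropic bone matrix degraded by porosity. The symmetry
#' axis of the matrix lies along the propagation direction (the long bone
#' axis), so \code{c33} is the axial stiffness and \code{c11} the radial one.
#' Porosity scales every stiffness constant by \code{(1 - porosity)^q} and
#' mixes the mass density linearly with the pore fluid (water).
#'
#' Default matrix constants are typical literature values for human cortical
#' bone; they are configuration, not ground truth, and every one of them can
#' be overridden.
#'
#' @param thickness Cortical thickness Ct.Th in mm (> 0).
#' @param porosity Cortical porosity Ct.Po as a fraction in [0, 1]
#'   (reported in percent elsewhere in the package).
#' @param c11,c13,c33,c55 Matrix elastic constants in GPa (transversely
#'   isotropic; 3 = symmetry axis = propagation axis).
#' @param rho_matrix Matrix mass density, kg/m^3.
#' @param rho_fluid Pore fluid mass density, kg/m^3.
#' @param q Porosity exponent of the stiffness power law (>= 1).
#' @return An object of class \code{plate_model}.
#' @examples
#' pm <- plate_model(thickness = 2.7, porosity = 0.10)
#' effective_properties(pm)
#' @export
plate_model <- function(thickness, porosity,
                        c11 = 26.8, c13 = 15.3, c33 = 35.1, c55 = 7.3,
                        rho_matrix = 1850, rho_fluid = 1000, q = 2) {
  if (!.is_num1(thickness) || thickness <= 0)
    .bdat_stop("thickness must be a positive scalar (mm)", "bdat_domain_error")
  if (!.is_num1(porosity) || porosity < 0 || porosity > 1)
    .bdat_stop("porosity must lie in [0, 1]", "bdat_domain_error")
  cc <- c(c11 = c11, c13 = c13, c33 = c33, c55 = c55)
  if (any(!vapply(cc, .is_num1, logical(1))) || any(cc <= 0))
    .bdat_stop("all stiffness constants must be positive scalars (GPa)",
               "bdat_domain_error")
  if (c11 * c33 - c13^2 <= 0)
    .bdat_stop("matrix stiffness not positive-definite (c11*c33 - c13^2 <= 0)",
               "bdat_model_error")
  if (!.is_num1(rho_matrix) || rho_matrix <= 0 ||
      !.is_num1(rho_fluid) || rho_fluid < 0)
    .bdat_stop("densities must be positive scalars (kg/m^3)", "bdat_domain_error")
  if (!.is_num1(q) || q < 1)
    .bdat_stop("porosity exponent q must be >= 1", "bdat_domain_error")
  structure(list(thickness = thickness, porosity = porosity,
                 c11 = c11, c13 = c13, c33 = c33, c55 = c55,
                 rho_matrix = rho_matrix, rho_fluid = rho_fluid, q = q),
            class = "plate_model")
}

#' @export
print.plate_model <- function(x, ...) {
  cat(sprintf("<plate_model> Ct.Th = %.3g mm, Ct.Po = %.3g %%\n",
              x$thickness, 100 * x$porosity))
  cat(sprintf("  matrix c11/c13/c33/c55 = %.3g/%.3g/%.3g/%.3g GPa, rho = %g kg/m^3, q = %g\n",
              x$c11, x$c13, x$c33, x$c55, x$rho_matrix, x$q))
  invisible(x)
}

#' Effective (homogenized) plate properties
#'
#' Applies the power-law stiffness rule c_ij(Po) = c_ij * (1 - Po)^q and the
#' linear density mixing rho(Po) = rho_matrix * (1 - Po) + rho_fluid * Po.
#'
#' @param model A \code{plate_model}.
#' @return List with effective constants \code{c11, c13, c33, c55} (GPa),
#'   density \code{rho} (kg/m^3) and the scale factor \code{stiffness_scale}.
#' @export
effective_properties <- function(model) {
  stopifnot(inherits(model, "plate_model"))
  s <- (1 - model$porosity)^model$q
  eff <- list(c11 = model$c11 * s, c13 = model$c13 * s,
              c33 = model$c33 * s, c55 = model$c55 * s,
              rho = model$rho_matrix * (1 - model$porosity) +
                model$rho_fluid * model$porosity,
              stiffness_scale = s)
  if (model$porosity < 1 &&
      (eff$c11 * eff$c33 - eff$c13^2 <= 0 || eff$c55 <= 0))
    .bdat_stop("effective stiffness not positive-definite", "bdat_model_error")
  eff
}
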