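# internal helpers shared across modules

.bdatr_cache <- new.env(parent = emptyenv())

#' Evaluate an expression under a fixed RNG seed
#' @noRd
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

#' Stop with a classed condition
#' @noRd
.bdat_stop <- function(msg, class) {
  stop(structure(class = c(class, "bdat_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

.is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Linear interpolation that refuses extrapolation
#' @noRd
.interp <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 1, ties = "ordered")$y
}
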