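# Nonparametric tests, correlations, ROC/AUC and logistic odds ratios used
# by the fracture-discrimination analyses.

#' Wilcoxon-Mann-Whitney test
#'
#' Exact two-sided p by full enumeration of group assignments when the
#' smaller sample has at most 8 observations (ties handled by mid-ranks);
#' otherwise the normal approximation with tie correction.
#'
#' @param a,b Numeric samples.
#' @return List with \code{statistic} (U for sample \code{a}),
#'   \code{p.value}, \code{method}, \code{degenerate} (all values tied).
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    .bdat_stop("both samples must be non-empty", "bdat_usage_error")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1L)
    return(list(statistic = U, p.value = 1, method = "degenerate",
                degenerate = TRUE))
  if (min(n1, n2) <= 8 && choose(n1 + n2, n1) <= 5e5) {
    idx <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    lo <- min(U, n1 * n2 - U)
    hi <- max(U, n1 * n2 - U)
    p <- (sum(Us <= lo + 1e-9) + sum(Us >= hi - 1e-9)) / ncol(idx)
    return(list(statistic = U, p.value = min(1, p),
                method = "exact enumeration", degenerate = FALSE))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  list(statistic = U, p.value = wt$p.value,
       method = "normal approximation, tie-corrected", degenerate = FALSE)
}

#' Spearman rank correlation with p-value
#'
#' Mid-rank rho via \code{stats::cor}; p by full permutation enumeration for
#' n <= 7, otherwise the t approximation
#' t = R sqrt((n-2)/(1-R^2)).
#'
#' @param x,y Paired numeric vectors (pairs with NA are dropped).
#' @return List with \code{estimate} (R), \code{p.value}, \code{n},
#'   \code{method}; \code{estimate} is NA with a flag if either rank vector
#'   is constant.
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) .bdat_stop("need at least 3 complete pairs", "bdat_usage_error")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(estimate = NA_real_, p.value = NA_real_, n = n,
                method = "undefined: zero rank variance"))
  R <- stats::cor(x, y, method = "spearman")
  if (n <= 7) {
    rx <- rank(x); ry <- rank(y)
    perms <- .permutations(n)
    Rs <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(Rs) >= abs(R) - 1e-12)
    return(list(estimate = R, p.value = p, n = n,
                method = "exact enumeration"))
  }
  tstat <- R * sqrt((n - 2) / max(1 - R^2, 1e-12))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(estimate = R, p.value = p, n = n, method = "t approximation")
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' ROC area under the curve with bootstrap confidence interval
#'
#' AUC is the Mann-Whitney (rank) estimator, ties counting one half. The
#' confidence interval is a seeded stratified bootstrap percentile interval.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Binary labels (0/1 or logical).
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return List with \code{auc}, \code{ci} (length 2), \code{se},
#'   \code{n_pos}, \code{n_neg}.
#' @export
roc_auc <- function(scores, labels, n_boot = 2000, conf = 0.95, seed = 1) {
  labels <- as.integer(as.logical(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    .bdat_stop("both classes must be present", "bdat_usage_error")
  auc_of <- function(s, l) {
    r <- rank(s)
    (sum(r[l == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  est <- auc_of(scores, labels)
  ipos <- which(labels == 1); ineg <- which(labels == 0)
  boots <- .with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- c(sample(ipos, n1, replace = TRUE), sample(ineg, n0, replace = TRUE))
    s <- scores[i]; l <- labels[i]
    r <- rank(s)
    (sum(r[l == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  list(auc = est,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       se = stats::sd(boots), n_pos = n1, n_neg = n0)
}

# build the binary outcome of a discrimination analysis: cases = the given
# fracture group(s), controls = NF
.outcome_mask <- function(cohort, outcome = c("F", "VF", "NVF")) {
  outcome <- match.arg(outcome)
  case_groups <- switch(outcome, F = c("VF", "NVF"), VF = "VF", NVF = "NVF")
  sel <- cohort$group %in% c("NF", case_groups)
  y <- as.integer(cohort$group[sel] %in% case_groups)
  list(sel = sel, y = y)
}

#' Logistic odds ratio per SD decrease, optionally covariate-adjusted
#'
#' Maximum-likelihood logistic regression (IRLS via \code{stats::glm},
#' convergence 1e-8) of the fracture outcome on the standardized parameter
#' plus covariates. The odds ratio is reported per one standard deviation
#' decrease of the parameter (so OR > 1 means risk increases as the
#' parameter decreases when the raw coefficient is negative), with a Wald
#' 95 percent interval, and the model AUC from the fitted probabilities.
#'
#' @param cohort A \code{cohort_table}.
#' @param parameter Column name of the parameter of interest.
#' @param outcome \code{"F"}, \code{"VF"} or \code{"NVF"} (cases vs NF).
#' @param covariates Covariate column names (\code{"sex"} enters as 0/1).
#' @param conf Confidence level for the Wald interval.
#' @return Class \code{logistic_result}: \code{or_per_sd_decrease},
#'   \code{ci}, \code{auc}, \code{p.value}, \code{separation} flag,
#'   \code{n}, \code{fit}.
#' @export
logistic_or <- function(cohort, parameter, outcome = "F",
                        covariates = c("age", "sex", "bmi"), conf = 0.95) {
  stopifnot(inherits(cohort, "cohort_table"))
  om <- .outcome_mask(cohort, outcome)
  df <- as.data.frame(cohort)[om$sel, , drop = FALSE]
  df$.y <- om$y
  use <- c(parameter, covariates)
  if ("sex" %in% use) df$sex <- as.integer(df$sex == "male")
  df <- df[stats::complete.cases(df[, c(".y", use)]), , drop = FALSE]
  if (sum(df$.y == 1) < 5 || sum(df$.y == 0) < 5)
    .bdat_stop("need at least 5 cases and 5 controls", "bdat_usage_error")
  sdp <- stats::sd(df[[parameter]])
  df$.x <- (df[[parameter]] - mean(df[[parameter]])) / sdp
  form <- stats::as.formula(paste(".y ~ .x",
                                  if (length(covariates))
                                    paste("+", paste(covariates, collapse = " + "))
                                  else ""))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)[".x"]
  se <- sqrt(stats::vcov(fit)[".x", ".x"])
  if (abs(beta) > 15) sep <- TRUE
  z <- stats::qnorm(1 - (1 - conf) / 2)
  # per SD *decrease*: flip the sign of the coefficient
  or_ <- exp(-beta)
  ci <- sort(exp(-c(beta - z * se, beta + z * se)))
  p <- 2 * stats::pnorm(-abs(beta / se))
  auc <- roc_auc(stats::fitted(fit), df$.y, n_boot = 200, seed = 1)$auc
  structure(list(parameter = parameter, covariates = covariates,
                 outcome = outcome, or_per_sd_decrease = unname(or_),
                 ci = unname(ci), p.value = unname(p), auc = auc,
                 separation = sep, n = nrow(df), fit = fit),
            class = "logistic_result")
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("<logistic_result> %s vs NF (%s): OR/SD-decrease = %.2f [%.2f-%.2f]%s, AUC = %.2f, n = %d\n",
              x$outcome, x$parameter, x$or_per_sd_decrease, x$ci[1], x$ci[2],
              if (x$separation) " (separation: unstable)" else "",
              x$auc, x$n))
  invisible(x)
}

#' Univariate variable screening
#'
#' Two-sided Wilcoxon-Mann-Whitney p per numeric candidate (fractured group
#' vs NF); gender is screened with Fisher's exact test. Variables with
#' p < alpha are selected. Deterministic.
#'
#' @param cohort A \code{cohort_table}.
#' @param outcome \code{"F"}, \code{"VF"} or \code{"NVF"}.
#' @param alpha Selection level (0.05 and 0.01 are the two reported tiers).
#' @param candidates Candidate columns; default: every numeric cohort
#'   variable present plus sex.
#' @return data.frame with variable, p, selected; attribute
#'   \code{"selected"} carries the selected names.
#' @export
select_variables <- function(cohort, outcome = "F", alpha = 0.05,
                             candidates = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  om <- .outcome_mask(cohort, outcome)
  df <- as.data.frame(cohort)[om$sel, , drop = FALSE]
  y <- om$y
  if (is.null(candidates)) {
    candidates <- intersect(.cohort_numeric_vars, names(df))
    candidates <- candidates[vapply(candidates, function(v)
      sum(!is.na(df[[v]])) > 0 && stats::var(df[[v]], na.rm = TRUE) > 0,
      logical(1))]
    if ("sex" %in% names(df)) candidates <- c(candidates, "sex")
  }
  ps <- vapply(candidates, function(v) {
    if (v == "sex") {
      tab <- table(factor(df$sex, levels = c("female", "male")), y)
      if (any(dim(tab) < 2) || any(rowSums(tab) == 0)) return(NA_real_)
      return(stats::fisher.test(tab)$p.value)
    }
    x <- df[[v]]
    a <- x[y == 0]; b <- x[y == 1]
    if (all(is.na(a)) || all(is.na(b))) return(NA_real_)
    mann_whitney(a, b)$p.value
  }, numeric(1))
  out <- data.frame(variable = candidates, p = unname(ps),
                    selected = !is.na(ps) & ps < alpha)
  attr(out, "selected") <- out$variable[out$selected]
  out
}
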