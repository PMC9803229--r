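# Partial least squares (NIPALS, single response) and the leave-one-out
# cross-validated discrimination analyses built on it. Standardization is
# always refitted inside the training data of each fold (no leakage).

#' Fit a PLS1 regression (NIPALS)
#'
#' Columns of X are centered and scaled internally (zero-variance columns are
#' dropped with a warning), y is centered. Score vectors are mutually
#' orthogonal by construction; the regression vector is returned in the
#' original units.
#'
#' @param X Numeric matrix (observations x variables).
#' @param y Numeric response.
#' @param n_latent Number of latent variables (<= ncol(X)).
#' @return Class \code{pls_fit}: weights \code{W}, loadings \code{P},
#'   scores \code{TT}, \code{q}, \code{coefficients} (original units, with
#'   intercept), bookkeeping for prediction.
#' @export
pls_fit <- function(X, y, n_latent = 2) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) .bdat_stop("nrow(X) != length(y)", "bdat_usage_error")
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  if (!ncol(X)) .bdat_stop("no usable predictor columns", "bdat_usage_error")
  n_latent <- min(n_latent, ncol(X), nrow(X) - 1L)
  mx <- colMeans(X)
  Xs <- sweep(sweep(X, 2, mx), 2, sds, "/")
  my <- mean(y)
  yr <- y - my
  p <- ncol(Xs)
  W <- P <- matrix(0, p, n_latent)
  TT <- matrix(0, nrow(Xs), n_latent)
  q <- numeric(n_latent)
  Xr <- Xs
  for (a in seq_len(n_latent)) {
    w <- crossprod(Xr, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { n_latent <- a - 1L; break }
    w <- w / nw
    tt <- Xr %*% w
    t2 <- sum(tt^2)
    pp <- crossprod(Xr, tt) / t2
    qq <- sum(yr * tt) / t2
    W[, a] <- w; P[, a] <- pp; TT[, a] <- tt; q[a] <- qq
    Xr <- Xr - tt %*% t(pp)
    yr <- yr - qq * tt
  }
  if (n_latent == 0L) .bdat_stop("response orthogonal to predictors", "bdat_model_error")
  W <- W[, seq_len(n_latent), drop = FALSE]
  P <- P[, seq_len(n_latent), drop = FALSE]
  TT <- TT[, seq_len(n_latent), drop = FALSE]
  q <- q[seq_len(n_latent)]
  Bstd <- W %*% solve(crossprod(P, W), q)
  b <- as.numeric(Bstd) / sds
  intercept <- my - sum(b * mx)
  structure(list(W = W, P = P, TT = TT, q = q, n_latent = n_latent,
                 x_center = mx, x_scale = sds, y_center = my,
                 coefficients = c(`(Intercept)` = intercept,
                                  stats::setNames(b, colnames(X))),
                 columns = colnames(X)),
            class = "pls_fit")
}

#' @export
predict.pls_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$columns) && !is.null(colnames(X)))
    X <- X[, object$columns, drop = FALSE]
  b <- object$coefficients
  drop(X %*% b[-1] + b[1])
}

# deterministic stratified fold assignment: cycle folds through the
# class-sorted observations
.strat_folds <- function(y, k) {
  f <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    f[i] <- rep_len(seq_len(k), length(i))
  }
  f
}

# inner selection of the latent-variable count by k-fold CV error on the
# training data only
.select_lv <- function(X, y, max_lv, k = 5) {
  p <- ncol(X)
  lvs <- seq_len(min(max_lv, p))
  if (length(lvs) == 1L) return(1L)
  folds <- .strat_folds(y, min(k, length(y)))
  err <- numeric(length(lvs))
  for (fi in unique(folds)) {
    tr <- folds != fi
    if (length(unique(y[tr])) < 2) next
    for (li in seq_along(lvs)) {
      fit <- tryCatch(pls_fit(X[tr, , drop = FALSE], y[tr], lvs[li]),
                      error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) { err[li] <- Inf; next }
      pred <- predict(fit, X[!tr, , drop = FALSE])
      err[li] <- err[li] + sum((y[!tr] - pred)^2)
    }
  }
  lvs[which.min(err)]
}

# 2x2 odds ratio with Woolf (log) confidence interval; Haldane 0.5
# correction when a cell is empty
.table_or <- function(pred_pos, truth, conf = 0.95) {
  a <- sum(pred_pos & truth == 1); b <- sum(pred_pos & truth == 0)
  cc <- sum(!pred_pos & truth == 1); d <- sum(!pred_pos & truth == 0)
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  or_ <- a * d / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or_ = or_, ci = exp(log(or_) + c(-z, z) * se), corrected = corrected)
}

#' PLS discrimination with leave-one-out cross-validation
#'
#' For every left-out patient the predictors are standardized on the
#' remaining patients, the latent-variable count (1..min(4, p)) is chosen by
#' stratified 5-fold error inside the training set, a PLS1 fit on the 0/1
#' outcome produces the out-of-fold score. AUC and its bootstrap CI come
#' from the out-of-fold scores; the operating threshold is Youden-optimal on
#' those scores; the odds ratio is the 2x2 cross-product at that threshold
#' with a Woolf CI.
#'
#' @param cohort A \code{cohort_table}.
#' @param variables Predictor columns (\code{"sex"} enters as 0/1).
#' @param outcome \code{"F"}, \code{"VF"} or \code{"NVF"} (cases vs NF).
#' @param max_lv Maximum latent variables.
#' @param n_boot Bootstrap replicates for the AUC CI.
#' @param seed Integer seed (bootstrap).
#' @return Class \code{discrimination_result} with \code{auc}, \code{auc_ci},
#'   \code{or_}, \code{or_ci}, \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{threshold}, \code{scores}, \code{y},
#'   \code{n_latent}, \code{univariate_p}, \code{degenerate}.
#' @export
pls_loocv_discriminate <- function(cohort, variables, outcome = "F",
                                   max_lv = 4, n_boot = 2000, seed = 1) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!length(variables)) .bdat_stop("no variables given", "bdat_usage_error")
  om <- .outcome_mask(cohort, outcome)
  df <- as.data.frame(cohort)[om$sel, , drop = FALSE]
  df$.y <- om$y
  if ("sex" %in% variables) df$sex <- as.integer(df$sex == "male")
  df <- df[stats::complete.cases(df[, c(".y", variables)]), , drop = FALSE]
  y <- df$.y
  if (sum(y == 1) < 5 || sum(y == 0) < 5)
    .bdat_stop("need at least 5 cases and 5 controls", "bdat_usage_error")
  X <- as.matrix(df[, variables, drop = FALSE])
  n <- nrow(X)
  scores <- rep(NA_real_, n)
  lv_used <- integer(n)
  if (all(apply(X, 2, stats::sd) == 0)) {
    # duplicated identical patients: no usable signal at all
    scores <- rep(0, n)
    lv_used <- rep(NA_integer_, n)
  } else for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    if (length(unique(ytr)) < 2)
      .bdat_stop(sprintf("degenerate fold %d: single-class training set", i),
                 "bdat_model_error")
    lv <- .select_lv(Xtr, ytr, max_lv)
    fit <- pls_fit(Xtr, ytr, lv)
    scores[i] <- predict(fit, X[i, , drop = FALSE])
    lv_used[i] <- fit$n_latent
  }
  degenerate <- stats::sd(scores) < 1e-12
  uni <- vapply(variables, function(v) {
    if (v == "sex") {
      tab <- table(df[[v]], y)
      if (any(dim(tab) < 2)) return(NA_real_)
      return(stats::fisher.test(tab)$p.value)
    }
    mann_whitney(df[[v]][y == 0], df[[v]][y == 1])$p.value
  }, numeric(1))
  if (degenerate) {
    return(structure(list(outcome = outcome, variables = variables,
                          univariate_p = uni, n_latent = NA_integer_,
                          scores = scores, y = y, auc = 0.5,
                          auc_ci = c(NA_real_, NA_real_),
                          or_ = NA_real_, or_ci = c(NA_real_, NA_real_),
                          accuracy = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_, threshold = NA_real_,
                          n = n, degenerate = TRUE),
                     class = "discrimination_result"))
  }
  ra <- roc_auc(scores, y, n_boot = n_boot, seed = seed)
  # Youden-optimal threshold on the out-of-fold scores
  cand <- sort(unique(scores))
  cand <- (c(cand[1] - 1e-9, cand) + c(cand, cand[length(cand)] + 1e-9)) / 2
  youden <- vapply(cand, function(th) {
    sens <- mean(scores[y == 1] > th)
    spec <- mean(scores[y == 0] <= th)
    sens + spec - 1
  }, numeric(1))
  th <- cand[which.max(youden)]
  pred_pos <- scores > th
  sens <- mean(pred_pos[y == 1])
  spec <- mean(!pred_pos[y == 0])
  acc <- mean((pred_pos & y == 1) | (!pred_pos & y == 0))
  tor <- .table_or(pred_pos, y)
  structure(list(outcome = outcome, variables = variables,
                 univariate_p = uni,
                 n_latent = as.integer(stats::median(lv_used)),
                 scores = scores, y = y,
                 auc = ra$auc, auc_ci = ra$ci, auc_se = ra$se,
                 or_ = tor$or_, or_ci = tor$ci, or_corrected = tor$corrected,
                 accuracy = acc, sensitivity = sens, specificity = spec,
                 threshold = th, n = n, degenerate = FALSE),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("<discrimination_result> %s vs NF, %d patients, vars: %s\n",
              x$outcome, x$n, paste(x$variables, collapse = ", ")))
  if (x$degenerate) {
    cat("  degenerate out-of-fold scores; threshold metrics undefined\n")
  } else {
    cat(sprintf("  AUC %.2f [%.2f-%.2f]  OR %.1f [%.1f-%.1f]%s  acc %.2f sens %.2f spec %.2f (LV %d)\n",
                x$auc, x$auc_ci[1], x$auc_ci[2], x$or_, x$or_ci[1], x$or_ci[2],
                if (isTRUE(x$or_corrected)) "*" else "",
                x$accuracy, x$sensitivity, x$specificity, x$n_latent))
  }
  invisible(x)
}

#' PLS regression of aBMD from ultrasound and anthropometric predictors
#'
#' LOOCV PLS1 regression of one DXA aBMD variable on the five ultrasound
#' parameters plus age, sex, height, weight and BMI; reports the R-squared
#' of the out-of-fold predictions.
#'
#' @param cohort A \code{cohort_table}.
#' @param target \code{"abmd_total"}, \code{"abmd_fn"} or \code{"abmd_spine"}.
#' @param predictors Predictor columns.
#' @param max_lv Maximum latent variables.
#' @return List with \code{predictions} (data.frame observed/predicted),
#'   \code{r2}, \code{n}.
#' @export
pls_regress_abmd <- function(cohort,
                             target = c("abmd_fn", "abmd_total", "abmd_spine"),
                             predictors = c("vfas", "va0", "ct_th", "ct_po",
                                            "ratio", "age", "sex", "height",
                                            "weight", "bmi"),
                             max_lv = 4) {
  stopifnot(inherits(cohort, "cohort_table"))
  target <- match.arg(target)
  df <- as.data.frame(cohort)
  if ("sex" %in% predictors) df$sex <- as.integer(df$sex == "male")
  df <- df[stats::complete.cases(df[, c(target, predictors)]), , drop = FALSE]
  y <- df[[target]]
  X <- as.matrix(df[, predictors, drop = FALSE])
  n <- nrow(X)
  if (n < 10) .bdat_stop("too few complete records", "bdat_usage_error")
  pred <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lv <- .select_lv(X[-i, , drop = FALSE],
                     as.integer(y[-i] > stats::median(y[-i])), max_lv)
    fit <- pls_fit(X[-i, , drop = FALSE], y[-i], lv)
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(predictions = data.frame(observed = y, predicted = pred),
       r2 = r2, n = n, target = target)
}

# candidate variable sets per technique
.candidates_bdat <- c("vfas", "va0", "ct_th", "ct_po", "ratio",
                      "age", "height", "weight", "bmi", "sex")
.candidates_dxa <- c("abmd_total", "abmd_fn", "abmd_spine",
                     "age", "height", "weight", "bmi", "sex")

# one report cell: screen candidates at the tier, run PLS-LOOCV on the
# selected set (or mark non-significant)
.report_cell <- function(cohort, candidates, outcome, alpha, n_boot, seed) {
  screen <- tryCatch(select_variables(cohort, outcome, alpha,
                                      candidates = candidates),
                     error = function(e) NULL)
  if (is.null(screen)) return(list(status = "insufficient data"))
  sel <- attr(screen, "selected")
  cell <- list(screen = screen, variables = sel)
  if (length(sel) < 1) {
    cell$status <- "not significant"
    return(cell)
  }
  res <- tryCatch(pls_loocv_discriminate(cohort, sel, outcome,
                                         n_boot = n_boot, seed = seed),
                  error = function(e) NULL)
  if (is.null(res)) {
    cell$status <- "insufficient data"
    return(cell)
  }
  cell$status <- "ok"
  cell$result <- res
  cell$metrics <- list(auc = res$auc, auc_ci = res$auc_ci, or_ = res$or_,
                       or_ci = res$or_ci, accuracy = res$accuracy,
                       sensitivity = res$sensitivity,
                       specificity = res$specificity,
                       n_latent = res$n_latent)
  cell
}

#' Structured fracture-discrimination report
#'
#' Reproduces the layout of the published discrimination table: the
#' ultrasound-only population, and the DXA-matched population analysed with
#' ultrasound, DXA and combined variable sets; outcomes F and NVF (VF is
#' attempted and reported non-significant when no variable passes
#' screening); two screening tiers (p < 0.05, p < 0.01); per cell the
#' univariate p values and the PLS-LOOCV metrics. No multiple-testing
#' adjustment is applied (noted in the footer).
#'
#' @param cohort_bdat Ultrasound-complete population (\code{cohort_table}).
#' @param cohort_matched Population with both techniques available.
#' @param outcomes Outcomes to attempt.
#' @param tiers Screening levels.
#' @param n_boot Bootstrap replicates for AUC CIs.
#' @param seed Integer seed.
#' @return Class \code{table4_report}: nested list populations -> outcomes
#'   -> tiers -> cells.
#' @export
table4_report <- function(cohort_bdat, cohort_matched,
                          outcomes = c("F", "NVF", "VF"),
                          tiers = c(0.05, 0.01), n_boot = 2000, seed = 1) {
  pops <- list(
    bdat_full = list(cohort = cohort_bdat, candidates = .candidates_bdat,
                     label = "BDAT, full population"),
    bdat_matched = list(cohort = cohort_matched, candidates = .candidates_bdat,
                        label = "BDAT, DXA-matched population"),
    dxa_matched = list(cohort = cohort_matched, candidates = .candidates_dxa,
                       label = "DXA, DXA-matched population"),
    combined_matched = list(cohort = cohort_matched,
                            candidates = union(.candidates_bdat, .candidates_dxa),
                            label = "BDAT & DXA, DXA-matched population"))
  report <- list()
  for (pn in names(pops)) {
    pop <- pops[[pn]]
    entry <- list(label = pop$label, n = nrow(pop$cohort),
                  n_nf = sum(pop$cohort$group == "NF"),
                  outcomes = list())
    for (oc in outcomes) {
      tiers_out <- list()
      for (al in tiers) {
        tiers_out[[paste0("p", al)]] <-
          .report_cell(pop$cohort, pop$candidates, oc, al, n_boot, seed)
      }
      entry$outcomes[[oc]] <- tiers_out
    }
    report[[pn]] <- entry
  }
  structure(list(populations = report,
                 footer = "no multiple-testing adjustment applied",
                 seed = seed),
            class = "table4_report")
}

#' @export
print.table4_report <- function(x, ...) {
  cat("<table4_report>\n")
  for (pn in names(x$populations)) {
    pop <- x$populations[[pn]]
    cat(sprintf("%s (n = %d, NF = %d)\n", pop$label, pop$n, pop$n_nf))
    for (oc in names(pop$outcomes)) {
      for (tn in names(pop$outcomes[[oc]])) {
        cell <- pop$outcomes[[oc]][[tn]]
        if (identical(cell$status, "ok")) {
          m <- cell$metrics
          cat(sprintf("  %-3s %-6s AUC %.2f [%.2f-%.2f] OR %5.1f [%5.1f-%5.1f] acc %.2f sens %.2f spec %.2f (%s)\n",
                      oc, tn, m$auc, m$auc_ci[1], m$auc_ci[2],
                      m$or_, m$or_ci[1], m$or_ci[2], m$accuracy,
                      m$sensitivity, m$specificity,
                      paste(cell$variables, collapse = "+")))
        } else {
          cat(sprintf("  %-3s %-6s %s\n", oc, tn, cell$status))
        }
      }
    }
  }
  cat(x$footer, "\n")
  invisible(x)
}

#' Write a discrimination report to JSON
#' @param report A \code{table4_report}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "table4_report"))
  strip <- function(x) {
    if (inherits(x, "discrimination_result")) return(NULL)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  obj <- list(format = "bdat-report-1", report = strip(unclass(report)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
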