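test_that("Mann-Whitney matches enumeration and the standard implementation", {
  expect_equal(mann_whitney(c(5, 5, 5), c(5, 5))$p.value, 1)  # all tied

  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p.value, 0.1)   # 2 of the 20 arrangements are as extreme

  # exact branch agrees with wilcox.test's exact p on untied data
  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(7) + runif(1, -1, 1)
    expect_equal(mann_whitney(a, b)$p.value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # large-sample branch = tie-corrected normal approximation
  set.seed(12)
  a <- round(rnorm(30), 1); b <- round(rnorm(35) + 0.3, 1)
  expect_equal(mann_whitney(a, b)$p.value,
               suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value),
               tolerance = 1e-12)
  # strongly separated samples
  expect_lt(mann_whitney(rnorm(100), rnorm(100) + 5)$p.value, 1e-6)
})

test_that("Spearman correlation handles monotone, tied and degenerate input", {
  expect_equal(spearman(1:10, (1:10)^3)$estimate, 1)
  expect_equal(spearman(1:10, -(1:10))$estimate, -1)
  # tied example equals the mid-rank formula used by stats::cor
  x <- c(1, 2, 2, 3, 4, 5, 5, 6)
  y <- c(2, 1, 3, 3, 5, 4, 6, 6)
  expect_equal(spearman(x, y)$estimate,
               cor(rank(x), rank(y)), tolerance = 1e-12)
  # exact enumeration branch matches the classical exact test on untied data
  set.seed(3)
  xs <- rnorm(6); ys <- rnorm(6)
  expect_equal(spearman(xs, ys)$p.value,
               cor.test(xs, ys, method = "spearman", exact = TRUE)$p.value,
               tolerance = 1e-9)
  expect_true(is.na(spearman(rep(1, 5), 1:5)$estimate))
  expect_error(spearman(1:2, 2:1), class = "bdat_usage_error")
})

test_that("AUC equals the rank estimator, cross-checked against pROC", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1), n_boot = 50)$auc, 1)
  # 4-point hand case: 3 concordant pairs of 4 -> 0.75
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1),
                       n_boot = 50)$auc, 0.75)
  set.seed(4)
  s <- rnorm(300); l <- rbinom(300, 1, 0.4)
  expect_equal(roc_auc(s, l, n_boot = 50)$auc,
               as.numeric(suppressMessages(pROC::auc(l, s, direction = "<"))),
               tolerance = 1e-12)
  # labels independent of scores at n = 1e4: AUC ~ 0.5
  set.seed(5)
  big <- roc_auc(rnorm(1e4), rbinom(1e4, 1, 0.5), n_boot = 50)
  expect_equal(big$auc, 0.5, tolerance = 0.02)
  # CI is a percentile interval around the estimate, reproducible by seed
  r1 <- roc_auc(s, l, n_boot = 200, seed = 9)
  r2 <- roc_auc(s, l, n_boot = 200, seed = 9)
  expect_identical(r1$ci, r2$ci)
  expect_lte(r1$ci[1], r1$auc); expect_gte(r1$ci[2], r1$auc)
  expect_error(roc_auc(1:5, rep(1, 5), n_boot = 10), class = "bdat_usage_error")
})

test_that("logistic odds ratios recover known effects and the 2x2 cross-product", {
  # independent parameter, large n: OR -> 1
  m <- bdatr:::.group_marginals()
  co <- null_cohort(400, seed = 21)
  lr0 <- logistic_or(co, "vfas", "NVF", covariates = character(0))
  expect_equal(lr0$or_per_sd_decrease, 1, tolerance = 0.25)

  # synthetic logistic data with known slope: recovery within 2 SE
  set.seed(22)
  n <- 600
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.8 + 0.9 * x))
  df <- data.frame(id = seq_len(n), age = 70, sex = "female", height = 165,
                   weight = 70, bmi = 25.7,
                   group = ifelse(y == 1, "NVF", "NF"),
                   fracture_site = ifelse(y == 1, "femoral neck", "none"),
                   traumatic = FALSE, us_failed = FALSE, dxa_failed = FALSE,
                   vfas = x, va0 = 1680, ct_th = 2.7, ct_po = 10,
                   ratio = 10 / 2.7, abmd_total = 0.85, abmd_fn = 0.7,
                   abmd_spine = 1)
  co2 <- structure(df, class = c("cohort_table", "data.frame"))
  lr <- logistic_or(co2, "vfas", "NVF", covariates = character(0))
  beta_hat <- -log(lr$or_per_sd_decrease) / sd(x)
  se <- sqrt(vcov(lr$fit)[".x", ".x"]) / sd(x)
  expect_lt(abs(beta_hat - 0.9), 2 * se)

  # binary parameter, no covariates: equals the classical cross-product OR
  set.seed(23)
  xb <- rbinom(n, 1, 0.5)
  yb <- rbinom(n, 1, plogis(-1 + 1.2 * xb))
  dfb <- df
  dfb$vfas <- xb
  dfb$group <- ifelse(yb == 1, "NVF", "NF")
  cob <- structure(dfb, class = c("cohort_table", "data.frame"))
  lrb <- logistic_or(cob, "vfas", "NVF", covariates = character(0))
  tab <- table(xb, yb)
  or_cross <- tab[2, 2] * tab[1, 1] / (tab[1, 2] * tab[2, 1])
  beta_raw <- -log(lrb$or_per_sd_decrease) / sd(xb)
  expect_equal(exp(beta_raw), or_cross, tolerance = 1e-6)
})

test_that("variable screening keeps shifted variables and is monotone in alpha", {
  co <- synthesize_cohort(cohort_spec(n = c(NF = 120, NVF = 40),
                                      failure_rule = FALSE), seed = 31)
  co$height <- 165                       # constant: never selectable
  sv05 <- select_variables(co, "NVF", 0.05)
  sv01 <- select_variables(co, "NVF", 0.01)
  expect_false("height" %in% sv05$variable)
  expect_true(all(attr(sv01, "selected") %in% attr(sv05, "selected")))
  # a strongly shifted variable is selected at both tiers
  co$vfas <- co$vfas - 300 * (co$group == "NVF")
  expect_true("vfas" %in% attr(select_variables(co, "NVF", 0.01), "selected"))
})

test_that("PLS1 equals least squares at full rank and keeps scores orthogonal", {
  set.seed(41)
  X <- matrix(rnorm(40), 40, 1)
  y <- 2 + 3 * X[, 1] + rnorm(40, sd = 0.2)
  f1 <- pls_fit(X, y, 1)
  expect_equal(unname(f1$coefficients), unname(coef(lm(y ~ X))),
               tolerance = 1e-10)

  X3 <- matrix(rnorm(150), 50, 3)
  y3 <- X3 %*% c(1, -2, 0.5) + rnorm(50, sd = 0.1)
  f3 <- pls_fit(X3, y3, 3)
  expect_equal(unname(f3$coefficients), unname(coef(lm(y3 ~ X3))),
               tolerance = 1e-8)
  G <- crossprod(f3$TT)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)

  # small-case oracle: independent SVD/deflation implementation
  pls_oracle <- function(X, y, a) {
    sx <- apply(X, 2, sd); mx <- colMeans(X)
    Xs <- scale(X); ys <- y - mean(y)
    W <- P <- NULL; q <- c()
    for (i in seq_len(a)) {
      w <- svd(crossprod(Xs, ys))$u[, 1] *
        sign(sum(crossprod(Xs, ys) * svd(crossprod(Xs, ys))$u[, 1]))
      tt <- Xs %*% w
      p <- crossprod(Xs, tt) / sum(tt^2)
      qq <- sum(ys * tt) / sum(tt^2)
      Xs <- Xs - tt %*% t(p); ys <- ys - qq * tt
      W <- cbind(W, w); P <- cbind(P, p); q <- c(q, qq)
    }
    b <- (W %*% solve(t(P) %*% W, q)) / sx
    c(mean(y) - sum(b * mx), b)
  }
  set.seed(42)
  X5 <- matrix(rnorm(15), 5, 3)
  y5 <- rnorm(5)
  f2 <- pls_fit(X5, y5, 2)
  expect_equal(unname(f2$coefficients), unname(pls_oracle(X5, y5, 2)),
               tolerance = 1e-6)
  expect_warning(pls_fit(cbind(X5, 0), y5, 2), "zero-variance")
})

test_that("LOOCV discrimination is unbiased under the null and strong when separated", {
  # group labels independent of every variable: the out-of-fold AUC of one
  # n = 200 cohort scatters with SD ~ 0.07, so the +-0.05 null property is
  # checked on the mean over six cohorts
  null_aucs <- vapply(1:6, function(s) {
    co <- null_cohort(100, seed = 50 + s)
    pls_loocv_discriminate(co, c("vfas", "va0", "ct_th", "ct_po"),
                           "NVF", n_boot = 50, seed = 1)$auc
  }, numeric(1))
  expect_lt(abs(mean(null_aucs) - 0.5), 0.05)

  # two-class Gaussians at Mahalanobis separation 3: binormal AUC
  # Phi(3/sqrt(2)) ~ 0.983 -> expect > 0.95 out of fold
  m <- bdatr:::.group_marginals()
  m2 <- m$NF
  m2[["vfas"]] <- m$NF[["vfas"]] - 3 * m$NF[["vfas_sd"]]
  sep <- synthesize_cohort(cohort_spec(n = c(NF = 60, NVF = 60),
                                       marginals = list(NF = m$NF, NVF = m2),
                                       failure_rule = FALSE), seed = 52)
  sep_res <- pls_loocv_discriminate(sep, c("vfas", "va0"), "NVF",
                                    n_boot = 100, seed = 1)
  expect_gt(sep_res$auc, 0.95)
  expect_gt(sep_res$or_, 1)
  expect_lte(sep_res$or_ci[1], sep_res$or_)

  # duplicated identical patients: degenerate scores flagged
  dup <- null_cohort(30, seed = 53)
  m_nf <- bdatr:::.group_marginals()$NF
  for (v in c("vfas", "va0", "ct_th", "ct_po", "age", "height",
              "weight", "bmi", "abmd_total", "abmd_fn", "abmd_spine"))
    dup[[v]] <- m_nf[[v]]
  dup$ratio <- dup$ct_po / dup$ct_th
  dup_res <- pls_loocv_discriminate(dup, c("vfas", "va0"), "NVF",
                                    n_boot = 50, seed = 1)
  expect_true(dup_res$degenerate)
  expect_true(is.na(dup_res$accuracy))
})

test_that("aBMD regression is leakage-free", {
  co <- synthesize_cohort(cohort_spec(n = c(NF = 150), failure_rule = FALSE),
                          seed = 61)
  # leakage control: target smuggled in as a predictor gives R^2 ~ 1
  co$ratio <- co$abmd_fn
  leak <- pls_regress_abmd(co, "abmd_fn")
  expect_gt(leak$r2, 0.99)
  # target independent of all predictors: out-of-fold R^2 stays near zero
  co2 <- synthesize_cohort(cohort_spec(n = c(NF = 400), failure_rule = FALSE),
                           seed = 62)
  co2$abmd_fn <- withr::with_seed(63, rnorm(400, 0.7, 0.13))
  indep <- pls_regress_abmd(co2, "abmd_fn")
  expect_lt(indep$r2, 0.05)
  # calibrated correlations give a moderate predictive R^2
  co3 <- synthesize_cohort(cohort_spec(n = c(NF = 250), failure_rule = FALSE),
                           seed = 64)
  cal <- pls_regress_abmd(co3, "abmd_fn")
  expect_gt(cal$r2, 0.1); expect_lt(cal$r2, 0.5)
})

test_that("univariate screening holds its type-I error rate under the null", {
  hits <- 0; total <- 0
  for (s in 1:200) {
    co <- null_cohort(30, seed = 1000 + s)
    sv <- select_variables(co, "NVF", 0.05)
    hits <- hits + sum(sv$selected)
    total <- total + nrow(sv)
  }
  rate <- 100 * hits / total
  expect_gt(rate, 3); expect_lt(rate, 7)
})

test_that("the discrimination report has the published structure", {
  fx <- fixture_cohort()
  c106 <- apply_exclusions(fx, c("drop_traumatic", "drop_us_failed"))
  c87 <- apply_exclusions(fx, c("drop_traumatic", "drop_us_failed",
                                "drop_dxa_failed"))
  rep <- table4_report(c106, c87, n_boot = 50, seed = 1)
  expect_s3_class(rep, "table4_report")
  expect_equal(names(rep$populations),
               c("bdat_full", "bdat_matched", "dxa_matched", "combined_matched"))
  expect_equal(rep$populations$bdat_full$n, 106)
  expect_equal(rep$populations$bdat_full$n_nf, 79)
  expect_equal(rep$populations$bdat_matched$n, 87)
  expect_equal(rep$populations$bdat_matched$n_nf, 64)
  expect_equal(names(rep$populations$bdat_full$outcomes), c("F", "NVF", "VF"))
  expect_equal(names(rep$populations$bdat_full$outcomes$F), c("p0.05", "p0.01"))
  # every cell carries a status and its screening table
  cell <- rep$populations$bdat_full$outcomes$F$p0.05
  expect_true(cell$status %in% c("ok", "not significant", "insufficient data"))
  expect_s3_class(cell$screen, "data.frame")

  # synthetic cohort: deterministic under a fixed seed, VF null non-significant
  co <- synthesize_cohort(cohort_spec(failure_rule = FALSE), seed = 71)
  r1 <- table4_report(co, co, outcomes = c("NVF", "VF"), n_boot = 50, seed = 2)
  r2 <- table4_report(co, co, outcomes = c("NVF", "VF"), n_boot = 50, seed = 2)
  expect_identical(r1, r2)
  path <- tempfile(fileext = ".json")
  write_report_json(r1, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
  unlink(path)
})
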