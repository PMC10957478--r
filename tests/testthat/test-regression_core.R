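rand_instance <- function(n, k = 2L, n_case = 3L, n_reader = 4L) {
  X <- cbind(1, matrix(rnorm(n * (k - 1L)), n))
  colnames(X) <- c("(Intercept)", paste0("b", seq_len(k - 1L)))
  list(y = rnorm(n), X = X,
       cc = sample(paste0("c", seq_len(n_case)), n, replace = TRUE),
       cr = sample(paste0("r", seq_len(n_reader)), n, replace = TRUE))
}

test_that("fit_ols point estimates equal lm and zero residuals give zero vcov", {
  set.seed(1)
  inst <- rand_instance(20)
  fit <- fit_ols(inst$y, inst$X, inst$cc, inst$cr)
  expect_equal(unname(fit$coef),
               unname(coef(lm(inst$y ~ inst$X[, 2]))), tolerance = 1e-10)
  # exact fit -> covariance exactly zero
  y0 <- as.numeric(inst$X %*% c(1, 2))
  fit0 <- fit_ols(y0, inst$X, inst$cc, inst$cr)
  expect_equal(max(abs(fit0$vcov)), 0)
})

test_that("singleton clusters collapse to the HC0 sandwich", {
  set.seed(2)
  inst <- rand_instance(25)
  ids <- as.character(seq_along(inst$y))
  fit <- fit_ols(inst$y, inst$X, ids, ids)
  e <- inst$y - inst$X %*% solve(crossprod(inst$X), crossprod(inst$X, inst$y))
  A <- solve(crossprod(inst$X))
  hc0 <- A %*% (t(inst$X) %*% diag(as.numeric(e)^2) %*% inst$X) %*% A
  expect_equal(unname(fit$vcov), unname(hc0), tolerance = 1e-10)
})

test_that("two-way covariance matches the brute-force oracle (incl. 6-obs case)", {
  # fixed 6-observation instance: 2 cases x 3 readers
  y <- c(1.2, -0.4, 0.7, 2.1, -1.3, 0.5)
  X <- cbind(`(Intercept)` = 1, x = c(0, 1, 0, 1, 0, 1))
  cc <- c("c1", "c1", "c1", "c2", "c2", "c2")
  cr <- c("r1", "r2", "r3", "r1", "r2", "r3")
  fit <- suppressWarnings(fit_ols(y, X, cc, cr))
  expect_equal(unname(fit$vcov), unname(oracle_crve(y, X, cc, cr)),
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:30) {
    inst <- rand_instance(sample(6:30, 1), n_case = sample(2:6, 1),
                          n_reader = sample(2:6, 1))
    fit <- suppressWarnings(fit_ols(inst$y, inst$X, inst$cc, inst$cr))
    V <- oracle_crve(inst$y, inst$X, inst$cc, inst$cr)
    expect_equal(unname(fit$vcov), unname(V),
                 tolerance = 1e-10 * max(abs(V), 1))
    expect_true(all(diag(fit$vcov) >= -1e-14))
  }
})

test_that("rank deficiency and degenerate clusters are reported", {
  y <- rnorm(10)
  X <- cbind(a = rep(1, 10), b = rep(2, 10))
  expect_error(fit_ols(y, X, 1:10, 1:10), "collinear")
  X2 <- cbind(`(Intercept)` = rep(1, 10), x = rnorm(10))
  expect_warning(fit_ols(y, X2, rep("c", 10), rep(1:5, 2)), "single cluster")
})

test_that("treatment_effect_model recovers mean differences", {
  b <- bundle_from_errors(list(
    r1 = list(u = c(A = 12, B = 12), a = c(C = 9, D = 9)),
    r2 = list(u = c(E = 12, F = 12), a = c(G = 9, H = 9))))
  dt <- hetfx:::read_errors(b, "all", "abs_error")
  fit <- suppressWarnings(treatment_effect_model(dt))
  expect_equal(fit$coef[["(Intercept)"]], 12)
  expect_equal(fit$te, 3)

  # identical conditions -> TE 0; row permutation leaves estimates unchanged
  dt0 <- dt; dt0$error <- 10
  fit0 <- suppressWarnings(treatment_effect_model(dt0))
  expect_equal(fit0$te, 0)
  perm <- dt[sample(nrow(dt)), ]
  fitp <- suppressWarnings(treatment_effect_model(perm))
  expect_equal(fitp$coef, fit$coef)
  expect_error(treatment_effect_model(dt[dt$assisted == 1L, ]),
               "both conditions")
})

test_that("subgroup_te_model is saturated in subgroup means", {
  b <- bundle_from_errors(list(
    g1a = list(u = c(A = 10, B = 10), a = c(C = 8, D = 8)),
    g1b = list(u = c(E = 10, F = 10), a = c(G = 8, H = 8)),
    g2a = list(u = c(I = 20, J = 20), a = c(K = 15, L = 15)),
    g2b = list(u = c(M = 20, N = 20), a = c(O = 15, P = 15))))
  dt <- hetfx:::read_errors(b, "all", "abs_error")
  dt$subgroup <- ifelse(grepl("^g1", dt$radiologist_id), "g1", "g2")
  fit <- suppressWarnings(subgroup_te_model(dt))
  expect_equal(fit$subgroups$te, c(2, 5))
  # identical data in both subgroups -> equal TEs
  dt2 <- dt; dt2$error <- ifelse(dt2$assisted == 1L, 5, 9)
  fit2 <- suppressWarnings(subgroup_te_model(dt2))
  expect_equal(fit2$subgroups$te, c(4, 4))
  # one subgroup collapses to the overall model
  dt$subgroup <- "only"
  fit1 <- suppressWarnings(subgroup_te_model(dt))
  fit_all <- suppressWarnings(treatment_effect_model(dt))
  expect_equal(unname(fit1$subgroups$te), fit_all$te)
  # empty cell is named
  dt3 <- dt
  dt3$subgroup <- ifelse(grepl("^g1", dt3$radiologist_id), "g1", "g2")
  dt3 <- dt3[!(dt3$subgroup == "g2" & dt3$assisted == 1L), ]
  expect_error(subgroup_te_model(dt3), "empty subgroup-condition cell.*g2")
})

test_that("wald_joint_equality: closed form at k=2, extremes behave", {
  V <- diag(c(0.5, 0.2, 0.3))
  dimnames(V) <- list(letters[1:3], letters[1:3])
  fit <- structure(list(coef = c(a = 1, b = 1, c = 1), vcov = V,
                        n_clusters = c(case = 10L, reader = 8L)),
                   class = "fit_result")
  t0 <- wald_joint_equality(fit, c("a", "b", "c"))
  expect_equal(t0$statistic, 0); expect_equal(t0$p_value, 1)

  fit$coef <- c(a = 1, b = 2.5, c = 1)
  t2 <- wald_joint_equality(fit, c("a", "b"))
  expect_equal(t2$statistic, (1 - 2.5)^2 / (0.5 + 0.2))
  expect_equal(t2$p_value, pchisq(t2$statistic, 1, lower.tail = FALSE))

  fit$coef <- c(a = 0, b = 0, c = 10)
  fit$vcov <- diag(1e-6, 3); dimnames(fit$vcov) <- dimnames(V)
  expect_lt(wald_joint_equality(fit, letters[1:3])$p_value, 1e-10)
})

test_that("unpaired t-test matches the textbook pooled formula", {
  a <- c(0.1, -0.1, 0.2, -0.2)
  b <- c(1.1, 0.9, 1.3, 0.7)
  res <- unpaired_t_test(a, b)
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  tman <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(res$statistic, tman)
  expect_equal(res$p_value, 2 * pt(abs(tman), 6, lower.tail = FALSE))
  # antisymmetry
  res2 <- unpaired_t_test(b, a)
  expect_equal(res2$statistic, -res$statistic)
  expect_equal(res2$p_value, res$p_value)
  # identical groups -> p = 1 via degenerate flag
  resd <- unpaired_t_test(c(1, 1), c(1, 1))
  expect_equal(resd$p_value, 1)
  expect_true(resd$degenerate)
  expect_error(unpaired_t_test(1, c(1, 2)), "at least two")
})

test_that("benjamini_hochberg implements the step-up rule", {
  r <- benjamini_hochberg(c(0.01, 0.02, 0.04, 0.5), q = 0.05)
  expect_equal(r$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(benjamini_hochberg(rep(0, 5))$reject, rep(TRUE, 5))
  expect_equal(benjamini_hochberg(rep(1, 5))$reject, rep(FALSE, 5))
  # adjusted p agrees with stats::p.adjust (independent implementation)
  set.seed(4)
  for (i in 1:20) {
    p <- runif(8)
    r <- benjamini_hochberg(p, q = 0.05)
    expect_equal(r$adjusted, p.adjust(p, "BH"))
    expect_equal(r$reject, oracle_bh_reject(p, 0.05))
    # equivalence of the two views of BH
    expect_equal(r$reject, r$adjusted <= 0.05)
  }
})

test_that("auroc_bin_f_test follows the stated SSB/SSW construction", {
  # equal AUROCs -> F = 0, p = 1
  t0 <- auroc_bin_f_test(c(0.8, 0.8), c(0.01, 0.01), c(10, 10))
  expect_equal(t0$statistic, 0); expect_equal(t0$p_value, 1)
  # hand-computed fixture: two groups, equal n, symmetric deviation
  g <- c(0.7, 0.9); se <- c(0.05, 0.05); n <- c(10, 10)
  grand <- 0.8
  ssb <- sum(n * (g - grand)^2)
  ssw <- sum((n - 1) * n * se^2)
  Fman <- (ssb / 1) / (ssw / 18)
  res <- auroc_bin_f_test(g, se, n)
  expect_equal(res$statistic, Fman)
  expect_equal(res$p_value, pf(Fman, 1, 18, lower.tail = FALSE))
  # doubling every se divides F by 4
  res2 <- auroc_bin_f_test(g, 2 * se, n)
  expect_equal(res2$statistic, res$statistic / 4)
  expect_error(auroc_bin_f_test(c(0.7, NA), se, n), "undefined")
  expect_error(auroc_bin_f_test(0.7, 0.1, 10), "at least two")
})
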