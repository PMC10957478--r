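# OLS with two-way (case x reader) cluster-robust covariance and the test
# battery: Wald joint equality, unpaired t, Benjamini-Hochberg, and the
# between/within F-test for binned AUROCs.
#
# The two-way covariance is the inclusion-exclusion combination
#   V = V_case + V_reader - V_(case ^ reader)
# where each term is a one-way cluster sandwich (no small-sample inflation by
# default; config-exposed) and the intersection clusters are the unique
# (case, reader) pairs. Negative eigenvalues arising from the subtraction are
# truncated to zero with a warning.

one_way_meat <- function(X, e, cluster) {
  Xe <- X * e
  # sum X_g'e_g per cluster, then outer products
  S <- rowsum(Xe, group = cluster, reorder = FALSE)
  crossprod(as.matrix(S))
}

#' Ordinary least squares with two-way cluster-robust covariance
#'
#' @param y numeric outcome vector.
#' @param X design matrix (include the intercept column yourself); column
#'   names are kept as coefficient names.
#' @param cluster_case,cluster_reader cluster identifier vectors aligned with
#'   rows of `X`. If one dimension has a single cluster it is dropped with a
#'   warning and the fit falls back to one-way clustering on the other.
#' @param ssc finite-sample cluster adjustment: `"none"` (default) or
#'   `"cr1"`, which inflates each one-way meat by G/(G-1) * (n-1)/(n-k).
#' @return object of class `fit_result` with elements `coef`, `vcov`,
#'   `n_obs`, `n_clusters`, `residual_sd`, `repaired` (TRUE when negative
#'   eigenvalues were truncated).
#' @export
fit_ols <- function(y, X, cluster_case, cluster_reader,
                    ssc = c("none", "cr1")) {
  ssc <- match.arg(ssc)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(y) == nrow(X), length(cluster_case) == nrow(X),
            length(cluster_reader) == nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  e <- as.numeric(y - X %*% beta)
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  n <- nrow(X); k <- ncol(X)

  dims <- list(case = cluster_case, reader = cluster_reader)
  g <- vapply(dims, function(cl) length(unique(cl)), integer(1))
  use <- g > 1L
  if (!any(use)) {
    warning("both cluster dimensions have a single cluster; ",
            "falling back to HC0 per-observation clusters")
    dims <- list(obs = seq_len(n)); use <- TRUE
  } else if (!all(use)) {
    warning(sprintf("cluster dimension '%s' has a single cluster; using one-way clustering",
                    names(dims)[!use]))
    dims <- dims[use]
  }
  adj <- function(G) if (ssc == "cr1") G / (G - 1) * (n - 1) / (n - k) else 1
  meat <- 0
  for (cl in dims) {
    G <- length(unique(cl))
    meat <- meat + adj(G) * one_way_meat(X, e, cl)
  }
  if (length(dims) == 2L) {
    inter <- paste(dims[[1L]], dims[[2L]], sep = "\r")
    Gi <- length(unique(inter))
    meat <- meat - adj(Gi) * one_way_meat(X, e, inter)
  }
  V <- XtXinv %*% meat %*% XtXinv
  V <- (V + t(V)) / 2
  repaired <- FALSE
  ev <- eigen(V, symmetric = TRUE)
  if (any(ev$values < 0)) {
    if (any(ev$values < -1e-10 * max(abs(ev$values), 1e-300))) {
      warning("two-way cluster covariance had negative eigenvalue(s); truncated to zero")
      repaired <- TRUE
    }
    V <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    V <- (V + t(V)) / 2
  }
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(coef = setNames(as.numeric(beta), colnames(X)), vcov = V,
                 n_obs = n,
                 n_clusters = vapply(dims, function(cl)
                   length(unique(cl)), integer(1)),
                 residual_sd = sd(e), residuals = e, repaired = repaired),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  tab <- data.frame(estimate = x$coef, se = se,
                    ci_lo = x$coef - qnorm(0.975) * se,
                    ci_hi = x$coef + qnorm(0.975) * se)
  cat(sprintf("<fit_result> n = %d, clusters: %s\n", x$n_obs,
              paste(sprintf("%s=%d", names(x$n_clusters), x$n_clusters),
                    collapse = ", ")))
  print(round(tab, 4))
  invisible(x)
}

test_result <- function(statistic, distribution, df, p_value, hypothesis,
                        degenerate = FALSE) {
  structure(list(statistic = statistic, distribution = distribution,
                 df = df, p_value = p_value, hypothesis = hypothesis,
                 degenerate = degenerate), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s\n  %s(%s) = %.4g, p = %.4g%s\n",
              x$hypothesis, x$distribution,
              paste(x$df, collapse = ","), x$statistic, x$p_value,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Overall treatment-effect model: error ~ 1 + treatment
#'
#' Intercept estimates the mean unassisted error; the treatment coefficient
#' estimates mean assisted minus mean unassisted error. The reported
#' treatment effect is the negated treatment coefficient (positive =
#' improvement in error). Inference is two-way cluster-robust (case, reader).
#'
#' @param data data.frame/data.table with columns `error`, `assisted` (0/1),
#'   `case_id`, `radiologist_id`.
#' @param ... passed to [fit_ols()].
#' @return a `fit_result` with extra elements `te`, `te_se`, `te_ci`.
#' @export
treatment_effect_model <- function(data, ...) {
  data <- as.data.table(data)
  if (uniqueN(data$assisted) < 2L) {
    stop("treatment_effect_model: both conditions must be present")
  }
  X <- cbind(`(Intercept)` = 1, treatment = as.numeric(data$assisted))
  fit <- fit_ols(data$error, X, data$case_id, data$radiologist_id, ...)
  fit$te <- -fit$coef[["treatment"]]
  fit$te_se <- sqrt(fit$vcov["treatment", "treatment"])
  fit$te_ci <- fit$te + c(-1, 1) * qnorm(0.975) * fit$te_se
  fit
}

#' Subgroup treatment-effect model: error ~ 1 + subgroup + treatment:subgroup
#'
#' A saturated-in-subgroup model: subgroup main effects plus one
#' treatment-by-subgroup interaction per subgroup. Each interaction
#' coefficient is that subgroup's assisted-minus-unassisted mean shift; the
#' per-subgroup treatment effect is its negation (for error metrics).
#'
#' @param data as in [treatment_effect_model()] plus a `subgroup` column.
#' @param ... passed to [fit_ols()].
#' @return a `fit_result` with `subgroups` (a data.table of per-subgroup TE,
#'   se, CI, n reads) and `interaction_names`.
#' @export
subgroup_te_model <- function(data, ...) {
  data <- as.data.table(data)
  if (anyNA(data$subgroup)) stop("subgroup labels contain NA")
  lv <- sort(unique(as.character(data$subgroup)))
  cell <- data[, .N, by = .(subgroup, assisted)]
  full <- CJ(subgroup = lv, assisted = c(0L, 1L))
  missing_cell <- full[!cell, on = c("subgroup", "assisted")]
  if (nrow(missing_cell)) {
    stop(sprintf("empty subgroup-condition cell: subgroup '%s', %s",
                 missing_cell$subgroup[1L],
                 ifelse(missing_cell$assisted[1L] == 1L, "assisted",
                        "unassisted")))
  }
  g <- factor(as.character(data$subgroup), levels = lv)
  X <- cbind(`(Intercept)` = rep(1, nrow(data)))
  if (length(lv) > 1L) {
    for (l in lv[-1L]) X <- cbind(X, as.numeric(g == l))
    colnames(X)[-1L] <- paste0("subgroup:", lv[-1L])
  }
  for (l in lv) X <- cbind(X, as.numeric(g == l & data$assisted == 1L))
  inames <- paste0("treatment:", lv)
  colnames(X)[(ncol(X) - length(lv) + 1L):ncol(X)] <- inames
  fit <- fit_ols(data$error, X, data$case_id, data$radiologist_id, ...)
  te <- -fit$coef[inames]
  se <- sqrt(diag(fit$vcov)[inames])
  fit$subgroups <- data.table(subgroup = lv, te = as.numeric(te),
                              se = as.numeric(se),
                              ci_lo = as.numeric(te - qnorm(0.975) * se),
                              ci_hi = as.numeric(te + qnorm(0.975) * se),
                              n = data[, .N,
                                       by = .(subgroup = as.character(subgroup))][
                                match(lv, subgroup), N])
  fit$interaction_names <- inames
  fit
}

#' Wald test of joint equality among a set of coefficients
#'
#' Chi-square Wald statistic on the (k-1) pairwise-difference restrictions,
#' using the fit's cluster-robust covariance. A t-reference with
#' min(G_case, G_reader) - 1 dof can be requested for k = 2.
#'
#' @param fit a `fit_result`.
#' @param coef_names names of >= 2 coefficients to compare.
#' @param reference `"chisq"` (default) or `"t"` (k = 2 only).
#' @return a `test_result`.
#' @export
wald_joint_equality <- function(fit, coef_names,
                                reference = c("chisq", "t")) {
  reference <- match.arg(reference)
  k <- length(coef_names)
  if (k < 2L) stop("need at least two coefficients")
  b <- fit$coef[coef_names]
  V <- fit$vcov[coef_names, coef_names, drop = FALSE]
  R <- matrix(0, k - 1L, k)
  for (i in seq_len(k - 1L)) { R[i, i] <- 1; R[i, i + 1L] <- -1 }
  d <- as.numeric(R %*% b)
  Vd <- R %*% V %*% t(R)
  if (all(abs(d) < 1e-14)) {
    return(test_result(0, "chisq", k - 1L, 1,
                       "joint equality of coefficients"))
  }
  sol <- tryCatch(solve(Vd, d), error = function(e)
    stop("singular restricted covariance in joint equality test", call. = FALSE))
  stat <- sum(d * sol)
  if (reference == "t") {
    if (k != 2L) stop("t reference only available for two coefficients")
    df <- min(fit$n_clusters) - 1L
    tstat <- d / sqrt(Vd[1, 1])
    return(test_result(as.numeric(tstat), "t", df,
                       2 * pt(abs(tstat), df, lower.tail = FALSE),
                       "equality of two coefficients"))
  }
  test_result(stat, "chisq", k - 1L,
              pchisq(stat, k - 1L, lower.tail = FALSE),
              "joint equality of coefficients")
}

#' Wald test of a single coefficient against zero
#' @param fit a `fit_result`.
#' @param coef_name coefficient to test.
#' @return a `test_result` (chi-square, 1 dof).
#' @export
wald_zero <- function(fit, coef_name) {
  b <- fit$coef[[coef_name]]
  v <- fit$vcov[coef_name, coef_name]
  stat <- b^2 / v
  test_result(stat, "chisq", 1L, pchisq(stat, 1L, lower.tail = FALSE),
              paste0(coef_name, " = 0"))
}

#' Two-sided unpaired t-test
#'
#' Pooled-variance Student test by default (Welch with `var_equal = FALSE`).
#' @param group_a,group_b numeric vectors (n >= 2 each).
#' @param var_equal pool the variances (default TRUE).
#' @return a `test_result`; degenerate flag set when pooled variance is zero.
#' @export
unpaired_t_test <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least two observations")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    same <- mean(group_a) == mean(group_b)
    return(test_result(if (same) 0 else Inf, "t",
                       length(group_a) + length(group_b) - 2L,
                       if (same) 1 else 0,
                       "unpaired t-test (zero pooled variance)",
                       degenerate = TRUE))
  }
  tt <- t.test(group_a, group_b, var.equal = var_equal)
  test_result(unname(tt$statistic), "t", unname(tt$parameter),
              tt$p.value, "two-sided unpaired t-test")
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param p_values numeric p-values in \[0, 1\].
#' @param q target false discovery rate (default 0.05).
#' @return list with `reject` (logical, in input order) and `adjusted`
#'   (BH-adjusted p-values, capped at 1).
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  if (m == 0L) return(list(reject = logical(0), adjusted = numeric(0)))
  o <- order(p_values)
  ps <- p_values[o]
  # step-up: largest j with p_(j) <= j*q/m; reject all smaller ranks
  thresh <- seq_len(m) * q / m
  jmax <- suppressWarnings(max(which(ps <= thresh)))
  reject_sorted <- rep(FALSE, m)
  if (is.finite(jmax)) reject_sorted[seq_len(jmax)] <- TRUE
  adj_sorted <- rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  reject <- adjusted <- rep(NA, m)
  reject[o] <- reject_sorted
  adjusted[o] <- adj_sorted
  list(reject = as.logical(reject), adjusted = as.numeric(adjusted))
}

#' F-test for equality of binned AUROCs
#'
#' One-way ANOVA style F built from group AUROCs, their standard errors and
#' group sizes: SSB = sum n_g (AUROC_g - grand)^2 with the n-weighted grand
#' mean; SSW back-converts each group's se of the mean to a within-group sum
#' of squares, SSW = sum (n_g - 1) n_g se_g^2;
#' F = (SSB/(k-1)) / (SSW/(N-k)).
#'
#' @param group_aurocs,group_ses,group_ns aligned vectors over >= 2 groups.
#' @return a `test_result` (F with k-1 and N-k dof).
#' @export
auroc_bin_f_test <- function(group_aurocs, group_ses, group_ns) {
  k <- length(group_aurocs)
  if (k < 2L) stop("need at least two groups")
  if (anyNA(group_aurocs)) stop("undefined group AUROC")
  if (any(group_ns < 2L)) stop("each group needs n >= 2")
  N <- sum(group_ns)
  grand <- sum(group_ns * group_aurocs) / N
  ssb <- sum(group_ns * (group_aurocs - grand)^2)
  ssw <- sum((group_ns - 1) * group_ns * group_ses^2)
  if (ssw == 0) {
    return(test_result(if (ssb == 0) 0 else Inf, "F", c(k - 1L, N - k),
                       if (ssb == 0) 1 else 0,
                       "equality of binned AUROCs", degenerate = TRUE))
  }
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  test_result(Fstat, "F", c(k - 1L, N - k),
              pf(Fstat, k - 1L, N - k, lower.tail = FALSE),
              "equality of binned AUROCs")
}
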