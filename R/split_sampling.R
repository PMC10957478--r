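# Split-sampling regression designs and attenuation-bias correction.
#
# Regressing a change score (treatment effect) on a baseline computed from
# the same noisy reads manufactures a spurious positive slope (reversion to
# the mean). The split designs compute the dependent variable from a held-out
# case and the independent variable from the *other* unassisted cases, so no
# read's noise enters both sides. The remaining downward bias from measuring
# the baseline with error (attenuation) is corrected by dividing the slope
# and its standard error by the estimated reliability ratio lambda.
#
# Design rows (one per held-out case i and reader r):
#   te, non-repeated:       y = u_i - mean(a),  x = leave-one-out mean(u)
#   te, repeated:           y = u_i - a_i,      x = leave-one-out mean(u)
#   assisted, non-repeated: y = a_i,            x = full mean(u)  (disjoint)
#   assisted, repeated:     y = a_i,            x = leave-one-out mean(u)
#   naive (diagnostic):     y as te,            x = full mean(u) incl. case i

# per-reader unassisted/assisted error tables (clinical history pooled; for
# the repeated design the per-case error is the mean over history conditions)
reader_error_tables <- function(bundle, scope = "all") {
  dt <- read_errors(bundle, scope, "abs_error")
  u <- dt[assisted == 0L, .(u = mean(error)),
          by = .(radiologist_id, design, case_id)]
  a <- dt[assisted == 1L, .(a = mean(error)),
          by = .(radiologist_id, design, case_id)]
  list(u = u, a = a)
}

loo_mean <- function(x) (sum(x) - x) / (length(x) - 1)

#' Build the split-sampling treatment-effect design
#'
#' @param bundle a `study_bundle`.
#' @param scope `"all"` or a vector of pathology labels.
#' @param designs which reader designs to include (both by default; their
#'   rows are concatenated for one pooled regression).
#' @return data.table of `SplitDesignRow`s: radiologist_id,
#'   held_out_case_id, design_kind, y, x, N_u. Readers with fewer than two
#'   unassisted cases are skipped with a message; repeated-design rows
#'   lacking the paired assisted read are skipped.
#' @export
build_te_design <- function(bundle, scope = "all",
                            designs = c("non_repeated", "repeated")) {
  tabs <- reader_error_tables(bundle, scope)
  out <- list()
  if ("non_repeated" %in% designs &&
      nrow(tabs$u[design == "non_repeated"])) {
    u <- tabs$u[design == "non_repeated"]
    abar <- tabs$a[design == "non_repeated",
                   .(abar = mean(a), Na = .N), by = radiologist_id]
    u <- merge(u, abar, by = "radiologist_id")
    skip <- u[, .N, by = radiologist_id][N < 2L]
    if (nrow(skip)) {
      message(sprintf("build_te_design: skipping %d non-repeated reader(s) with N_u < 2",
                      nrow(skip)))
      u <- u[!skip$radiologist_id, on = "radiologist_id"]
    }
    out$nr <- u[, .(held_out_case_id = case_id,
                    design_kind = "te_nonrepeated",
                    y = u - abar, x = loo_mean(u), N_u = .N),
                by = radiologist_id]
  }
  if ("repeated" %in% designs && nrow(tabs$u[design == "repeated"])) {
    u <- tabs$u[design == "repeated"]
    a <- tabs$a[design == "repeated"]
    # leave-one-out x uses ALL unassisted cases other than i, even if some
    # lack the paired assisted read that would let them contribute a y
    ustat <- u[, .(u_sum = sum(u), N_u = .N), by = radiologist_id]
    m <- merge(u, a[, .(radiologist_id, case_id, a)],
               by = c("radiologist_id", "case_id"))
    n_drop <- nrow(u) - nrow(m)
    if (n_drop > 0) {
      message(sprintf("build_te_design: %d repeated-design row(s) lack a paired assisted read",
                      n_drop))
    }
    m <- merge(m, ustat, by = "radiologist_id")
    skip <- m[N_u < 2L, unique(radiologist_id)]
    if (length(skip)) {
      message(sprintf("build_te_design: skipping %d repeated reader(s) with N_u < 2",
                      length(skip)))
      m <- m[!skip, on = "radiologist_id"]
    }
    out$rp <- m[, .(radiologist_id, held_out_case_id = case_id,
                    design_kind = "te_repeated",
                    y = u - a, x = (u_sum - u) / (N_u - 1L), N_u)]
  }
  rbindlist(out, use.names = TRUE)[]
}

#' Build the split-sampling assisted-error design
#'
#' One row per assisted case: y is the assisted error; x is the reader's
#' full unassisted mean in the non-repeated design (case sets already
#' disjoint) or the leave-one-out unassisted mean in the repeated design.
#' @inheritParams build_te_design
#' @return data.table of `SplitDesignRow`s.
#' @export
build_assisted_design <- function(bundle, scope = "all",
                                  designs = c("non_repeated", "repeated")) {
  tabs <- reader_error_tables(bundle, scope)
  out <- list()
  if ("non_repeated" %in% designs &&
      nrow(tabs$u[design == "non_repeated"])) {
    xr <- tabs$u[design == "non_repeated",
                 .(x = mean(u), N_u = .N), by = radiologist_id][N_u >= 2L]
    a <- merge(tabs$a[design == "non_repeated"], xr, by = "radiologist_id")
    out$nr <- a[, .(radiologist_id, held_out_case_id = case_id,
                    design_kind = "assisted_nonrepeated", y = a, x, N_u)]
  }
  if ("repeated" %in% designs && nrow(tabs$u[design == "repeated"])) {
    u <- tabs$u[design == "repeated"]
    m <- merge(u, tabs$a[design == "repeated", .(radiologist_id, case_id, a)],
               by = c("radiologist_id", "case_id"))
    skip <- m[, .N, by = radiologist_id][N < 2L]
    if (nrow(skip)) m <- m[!skip$radiologist_id, on = "radiologist_id"]
    out$rp <- m[, .(held_out_case_id = case_id,
                    design_kind = "assisted_repeated",
                    y = a, x = loo_mean(u), N_u = .N),
                by = radiologist_id]
  }
  rbindlist(out, use.names = TRUE)[]
}

#' Build the deliberately biased naive design (diagnostic)
#'
#' Same dependent variable as [build_te_design()], but the independent
#' variable is the full-sample mean unassisted error including the held-out
#' case — the construction that manufactures reversion-to-the-mean bias.
#' An aggregated per-reader variant (mean y on mean x, one row per reader)
#' is returned with `aggregate = TRUE`.
#'
#' @inheritParams build_te_design
#' @param aggregate collapse to one row per reader.
#' @return data.table of `SplitDesignRow`s with design_kind `"naive_te"`.
#' @export
build_naive_design <- function(bundle, scope = "all",
                               designs = c("non_repeated", "repeated"),
                               aggregate = FALSE) {
  tabs <- reader_error_tables(bundle, scope)
  out <- list()
  if ("non_repeated" %in% designs &&
      nrow(tabs$u[design == "non_repeated"])) {
    u <- tabs$u[design == "non_repeated"]
    abar <- tabs$a[design == "non_repeated", .(abar = mean(a)),
                   by = radiologist_id]
    u <- merge(u, abar, by = "radiologist_id")
    u <- u[, if (.N >= 2L) .SD, by = radiologist_id]
    out$nr <- u[, .(held_out_case_id = case_id, design_kind = "naive_te",
                    y = u - abar, x = mean(u), N_u = .N),
                by = radiologist_id]
  }
  if ("repeated" %in% designs && nrow(tabs$u[design == "repeated"])) {
    u <- tabs$u[design == "repeated"]
    m <- merge(u, tabs$a[design == "repeated", .(radiologist_id, case_id, a)],
               by = c("radiologist_id", "case_id"))
    m <- m[, if (.N >= 2L) .SD, by = radiologist_id]
    out$rp <- m[, .(held_out_case_id = case_id, design_kind = "naive_te",
                    y = u - a, x = mean(u), N_u = .N),
                by = radiologist_id]
  }
  res <- rbindlist(out, use.names = TRUE)
  if (aggregate) {
    res <- res[, .(held_out_case_id = NA_character_,
                   design_kind = "naive_te_aggregated",
                   y = mean(y), x = x[1L], N_u = N_u[1L]),
               by = radiologist_id]
  }
  res[]
}

#' Estimate the reliability ratio lambda of reader mean unassisted error
#'
#' lambda = (Var(x~) - E[eta^2]) / Var(x~) where Var(x~) is the population
#' variance of the observed reader means and E[eta^2] is estimated by the
#' mean squared standard error of those means.
#'
#' @param values observed per-reader mean unassisted errors.
#' @param ses their standard errors of the mean.
#' @return list with `lambda_hat`, `eta_sq_hat`, `xvar_hat`. Errors out
#'   (non-identifiable) when the estimate is <= 0: measurement noise swamps
#'   the between-reader signal.
#' @export
estimate_lambda <- function(values, ses) {
  ok <- is.finite(values) & is.finite(ses)
  if (sum(ok) < 2L) stop("estimate_lambda: need at least 2 readers")
  v <- values[ok]; s <- ses[ok]
  xvar <- mean((v - mean(v))^2)
  eta_sq <- mean(s^2)
  lam <- (xvar - eta_sq) / xvar
  if (!is.finite(lam) || lam <= 0) {
    stop(sprintf(paste0("non-identifiable reliability: Var(x~) = %.4g <= ",
                        "E[eta^2] = %.4g (measurement noise swamps signal)"),
                 xvar, eta_sq), call. = FALSE)
  }
  list(lambda_hat = lam, eta_sq_hat = eta_sq, xvar_hat = xvar)
}

#' Correct a split-design slope for attenuation bias
#'
#' beta_hat = gamma_hat / lambda_hat and se(beta_hat) = se(gamma_hat) /
#' lambda_hat; the intercept is left unadjusted.
#'
#' @param fit a `fit_result` from a split design with a coefficient named
#'   `x` (the slope on the unassisted baseline).
#' @param lambda_hat reliability ratio in (0, 1\].
#' @param slope_name name of the slope coefficient (default `"x"`).
#' @return object of class `attenuation_estimate` with gamma_hat,
#'   se_gamma, lambda_hat, beta_hat, se_beta, and the slope's zero test
#'   before and after adjustment.
#' @export
attenuation_adjust <- function(fit, lambda_hat, slope_name = "x") {
  if (!is.numeric(lambda_hat) || lambda_hat <= 0 || lambda_hat > 1) {
    stop("lambda_hat must lie in (0, 1]")
  }
  gam <- fit$coef[[slope_name]]
  se_gam <- sqrt(fit$vcov[slope_name, slope_name])
  beta <- gam / lambda_hat
  se_beta <- se_gam / lambda_hat
  z <- if (se_beta > 0) beta / se_beta else NA_real_
  structure(list(gamma_hat = gam, se_gamma = se_gam,
                 lambda_hat = lambda_hat,
                 beta_hat = beta, se_beta = se_beta,
                 ci = beta + c(-1, 1) * qnorm(0.975) * se_beta,
                 p_value = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
                 fit = fit), class = "attenuation_estimate")
}

#' @export
print.attenuation_estimate <- function(x, ...) {
  cat(sprintf("<attenuation_estimate> gamma = %.4g (se %.4g), lambda = %.4g\n",
              x$gamma_hat, x$se_gamma, x$lambda_hat))
  cat(sprintf("  beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$beta_hat, x$se_beta, x$ci[1], x$ci[2], x$p_value))
  invisible(x)
}

#' Split-sampling regression of treatment effect (or assisted error) on
#' unassisted baseline, with attenuation correction
#'
#' Builds the requested design, fits `y ~ 1 + x` with two-way cluster-robust
#' covariance (held-out case, reader), estimates lambda from the same reader
#' set's unassisted summaries scope-by-scope, and divides the slope and its
#' se by lambda.
#'
#' @param bundle a `study_bundle`.
#' @param outcome `"te"`, `"assisted"`, or `"naive"` (diagnostic).
#' @param scope `"all"` or pathology labels.
#' @param adjust apply the attenuation correction (default TRUE).
#' @param ... passed to [fit_ols()].
#' @return an `attenuation_estimate` (or a `fit_result` when
#'   `adjust = FALSE`).
#' @export
split_regression <- function(bundle, outcome = c("te", "assisted", "naive"),
                             scope = "all", adjust = TRUE, ...) {
  outcome <- match.arg(outcome)
  rows <- switch(outcome,
                 te = build_te_design(bundle, scope),
                 assisted = build_assisted_design(bundle, scope),
                 naive = build_naive_design(bundle, scope))
  if (nrow(rows) == 0L) stop("split_regression: empty design")
  X <- cbind(`(Intercept)` = 1, x = rows$x)
  fit <- fit_ols(rows$y, X, rows$held_out_case_id, rows$radiologist_id, ...)
  fit$design_rows <- rows
  if (!adjust) return(fit)
  # Reliability of the actual regressor column: xvar is the variance of the
  # x values entering the fit; the measurement-noise term is each row's
  # squared standard error of its own x (a mean over N_u - 1 cases for
  # leave-one-out kinds, N_u otherwise).
  u_tab <- reader_error_tables(bundle, scope)$u
  loo_kinds <- c("te_nonrepeated", "te_repeated", "assisted_repeated")
  sd_tab <- u_tab[, .(sd_u = sd(u), N_cases = .N), by = radiologist_id]
  rr <- merge(rows, sd_tab, by = "radiologist_id")
  rr[, se_x := sd_u / sqrt(ifelse(design_kind %in% loo_kinds,
                                  pmax(N_cases - 1L, 1L), N_cases))]
  lam <- estimate_lambda(rr$x, rr$se_x)
  out <- attenuation_adjust(fit, lam$lambda_hat)
  out$eta_sq_hat <- lam$eta_sq_hat
  out$xvar_hat <- lam$xvar_hat
  out
}

#' Split-half AUROC regression (aggregate-metric interpretation)
#'
#' AUROC is an aggregate over cases, so the leave-one-case-out split is not
#' defined at the case level. Interpretation used here: each reader's
#' unassisted cases are split into two disjoint halves (seeded); the
#' baseline x is the unassisted AUROC on half A and the outcome is either
#' the treatment effect (assisted AUROC on all assisted cases minus
#' unassisted AUROC on half B) or the assisted AUROC. One row per reader;
#' clustering is one-way by reader. Readers with an undefined AUROC on
#' either piece are dropped with a message.
#'
#' @param bundle a `study_bundle`.
#' @param outcome `"te"` or `"assisted"`.
#' @param scope `"all"` or pathology labels.
#' @param seed seed for the half split.
#' @param ... passed to [fit_ols()].
#' @return a `fit_result` with `design_rows` attached.
#' @export
split_auroc_regression <- function(bundle, outcome = c("te", "assisted"),
                                   scope = "all", seed = 1L, ...) {
  outcome <- match.arg(outcome)
  dt <- read_errors(bundle, scope, "abs_error")
  set.seed(seed)
  rows <- dt[, {
    ucases <- unique(case_id[assisted == 0L])
    if (length(ucases) >= 4L) {
      half_a <- sample(ucases, floor(length(ucases) / 2))
      ua <- .SD[assisted == 0L & case_id %in% half_a]
      ub <- .SD[assisted == 0L & !case_id %in% half_a]
      as_ <- .SD[assisted == 1L]
      x <- tryCatch(auroc(ua$predicted_prob, ua$truth_label),
                    error = function(e) NA_real_)
      auc_b <- tryCatch(auroc(ub$predicted_prob, ub$truth_label),
                        error = function(e) NA_real_)
      auc_as <- tryCatch(auroc(as_$predicted_prob, as_$truth_label),
                         error = function(e) NA_real_)
      y <- if (outcome == "te") auc_as - auc_b else auc_as
      .(x = x, y = y)
    }
  }, by = radiologist_id]
  n_bad <- sum(!complete.cases(rows))
  if (n_bad) {
    message(sprintf("split_auroc_regression: dropping %d reader(s) with undefined AUROC",
                    n_bad))
    rows <- rows[complete.cases(rows)]
  }
  if (nrow(rows) < 3L) stop("split_auroc_regression: too few readers")
  X <- cbind(`(Intercept)` = 1, x = rows$x)
  fit <- fit_ols(rows$y, X, rows$radiologist_id, rows$radiologist_id, ...)
  fit$design_rows <- rows
  fit
}
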