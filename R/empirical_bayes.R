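# Normal-normal empirical Bayes shrinkage of per-reader summaries.
#
# Each reader contributes a raw mean mu_r with standard error sigma_r. The
# prior mean is the grand mean of the raw values; the prior variance is the
# method-of-moments plug-in: population variance of the raw values minus the
# mean squared standard error (clipped at zero with a loud flag). The
# posterior for each reader is the conjugate normal-normal update; posterior
# means are the de-noised heterogeneity estimates.

#' Estimate the normal prior from reader summaries
#'
#' @param values raw per-reader means.
#' @param ses their standard errors of the mean.
#' @param variance `"population"` (divide by n; default, matching the
#'   method-of-moments derivation) or `"sample"` (n - 1).
#' @return list with `mu0`, `sigma0_sq`, `clipped` (TRUE when the plug-in
#'   estimate was negative and clipped to 0) and `sigma0_sq_raw` (the
#'   unclipped plug-in, useful for unbiased recovery checks).
#' @export
estimate_prior <- function(values, ses,
                           variance = c("population", "sample")) {
  variance <- match.arg(variance)
  ok <- is.finite(values) & is.finite(ses)
  if (sum(ok) < 2L) stop("estimate_prior: need at least 2 readers with finite se")
  v <- values[ok]; s <- ses[ok]
  mu0 <- mean(v)
  raw_var <- if (variance == "population") mean((v - mu0)^2) else var(v)
  s0 <- raw_var - mean(s^2)
  clipped <- s0 < 0
  list(mu0 = mu0, sigma0_sq = max(0, s0), clipped = clipped,
       sigma0_sq_raw = s0)
}

#' Normal-normal posterior update for one reader
#'
#' posterior mean = (sigma_r^2 mu0 + sigma0^2 mu_r) / (sigma0^2 + sigma_r^2);
#' posterior variance = sigma0^2 sigma_r^2 / (sigma0^2 + sigma_r^2).
#'
#' @param mu_r raw reader mean.
#' @param sigma_r its standard error (>= 0).
#' @param mu0,sigma0_sq prior mean and variance.
#' @return list with `mean` and `var`.
#' @export
shrink <- function(mu_r, sigma_r, mu0, sigma0_sq) {
  stopifnot(sigma_r >= 0, sigma0_sq >= 0)
  s_r2 <- sigma_r^2
  if (s_r2 == 0 && sigma0_sq == 0) {
    stop("degenerate input: both sigma_r and sigma0_sq are zero")
  }
  list(mean = (s_r2 * mu0 + sigma0_sq * mu_r) / (sigma0_sq + s_r2),
       var = sigma0_sq * s_r2 / (sigma0_sq + s_r2))
}

#' Empirical Bayes shrinkage across all readers
#'
#' Readers whose standard error is zero (zero within-reader variance, which
#' makes inference on that reader impossible) or not finite are handled by
#' `exclusion_rule`: `"drop"` (default) removes them from both the prior
#' estimate and the output, listing them in `excluded_readers`; `"keep"`
#' retains se-zero readers (their posterior equals their raw value).
#'
#' @param summaries data.frame/data.table with columns `radiologist_id`,
#'   `value`, `se` — e.g. the `condition == "effect"` rows of
#'   [reader_summaries()].
#' @param exclusion_rule `"drop"` or `"keep"`.
#' @param variance passed to [estimate_prior()].
#' @return object of class `shrinkage_result`: `prior` (mu0, sigma0_sq,
#'   clipped), `table` (radiologist_id, raw, se, posterior_mean,
#'   posterior_var), `excluded_readers`.
#' @export
shrink_all <- function(summaries, exclusion_rule = c("drop", "keep"),
                       variance = "population") {
  exclusion_rule <- match.arg(exclusion_rule)
  dt <- as.data.table(summaries)
  check_columns(dt, c("radiologist_id", "value", "se"), "summaries")
  bad <- !is.finite(dt$value) | !is.finite(dt$se) |
    (exclusion_rule == "drop" & dt$se == 0)
  excluded <- dt$radiologist_id[bad]
  keep <- dt[!bad]
  if (nrow(keep) == 0L) stop("shrink_all: all readers excluded")
  prior <- estimate_prior(keep$value, keep$se, variance = variance)
  if (prior$clipped) {
    warning("prior variance estimate was negative and clipped to 0; ",
            "all readers shrink fully to the grand mean")
  }
  post <- if (prior$sigma0_sq == 0 && any(keep$se == 0)) {
    stop("degenerate shrinkage: prior variance 0 with se-zero readers kept")
  } else {
    mapply(function(m, s) unlist(shrink(m, s, prior$mu0, prior$sigma0_sq)),
           keep$value, keep$se)
  }
  structure(list(
    prior = prior,
    table = data.table(radiologist_id = keep$radiologist_id,
                       raw = keep$value, se = keep$se,
                       posterior_mean = as.numeric(post["mean", ]),
                       posterior_var = as.numeric(post["var", ])),
    excluded_readers = excluded), class = "shrinkage_result")
}

#' @export
print.shrinkage_result <- function(x, ...) {
  cat(sprintf("<shrinkage_result> %d readers (%d excluded)\n",
              nrow(x$table), length(x$excluded_readers)))
  cat(sprintf("  prior: mu0 = %.4g, sigma0^2 = %.4g%s\n", x$prior$mu0,
              x$prior$sigma0_sq,
              if (x$prior$clipped) " [clipped at 0]" else ""))
  invisible(x)
}
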