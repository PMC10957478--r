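# Pipeline orchestration: simulate/load -> summarize -> shrink -> regress ->
# subgroup/bin analyses -> report tables.

#' Binned scatter summary (binscatter)
#'
#' Bins are evenly spaced on the range of x; each bin reports the mean of y
#' with a cluster-robust 95% CI (intercept-only OLS within the bin), plus
#' the coefficients of the overall fitted line.
#'
#' @param x,y numeric vectors.
#' @param n_bins number of bins (default 5).
#' @param cluster_case,cluster_reader optional cluster ids (default: each
#'   observation its own cluster, i.e. heteroskedasticity-robust).
#' @return list with `bins` (data.table: bin, x_center, mean, ci_lo, ci_hi,
#'   n; empty bins reported with NA, not interpolated) and `line`
#'   (intercept/slope fit).
#' @export
binscatter <- function(x, y, n_bins = 5L, cluster_case = NULL,
                       cluster_reader = NULL) {
  stopifnot(length(x) == length(y))
  if (length(x) < n_bins) stop("need at least n_bins observations")
  if (is.null(cluster_case)) cluster_case <- seq_along(x)
  if (is.null(cluster_reader)) cluster_reader <- seq_along(x)
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  b <- findInterval(x, edges, rightmost.closed = TRUE)
  rows <- lapply(seq_len(n_bins), function(i) {
    idx <- which(b == i)
    if (length(idx) == 0L) {
      return(data.table(bin = i, x_center = (edges[i] + edges[i + 1L]) / 2,
                        mean = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        n = 0L))
    }
    if (length(idx) == 1L) {
      return(data.table(bin = i, x_center = (edges[i] + edges[i + 1L]) / 2,
                        mean = y[idx], ci_lo = NA_real_, ci_hi = NA_real_,
                        n = 1L))
    }
    fit <- fit_ols(y[idx], cbind(`(Intercept)` = rep(1, length(idx))),
                   cluster_case[idx], cluster_reader[idx])
    se <- sqrt(fit$vcov[1, 1])
    data.table(bin = i, x_center = (edges[i] + edges[i + 1L]) / 2,
               mean = fit$coef[[1]], ci_lo = fit$coef[[1]] - qnorm(0.975) * se,
               ci_hi = fit$coef[[1]] + qnorm(0.975) * se, n = length(idx))
  })
  line <- fit_ols(y, cbind(`(Intercept)` = 1, x = x),
                  cluster_case, cluster_reader)
  list(bins = rbindlist(rows), line = line)
}

#' Analysis configuration
#'
#' @param sim a [sim_config()] to simulate inputs, or NULL to load them.
#' @param input_dir directory of CSVs for [load_bundle()] (ignored when
#'   `sim` is given).
#' @param scopes pathology scopes to analyze; `"all"` pools the 15 labels.
#' @param high_prevalence_threshold cutoff for the TE-shrinkage filter.
#' @param abs_edges,signed_edges AI-error bin edges.
#' @param fdr FDR levels.
#' @param naive_diagnostic include the reversion-to-the-mean diagnostic.
#' @param use_shrunk report oracle-split heterogeneity on shrunk (TRUE,
#'   default) or raw per-reader effects.
#' @param auroc_analyses include the AUROC counterparts (slower).
#' @param seed master seed.
#' @return object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(sim = sim_config(), input_dir = NULL,
                            scopes = "all",
                            high_prevalence_threshold = 0.10,
                            abs_edges = default_bin_edges("absolute"),
                            signed_edges = default_bin_edges("signed"),
                            fdr = c(0.05, 0.01),
                            naive_diagnostic = TRUE, use_shrunk = TRUE,
                            auroc_analyses = FALSE, seed = 1L) {
  if (is.null(sim) && is.null(input_dir)) {
    stop("either sim or input_dir must be given")
  }
  structure(list(sim = sim, input_dir = input_dir, scopes = scopes,
                 high_prevalence_threshold = high_prevalence_threshold,
                 abs_edges = abs_edges, signed_edges = signed_edges,
                 fdr = fdr, naive_diagnostic = naive_diagnostic,
                 use_shrunk = use_shrunk, auroc_analyses = auroc_analyses,
                 seed = as.integer(seed)), class = "analysis_config")
}

#' Run the full heterogeneity analysis pipeline
#'
#' Sequence: obtain the bundle (simulate or load); per-reader treatment
#' effect summaries and empirical Bayes shrinkage (overall and for
#' high-prevalence pathologies); oracle and combined-characteristics
#' subgroup reports; split-sampling treatment-effect and assisted-error
#' regressions with attenuation correction (plus the naive diagnostic);
#' AI absolute- and signed-error bin analyses; binscatter tables. Writes CSV
#' tables plus one machine-readable JSON summary and a manifest when `out`
#' is given.
#'
#' @param config an [analysis_config()].
#' @param out optional output directory.
#' @return list (class `analysis_report`) with all result objects and the
#'   resolved config.
#' @export
run_full_analysis <- function(config = analysis_config(), out = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  t0 <- Sys.time()
  log_stage <- function(fmt, ...) message(sprintf(paste0("[hetfx] ", fmt), ...))
  stage <- "inputs"
  res <- list(config = config)
  tryCatch({
    if (!is.null(config$sim)) {
      log_stage("simulating study (seed %d)", config$seed)
      sim <- generate_study(config$sim, seed = config$seed)
      bundle <- sim$bundle
      res$sim_truth_seed <- config$seed
    } else {
      log_stage("loading bundle from %s", config$input_dir)
      bundle <- load_bundle(list(
        reads = file.path(config$input_dir, "reads.csv"),
        truths = file.path(config$input_dir, "truths.csv"),
        ai = file.path(config$input_dir, "ai.csv"),
        profiles = if (file.exists(file.path(config$input_dir, "profiles.csv")))
          file.path(config$input_dir, "profiles.csv")))
    }
    res$n_reads <- nrow(bundle$reads)

    stage <- "summaries"
    summ <- reader_summaries(bundle, "abs_error", "all")
    res$reader_summaries <- summ
    eff <- summ[condition == "effect"]

    stage <- "shrinkage"
    res$shrinkage_all <- shrink_all(eff)
    hp <- high_prevalence_filter(bundle, config$high_prevalence_threshold)
    res$high_prevalence <- hp
    res$shrinkage_by_pathology <- lapply(setNames(hp, hp), function(p) {
      s <- reader_summaries(bundle, "abs_error", p)[condition == "effect"]
      tryCatch(shrink_all(s), error = function(e) e)
    })
    tab <- res$shrinkage_all$table
    v <- if (config$use_shrunk) tab$posterior_mean else tab$raw
    res$heterogeneity <- list(range = range(v), iqr = unname(diff(
      quantile(v, c(0.25, 0.75)))), n_readers = nrow(tab))
    log_stage("TE heterogeneity: range [%.3f, %.3f], IQR %.3f",
              res$heterogeneity$range[1], res$heterogeneity$range[2],
              res$heterogeneity$iqr)

    stage <- "oracle subgroup"
    shrunk <- setNames(tab$posterior_mean, tab$radiologist_id)
    assign_oracle <- oracle_split(res$shrinkage_all,
                                  use = if (config$use_shrunk) "posterior"
                                        else "raw")
    res$oracle <- subgroup_effect_report(assign_oracle, bundle, "all",
                                         shrunk_te = shrunk)

    stage <- "characteristic subgroups"
    if (!is.null(bundle$profiles)) {
      p <- bundle$profiles
      raw_te <- setNames(eff$value, eff$radiologist_id)
      chars <- list(
        experience = setNames(p$years_experience, p$radiologist_id),
        thoracic = setNames(p$thoracic_subspecialty, p$radiologist_id),
        ai_experience = setNames(p$ai_experience, p$radiologist_id))
      res$characteristic_subgroups <- lapply(chars, function(v) {
        tryCatch({
          a <- median_split(v)
          subgroup_effect_report(a, bundle, "all")
        }, error = function(e) e)
      })
      res$combined <- tryCatch({
        a <- combined_characteristics_split(p, raw_te, seed = config$seed)
        list(assignment = a,
             report = subgroup_effect_report(a, bundle, "all"))
      }, error = function(e) e)
    }

    stage <- "split-sampling regressions"
    res$te_regression <- split_regression(bundle, "te", "all")
    res$assisted_regression <- split_regression(bundle, "assisted", "all")
    if (config$naive_diagnostic) {
      res$naive_regression <- split_regression(bundle, "naive", "all")
      agg <- build_naive_design(bundle, aggregate = TRUE)
      fit_agg <- fit_ols(agg$y, cbind(`(Intercept)` = 1, x = agg$x),
                         agg$radiologist_id, agg$radiologist_id)
      res$naive_regression_aggregated <- fit_agg
    }
    rows <- res$te_regression$fit$design_rows
    res$binscatter_te <- binscatter(rows$x, rows$y, 5L,
                                    rows$held_out_case_id,
                                    rows$radiologist_id)

    stage <- "AI error bins"
    res$abs_error_bins <- ai_error_bin_analysis(bundle, config$abs_edges,
                                                "absolute", "all")
    res$signed_error_bins <- ai_error_bin_analysis(bundle,
                                                   config$signed_edges,
                                                   "signed", "all")

    if (config$auroc_analyses) {
      stage <- "AUROC analyses"
      res$auroc_te_regression <- tryCatch(
        split_auroc_regression(bundle, "te", "all", seed = config$seed),
        error = function(e) e)
      res$auroc_bins <- tryCatch(auroc_bin_analysis(bundle, config$abs_edges),
                                 error = function(e) e)
    }
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  res$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(res) <- "analysis_report"
  if (!is.null(out)) write_report(res, out)
  res
}

#' Write an analysis report to CSV tables and a JSON summary
#' @param report an `analysis_report`.
#' @param out output directory.
#' @return invisibly, the directory.
#' @export
write_report <- function(report, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  fwrite(report$reader_summaries, file.path(out, "reader_summaries.csv"))
  shr <- copy(report$shrinkage_all$table)
  fwrite(shr, file.path(out, "shrinkage.csv"))
  fwrite(report$abs_error_bins$bins, file.path(out, "bins_absolute.csv"))
  fwrite(report$signed_error_bins$bins, file.path(out, "bins_signed.csv"))
  te <- report$te_regression
  summary_json <- list(
    n_reads = report$n_reads,
    heterogeneity = report$heterogeneity,
    shrinkage_prior = report$shrinkage_all$prior,
    oracle_gap = if (!is.null(report$oracle$t_test))
      report$oracle$t_test$p_value,
    te_regression = list(gamma = te$gamma_hat, lambda = te$lambda_hat,
                         beta = te$beta_hat, se_beta = te$se_beta,
                         p = te$p_value),
    assisted_regression = list(beta = report$assisted_regression$beta_hat,
                               p = report$assisted_regression$p_value),
    naive_regression = if (!is.null(report$naive_regression))
      list(beta = report$naive_regression$beta_hat,
           gamma = report$naive_regression$gamma_hat,
           p = report$naive_regression$p_value),
    abs_bins_joint_p = report$abs_error_bins$joint_test$p_value,
    signed_bins_joint_p = report$signed_error_bins$joint_test$p_value,
    seed = report$config$seed, elapsed_s = report$elapsed_s)
  jsonlite::write_json(summary_json, file.path(out, "summary.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  manifest <- list(
    n_reads = report$n_reads,
    n_readers = report$heterogeneity$n_readers,
    excluded_readers = report$shrinkage_all$excluded_readers,
    high_prevalence = report$high_prevalence,
    scopes = report$config$scopes, seed = report$config$seed)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(out)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  reads: %d, readers: %d\n", x$n_reads,
              x$heterogeneity$n_readers))
  cat(sprintf("  TE range [%.3f, %.3f], IQR %.3f (shrunk: %s)\n",
              x$heterogeneity$range[1], x$heterogeneity$range[2],
              x$heterogeneity$iqr, x$config$use_shrunk))
  cat(sprintf("  split TE slope beta = %.3f (p = %.3g); naive beta = %s\n",
              x$te_regression$beta_hat, x$te_regression$p_value,
              if (is.null(x$naive_regression)) "off"
              else sprintf("%.3f", x$naive_regression$beta_hat)))
  invisible(x)
}
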