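# Subgroup construction (oracle, single-characteristic, combined
# characteristics) and AI-error bin analyses.

#' Median split of per-reader values into binary subgroups
#'
#' Low group: value <= median; high group: value > median (the tie rule is
#' config-exposed: `"le"` places exact-median readers low, `"lt"` high).
#'
#' @param values named numeric vector (names = radiologist ids).
#' @param tie_rule `"le"` (default) or `"lt"`.
#' @param labels group labels, low then high.
#' @return object of class `subgroup_assignment`: `groups` (named character
#'   vector), `splitter` description, `sizes`.
#' @export
median_split <- function(values, tie_rule = c("le", "lt"),
                         labels = c("low", "high")) {
  tie_rule <- match.arg(tie_rule)
  if (length(values) < 2L) stop("median_split: need at least 2 readers")
  if (is.null(names(values))) stop("median_split: values must be named by reader")
  med <- median(values)
  low <- if (tie_rule == "le") values <= med else values < med
  if (all(low) || !any(low)) {
    stop("degenerate split: one group is empty (all values identical?)")
  }
  groups <- setNames(ifelse(low, labels[1L], labels[2L]), names(values))
  structure(list(groups = groups,
                 splitter = list(cutoff = med, tie_rule = tie_rule),
                 sizes = table(groups)), class = "subgroup_assignment")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat("<subgroup_assignment>", paste(sprintf("%s=%d", names(x$sizes),
                                             as.integer(x$sizes)),
                                     collapse = ", "), "\n")
  invisible(x)
}

#' Oracle subgroup split on empirical-Bayes-shrunk treatment effects
#'
#' The benchmark an ideal predictor would achieve: readers split at the
#' median of their shrunk per-reader treatment effects.
#'
#' @param shrinkage a `shrinkage_result` from [shrink_all()].
#' @param use one of `"posterior"` (default) or `"raw"`.
#' @param ... passed to [median_split()].
#' @return a `subgroup_assignment`.
#' @export
oracle_split <- function(shrinkage, use = c("posterior", "raw"), ...) {
  stopifnot(inherits(shrinkage, "shrinkage_result"))
  use <- match.arg(use)
  v <- if (use == "posterior") shrinkage$table$posterior_mean
       else shrinkage$table$raw
  median_split(setNames(v, shrinkage$table$radiologist_id), ...)
}

#' Combined-characteristics subgroup split by cross-fitted prediction
#'
#' Readers are split into random halves (seeded). A linear model of the
#' per-reader treatment effect on an intercept plus three binary
#' characteristics (years of experience <= the dataset median, thoracic
#' subspecialty, AI-tool experience) is fit on one half and used to score
#' the other half; scores are thresholded at the grand median treatment
#' effect (computed from all included readers). Halves are then swapped so
#' every reader is assigned.
#'
#' @param profiles `ReaderProfile` table.
#' @param te named per-reader treatment effects (names = radiologist ids).
#' @param seed seed for the half split.
#' @param years_cutoff experience cutoff; default the profile median.
#' @return a `subgroup_assignment` with extra elements `coefficients`
#'   (per-fold fitted coefficient vectors) and `scores`.
#' @export
combined_characteristics_split <- function(profiles, te, seed = 1L,
                                           years_cutoff = NULL) {
  profiles <- as.data.table(profiles)
  te <- te[names(te) %in% profiles$radiologist_id]
  if (length(te) < 4L) stop("need at least 4 readers with profiles")
  if (is.null(years_cutoff)) years_cutoff <- median(profiles$years_experience)
  p <- profiles[match(names(te), radiologist_id)]
  Xc <- cbind(`(Intercept)` = 1,
              exp_le_median = as.numeric(p$years_experience <= years_cutoff),
              thoracic = as.numeric(p$thoracic_subspecialty),
              ai_experience = as.numeric(p$ai_experience))
  n <- length(te)
  set.seed(seed)
  half1 <- sample(n, floor(n / 2))
  folds <- list(list(train = half1, test = setdiff(seq_len(n), half1)),
                list(train = setdiff(seq_len(n), half1), test = half1))
  grand_med <- median(te)
  scores <- rep(NA_real_, n)
  coefs <- list()
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; tst <- folds[[f]]$test
    Xtr <- Xc[tr, , drop = FALSE]
    keep <- c(TRUE, apply(Xtr[, -1L, drop = FALSE], 2L,
                          function(col) length(unique(col)) > 1L))
    if (!all(keep)) {
      warning("constant characteristic(s) in training half dropped: ",
              paste(colnames(Xc)[!keep], collapse = ", "))
    }
    b <- qr.coef(qr(Xtr[, keep, drop = FALSE]), te[tr])
    coefs[[f]] <- b
    scores[tst] <- as.numeric(Xc[tst, keep, drop = FALSE] %*% b)
  }
  groups <- setNames(ifelse(scores <= grand_med, "low", "high"), names(te))
  if (length(unique(groups)) < 2L) {
    stop("degenerate split: all predicted scores on one side of the median")
  }
  structure(list(groups = groups,
                 splitter = list(cutoff = grand_med, tie_rule = "le",
                                 years_cutoff = years_cutoff),
                 sizes = table(groups), coefficients = coefs,
                 scores = setNames(scores, names(te))),
            class = "subgroup_assignment")
}

#' Per-group treatment effects and heterogeneity tests for an assignment
#'
#' Runs the subgroup treatment-effect model and the Wald joint-equality test
#' on read-level data. With `scope = "per_pathology"` the analysis is run on
#' each pathology and Benjamini-Hochberg correction is applied across them;
#' with a single scope exactly one unadjusted test is run. When shrunk
#' per-reader effects are supplied the two-group unpaired t-test is added
#' (the oracle-benchmark comparison).
#'
#' @param assignment a `subgroup_assignment`.
#' @param bundle a `study_bundle`.
#' @param scope `"all"`, a vector of labels, or `"per_pathology"`.
#' @param shrunk_te optional named shrunk per-reader effects for the t-test.
#' @param fdr FDR levels for the per-pathology correction.
#' @param ... passed to [fit_ols()].
#' @return for a single scope, a list (class `subgroup_report`) with `fit`,
#'   `subgroups`, `joint_test`, optional `t_test`; for `"per_pathology"`, a
#'   data.table with one row per pathology plus BH-adjusted p-values.
#' @export
subgroup_effect_report <- function(assignment, bundle, scope = "all",
                                   shrunk_te = NULL, fdr = c(0.05, 0.01),
                                   ...) {
  stopifnot(inherits(assignment, "subgroup_assignment"))
  if (identical(scope, "per_pathology")) {
    paths <- bundle$pathologies
    reps <- lapply(paths, function(p)
      tryCatch(subgroup_effect_report(assignment, bundle, p,
                                      shrunk_te = shrunk_te, ...),
               error = function(e) e))
    ok <- !vapply(reps, inherits, logical(1), "error")
    tab <- rbindlist(lapply(which(ok), function(i) data.table(
      pathology = paths[i], p_value = reps[[i]]$joint_test$p_value)))
    bh <- benjamini_hochberg(tab$p_value, q = fdr[1L])
    tab[, `:=`(p_adjusted = bh$adjusted, reject_fdr1 = bh$reject)]
    tab[, reject_fdr2 := benjamini_hochberg(p_value, q = fdr[2L])$reject]
    return(list(table = tab[], reports = setNames(reps[ok], paths[ok]),
                failed = paths[!ok]))
  }
  dt <- read_errors(bundle, scope, "abs_error")
  dt[, subgroup := assignment$groups[radiologist_id]]
  n_un <- sum(is.na(dt$subgroup))
  if (n_un) {
    message(sprintf("subgroup_effect_report: %d read(s) from unassigned readers dropped",
                    n_un))
    dt <- dt[!is.na(subgroup)]
  }
  fit <- subgroup_te_model(dt, ...)
  jt <- wald_joint_equality(fit, fit$interaction_names)
  out <- list(fit = fit, subgroups = fit$subgroups, joint_test = jt)
  if (!is.null(shrunk_te)) {
    g <- assignment$groups[names(shrunk_te)]
    lv <- sort(unique(g[!is.na(g)]))
    if (length(lv) == 2L &&
        min(table(g[!is.na(g)])) >= 2L) {
      out$t_test <- unpaired_t_test(shrunk_te[!is.na(g) & g == lv[1L]],
                                    shrunk_te[!is.na(g) & g == lv[2L]])
    } else {
      message("subgroup_effect_report: t-test skipped (a group has < 2 readers)")
    }
  }
  class(out) <- "subgroup_report"
  out
}

#' High-prevalence pathology filter
#'
#' Labels with strict prevalence above the threshold under the binary truth
#' labels (a prevalence of exactly the threshold is excluded).
#'
#' @param truths `CaseTruth` table (or a `study_bundle`).
#' @param threshold prevalence cutoff (default 0.10).
#' @return character vector of pathology labels.
#' @export
high_prevalence_filter <- function(truths, threshold = 0.10) {
  if (inherits(truths, "study_bundle")) truths <- truths$truths
  truths <- as.data.table(truths)
  prev <- truths[, .(prevalence = mean(truth_label)), by = pathology]
  prev[prevalence > threshold, pathology]
}

#' Default AI-error bin edges
#'
#' Absolute error: five bins \[0,20), \[20,40), \[40,60), \[60,80),
#' \[80,100\]. Signed error: ten width-20 bins spanning \[-100,100\].
#' Interior boundaries are left-closed; the last bin is closed.
#' @param error_kind `"absolute"` or `"signed"`.
#' @return numeric vector of edges.
#' @export
default_bin_edges <- function(error_kind = c("absolute", "signed")) {
  error_kind <- match.arg(error_kind)
  if (error_kind == "absolute") seq(0, 100, by = 20)
  else seq(-100, 100, by = 20)
}

assign_bins <- function(x, edges) {
  if (any(x < edges[1L] | x > edges[length(edges)])) {
    stop("AI error outside the bin edge span")
  }
  # left-closed bins, last bin closed on the right
  b <- findInterval(x, edges, rightmost.closed = TRUE, left.open = FALSE)
  b
}

bin_label <- function(edges) {
  k <- length(edges) - 1L
  sprintf("[%g,%g%s", edges[-length(edges)], edges[-1L],
          c(rep(")", k - 1L), "]"))
}

#' Treatment effects binned by AI error
#'
#' Each read is assigned a bin by its case's AI error for that pathology
#' (absolute or signed); per-bin treatment effects come from the subgroup
#' model with bins as subgroups, and heterogeneity across bins is tested by
#' Wald joint equality. Empty bins are dropped with a note.
#'
#' @param bundle a `study_bundle`.
#' @param edges strictly increasing bin edges covering the error range
#'   (defaults per `error_kind`).
#' @param error_kind `"absolute"` or `"signed"` AI error.
#' @param scope `"all"` or pathology labels.
#' @param min_cases_per_bin minimum number of distinct patient cases a bin
#'   must contain to enter the analysis (default 10). The joint test's
#'   cluster-robust covariance is asymptotic in the number of case clusters
#'   per bin; bins informed by one or two cases make it badly anti-
#'   conservative, so under-populated bins are dropped like empty ones,
#'   with a note.
#' @param ... passed to [fit_ols()].
#' @return object of class `binned_effect_table`: `bins` (per-bin TE, CI,
#'   n), `joint_test`, `dropped_bins`, `edges`.
#' @export
ai_error_bin_analysis <- function(bundle, edges = NULL,
                                  error_kind = c("absolute", "signed"),
                                  scope = "all", min_cases_per_bin = 10L,
                                  ...) {
  error_kind <- match.arg(error_kind)
  if (is.null(edges)) edges <- default_bin_edges(error_kind)
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  dt <- read_errors(bundle, scope, "abs_error")
  dt <- merge(dt, bundle$ai, by = c("case_id", "pathology"), sort = FALSE)
  dt[, ai_error := if (error_kind == "absolute")
    abs(ai_prob - truth_prob) else ai_prob - truth_prob]
  dt[, bin := assign_bins(ai_error, edges)]
  labels <- bin_label(edges)
  support <- dt[, .(cases = uniqueN(case_id)), by = bin]
  present <- sort(support[cases >= min_cases_per_bin, bin])
  dropped <- setdiff(seq_along(labels), present)
  if (length(dropped)) {
    message(sprintf(
      "ai_error_bin_analysis: dropping %d empty/under-populated bin(s): %s",
      length(dropped), paste(labels[dropped], collapse = " ")))
    dt <- dt[bin %in% present]
  }
  if (nrow(dt) == 0L) stop("no bin meets min_cases_per_bin")
  dt[, subgroup := sprintf("bin%02d", bin)]
  fit <- subgroup_te_model(dt, ...)
  jt <- if (length(present) >= 2L) {
    wald_joint_equality(fit, fit$interaction_names)
  } else NULL
  bins <- fit$subgroups
  bins[, bin := as.integer(sub("bin", "", subgroup))]
  bins[, label := labels[bin]]
  setcolorder(bins, c("bin", "label", "te", "se", "ci_lo", "ci_hi", "n"))
  structure(list(bins = bins[, !"subgroup"], joint_test = jt,
                 dropped_bins = labels[dropped], edges = edges,
                 error_kind = error_kind, fit = fit),
            class = "binned_effect_table")
}

#' @export
print.binned_effect_table <- function(x, ...) {
  cat(sprintf("<binned_effect_table> %s AI error, %d bins\n", x$error_kind,
              nrow(x$bins)))
  print(x$bins[, .(label, te = round(te, 3), ci_lo = round(ci_lo, 3),
                   ci_hi = round(ci_hi, 3), n)])
  if (!is.null(x$joint_test)) {
    cat(sprintf("  joint equality: chisq(%d) = %.3f, p = %.3g\n",
                x$joint_test$df, x$joint_test$statistic, x$joint_test$p_value))
  }
  invisible(x)
}

#' Per-bin AUROC treatment effects with the between/within F-test
#'
#' For each AI absolute-error bin, the unassisted and assisted AUROCs are
#' computed over all reads in the bin; the per-bin treatment effect is their
#' difference. Heterogeneity across bins uses [auroc_bin_f_test()] with the
#' read counts as group sizes and seeded case-bootstrap standard errors. An
#' undefined per-bin AUROC (single-class bin) aborts the analysis for this
#' scope, mirroring the aggregate-metric feasibility constraint.
#'
#' @param bundle a `study_bundle`.
#' @param edges absolute-error bin edges.
#' @param scope `"all"` or pathology labels.
#' @param boot_reps,seed bootstrap controls for the per-bin AUROC se.
#' @return list with `bins` (per-bin/condition AUROCs, TE, n) and `f_test`.
#' @export
auroc_bin_analysis <- function(bundle, edges = default_bin_edges("absolute"),
                               scope = "all", boot_reps = 100L, seed = 11L) {
  dt <- read_errors(bundle, scope, "abs_error")
  dt <- merge(dt, bundle$ai, by = c("case_id", "pathology"), sort = FALSE)
  dt[, bin := assign_bins(abs(ai_prob - truth_prob), edges)]
  labels <- bin_label(edges)
  set.seed(seed)
  per_bin <- dt[, {
    res <- lapply(c(0L, 1L), function(cond) {
      sub <- .SD[assisted == cond]
      val <- tryCatch(auroc(sub$predicted_prob, sub$truth_label),
                      error = function(e) NA_real_)
      list(val = val,
           se = if (is.na(val)) NA_real_ else auroc_boot_se(sub, boot_reps),
           n = nrow(sub))
    })
    .(auroc_unassisted = res[[1]]$val, auroc_assisted = res[[2]]$val,
      se_unassisted = res[[1]]$se, se_assisted = res[[2]]$se,
      te = res[[2]]$val - res[[1]]$val, n = res[[1]]$n + res[[2]]$n)
  }, by = bin][order(bin)]
  if (anyNA(per_bin$te)) {
    stop("undefined AUROC in a bin (single-class); AUROC bin analysis not feasible for this scope")
  }
  per_bin[, label := labels[bin]]
  # the treatment-effect F compares per-bin TEs; use the per-bin TE se from
  # independent combination of the two condition bootstrap ses
  te_se <- sqrt(per_bin$se_unassisted^2 + per_bin$se_assisted^2)
  ft <- auroc_bin_f_test(per_bin$te, te_se, per_bin$n)
  list(bins = per_bin[], f_test = ft)
}
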