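# Read-level and reader-level performance metrics.
#
# Calibration is measured by absolute error between the reader's predicted
# probability and the consensus truth probability (0-100 scale);
# discrimination by the empirical (Mann-Whitney) AUROC against binary truth
# labels. Treatment-effect sign conventions:
#   * errors:  TE = unassisted - assisted  (positive = improvement)
#   * AUROC / sensitivity / specificity: TE = assisted - unassisted

#' Absolute error of a predicted probability
#' @param predicted_prob,truth_prob numerics in \[0, 100\].
#' @return |predicted - truth|, in \[0, 100\].
#' @export
absolute_error <- function(predicted_prob, truth_prob) {
  check_prob_range(predicted_prob, "predicted_prob")
  check_prob_range(truth_prob, "truth_prob")
  abs(predicted_prob - truth_prob)
}

#' Signed error of a predicted probability
#'
#' Negative values mean underestimation of the truth probability.
#' @inheritParams absolute_error
#' @return predicted - truth, in \[-100, 100\].
#' @export
signed_error <- function(predicted_prob, truth_prob) {
  check_prob_range(predicted_prob, "predicted_prob")
  check_prob_range(truth_prob, "truth_prob")
  predicted_prob - truth_prob
}

#' Empirical AUROC (Mann-Whitney probability with half-credit ties)
#'
#' Over all (positive, negative) pairs: credit 1 when the positive scores
#' higher, 0.5 on ties. Computed via midranks.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (at least one of each class).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("undefined AUROC: need at least one positive and one negative label",
         call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity at a probability threshold
#'
#' The reader's (or AI's) predicted probability is binarized at `threshold`
#' (predicted positive when `prob >= threshold`).
#'
#' @param predicted_probs numerics in \[0, 100\].
#' @param truth_labels 0/1 labels.
#' @param threshold decision threshold on the 0-100 scale (default 50).
#' @return list with `sens` and `spec`; a component is `NA` (with attribute
#'   `undefined = TRUE`) when its class is absent.
#' @export
sensitivity_specificity <- function(predicted_probs, truth_labels,
                                    threshold = 50) {
  if (threshold < 0 || threshold > 100) stop("threshold must be in [0,100]")
  pos <- truth_labels == 1L
  pred_pos <- predicted_probs >= threshold
  sens <- if (any(pos)) mean(pred_pos[pos]) else NA_real_
  spec <- if (any(!pos)) mean(!pred_pos[!pos]) else NA_real_
  out <- list(sens = sens, spec = spec)
  if (is.na(sens) || is.na(spec)) attr(out, "undefined") <- TRUE
  out
}

# per-read metric values joined onto the read table; scope filters pathology
read_errors <- function(bundle, scope = "all",
                        metric = c("abs_error", "signed_error")) {
  metric <- match.arg(metric)
  dt <- merge(bundle$reads,
              bundle$truths[, .(case_id, pathology, truth_prob, truth_label)],
              by = c("case_id", "pathology"), sort = FALSE)
  if (!identical(scope, "all")) dt <- dt[pathology %in% scope]
  dt[, error := if (metric == "abs_error")
    abs(predicted_prob - truth_prob) else predicted_prob - truth_prob]
  dt
}

se_mean <- function(x) {
  n <- length(x)
  if (n <= 1L) return(NA_real_)
  sd(x) / sqrt(n)
}

#' Per-reader summaries of a metric by condition
#'
#' For each reader returns rows for the unassisted mean, assisted mean and
#' the treatment effect, each with its standard error of the mean and read
#' count. The effect row follows the sign conventions above. For the
#' mean-error metrics the effect standard error uses the independent-samples
#' formula in the non-repeated design and the paired per-case-difference
#' formula in the repeated design (clinical-history conditions are pooled, so
#' a repeated-design case contributes the difference of its per-case means).
#'
#' For `auroc`, `sens` and `spec` the per-condition value is computed over
#' all the reader's reads in scope; sens/spec standard errors are binomial,
#' AUROC standard errors come from a seeded case-level bootstrap (or the
#' DeLong analytic variance with `auroc_se = "delong"`); effect rows combine
#' the two conditions as independent.
#'
#' @param bundle a `study_bundle`.
#' @param metric one of `abs_error`, `signed_error`, `auroc`, `sens`, `spec`.
#' @param pathology_scope `"all"` (pool reads across pathologies) or a
#'   vector of pathology labels.
#' @param reader_threshold threshold binarizing reader probabilities for
#'   sens/spec (default 50).
#' @param auroc_se `"bootstrap"` (default) or `"delong"`.
#' @param boot_reps,boot_seed bootstrap controls.
#' @return data.table with columns radiologist_id, scope, condition
#'   (`unassisted`/`assisted`/`effect`), value, se, n, flagged. Readers with
#'   zero reads in a condition are excluded with a message; se = 0 or NA
#'   rows are flagged.
#' @export
reader_summaries <- function(bundle, metric = c("abs_error", "signed_error",
                                                "auroc", "sens", "spec"),
                             pathology_scope = "all", reader_threshold = 50,
                             auroc_se = c("bootstrap", "delong"),
                             boot_reps = 100L, boot_seed = 7L) {
  metric <- match.arg(metric)
  auroc_se <- match.arg(auroc_se)
  scope_lab <- paste(pathology_scope, collapse = "+")
  if (metric %in% c("abs_error", "signed_error")) {
    dt <- read_errors(bundle, pathology_scope, metric)
    cond <- dt[, .(value = mean(error), se = se_mean(error), .N),
               by = .(radiologist_id, assisted)]
    bad <- cond[, .N, by = radiologist_id][N < 2L]
    if (nrow(bad)) {
      message(sprintf("reader_summaries: excluding %d reader(s) lacking a condition",
                      nrow(bad)))
      cond <- cond[!bad$radiologist_id, on = "radiologist_id"]
      dt <- dt[!bad$radiologist_id, on = "radiologist_id"]
    }
    eff_nr <- if (nrow(dt[design == "non_repeated"])) {
      dt[design == "non_repeated",
         if (uniqueN(assisted) == 2L) {
           u <- error[assisted == 0L]; a <- error[assisted == 1L]
           .(value = mean(u) - mean(a),
             se = sqrt(se_mean(u)^2 + se_mean(a)^2),
             n = .N)
         }, by = radiologist_id]
    }
    eff_rp <- if (nrow(dt[design == "repeated"])) {
      dt[design == "repeated", {
        pc <- .SD[, .(u = mean(error[assisted == 0L]),
                      a = mean(error[assisted == 1L])), by = case_id]
        d <- pc$u - pc$a
        .(value = mean(d), se = se_mean(d), n = .N)
      }, by = radiologist_id]
    }
    eff <- rbindlist(list(eff_nr, eff_rp), use.names = TRUE)
    out <- rbindlist(list(
      cond[, .(radiologist_id,
               condition = ifelse(assisted == 1L, "assisted", "unassisted"),
               value, se, n = N)],
      eff[, .(radiologist_id, condition = "effect", value, se, n)]),
      use.names = TRUE)
  } else {
    dt <- read_errors(bundle, pathology_scope, "abs_error")
    per_cond <- function(sub) {
      if (metric == "auroc") {
        val <- tryCatch(auroc(sub$predicted_prob, sub$truth_label),
                        error = function(e) NA_real_)
        se <- if (is.na(val)) NA_real_
        else if (auroc_se == "delong") delong_se(sub$predicted_prob,
                                                 sub$truth_label)
        else auroc_boot_se(sub, boot_reps)
        list(value = val, se = se, n = nrow(sub))
      } else {
        ss <- sensitivity_specificity(sub$predicted_prob, sub$truth_label,
                                      reader_threshold)
        v <- if (metric == "sens") ss$sens else ss$spec
        m <- if (metric == "sens") sum(sub$truth_label == 1L)
             else sum(sub$truth_label == 0L)
        list(value = v,
             se = if (is.na(v) || m == 0L) NA_real_
                  else sqrt(v * (1 - v) / m),
             n = nrow(sub))
      }
    }
    set.seed(boot_seed)
    cond <- dt[, per_cond(.SD), by = .(radiologist_id, assisted)]
    keep <- cond[, .(ok = .N == 2L && !anyNA(value)), by = radiologist_id]
    drop <- keep[ok == FALSE, radiologist_id]
    if (length(drop)) {
      message(sprintf("reader_summaries: excluding %d reader(s) with undefined %s",
                      length(drop), metric))
      cond <- cond[!drop, on = "radiologist_id"]
    }
    eff <- cond[, .(value = value[assisted == 1L] - value[assisted == 0L],
                    se = sqrt(sum(se^2)), n = sum(n)), by = radiologist_id]
    out <- rbindlist(list(
      cond[, .(radiologist_id,
               condition = ifelse(assisted == 1L, "assisted", "unassisted"),
               value, se, n)],
      eff[, .(radiologist_id, condition = "effect", value, se, n)]),
      use.names = TRUE)
  }
  out[, scope := scope_lab]
  out[, flagged := is.na(se) | se == 0]
  setcolorder(out, c("radiologist_id", "scope", "condition", "value", "se",
                     "n", "flagged"))
  out[]
}

# case-level bootstrap se of an AUROC (cases resampled, reads follow)
auroc_boot_se <- function(sub, reps) {
  cases <- unique(sub$case_id)
  if (length(cases) < 2L) return(NA_real_)
  vals <- vapply(seq_len(reps), function(i) {
    cs <- sample(cases, replace = TRUE)
    idx <- unlist(lapply(cs, function(cid) which(sub$case_id == cid)))
    tryCatch(auroc(sub$predicted_prob[idx], sub$truth_label[idx]),
             error = function(e) NA_real_)
  }, numeric(1))
  stats::sd(vals[!is.na(vals)])
}

# DeLong analytic standard error of an empirical AUROC
delong_se <- function(scores, labels) {
  xs <- scores[labels == 1L]
  ys <- scores[labels == 0L]
  m <- length(xs); n <- length(ys)
  v10 <- vapply(xs, function(x) mean((x > ys) + 0.5 * (x == ys)), numeric(1))
  v01 <- vapply(ys, function(y) mean((xs > y) + 0.5 * (xs == y)), numeric(1))
  s10 <- if (m > 1L) var(v10) else 0
  s01 <- if (n > 1L) var(v01) else 0
  sqrt(s10 / m + s01 / n)
}
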