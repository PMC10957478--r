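# Domain types and validated IO for reader-study tables.
#
# A study bundle holds four long-format tables:
#   reads    - one row per (radiologist, case, pathology, condition) with the
#              reader's predicted probability on a 0-100 scale
#   truths   - expert-consensus continuous ground-truth probability per
#              (case, pathology), plus the derived binary label
#   ai       - one AI-predicted probability per (case, pathology)
#   profiles - per-radiologist characteristics (may be missing for some)

#' Default list of the 15 pathology labels
#'
#' The flat label set used throughout: one binary diagnostic task per label.
#' @return character vector of length 15.
#' @export
default_pathologies <- function() {
  c("abnormal", "airspace_opacity", "atelectasis", "bacterial_lobar_pneumonia",
    "cardiomediastinal_abnormality", "cardiomegaly", "consolidation", "edema",
    "lesion", "pleural_effusion", "pleural_other", "pneumothorax",
    "rib_fracture", "shoulder_fracture", "support_device_hardware")
}

#' Consensus ground truth from a panel of expert probabilities
#'
#' The continuous ground-truth probability for a (case, pathology) is the
#' arithmetic mean of the experts' predicted probabilities on the 0-100 scale.
#'
#' @param expert_probs numeric vector of expert probabilities in \[0, 100\].
#' @return scalar mean probability.
#' @examples
#' ground_truth_from_experts(c(91, 92, 92, 100, 100)) # 95
#' @export
ground_truth_from_experts <- function(expert_probs) {
  if (length(expert_probs) == 0L) {
    stop("ground_truth_from_experts: need at least one expert probability")
  }
  check_prob_range(expert_probs, "expert_probs")
  mean(expert_probs)
}

#' Derive binary truth labels from continuous truth probabilities
#'
#' @param truth_prob numeric vector in \[0, 100\].
#' @param threshold threshold on the 0-100 scale (default 50).
#' @param rule `">="` (default: an exact-threshold consensus counts as
#'   present) or `">"`.
#' @return integer vector of 0/1 labels.
#' @export
truth_label_from_prob <- function(truth_prob, threshold = 50, rule = c(">=", ">")) {
  rule <- match.arg(rule)
  check_prob_range(truth_prob, "truth_prob")
  if (rule == ">=") as.integer(truth_prob >= threshold)
  else as.integer(truth_prob > threshold)
}

check_prob_range <- function(x, name, lo = 0, hi = 100) {
  bad <- which(!is.finite(x) | x < lo | x > hi)
  if (length(bad)) {
    stop(sprintf("%s outside [%g,%g] at row %d (value %s)",
                 name, lo, hi, bad[1L], format(x[bad[1L]])), call. = FALSE)
  }
  invisible(TRUE)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("schema error in %s: missing column(s) %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a validated study bundle
#'
#' @param reads data.frame with columns radiologist_id, case_id, pathology,
#'   design ("non_repeated"/"repeated"), assisted (0/1), clinical_history
#'   (0/1), session (integer or NA), predicted_prob (0-100).
#' @param truths data.frame with case_id, pathology, truth_prob; a
#'   truth_label column is derived if absent.
#' @param ai data.frame with case_id, pathology, ai_prob.
#' @param profiles optional data.frame with radiologist_id, years_experience,
#'   thoracic_subspecialty, ai_experience.
#' @param pathologies ordered label list (default [default_pathologies()]).
#' @param truth_threshold,truth_rule passed to [truth_label_from_prob()].
#' @return object of class `study_bundle`.
#' @export
study_bundle <- function(reads, truths, ai, profiles = NULL,
                         pathologies = default_pathologies(),
                         truth_threshold = 50, truth_rule = ">=") {
  reads <- as.data.table(reads)
  truths <- as.data.table(truths)
  ai <- as.data.table(ai)
  check_columns(reads, c("radiologist_id", "case_id", "pathology", "design",
                         "assisted", "predicted_prob"), "reads")
  check_columns(truths, c("case_id", "pathology", "truth_prob"), "truths")
  check_columns(ai, c("case_id", "pathology", "ai_prob"), "ai")
  if (!"clinical_history" %in% names(reads)) reads[, clinical_history := NA_integer_]
  if (!"session" %in% names(reads)) reads[, session := NA_integer_]

  if (nrow(reads)) {
    check_prob_range(reads$predicted_prob, "reads$predicted_prob")
    bad_design <- setdiff(unique(reads$design), c("non_repeated", "repeated"))
    if (length(bad_design)) {
      stop("reads$design must be non_repeated or repeated; saw: ",
           paste(bad_design, collapse = ", "))
    }
    # uniqueness: once per (reader, case, pathology) in non-repeated;
    # once per condition in repeated
    dup <- reads[design == "non_repeated",
                 .N, by = .(radiologist_id, case_id, pathology)][N > 1L]
    if (nrow(dup)) {
      stop(sprintf("duplicate non-repeated read for reader %s case %s (%s)",
                   dup$radiologist_id[1L], dup$case_id[1L], dup$pathology[1L]))
    }
    dup2 <- reads[design == "repeated",
                  .N, by = .(radiologist_id, case_id, pathology, assisted,
                             clinical_history)][N > 1L]
    if (nrow(dup2)) {
      stop(sprintf("duplicate repeated-design read for reader %s case %s",
                   dup2$radiologist_id[1L], dup2$case_id[1L]))
    }
  }
  check_prob_range(truths$truth_prob, "truths$truth_prob")
  check_prob_range(ai$ai_prob, "ai$ai_prob")
  if (anyDuplicated(truths[, .(case_id, pathology)])) {
    stop("truths: more than one row per (case_id, pathology)")
  }
  if (anyDuplicated(ai[, .(case_id, pathology)])) {
    stop("ai: more than one row per (case_id, pathology)")
  }
  if (!"truth_label" %in% names(truths)) {
    truths[, truth_label := truth_label_from_prob(truth_prob, truth_threshold,
                                                  truth_rule)]
  }

  # referential integrity: every read resolves to one truth and one AI row
  if (nrow(reads)) {
    key_reads <- unique(reads[, .(case_id, pathology)])
    miss_t <- key_reads[!truths, on = c("case_id", "pathology")]
    if (nrow(miss_t)) {
      stop(sprintf("integrity error: read references (%s, %s) with no truth row",
                   miss_t$case_id[1L], miss_t$pathology[1L]))
    }
    miss_a <- key_reads[!ai, on = c("case_id", "pathology")]
    if (nrow(miss_a)) {
      stop(sprintf("integrity error: read references (%s, %s) with no AI row",
                   miss_a$case_id[1L], miss_a$pathology[1L]))
    }
  }
  if (!is.null(profiles)) {
    profiles <- as.data.table(profiles)
    check_columns(profiles, c("radiologist_id", "years_experience",
                              "thoracic_subspecialty", "ai_experience"),
                  "profiles")
    if (anyDuplicated(profiles$radiologist_id)) {
      stop("profiles: more than one row per radiologist_id")
    }
    if (any(profiles$years_experience < 0, na.rm = TRUE)) {
      stop("profiles$years_experience must be nonnegative")
    }
  }
  structure(list(reads = reads, truths = truths, ai = ai,
                 profiles = profiles, pathologies = pathologies),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("<study_bundle>\n")
  cat(sprintf("  reads:    %d (%d readers, %d cases)\n", nrow(x$reads),
              length(unique(x$reads$radiologist_id)),
              length(unique(x$reads$case_id))))
  cat(sprintf("  truths:   %d  ai: %d  pathologies: %d\n",
              nrow(x$truths), nrow(x$ai), length(x$pathologies)))
  cat(sprintf("  profiles: %s\n",
              if (is.null(x$profiles)) "none" else nrow(x$profiles)))
  invisible(x)
}

#' Load a study bundle from delimited files
#'
#' Files are UTF-8 comma-separated with a header row; booleans are 0/1 and
#' identifiers are opaque strings. Column renames can be supplied through
#' `schema`, e.g. `list(reads = c(predicted_prob = "prob"))` maps the file's
#' `prob` column onto `predicted_prob`.
#'
#' @param paths named list/vector with elements `reads`, `truths`, `ai` and
#'   optionally `profiles`.
#' @param schema optional per-table column rename maps (canonical = file name).
#' @param pathologies pathology list (default taken from the truth table's
#'   labels, ordered by [default_pathologies()] where applicable).
#' @param ... passed to [study_bundle()].
#' @return a validated `study_bundle`.
#' @export
load_bundle <- function(paths, schema = NULL, pathologies = NULL, ...) {
  read_one <- function(key, required = TRUE) {
    p <- paths[[key]]
    if (is.null(p)) {
      if (required) stop("load_bundle: paths$", key, " is missing")
      return(NULL)
    }
    if (!file.exists(p)) stop("load_bundle: file not found: ", p)
    df <- fread(p, colClasses = list(character = intersect(
      c("radiologist_id", "case_id", "pathology", "design"),
      names(fread(p, nrows = 0L)))))
    ren <- schema[[key]]
    if (!is.null(ren)) setnames(df, old = unname(ren), new = names(ren),
                                skip_absent = TRUE)
    df
  }
  reads <- read_one("reads")
  truths <- read_one("truths")
  ai <- read_one("ai")
  profiles <- read_one("profiles", required = FALSE)
  if (is.null(pathologies)) {
    labs <- unique(truths$pathology)
    pathologies <- c(intersect(default_pathologies(), labs),
                     setdiff(labs, default_pathologies()))
  }
  b <- study_bundle(reads, truths, ai, profiles, pathologies = pathologies, ...)
  message(sprintf("loaded bundle: %d reads, %d truths, %d ai rows, %s profiles",
                  nrow(b$reads), nrow(b$truths), nrow(b$ai),
                  if (is.null(b$profiles)) 0L else nrow(b$profiles)))
  b
}

#' Write a study bundle to a directory of CSV files
#'
#' @param bundle a `study_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reads = file.path(dir, "reads.csv"),
             truths = file.path(dir, "truths.csv"),
             ai = file.path(dir, "ai.csv"))
  fwrite(bundle$reads, paths[["reads"]])
  fwrite(bundle$truths, paths[["truths"]])
  fwrite(bundle$ai, paths[["ai"]])
  if (!is.null(bundle$profiles)) {
    paths <- c(paths, profiles = file.path(dir, "profiles.csv"))
    fwrite(bundle$profiles, paths[["profiles"]])
  }
  invisible(paths)
}
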