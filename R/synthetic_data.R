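# Synthetic reader-study generator.
#
# Emulates the structure of a two-design chest X-ray reader study: 107
# non-repeated-design readers (60 cases each, 30 assisted / 30 unassisted,
# half of each with clinical histories), 33 repeated-design readers (60 cases
# under all four conditions), a 324-case pool, 15 pathologies with
# heterogeneous prevalence, continuous expert-consensus truths, AI
# predictions with a controllable signed-error distribution, and per-reader
# heterogeneous true treatment effects tau_r on absolute error.
#
# Every downstream stage has a recovery test against the emitted truth
# record, which is never visible to analysis code outside of tests.

#' Default pathology prevalence map
#'
#' Fifteen labels with heterogeneous prevalence; five exceed the 10%
#' high-prevalence cutoff used by the treatment-effect shrinkage analyses.
#' @return named numeric vector (proportions in \[0,1\]).
#' @export
default_prevalences <- function() {
  c(abnormal = 0.60, airspace_opacity = 0.35, atelectasis = 0.15,
    bacterial_lobar_pneumonia = 0.05, cardiomediastinal_abnormality = 0.20,
    cardiomegaly = 0.12, consolidation = 0.08, edema = 0.10, lesion = 0.06,
    pleural_effusion = 0.15, pleural_other = 0.03, pneumothorax = 0.03,
    rib_fracture = 0.04, shoulder_fracture = 0.02,
    support_device_hardware = 0.30)
}

#' Simulation configuration
#'
#' Defaults are the study conditions the generator emulates: reader counts
#' 107/33, 60 cases per reader split 30/30 by assistance, a 324-case pool and
#' 15 pathologies. Skill and effect-size defaults are on the 0-100 absolute
#' error scale: mean unassisted error 10 (observed reader averages span
#' roughly 6-14), mean treatment effect 0.06 with variance 0.35 (so the IQR
#' of true effects is about 0.8).
#'
#' @param n_readers_nonrepeated,n_readers_repeated reader counts per design.
#' @param n_cases_per_reader cases read per reader (must be even).
#' @param case_pool_size size of the shared case pool.
#' @param pathology_prevalences named map label -> prevalence in \[0,1\].
#' @param truth_model Beta parameters (on \[0,1\], scaled to 0-100) for
#'   truth probabilities of present and absent cases; draws are rejected
#'   across the 50 threshold so realized prevalence converges to the map.
#' @param reader_skill mean/sd of per-reader mean unassisted absolute error
#'   mu_r^u (truncated below at `min`).
#' @param te_heterogeneity mean and variance of the per-reader true
#'   treatment effect tau_r, plus `skill_slope`: tau_r gains
#'   `skill_slope * (mu_r^u - mean skill)`, planting a true slope for
#'   split-sampling recovery tests (default 0: effect independent of skill).
#' @param read_noise `shape` of the Gamma draw for per-read absolute error
#'   (variance = mean^2/shape); `Inf` gives noiseless reads equal to the mean.
#' @param ai_error_model signed AI error: magnitude ~ Gamma(`shape`,
#'   mean `scale`), sign positive with probability `p_positive`, plus
#'   `location` shift.
#' @param characteristics marginal rates for thoracic subspecialty and AI
#'   experience, log-scale sd of years of experience around `years_median`,
#'   `missing_rate` of absent survey profiles, and `link` (length-3
#'   coefficients adding to tau_r for experience<=median/thoracic/AI-exp;
#'   default all 0, i.e. characteristics carry no signal).
#' @param mechanistic reader AI-anchoring weights for mechanistic mode and
#'   `mc_reps` Monte-Carlo draws for its internal tau_r oracle.
#' @param mode `"direct"` (errors drawn around stated reader means) or
#'   `"mechanistic"` (assisted prediction is a weighted blend of the
#'   reader's own draw and the AI prediction).
#' @param seed default seed used when [generate_study()] is not given one.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_readers_nonrepeated = 107L,
                       n_readers_repeated = 33L,
                       n_cases_per_reader = 60L,
                       case_pool_size = 324L,
                       pathology_prevalences = default_prevalences(),
                       truth_model = list(present = c(8, 2), absent = c(2, 18)),
                       reader_skill = list(mean = 10, sd = 2, min = 1),
                       te_heterogeneity = list(mean = 0.06, var = 0.35,
                                               skill_slope = 0),
                       read_noise = list(shape = 1.5),
                       ai_error_model = list(location = 0, scale = 12,
                                             shape = 1, p_positive = 0.5),
                       characteristics = list(thoracic_rate = 0.26,
                                              ai_exp_rate = 0.54,
                                              years_median = 6,
                                              years_log_sd = 0.6,
                                              missing_rate = 0.03,
                                              link = c(0, 0, 0)),
                       mechanistic = list(weight_mean = 0.3, weight_sd = 0.1,
                                          mc_reps = 50L),
                       mode = c("direct", "mechanistic"),
                       seed = 1L) {
  mode <- match.arg(mode)
  pathology_prevalences <- unlist(pathology_prevalences)  # JSON configs
  if (n_cases_per_reader %% 2L != 0L) {
    stop("n_cases_per_reader must be even (cases split half/half by assistance)")
  }
  pr <- pathology_prevalences
  if (is.null(names(pr)) || any(!nzchar(names(pr)))) {
    stop("pathology_prevalences must be a named vector")
  }
  if (any(pr < 0 | pr > 1)) stop("prevalences must lie in [0,1]")
  if (te_heterogeneity$var < 0) stop("te_heterogeneity$var must be >= 0")
  if (n_cases_per_reader > case_pool_size) {
    stop("n_cases_per_reader cannot exceed case_pool_size")
  }
  structure(list(n_readers_nonrepeated = as.integer(n_readers_nonrepeated),
                 n_readers_repeated = as.integer(n_readers_repeated),
                 n_cases_per_reader = as.integer(n_cases_per_reader),
                 case_pool_size = as.integer(case_pool_size),
                 pathology_prevalences = pr,
                 truth_model = truth_model,
                 reader_skill = reader_skill,
                 te_heterogeneity = te_heterogeneity,
                 read_noise = read_noise,
                 ai_error_model = ai_error_model,
                 characteristics = characteristics,
                 mechanistic = mechanistic,
                 mode = mode, seed = as.integer(seed)),
            class = "sim_config")
}

# Gamma draw with exact mean m and shape k; k = Inf degenerates to m.
rgamma_mean <- function(n, m, shape) {
  if (is.infinite(shape)) return(rep(m, length.out = n))
  out <- numeric(n)
  pos <- m > 0
  out[pos] <- rgamma(sum(pos), shape = shape, scale = m[pos] / shape)
  out
}

# Truth probability draws on [0,100]: present conditioned >= 50,
# absent conditioned < 50, by rejection from the configured Betas.
draw_truths <- function(n, present, beta_par) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- 100 * rbeta(length(todo), beta_par[1], beta_par[2])
    ok <- if (present) x >= 50 else x < 50
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

# Feasibility-aware prediction sign: fair coin among sides that stay inside
# [0,100]; if neither side fits, the smaller-violation side is used and the
# prediction clips (the realized error is recorded post-clip).
reconstruct_prediction <- function(truth, err) {
  up_ok <- truth + err <= 100
  dn_ok <- truth - err >= 0
  coin <- runif(length(err)) < 0.5
  sign <- ifelse(up_ok & dn_ok, ifelse(coin, 1, -1),
                 ifelse(up_ok, 1, ifelse(dn_ok, -1,
                        ifelse(100 - truth >= truth, 1, -1))))
  pmin(100, pmax(0, truth + sign * err))
}

#' Generate a synthetic reader study with known ground truth
#'
#' Returns the public bundle plus a truth record holding the per-reader true
#' parameters (mu_r^u, tau_r), case truths, AI signed errors and the realized
#' (post-clip) per-read errors. Analysis code must never read the truth
#' record; it exists for recovery tests.
#'
#' In direct mode each unassisted read's absolute error is Gamma-distributed
#' with mean mu_r^u and each assisted read's with mean max(0, mu_r^u - tau_r)
#' (a forced truncation is recorded in the truth record's notes). In
#' mechanistic mode the assisted prediction is
#' (1-w_r) * own draw + w_r * ai_prob and tau_r is a Monte-Carlo estimate
#' from an internal oracle.
#'
#' @param config a [sim_config()].
#' @param seed integer; defaults to `config$seed`.
#' @return list with elements `bundle` (a `study_bundle`) and `truth`
#'   (class `sim_truth`).
#' @export
generate_study <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  prev <- config$pathology_prevalences
  pathologies <- names(prev)
  n_case <- config$case_pool_size
  case_ids <- sprintf("case%04d", seq_len(n_case))

  # --- case pool: truths and AI predictions -------------------------------
  tm <- config$truth_model
  truth_list <- lapply(pathologies, function(p) {
    present <- rbinom(n_case, 1L, prev[[p]])
    tp <- numeric(n_case)
    if (any(present == 1L)) tp[present == 1L] <-
        draw_truths(sum(present), TRUE, tm$present)
    if (any(present == 0L)) tp[present == 0L] <-
        draw_truths(sum(present == 0L), FALSE, tm$absent)
    data.table(case_id = case_ids, pathology = p, truth_prob = tp)
  })
  truths <- rbindlist(truth_list)
  truths[, truth_label := truth_label_from_prob(truth_prob)]

  am <- config$ai_error_model
  n_ai <- nrow(truths)
  mag <- rgamma_mean(n_ai, rep(am$scale, n_ai), am$shape)
  sgn <- ifelse(runif(n_ai) < am$p_positive, 1, -1)
  ai_err_drawn <- am$location + sgn * mag
  ai <- truths[, .(case_id, pathology)]
  ai[, ai_prob := pmin(100, pmax(0, truths$truth_prob + ai_err_drawn))]
  ai_signed_error <- ai$ai_prob - truths$truth_prob  # realized, post-clip

  # --- readers ------------------------------------------------------------
  n_nr <- config$n_readers_nonrepeated
  n_rp <- config$n_readers_repeated
  reader_ids <- c(sprintf("N%03d", seq_len(n_nr)),
                  if (n_rp > 0) sprintf("P%03d", seq_len(n_rp)))
  designs <- c(rep("non_repeated", n_nr), rep("repeated", n_rp))
  sk <- config$reader_skill
  mu_u <- pmax(sk$min, rnorm(n_nr + n_rp, sk$mean, sk$sd))
  th <- config$te_heterogeneity
  tau <- th$mean + th$skill_slope * (mu_u - sk$mean) +
    rnorm(n_nr + n_rp, 0, sqrt(th$var))
  w <- pmin(1, pmax(0, rnorm(n_nr + n_rp, config$mechanistic$weight_mean,
                             config$mechanistic$weight_sd)))

  # --- characteristics (drawn before reads so a link can shift tau) -------
  ch <- config$characteristics
  years <- exp(rnorm(n_nr + n_rp, log(ch$years_median), ch$years_log_sd))
  thoracic <- rbinom(n_nr + n_rp, 1L, ch$thoracic_rate)
  ai_exp <- rbinom(n_nr + n_rp, 1L, ch$ai_exp_rate)
  if (any(ch$link != 0)) {
    tau <- tau + ch$link[1] * (years <= ch$years_median) +
      ch$link[2] * thoracic + ch$link[3] * ai_exp
  }
  keep_profile <- runif(n_nr + n_rp) >= ch$missing_rate
  profiles <- data.table(radiologist_id = reader_ids,
                         years_experience = round(years, 1),
                         thoracic_subspecialty = thoracic,
                         ai_experience = ai_exp)[keep_profile]

  notes <- character(0)
  mean_a <- mu_u - tau
  if (config$mode == "direct" && any(mean_a < 0)) {
    idx <- which(mean_a < 0)
    notes <- c(notes, sprintf(
      "assisted mean truncated at 0 for reader %s (mu=%.3f, tau=%.3f)",
      reader_ids[idx], mu_u[idx], tau[idx]))
    warning(sprintf(
      "%d reader(s) had tau_r > mu_r^u; assisted mean truncated at 0", length(idx)))
  }

  # --- read schedule ------------------------------------------------------
  npr <- config$n_cases_per_reader
  half <- npr %/% 2L
  quarter <- half %/% 2L
  sched <- vector("list", n_nr + n_rp)
  for (j in seq_along(reader_ids)) {
    cases <- sample(case_ids, npr)
    if (designs[j] == "non_repeated") {
      assisted <- c(rep(1L, half), rep(0L, half))
      hist <- c(rep(1L, quarter), rep(0L, half - quarter),
                rep(1L, quarter), rep(0L, half - quarter))
      sched[[j]] <- data.table(radiologist_id = reader_ids[j],
                               case_id = cases, design = "non_repeated",
                               assisted = assisted, clinical_history = hist,
                               session = NA_integer_)
    } else {
      # every case under all four conditions; condition order randomized per
      # reader by assigning conditions to sessions (metadata only)
      cond <- CJ(case_id = cases, assisted = c(0L, 1L),
                 clinical_history = c(0L, 1L))
      cond[, session := sample(4L), by = case_id]
      sched[[j]] <- data.table(radiologist_id = reader_ids[j],
                               case_id = cond$case_id, design = "repeated",
                               assisted = cond$assisted,
                               clinical_history = cond$clinical_history,
                               session = cond$session)
    }
  }
  sched <- rbindlist(sched)

  # expand across pathologies and attach truths/AI
  reads <- sched[rep(seq_len(nrow(sched)), each = length(pathologies))]
  reads[, pathology := rep(pathologies, times = nrow(sched))]
  reads <- merge(reads, truths[, .(case_id, pathology, truth_prob)],
                 by = c("case_id", "pathology"), sort = FALSE)
  reads <- merge(reads, ai, by = c("case_id", "pathology"), sort = FALSE)

  ridx <- match(reads$radiologist_id, reader_ids)
  shape <- config$read_noise$shape
  if (config$mode == "direct") {
    mean_read <- ifelse(reads$assisted == 1L,
                        pmax(0, mu_u[ridx] - tau[ridx]), mu_u[ridx])
    err <- rgamma_mean(nrow(reads), mean_read, shape)
    reads[, predicted_prob := reconstruct_prediction(truth_prob, err)]
  } else {
    own_err <- rgamma_mean(nrow(reads), mu_u[ridx], shape)
    own_pred <- reconstruct_prediction(reads$truth_prob, own_err)
    blend <- ifelse(reads$assisted == 1L,
                    (1 - w[ridx]) * own_pred + w[ridx] * reads$ai_prob,
                    own_pred)
    reads[, predicted_prob := pmin(100, pmax(0, blend))]
    tau <- mechanistic_tau_oracle(mu_u, w, truths, ai, config)
  }
  realized_error <- abs(reads$predicted_prob - reads$truth_prob)

  bundle <- study_bundle(
    reads[, .(radiologist_id, case_id, pathology, design, assisted,
              clinical_history, session, predicted_prob)],
    truths, ai, profiles, pathologies = pathologies)

  truth_rec <- structure(list(
    readers = data.table(radiologist_id = reader_ids, design = designs,
                         mu_u = mu_u, tau = tau, ai_weight = w),
    case_truths = truths,
    ai_signed_error = data.table(case_id = truths$case_id,
                                 pathology = truths$pathology,
                                 signed_error = ai_signed_error),
    realized_errors = data.table(
      radiologist_id = reads$radiologist_id, case_id = reads$case_id,
      pathology = reads$pathology, assisted = reads$assisted,
      clinical_history = reads$clinical_history, error = realized_error),
    notes = notes, config = config, seed = seed), class = "sim_truth")
  list(bundle = bundle, truth = truth_rec)
}

# Monte-Carlo oracle for tau_r in mechanistic mode: expected unassisted minus
# expected assisted absolute error over the case pool.
mechanistic_tau_oracle <- function(mu_u, w, truths, ai, config) {
  reps <- config$mechanistic$mc_reps
  shape <- config$read_noise$shape
  tp <- rep(truths$truth_prob, reps)
  ap <- rep(ai$ai_prob, reps)
  vapply(seq_along(mu_u), function(j) {
    err <- rgamma_mean(length(tp), rep(mu_u[j], length(tp)), shape)
    own <- reconstruct_prediction(tp, err)
    u_err <- abs(own - tp)
    a_pred <- pmin(100, pmax(0, (1 - w[j]) * own + w[j] * ap))
    mean(u_err) - mean(abs(a_pred - tp))
  }, numeric(1))
}

#' Generate reader characteristic profiles
#'
#' Standalone profile generator: marginal Bernoulli rates for thoracic
#' subspecialty and AI experience and a log-normal years-of-experience
#' distribution. Used by [generate_study()] internally; exported for
#' building profile tables for an existing reader list.
#'
#' @param reader_ids character vector of reader identifiers.
#' @param config a [sim_config()] (its `characteristics` entry is used).
#' @param seed integer seed.
#' @return data.table of `ReaderProfile` rows.
#' @export
generate_characteristics <- function(reader_ids, config = sim_config(),
                                     seed = config$seed) {
  if (length(reader_ids) == 0L) stop("reader list must be nonempty")
  ch <- config$characteristics
  for (r in c("thoracic_rate", "ai_exp_rate", "missing_rate")) {
    if (ch[[r]] < 0 || ch[[r]] > 1) stop(r, " must lie in [0,1]")
  }
  set.seed(seed)
  n <- length(reader_ids)
  keep <- runif(n) >= ch$missing_rate
  data.table(radiologist_id = reader_ids,
             years_experience = round(exp(rnorm(n, log(ch$years_median),
                                                ch$years_log_sd)), 1),
             thoracic_subspecialty = rbinom(n, 1L, ch$thoracic_rate),
             ai_experience = rbinom(n, 1L, ch$ai_exp_rate))[keep]
}

#' Write the truth record's summary tables as JSON
#'
#' Per-read realized errors are omitted from the JSON (they can be as large
#' as the read table itself); they remain available on the in-memory object.
#' @param truth a `sim_truth`.
#' @param path output file.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(list(readers = truth$readers,
                            ai_signed_error = truth$ai_signed_error,
                            notes = truth$notes, seed = truth$seed),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
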