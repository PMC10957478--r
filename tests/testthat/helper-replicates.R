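# Replicated-simulation helpers for the acceptance-style recovery checks.
# The study design mirrors the emulated experiment at desk scale: 140
# non-repeated readers, 60 cases each (30 unassisted / 30 assisted), one
# diagnostic task.

accept_config <- function(skill_slope = 0, te_var = 0.35) {
  sim_config(n_readers_nonrepeated = 140L, n_readers_repeated = 0L,
             n_cases_per_reader = 60L, case_pool_size = 324L,
             pathology_prevalences = c(abnormal = 0.3),
             te_heterogeneity = list(mean = 0.06, var = te_var,
                                     skill_slope = skill_slope))
}

# One replicate of the naive vs split-sampling comparison, plus the plug-in
# probability limits computed from the replicate's own drawn true parameters
# (the "known simulation variances"):
#   per-read error variance sigma_r^2 = mu_r^2 / shape      (Gamma draw)
#   measurement noise of a J-case mean: E[sigma_r^2] / J
#   naive slope limit  = (Cov(tau,mu) + Vfull) / (Var(mu) + Vfull)
#   true beta          = Cov(tau,mu) / Var(mu)
#   lambda (loo x)     = Var(mu) / (Var(mu) + Vloo)
split_replicate <- function(cfg, seed) {
  sim <- generate_study(cfg, seed = seed)
  naive <- suppressWarnings(suppressMessages(
    split_regression(sim$bundle, "naive", adjust = FALSE)))
  split <- suppressWarnings(suppressMessages(
    split_regression(sim$bundle, "te", adjust = TRUE)))
  mu <- sim$truth$readers$mu_u
  tau <- sim$truth$readers$tau
  popvar <- function(x) mean((x - mean(x))^2)
  vmu <- popvar(mu)
  cov_tm <- mean((tau - mean(tau)) * (mu - mean(mu)))
  nu <- cfg$n_cases_per_reader / 2L
  esig2 <- mean(mu^2) / cfg$read_noise$shape
  v_full <- esig2 / nu
  v_loo <- esig2 / (nu - 1L)
  list(naive_gamma = naive$coef[["x"]],
       split_gamma = split$gamma_hat,
       split_beta = split$beta_hat,
       lambda_hat = split$lambda_hat,
       naive_limit = (cov_tm + v_full) / (vmu + v_full),
       beta_true = cov_tm / vmu,
       lambda_loo = vmu / (vmu + v_loo))
}

run_split_replicates <- function(R, cfg, seed0) {
  res <- lapply(seq_len(R), function(r) split_replicate(cfg, seed0 + r))
  as.data.frame(do.call(rbind, lapply(res, function(x) unlist(x))))
}

# One replicate of treatment-effect shrinkage recovery against the truth
# record: unclipped prior-variance plug-in and the posterior-vs-raw MSE.
eb_replicate <- function(cfg, seed) {
  sim <- generate_study(cfg, seed = seed)
  s <- reader_summaries(sim$bundle, "abs_error", "all")
  eff <- s[s$condition == "effect"]
  prior <- estimate_prior(eff$value, eff$se)
  res <- shrink_all(eff[, c("radiologist_id", "value", "se")])
  truth <- sim$truth$readers
  tau <- truth$tau[match(res$table$radiologist_id, truth$radiologist_id)]
  c(sigma0_raw = prior$sigma0_sq_raw,
    mse_raw = mean((res$table$raw - tau)^2),
    mse_post = mean((res$table$posterior_mean - tau)^2))
}

# One replicate of the null-calibration check: no TE heterogeneity, no
# AI-error link; a random reader split and the AI-error bins should both
# reject at the nominal rate only.
null_replicate <- function(cfg, seed) {
  sim <- generate_study(cfg, seed = seed)
  ids <- unique(sim$bundle$reads$radiologist_id)
  set.seed(seed * 13L + 1L)
  assign <- median_split(setNames(runif(length(ids)), ids))
  sub_p <- suppressWarnings(suppressMessages(
    subgroup_effect_report(assign, sim$bundle, "all")))$joint_test$p_value
  bin_p <- suppressWarnings(suppressMessages(
    ai_error_bin_analysis(sim$bundle, error_kind = "absolute")
  ))$joint_test$p_value
  c(sub_p = sub_p, bin_p = bin_p)
}
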