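test_that("median_split applies the <= rule with configurable ties", {
  a <- median_split(c(r1 = 1, r2 = 2, r3 = 3))
  expect_equal(unname(a$groups[c("r1", "r2", "r3")]),
               c("low", "low", "high"))
  expect_equal(a$splitter$cutoff, 2)
  alt <- median_split(c(r1 = 1, r2 = 2, r3 = 3), tie_rule = "lt")
  expect_equal(unname(alt$groups[["r2"]]), "high")
  expect_error(median_split(c(r1 = 5, r2 = 5)), "degenerate")
  expect_error(median_split(c(r1 = 5)), "at least 2")
  expect_error(median_split(c(1, 2, 3)), "named")
})

test_that("oracle_split groups by shrunk treatment effects", {
  res <- structure(list(
    table = data.table::data.table(
      radiologist_id = c("a", "b", "c", "d"),
      raw = c(-2, -2, 2, 2), se = 1,
      posterior_mean = c(-1, -1, 1, 1), posterior_var = 0.5),
    prior = list(mu0 = 0, sigma0_sq = 1, clipped = FALSE),
    excluded_readers = character(0)), class = "shrinkage_result")
  a <- oracle_split(res)
  expect_equal(unname(a$groups[c("a", "b")]), c("low", "low"))
  expect_equal(unname(a$groups[c("c", "d")]), c("high", "high"))
  expect_equal(as.integer(a$sizes), c(2L, 2L))
  # symmetric values around 0 -> equal group sizes (even n)
  res$table$posterior_mean <- c(-3, -1, 1, 3)
  a2 <- oracle_split(res)
  expect_equal(as.integer(a2$sizes), c(2L, 2L))
})

test_that("combined characteristics split recovers a planted perfect signal", {
  set.seed(10)
  n <- 40L
  prof <- data.frame(radiologist_id = sprintf("r%02d", 1:n),
                     years_experience = runif(n, 1, 20),
                     thoracic_subspecialty = rep(c(0L, 1L), n / 2),
                     ai_experience = rbinom(n, 1, 0.5))
  te <- setNames(as.numeric(prof$thoracic_subspecialty), prof$radiologist_id)
  a <- combined_characteristics_split(prof, te, seed = 3L)
  # noise-free link: test-half groups reproduce the thoracic partition
  expect_equal(unname(a$groups[prof$thoracic_subspecialty == 1L]),
               rep("high", n / 2))
  expect_equal(unname(a$groups[prof$thoracic_subspecialty == 0L]),
               rep("low", n / 2))
  # deterministic given seed
  a2 <- combined_characteristics_split(prof, te, seed = 3L)
  expect_identical(a$groups, a2$groups)
  expect_length(a$coefficients, 2L)
})

test_that("constant training characteristics are dropped with a warning", {
  n <- 20L
  prof <- data.frame(radiologist_id = sprintf("r%02d", 1:n),
                     years_experience = runif(n, 1, 20),
                     thoracic_subspecialty = 0L,
                     ai_experience = rbinom(n, 1, 0.5))
  te <- setNames(rnorm(n), prof$radiologist_id)
  expect_warning(combined_characteristics_split(prof, te, seed = 1L),
                 "thoracic")
})

test_that("subgroup_effect_report runs the model, joint test and t-test", {
  sim <- generate_study(small_sim_config(), seed = 77L)
  s <- reader_summaries(sim$bundle, "abs_error", "all")
  eff <- s[s$condition == "effect", ]
  shr <- shrink_all(eff[, c("radiologist_id", "value", "se")])
  assign <- oracle_split(shr)
  rep1 <- suppressWarnings(
    subgroup_effect_report(assign, sim$bundle, "all",
                           shrunk_te = setNames(shr$table$posterior_mean,
                                                shr$table$radiologist_id)))
  expect_s3_class(rep1$joint_test, "test_result")
  expect_s3_class(rep1$t_test, "test_result")
  expect_equal(nrow(rep1$subgroups), 2L)
  # oracle split: high-group TE >= low-group TE by construction
  expect_gte(rep1$subgroups$te[rep1$subgroups$subgroup == "high"],
             rep1$subgroups$te[rep1$subgroups$subgroup == "low"])
})

test_that("per-pathology scope applies BH across pathologies", {
  cfg <- sim_config(n_readers_nonrepeated = 10L, n_readers_repeated = 0L,
                    n_cases_per_reader = 20L, case_pool_size = 40L,
                    pathology_prevalences = c(abnormal = 0.5, edema = 0.3,
                                              lesion = 0.2))
  sim <- generate_study(cfg, seed = 13L)
  ids <- unique(sim$bundle$reads$radiologist_id)
  assign <- median_split(setNames(seq_along(ids), ids))
  out <- suppressWarnings(suppressMessages(
    subgroup_effect_report(assign, sim$bundle, "per_pathology")))
  expect_equal(nrow(out$table), 3L)
  expect_true(all(c("p_value", "p_adjusted", "reject_fdr1") %in%
                    names(out$table)))
  expect_equal(out$table$p_adjusted,
               p.adjust(out$table$p_value, "BH"))
})

test_that("high_prevalence_filter is strict at the threshold", {
  truths <- data.frame(
    case_id = rep(sprintf("c%02d", 1:50), 3),
    pathology = rep(c("a12", "b10", "c00"), each = 50),
    truth_prob = 0,
    truth_label = c(rep(c(1L, 0L), c(6, 44)),   # 12%
                    rep(c(1L, 0L), c(5, 45)),   # exactly 10%
                    rep(0L, 50)))               # 0%
  expect_equal(high_prevalence_filter(truths), "a12")
  truths$truth_label <- 0L
  expect_length(high_prevalence_filter(truths), 0L)
})

test_that("bin assignment respects left-closed edges and boundary containment", {
  edges <- default_bin_edges("absolute")
  expect_equal(hetfx:::assign_bins(c(0, 19.999, 20, 80, 100), edges),
               c(1L, 1L, 2L, 5L, 5L))
  expect_error(hetfx:::assign_bins(101, edges), "outside")
  se <- default_bin_edges("signed")
  expect_equal(hetfx:::assign_bins(c(-100, -80, 0, 100), se),
               c(1L, 2L, 6L, 10L))
})

test_that("homogeneous effect gives identical bin TEs and p ~ 1", {
  # assisted error = unassisted - 1 everywhere, constructed by hand
  readers <- sprintf("r%02d", 1:8)
  errs <- lapply(readers, function(r) {
    list(u = setNames(rep(20, 10), sprintf("%s_u%02d", r, 1:10)),
         a = setNames(rep(19, 10), sprintf("%s_a%02d", r, 1:10)))
  })
  names(errs) <- readers
  b <- bundle_from_errors(errs)
  # spread AI errors over bins by varying ai_prob
  b$ai$ai_prob <- seq(0, 100, length.out = nrow(b$ai))
  tab <- suppressWarnings(suppressMessages(
    ai_error_bin_analysis(b, error_kind = "absolute")))
  expect_true(all(abs(tab$bins$te - 1) < 1e-10))
  expect_gt(tab$joint_test$p_value, 0.999)
})

test_that("a single all-covering bin reproduces the overall TE", {
  sim <- generate_study(small_sim_config(), seed = 99L)
  tab <- suppressWarnings(suppressMessages(
    ai_error_bin_analysis(sim$bundle, edges = c(0, 100))))
  dt <- hetfx:::read_errors(sim$bundle, "all", "abs_error")
  overall <- suppressWarnings(treatment_effect_model(dt))
  expect_equal(tab$bins$te, overall$te, tolerance = 1e-10)
  expect_equal(sum(tab$bins$n), nrow(dt))
})

test_that("signed-error bins distinguish under- from over-estimating AI", {
  cfg <- small_sim_config(
    ai_error_model = list(location = 0, scale = 30, shape = 2,
                          p_positive = 0.8))
  sim <- generate_study(cfg, seed = 23L)
  tab <- suppressWarnings(suppressMessages(
    ai_error_bin_analysis(sim$bundle, error_kind = "signed")))
  # with strong positive AI bias most reads land in positive-error bins
  pos_n <- sum(tab$bins$n[tab$bins$bin > 5L])
  expect_gt(pos_n / sum(tab$bins$n), 0.5)
  expect_true(all(diff(tab$bins$bin) > 0))
})

test_that("mechanistic AI anchoring makes bad AI harmful (rank check)", {
  # readers lean on the AI; TE should fall as AI absolute error rises
  cfg <- sim_config(n_readers_nonrepeated = 40L, n_readers_repeated = 0L,
                    n_cases_per_reader = 40L, case_pool_size = 120L,
                    pathology_prevalences = c(abnormal = 0.4),
                    mode = "mechanistic",
                    mechanistic = list(weight_mean = 0.6, weight_sd = 0.05,
                                       mc_reps = 5L),
                    ai_error_model = list(location = 0, scale = 25, shape = 1,
                                          p_positive = 0.5))
  sim <- generate_study(cfg, seed = 41L)
  tab <- suppressWarnings(suppressMessages(
    ai_error_bin_analysis(sim$bundle, edges = c(0, 20, 60, 100))))
  te <- tab$bins$te
  expect_gt(te[1L], te[length(te)])
})

test_that("auroc_bin_analysis reports per-bin AUROCs or aborts cleanly", {
  sim <- generate_study(small_sim_config(), seed = 61L)
  res <- tryCatch(
    auroc_bin_analysis(sim$bundle, edges = c(0, 30, 100), boot_reps = 20L),
    error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "not feasible")
  } else {
    expect_s3_class(res$f_test, "test_result")
    expect_true(all(res$bins$auroc_unassisted >= 0 &
                      res$bins$auroc_unassisted <= 1))
  }
})
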