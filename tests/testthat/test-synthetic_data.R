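test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_cases_per_reader = 59L), "even")
  expect_error(sim_config(pathology_prevalences = c(a = 1.2)), "\\[0,1\\]")
  expect_error(sim_config(pathology_prevalences = 0.5), "named")
  expect_error(sim_config(te_heterogeneity = list(mean = 0, var = -1,
                                                  skill_slope = 0)), ">= 0")
})

test_that("generated bundles have the stated shape and are seed-reproducible", {
  cfg <- small_sim_config()
  sim1 <- generate_study(cfg, seed = 5L)
  sim2 <- generate_study(cfg, seed = 5L)
  expect_identical(sim1$bundle$reads, sim2$bundle$reads)
  expect_identical(sim1$truth$readers, sim2$truth$readers)

  sim3 <- generate_study(cfg, seed = 6L)
  # different draws, identical shape
  expect_false(identical(sim1$bundle$reads$predicted_prob,
                         sim3$bundle$reads$predicted_prob))
  shape <- function(s) {
    r <- s$bundle$reads
    list(n = nrow(r),
         cond = as.vector(table(r$design, r$assisted)),
         truths = nrow(s$bundle$truths))
  }
  expect_identical(shape(sim1), shape(sim3))

  r <- sim1$bundle$reads
  # non-repeated readers: disjoint assisted/unassisted case sets, 10/10 here
  nr <- r[r$design == "non_repeated" & r$radiologist_id == "N001", ]
  expect_equal(sum(nr$assisted == 1L), sum(nr$assisted == 0L))
  expect_length(intersect(nr$case_id[nr$assisted == 1L],
                          nr$case_id[nr$assisted == 0L]), 0L)
  # repeated readers: every case under all four conditions
  rp <- r[r$design == "repeated" & r$radiologist_id == "P001", ]
  combos <- unique(rp[, c("case_id", "assisted", "clinical_history")])
  expect_equal(nrow(combos), length(unique(rp$case_id)) * 4L)
})

test_that("no-noise, no-effect config yields identical errors and zero TE", {
  cfg <- small_sim_config(
    te_heterogeneity = list(mean = 0, var = 0, skill_slope = 0),
    read_noise = list(shape = Inf))
  sim <- generate_study(cfg, seed = 2L)
  tr <- sim$truth$realized_errors
  merged <- merge(aggregate(error ~ radiologist_id, tr[tr$assisted == 0L, ], mean),
                  aggregate(error ~ radiologist_id, tr[tr$assisted == 1L, ], mean),
                  by = "radiologist_id")
  expect_equal(merged$error.x, merged$error.y, tolerance = 1e-12)
  s <- reader_summaries(sim$bundle, "abs_error", "all")
  expect_true(all(abs(s[s$condition == "effect", ]$value) < 1e-12))
})

test_that("direct mode recovers the planted mean treatment effect (LLN)", {
  # tau = 2 for every reader, many cases: per-reader mean(u) - mean(a) -> 2
  cfg <- sim_config(n_readers_nonrepeated = 30L, n_readers_repeated = 0L,
                    n_cases_per_reader = 300L, case_pool_size = 300L,
                    pathology_prevalences = c(abnormal = 0.4),
                    te_heterogeneity = list(mean = 2, var = 0,
                                            skill_slope = 0))
  sim <- generate_study(cfg, seed = 9L)
  s <- reader_summaries(sim$bundle, "abs_error", "all")
  eff <- s[s$condition == "effect", ]
  expect_equal(mean(eff$value), 2, tolerance = 0.15)
  # per-reader difference is unbiased: grand mean within 3 MC se
  expect_lt(abs(mean(eff$value) - 2), 3 * sd(eff$value) / sqrt(nrow(eff)))
})

test_that("realized pathology prevalence converges to the configured map", {
  cfg <- sim_config(n_readers_nonrepeated = 2L, n_readers_repeated = 0L,
                    n_cases_per_reader = 10L, case_pool_size = 4000L,
                    pathology_prevalences = c(abnormal = 0.6, edema = 0.1))
  sim <- generate_study(cfg, seed = 11L)
  prev <- tapply(sim$bundle$truths$truth_label, sim$bundle$truths$pathology,
                 mean)
  expect_lt(abs(prev[["abnormal"]] - 0.6), 0.04)
  expect_lt(abs(prev[["edema"]] - 0.1), 0.03)
})

test_that("an infeasible assisted mean is truncated with a warning and note", {
  cfg <- small_sim_config(
    reader_skill = list(mean = 2, sd = 0.1, min = 1),
    te_heterogeneity = list(mean = 6, var = 0, skill_slope = 0))
  expect_warning(sim <- generate_study(cfg, seed = 3L), "truncated")
  expect_gt(length(sim$truth$notes), 0L)
})

test_that("generate_characteristics honours rates and missingness", {
  cfg <- sim_config(characteristics = list(thoracic_rate = 0.25,
                                           ai_exp_rate = 0.5,
                                           years_median = 6,
                                           years_log_sd = 0.6,
                                           missing_rate = 0,
                                           link = c(0, 0, 0)))
  ids <- sprintf("r%05d", 1:10000)
  prof <- generate_characteristics(ids, cfg, seed = 4L)
  expect_equal(nrow(prof), 10000L)
  # realized proportions within 3 binomial standard errors
  expect_lt(abs(mean(prof$thoracic_subspecialty) - 0.25),
            3 * sqrt(0.25 * 0.75 / 10000))
  expect_lt(abs(mean(prof$ai_experience) - 0.5), 3 * sqrt(0.25 / 10000))
  expect_gt(min(prof$years_experience), 0)

  cfg1 <- sim_config(characteristics = list(thoracic_rate = 1,
                                            ai_exp_rate = 0.5,
                                            years_median = 6,
                                            years_log_sd = 0.6,
                                            missing_rate = 0,
                                            link = c(0, 0, 0)))
  prof1 <- generate_characteristics(ids[1:50], cfg1, seed = 4L)
  expect_true(all(prof1$thoracic_subspecialty == 1L))
  expect_error(generate_characteristics(character(0), cfg), "nonempty")
  cfg_bad <- cfg
  cfg_bad$characteristics$thoracic_rate <- 1.5
  expect_error(generate_characteristics(ids[1:5], cfg_bad), "\\[0,1\\]")
})

test_that("null characteristics link leaves tau uncorrelated with profiles", {
  cfg <- sim_config(n_readers_nonrepeated = 400L, n_readers_repeated = 0L,
                    n_cases_per_reader = 2L, case_pool_size = 50L,
                    pathology_prevalences = c(abnormal = 0.4),
                    characteristics = list(thoracic_rate = 0.3,
                                           ai_exp_rate = 0.5,
                                           years_median = 6,
                                           years_log_sd = 0.6,
                                           missing_rate = 0,
                                           link = c(0, 0, 0)))
  sim <- generate_study(cfg, seed = 8L)
  m <- merge(sim$truth$readers, sim$bundle$profiles, by = "radiologist_id")
  expect_lt(abs(cor(m$tau, m$thoracic_subspecialty)), 3 / sqrt(400))
  # and a planted link shifts tau for the linked group
  cfg$characteristics$link <- c(0, 1.5, 0)
  sim2 <- generate_study(cfg, seed = 8L)
  m2 <- merge(sim2$truth$readers, sim2$bundle$profiles, by = "radiologist_id")
  gap <- mean(m2$tau[m2$thoracic_subspecialty == 1L]) -
    mean(m2$tau[m2$thoracic_subspecialty == 0L])
  expect_equal(gap, 1.5, tolerance = 0.25)
})

test_that("mechanistic mode records a Monte-Carlo tau consistent with mixing", {
  cfg <- small_sim_config(mode = "mechanistic",
                          mechanistic = list(weight_mean = 0, weight_sd = 0,
                                             mc_reps = 20L))
  sim <- generate_study(cfg, seed = 12L)
  # zero AI weight: assistance changes nothing, tau ~ 0
  expect_lt(max(abs(sim$truth$readers$tau)), 0.6)
})

test_that("write_sim_truth writes the summary JSON", {
  sim <- generate_study(small_sim_config(), seed = 1L)
  f <- withr::local_tempfile(fileext = ".json")
  write_sim_truth(sim$truth, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(nrow(j$readers), nrow(sim$truth$readers))
  expect_equal(j$seed, 1L)
})
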