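# Fixture builders and independent oracles shared across test files.
# All fixtures are built in code; no data files.

# Bundle in which every read's absolute error is exactly specified:
# truth_prob = 50 everywhere, predicted = 50 + error (so error <= 50).
# errs: named list reader -> list(u = c(case = err, ...), a = c(...)).
# design: "non_repeated" (u/a case sets disjoint) or "repeated" (same cases).
bundle_from_errors <- function(errs, design = "non_repeated") {
  rows <- list()
  for (r in names(errs)) {
    for (cond in c("u", "a")) {
      e <- errs[[r]][[cond]]
      if (is.null(e)) next
      rows[[length(rows) + 1L]] <- data.frame(
        radiologist_id = r, case_id = names(e), pathology = "abnormal",
        design = design, assisted = as.integer(cond == "a"),
        clinical_history = 0L, session = NA_integer_,
        predicted_prob = 50 + unname(e))
    }
  }
  reads <- do.call(rbind, rows)
  cases <- unique(reads$case_id)
  truths <- data.frame(case_id = cases, pathology = "abnormal",
                       truth_prob = 50)
  ai <- data.frame(case_id = cases, pathology = "abnormal", ai_prob = 50)
  study_bundle(reads, truths, ai, pathologies = "abnormal")
}

# small single-pathology simulation config used by property tests
small_sim_config <- function(...) {
  sim_config(n_readers_nonrepeated = 12L, n_readers_repeated = 4L,
             n_cases_per_reader = 20L, case_pool_size = 60L,
             pathology_prevalences = c(abnormal = 0.4), ...)
}

# ---- independent oracles ------------------------------------------------

# brute-force two-way cluster sandwich: explicit per-cluster score sums,
# inclusion-exclusion, eigen-truncated like the implementation
oracle_crve <- function(y, X, c1, c2) {
  X <- as.matrix(X)
  A <- solve(t(X) %*% X)
  bhat <- A %*% t(X) %*% y
  e <- as.numeric(y - X %*% bhat)
  meat <- function(cl) {
    m <- matrix(0, ncol(X), ncol(X))
    for (g in unique(cl)) {
      s <- t(X[cl == g, , drop = FALSE]) %*% e[cl == g]
      m <- m + s %*% t(s)
    }
    m
  }
  V <- A %*% (meat(c1) + meat(c2) - meat(paste(c1, c2, sep = "|"))) %*% A
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  V <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  (V + t(V)) / 2
}

# all-pairs AUROC oracle
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# step-up BH oracle: explicit scan for the largest passing rank
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  jstar <- 0L
  for (j in seq_len(m)) if (ps[j] <= j * q / m) jstar <- j
  rej <- rep(FALSE, m)
  if (jstar > 0L) rej[o[seq_len(jstar)]] <- TRUE
  rej
}

expect_num_equal <- function(object, expected, tol = 1e-12) {
  expect_equal(object, expected, tolerance = tol)
}
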