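toy_part <- function(n, effect = 0, seed = 1) {
  f <- local({
    set.seed(seed)
    y <- rep(c("yes", "no"), length.out = n)
    x <- matrix(rnorm(n * 6), n, 6)
    x[y == "yes", ] <- x[y == "yes", ] + effect
    f <- as.data.frame(x)
    names(f) <- c("sacrate_adapt", "sacrate_isi", "sacrate_target",
                  "pupil_adapt", "pupil_isi", "pupil_target")
    f$decision <- y
    f$confidence <- "sure"
    f$is_interest <- TRUE
    f$condition <- "pos_topleft"
    f$is_catch <- FALSE
    f$blink_total <- abs(rnorm(n, 0.25, 0.05))
    f
  })
  f
}

test_that("permutation p-values follow the add-one formula and rank", {
  parts <- list(toy_part(40, effect = 2, seed = 1))
  res <- permutation_test(parts, "auc", n_perm = 19, seed = 4,
                          reuse_c = TRUE, folds = 5, repeats = 2)
  expect_length(res$null, 19)
  expect_gt(res$p, 0)
  expect_lte(res$p, 1)
  # strong signal: observed beats every permutation
  expect_equal(res$p, 1 / 20)
  # an observed value below the null median gives p > 0.5
  null_parts <- list(toy_part(40, effect = 0, seed = 2))
  res0 <- permutation_test(null_parts, "auc", n_perm = 19, seed = 4,
                           reuse_c = TRUE, folds = 5, repeats = 2)
  if (res0$observed < median(res0$null)) expect_gt(res0$p, 0.5)
  expect_error(permutation_test(parts, "auc", n_perm = 0), "at least 1")
})

test_that("JZS Bayes factors match an independent quadrature oracle", {
  skip_if_not_installed("pracma")
  oracle <- function(t, n, r = sqrt(2) / 2) {
    f <- function(d) dt(t, n - 1, ncp = d * sqrt(n)) *
      stats::dcauchy(d, 0, r)
    suppressWarnings(pracma::quadgk(f, -40, 40, tol = 1e-12) / dt(t, n - 1))
  }
  for (t in c(-2.2, 0, 0.8, 1.5, 3, 5)) {
    for (n in c(5, 7, 12, 30)) {
      mine <- gazedecoder:::jzs_bf10(t, n, sqrt(2) / 2)
      ref <- oracle(t, n)
      expect_lt(abs(mine - ref) / ref, 0.01,
                label = sprintf("t=%g n=%d", t, n))
    }
  }
})

test_that("Bayes factor behaves across effect sizes and flags categories", {
  # t = 0: the data favor the null
  x <- c(-1, 1, -0.5, 0.5, -0.2, 0.2)
  bf0 <- paired_bf10(x)
  expect_equal(bf0$t, 0)
  expect_lt(bf0$bf10, 1)
  expect_equal(bf0$category, "favors_null")
  # monotone in |t| at fixed n; large t is strong evidence
  bfs <- vapply(c(1, 2, 4, 8),
                function(t) gazedecoder:::jzs_bf10(t, 10, sqrt(2) / 2),
                numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_equal(bf_category(bfs[4]), "strong")
  expect_equal(bf_category(2), "anecdotal")
  expect_equal(bf_category(5), "moderate")
  expect_equal(bf_category(0.3), "favors_null")
  expect_error(paired_bf10(rep(1, 5)), "zero-variance")
  expect_error(paired_bf10(1), "at least 2")
})

test_that("weight summaries handle idiosyncratic and degenerate weights", {
  mk_res <- function(w) structure(list(weights = setNames(
    w, c("sacrate_adapt", "sacrate_isi", "sacrate_target",
         "pupil_adapt", "pupil_isi", "pupil_target"))),
    class = "decoding_result")
  # random-sign weights across participants: per-feature means near 0
  set.seed(3)
  idio <- lapply(1:8, function(i) mk_res(sample(c(-1, 1), 6, TRUE) *
                                           runif(6, 0.5, 1.5)))
  ws <- weight_summary(idio)
  means <- vapply(ws$per_feature, `[[`, 1, "mean")
  expect_true(all(abs(means) < 1))
  # identical weights: correlations undefined, flagged
  same <- lapply(1:4, function(i) mk_res(rep(1, 6)))
  ws2 <- weight_summary(same)
  expect_true(all(vapply(ws2$period_correlations, `[[`, TRUE, "undefined")))
  expect_true(all(vapply(ws2$per_feature, `[[`, "", "category") ==
                    "undefined"))
  # consistent weights: evidence grows with participant count
  consistent <- function(k) lapply(1:k, function(i) {
    set.seed(100 + i); mk_res(rnorm(6, mean = 1.5, sd = 0.3))
  })
  bf_small <- vapply(weight_summary(consistent(4))$per_feature,
                     `[[`, 1, "bf10")
  bf_large <- vapply(weight_summary(consistent(12))$per_feature,
                     `[[`, 1, "bf10")
  expect_gt(mean(bf_large), mean(bf_small))
  expect_error(weight_summary(idio[1:2]), "at least 3")
})

test_that("decision and confidence weight vectors are compared per person", {
  mk_res <- function(w) structure(list(weights = setNames(
    w, c("sacrate_adapt", "sacrate_isi", "sacrate_target",
         "pupil_adapt", "pupil_isi", "pupil_target"))),
    class = "decoding_result")
  set.seed(8)
  dec <- lapply(1:5, function(i) mk_res(rnorm(6)))
  conf <- lapply(1:5, function(i) mk_res(rnorm(6)))
  conf[[3]] <- list(excluded = TRUE)
  ws <- weight_summary(dec, conf_results = conf)
  expect_length(ws$decision_confidence_r$per_participant, 5)
  expect_true(is.na(ws$decision_confidence_r$per_participant[3]))
  expect_true(is.finite(ws$decision_confidence_r$mean))
})

test_that("blink comparison detects a planted effect and handles nulls", {
  # identical blink process for both labels: BF below 1 in most seeds
  null_bf <- vapply(1:12, function(s) {
    parts <- lapply(1:6, function(i) toy_part(40, seed = s * 10 + i))
    blink_comparison(parts)$bf10
  }, numeric(1))
  expect_gte(mean(null_bf < 1), 0.7)
  # doubled blink duration on yes trials: detected
  parts <- lapply(1:6, function(i) {
    f <- toy_part(40, seed = 400 + i)
    f$blink_total[f$decision == "yes"] <-
      f$blink_total[f$decision == "yes"] * 2
    f
  })
  eff <- blink_comparison(parts)
  expect_lt(eff$p, 0.05)
  expect_gt(eff$bf10, 3)
  expect_gt(eff$mean_yes, eff$mean_no)
  # single participant: degenerate
  expect_error(blink_comparison(parts[1]), "at least 2")
  # a participant missing one label is skipped with a warning
  broken <- parts
  broken[[2]]$decision <- "yes"
  expect_warning(blink_comparison(broken), "skipped")
})
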