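# small synthetic feature tables built directly (no eye traces needed)
toy_features <- function(n, effect = 0, seed = 1) {
  set.seed(seed)
  y <- rep(c("yes", "no"), length.out = n)
  x <- matrix(rnorm(n * 6), n, 6)
  x[y == "yes", ] <- x[y == "yes", ] + effect
  f <- as.data.frame(x)
  names(f) <- c("sacrate_adapt", "sacrate_isi", "sacrate_target",
                "pupil_adapt", "pupil_isi", "pupil_target")
  f$decision <- y
  f$confidence <- rep(c("sure", "maybe"), length.out = n)
  f$is_interest <- TRUE
  f$condition <- rep(c("pos_topleft", "pos_bottomright"), each = n / 2)
  f$is_catch <- FALSE
  f$blink_total <- 0
  f
}

test_that("stratified folds preserve class counts and catch tiny classes", {
  y <- rep(c("yes", "no"), c(12, 28))
  fm <- stratified_folds(y, folds = 4, repeats = 3, seed = 1)
  for (r in 1:3) for (f in 1:4) {
    sel <- fm[, r] == f
    expect_equal(sum(sel & y == "yes"), 3)
    expect_equal(sum(sel & y == "no"), 7)
  }
  expect_error(stratified_folds(rep(c("yes", "no"), c(4, 40)), folds = 10),
               "class 'yes' has 4")
})

test_that("no stratified fold ever contains a single class", {
  y <- rep(c("yes", "no"), c(10, 13))   # minimum class exactly = folds
  bad <- 0L
  for (s in 1:200) {
    fm <- stratified_folds(y, folds = 10, repeats = 5, seed = s)
    for (r in 1:5) {
      tab <- table(fm[, r], y)
      if (any(tab == 0)) bad <- bad + 1L
    }
  }
  expect_equal(bad, 0L)
})

test_that("AUC is exact Mann-Whitney and invariant to monotone transforms", {
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.1)
  pos <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  a <- gazedecoder:::auc_score(sc, pos)
  expect_equal(a, 8 / 9)   # 8 of 9 pairs correctly ordered
  expect_equal(gazedecoder:::auc_score(qlogis(sc), pos), a)
  expect_equal(gazedecoder:::auc_score(sc * 100 - 3, pos), a)
  skip_if_not_installed("pROC")
  p <- suppressMessages(pROC::auc(pROC::roc(pos, sc, quiet = TRUE)))
  expect_equal(a, as.numeric(p))
})

test_that("separable features decode perfectly, null features at chance", {
  sep <- toy_features(60, effect = 10, seed = 2)
  cv <- cross_validate(sep, sep$decision, "yes", C = 100, folds = 5,
                       repeats = 2, seed = 1)
  expect_equal(mean(cv$auc), 1.0)
  nulls <- vapply(1:8, function(s) {
    f <- toy_features(60, effect = 0, seed = s + 10)
    mean(cross_validate(f, f$decision, "yes", C = 10, folds = 5,
                        repeats = 2, seed = s)$auc)
  }, numeric(1))
  expect_lt(abs(mean(nulls) - 0.5), 0.06)
})

test_that("the sparsity grid is 31 log-spaced values on [1, 1000]", {
  grid <- session_config()$c_grid
  expect_length(grid, 31)
  expect_equal(grid[1], 1)
  expect_equal(grid[31], 1000)
  expect_equal(grid[16], 10^1.5)
  expect_equal(diff(log10(grid)), rep(0.1, 30))
})

test_that("stronger penalties never revive pruned weights", {
  f <- toy_features(80, effect = 0.6, seed = 5)
  x <- scale(gazedecoder:::feature_matrix(f))
  pos <- f$decision == "yes"
  grid <- session_config()$c_grid
  lam <- sort(1 / (grid * nrow(x)), decreasing = TRUE)
  fit <- suppressWarnings(glmnet::glmnet(
    x, factor(pos), family = "binomial", alpha = 1, lambda = lam,
    standardize = FALSE))
  nzero <- colSums(as.matrix(fit$beta) != 0)
  # lambda decreasing along the path: nonzero count nondecreasing
  expect_true(all(diff(nzero) >= 0))
})

test_that("the penalty prunes harder at the sparse end of the grid", {
  # under the null, fits at the strongest penalty on the grid (C = 1) drop
  # more weights than fits at the weakest (C = 1000), and the tie-break
  # prefers the sparser C
  zeros <- vapply(1:12, function(s) {
    f <- toy_features(60, effect = 0, seed = 100 + s)
    z_at <- function(cc) {
      fit <- grid_search_C(f, f$decision, "yes", c_grid = cc, folds = 5,
                           repeats = 2, seed = s)
      sum(fit$weights == 0)
    }
    c(sparse = z_at(1), dense = z_at(1000))
  }, numeric(2))
  expect_gt(sum(zeros["sparse", ]), sum(zeros["dense", ]))
  # exact ties in mean AUC resolve toward the smaller C
  f <- toy_features(40, effect = 10, seed = 7)   # separable: AUC 1 for all C
  fit <- grid_search_C(f, f$decision, "yes", folds = 5, repeats = 2,
                       seed = 1)
  expect_equal(fit$best_c, 1)
})

test_that("grid search is reproducible and standardization does not leak", {
  f <- toy_features(60, effect = 0.8, seed = 3)
  a <- grid_search_C(f, f$decision, "yes", folds = 5, repeats = 3, seed = 9)
  b <- grid_search_C(f, f$decision, "yes", folds = 5, repeats = 3, seed = 9)
  expect_identical(a$weights, b$weights)
  expect_identical(a$fold_metrics, b$fold_metrics)
  expect_equal(a$best_c, b$best_c)
  # standardization must be fit on the training fold only: warping the
  # held-out fold by a positive affine map leaves its own AUC unchanged
  # (the model is untouched and scores transform monotonically), which
  # fails if test rows leak into the standardization
  x <- gazedecoder:::feature_matrix(f)
  pos <- f$decision == "yes"
  fm <- stratified_folds(f$decision, folds = 2, repeats = 1, seed = 2)
  base <- gazedecoder:::cv_path(x, pos, 10, fm)
  x2 <- x
  x2[fm[, 1] == 1, ] <- x2[fm[, 1] == 1, ] * 100 + 1000
  warped <- gazedecoder:::cv_path(x2, pos, 10, fm)
  expect_equal(warped$auc[1, 1], base$auc[1, 1])
  # degenerate features are rejected
  fz <- f; fz$pupil_isi <- 1
  expect_error(grid_search_C(fz, fz$decision, "yes"), "degenerate")
})

test_that("decision decoding recovers a planted coupling", {
  fxd <- fx_decode_session(seed = 21)
  res <- decode_decision(fxd$features, "both", seed = 1, folds = 5,
                         repeats = 5)
  expect_gt(res$mean_auc, 0.65)
  expect_equal(res$variant, "both-positions")
  expect_equal(nrow(res$fold_metrics), 25)
  # fitted weights align with the planted all-positive coupling
  expect_gt(cor(res$weights, fxd$sim$truth$coupling), 0)
})

test_that("best-position AUC is at least the per-position average", {
  fxd <- fx_decode_session(seed = 21)
  per <- decode_decision(fxd$features, "per", seed = 1, folds = 5,
                         repeats = 3)
  best <- decode_decision(fxd$features, "best", seed = 1, folds = 5,
                          repeats = 3)
  expect_gte(best$mean_auc, per$mean_auc - 1e-12)
  expect_true(best$best_position %in% c("pos_topleft", "pos_bottomright"))
})

test_that("balanced resampling on balanced data matches the plain run", {
  f <- toy_features(80, effect = 0.8, seed = 6)   # exactly 40/40
  cfg <- session_config(balanced_repeats = 5L)
  plain <- decode_decision(f, "both", seed = 2, folds = 5, repeats = 3,
                           cfg = cfg)
  bal <- decode_decision(f, "balanced", seed = 2, folds = 5, repeats = 3,
                         cfg = cfg)
  expect_lt(abs(plain$mean_auc - bal$mean_auc), 0.05)
})

test_that("confidence decoding applies the participant-exclusion rule", {
  f <- toy_features(60, effect = 0, seed = 8)
  f$confidence <- c("maybe", rep("sure", 59))
  out <- decode_confidence(f, "all", seed = 1)
  expect_true(out$excluded)
  # a planted confidence signal is recovered
  f2 <- toy_features(80, effect = 0, seed = 9)
  f2$confidence <- rep(c("sure", "maybe"), 40)
  f2$pupil_isi <- f2$pupil_isi + ifelse(f2$confidence == "sure", 2, 0)
  res <- decode_confidence(f2, "all", seed = 1, folds = 5, repeats = 3)
  expect_false(res$excluded)
  expect_gt(res$mean_auc, 0.8)
  expect_error(decode_confidence(f2[0, ], "all"), "empty trial subset")
})

test_that("the group decoder needs 2+ participants and scores each one", {
  f1 <- toy_features(60, effect = 1, seed = 11)
  f2 <- toy_features(60, effect = 1, seed = 12)
  g <- group_decoder(list(f1, f2), seed = 1, folds = 5)
  expect_equal(nrow(g$held_out), 2)
  expect_gt(g$mean_auc, 0.7)   # shared signal transfers
  expect_error(group_decoder(list(f1)), "at least 2")
})
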