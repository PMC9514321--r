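#' Stratified fold assignment
#'
#' Assigns each observation to one of `folds` folds, separately within each
#' class so that every fold preserves the class proportions (within one
#' observation). One column per repeat, each reshuffled with a seed derived
#' from `seed`.
#'
#' @param y label vector (two classes).
#' @param folds number of folds.
#' @param repeats number of repeats.
#' @param seed integer seed.
#' @return integer matrix `length(y) x repeats` of fold ids in `1:folds`.
#' @export
stratified_folds <- function(y, folds = 10L, repeats = 10L, seed = 1L) {
  counts <- table(y)
  small <- counts[counts < folds]
  if (length(small)) {
    stop("class '", names(small)[1], "' has ", small[1],
         " trials, fewer than ", folds, " folds")
  }
  set.seed(seed)
  out <- matrix(0L, length(y), repeats)
  for (r in seq_len(repeats)) {
    for (cl in names(counts)) {
      idx <- which(y == cl)
      out[sample(idx), r] <- rep_len(seq_len(folds), length(idx))
    }
  }
  out
}

# exact Mann-Whitney AUC of scores for the positive class (midranks for ties)
auc_score <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Fit the L1 path on each fold once and score every C.
# x: numeric matrix; pos: logical positive-class labels;
# fold_matrix from stratified_folds. Returns list(acc, auc): arrays
# [n_fold_evals x n_C] in grid order.
cv_path <- function(x, pos, c_grid, fold_matrix) {
  n_c <- length(c_grid)
  evals <- ncol(fold_matrix) * max(fold_matrix)
  acc <- matrix(NA_real_, evals, n_c)
  auc <- matrix(NA_real_, evals, n_c)
  row <- 0
  for (r in seq_len(ncol(fold_matrix))) {
    fid <- fold_matrix[, r]
    for (f in seq_len(max(fid))) {
      row <- row + 1
      tr <- fid != f; te <- !tr
      mu <- colMeans(x[tr, , drop = FALSE])
      sg <- apply(x[tr, , drop = FALSE], 2, sd)
      sg[sg == 0] <- 1
      xtr <- scale(x[tr, , drop = FALSE], mu, sg)
      xte <- scale(x[te, , drop = FALSE], mu, sg)
      lam <- 1 / (c_grid * sum(tr))
      ord <- order(lam, decreasing = TRUE)
      # small training folds are the design here; glmnet's small-class
      # notice would fire on every fold
      fit <- suppressWarnings(
        glmnet::glmnet(xtr, factor(pos[tr], levels = c(FALSE, TRUE)),
                       family = "binomial", alpha = 1,
                       lambda = lam[ord], standardize = FALSE))
      # linear scores: same accuracy threshold (link 0 = probability 0.5)
      # and tie-free AUC even where the logistic saturates numerically
      sc <- predict(fit, xte, s = lam[ord], type = "link")
      sc <- sc[, order(ord), drop = FALSE]   # back to grid order
      for (j in seq_len(n_c)) {
        acc[row, j] <- mean((sc[, j] > 0) == pos[te])
        auc[row, j] <- auc_score(sc[, j], pos[te])
      }
    }
  }
  list(acc = acc, auc = auc)
}

# features -> numeric matrix of the six decoding features
feature_matrix <- function(features) {
  x <- as.matrix(features[, .feature_names])
  storage.mode(x) <- "double"
  x
}

#' Repeated stratified cross-validation at a fixed sparsity
#'
#' 10 x 10-fold stratified CV by default: folds preserve class proportions,
#' each repeat reshuffles with a derived seed, standardization (mean/SD) is
#' fit on the training folds only, an L1-regularized logistic model is fit
#' at sparsity `C` (larger C = weaker penalty), and accuracy (probability
#' threshold 0.5) and AUC are computed on each held-out fold.
#'
#' @param features feature table (rows = trials) carrying the six feature
#'   columns.
#' @param labels two-level vector aligned with `features`.
#' @param positive the label treated as the positive class.
#' @param C sparsity parameter (inverse penalty strength).
#' @param folds,repeats CV scheme (defaults 10 and 10).
#' @param seed integer seed for the fold shuffles.
#' @return data.frame with one row per fold evaluation: `repeat_id`,
#'   `fold`, `accuracy`, `auc`.
#' @export
cross_validate <- function(features, labels, positive = "yes", C = 1,
                           folds = 10L, repeats = 10L, seed = 1L) {
  pos <- labels == positive
  fm <- stratified_folds(labels, folds, repeats, seed)
  res <- cv_path(feature_matrix(features), pos, C, fm)
  data.frame(repeat_id = rep(seq_len(repeats), each = folds),
             fold = rep(seq_len(folds), repeats),
             accuracy = res$acc[, 1], auc = res$auc[, 1])
}

#' Grid search over the sparsity parameter
#'
#' Runs the full repeated stratified CV for every C on the grid (31 values
#' log-spaced on \[1, 1000\] by default), with the same folds for every C;
#' the best C maximizes mean AUC, ties going to the smaller (sparser) C.
#' Final weights come from a fit on all standardized data at the best C.
#'
#' @inheritParams cross_validate
#' @param c_grid sparsity grid (default `cfg$c_grid`).
#' @param cfg a [session_config()].
#' @return list of class `decoding_result`: `best_c`, `weights` (named
#'   6-vector on standardized features), `intercept`, `fold_metrics`
#'   (at the best C), `mean_accuracy`, `mean_auc`, `auc_by_c`.
#' @export
grid_search_C <- function(features, labels, positive = "yes",
                          c_grid = NULL, folds = 10L, repeats = 10L,
                          seed = 1L, cfg = session_config()) {
  c_grid <- c_grid %||% cfg$c_grid
  stopifnot(length(c_grid) >= 1)
  x <- feature_matrix(features)
  if (any(apply(x, 2, sd) == 0)) {
    stop("degenerate features: zero variance column")
  }
  pos <- labels == positive
  fm <- stratified_folds(labels, folds, repeats, seed)
  res <- cv_path(x, pos, c_grid, fm)
  mean_auc <- colMeans(res$auc, na.rm = TRUE)
  best_j <- which(mean_auc >= max(mean_auc) - 1e-12)[1]  # ties: smaller C
  best_c <- c_grid[best_j]
  xs <- scale(x)
  lam_all <- 1 / (c_grid * nrow(x))
  ord <- order(lam_all, decreasing = TRUE)
  fit <- suppressWarnings(
    glmnet::glmnet(xs, factor(pos, levels = c(FALSE, TRUE)),
                   family = "binomial", alpha = 1,
                   lambda = lam_all[ord], standardize = FALSE))
  w <- as.numeric(coef(fit, s = 1 / (best_c * nrow(x))))
  structure(list(
    best_c = best_c,
    weights = setNames(w[-1], .feature_names),
    intercept = w[1],
    fold_metrics = data.frame(
      repeat_id = rep(seq_len(repeats), each = folds),
      fold = rep(seq_len(folds), repeats),
      accuracy = res$acc[, best_j], auc = res$auc[, best_j]),
    mean_accuracy = mean(res$acc[, best_j], na.rm = TRUE),
    mean_auc = mean(res$auc[, best_j], na.rm = TRUE),
    auc_by_c = setNames(mean_auc, signif(c_grid, 6)),
    n_trials = nrow(features),
    positive = positive),
    class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result%s> n = %d, C = %.4g\n",
              if (!is.null(x$variant)) paste0(" ", x$variant) else "",
              x$n_trials, x$best_c))
  cat(sprintf("  accuracy = %.3f, AUC = %.3f\n",
              x$mean_accuracy, x$mean_auc))
  nz <- sum(x$weights != 0)
  cat(sprintf("  %d / %d nonzero weights\n", nz, length(x$weights)))
  invisible(x)
}

#' Decode the perceptual decision (yes/no) of one participant
#'
#' All variants operate on the positions-of-interest trials:
#' \describe{
#'   \item{both}{one decoder over both positions (the main analysis).}
#'   \item{per}{one decoder per position; metrics averaged.}
#'   \item{best}{per-position decoding, keeping the position with the
#'     higher AUC.}
#'   \item{balanced}{the majority class is undersampled to the minority
#'     size, repeated `cfg$balanced_repeats` times with derived seeds, and
#'     metrics averaged — the control for class imbalance.}
#' }
#'
#' @param features a session feature table from [build_features()].
#' @param variant one of "both", "per", "best", "balanced".
#' @param seed integer seed (folds, resampling).
#' @param folds,repeats CV scheme.
#' @param cfg a [session_config()].
#' @return a `decoding_result`; for "per"/"best" it carries a
#'   `per_position` list of the position fits.
#' @export
decode_decision <- function(features, variant = c("both", "per", "best",
                                                  "balanced"),
                            seed = 1L, folds = NULL, repeats = NULL,
                            cfg = session_config()) {
  variant <- match.arg(variant)
  folds <- folds %||% cfg$cv_folds
  repeats <- repeats %||% cfg$cv_repeats
  dat <- features[features$is_interest, , drop = FALSE]
  if (nrow(dat) == 0) stop("no positions-of-interest trials selected")
  if (variant == "both") {
    res <- grid_search_C(dat, dat$decision, "yes", folds = folds,
                         repeats = repeats, seed = seed, cfg = cfg)
    res$variant <- "both-positions"
    return(res)
  }
  if (variant %in% c("per", "best")) {
    fits <- list()
    for (pos in .pos_interest) {
      sub <- dat[dat$condition == pos, , drop = FALSE]
      counts <- table(sub$decision)
      if (length(counts) < 2 || min(counts) < folds) {
        warning("position ", pos, " skipped: a class has fewer than ",
                folds, " trials")
        next
      }
      fits[[pos]] <- grid_search_C(sub, sub$decision, "yes", folds = folds,
                                   repeats = repeats, seed = seed, cfg = cfg)
    }
    if (length(fits) == 0) stop("no position had enough trials per class")
    if (variant == "per") {
      res <- fits[[1]]
      res$mean_accuracy <- mean(vapply(fits, `[[`, 1, "mean_accuracy"))
      res$mean_auc <- mean(vapply(fits, `[[`, 1, "mean_auc"))
      res$variant <- "per-position"
    } else {
      res <- fits[[which.max(vapply(fits, `[[`, 1, "mean_auc"))]]
      res$variant <- "best-position"
      res$best_position <- names(fits)[which.max(vapply(fits, `[[`, 1,
                                                        "mean_auc"))]
    }
    res$per_position <- fits
    return(res)
  }
  # balanced: undersample the majority class, repeat, average
  set.seed(seed)
  reps <- cfg$balanced_repeats
  sub_seeds <- sample.int(.Machine$integer.max - 1, reps)
  counts <- table(dat$decision)
  minority <- names(which.min(counts))
  majority <- setdiff(names(counts), minority)
  accs <- numeric(reps); aucs <- numeric(reps)
  last <- NULL
  for (r in seq_len(reps)) {
    set.seed(sub_seeds[r])
    keep_maj <- sample(which(dat$decision == majority), min(counts))
    sub <- dat[c(which(dat$decision == minority), keep_maj), , drop = FALSE]
    last <- grid_search_C(sub, sub$decision, "yes", folds = folds,
                          repeats = repeats, seed = sub_seeds[r], cfg = cfg)
    accs[r] <- last$mean_accuracy; aucs[r] <- last$mean_auc
  }
  res <- last
  res$mean_accuracy <- mean(accs)
  res$mean_auc <- mean(aucs)
  res$variant <- "balanced"
  res
}

#' Decode perceptual confidence (sure/maybe)
#'
#' Same machinery as [decode_decision()] with confidence labels, on all
#' positions-of-interest trials or restricted to yes-only / no-only
#' decisions. A participant whose minority confidence class has fewer than
#' 2 trials is excluded (returned with `excluded = TRUE` and no fit), the
#' published participant-exclusion rule. When a confidence class has fewer
#' members than the requested folds, the fold count drops to that class
#' size (with a warning) rather than failing.
#'
#' @param features session feature table.
#' @param subset "all", "yes" (yes-trials only) or "no".
#' @param seed integer seed.
#' @param folds,repeats CV scheme.
#' @param cfg a [session_config()].
#' @return a `decoding_result` (variant `confidence-<subset>`), or
#'   `list(excluded = TRUE, n_minority = ...)`.
#' @export
decode_confidence <- function(features, subset = c("all", "yes", "no"),
                              seed = 1L, folds = NULL, repeats = NULL,
                              cfg = session_config()) {
  subset <- match.arg(subset)
  folds <- folds %||% cfg$cv_folds
  repeats <- repeats %||% cfg$cv_repeats
  dat <- features[features$is_interest, , drop = FALSE]
  if (subset != "all") dat <- dat[dat$decision == subset, , drop = FALSE]
  if (nrow(dat) == 0) stop("empty trial subset '", subset, "'")
  counts <- table(factor(dat$confidence, levels = c("maybe", "sure")))
  if (min(counts) < 2) {
    return(list(excluded = TRUE, n_minority = min(counts),
                variant = paste0("confidence-", subset)))
  }
  if (min(counts) < folds) {
    warning("confidence class '", names(which.min(counts)), "' has ",
            min(counts), " trials; reducing folds to that size")
    folds <- min(counts)
  }
  res <- grid_search_C(dat, dat$confidence, "sure", folds = folds,
                       repeats = repeats, seed = seed, cfg = cfg)
  res$variant <- paste0("confidence-", subset)
  res$excluded <- FALSE
  res
}

#' Leave-one-participant-out group decoder
#'
#' Trains on the pooled positions-of-interest trials of all but one
#' participant and tests on the held-out participant's full session,
#' repeated over every participant. Standardization and the sparsity choice
#' (an inner repeated sCV grid search on the training pool) use the
#' training participants only.
#'
#' @param features_list list of per-participant feature tables.
#' @param seed integer seed.
#' @param inner_repeats repeats of the inner selection CV (default 2; the
#'   pooled training set is large, so fewer repeats suffice).
#' @param folds inner CV folds.
#' @param cfg a [session_config()].
#' @return a `decoding_result` (variant "group") with `held_out`: one row
#'   per participant (`accuracy`, `auc`, `best_c`).
#' @export
group_decoder <- function(features_list, seed = 1L, inner_repeats = 2L,
                          folds = NULL, cfg = session_config()) {
  if (length(features_list) < 2) stop("need at least 2 participants")
  folds <- folds %||% cfg$cv_folds
  rows <- list()
  for (p in seq_along(features_list)) {
    train <- do.call(rbind, lapply(features_list[-p], function(f) {
      f[f$is_interest, , drop = FALSE]
    }))
    test <- features_list[[p]]
    test <- test[test$is_interest, , drop = FALSE]
    fit <- grid_search_C(train, train$decision, "yes", folds = folds,
                         repeats = inner_repeats, seed = seed, cfg = cfg)
    xtr <- feature_matrix(train)
    mu <- colMeans(xtr); sg <- apply(xtr, 2, sd); sg[sg == 0] <- 1
    xte <- scale(feature_matrix(test), mu, sg)
    sc <- as.numeric(xte %*% fit$weights + fit$intercept)
    pr <- 1 / (1 + exp(-sc))
    pos <- test$decision == "yes"
    rows[[p]] <- data.frame(participant = p,
                            accuracy = mean((pr > 0.5) == pos),
                            auc = auc_score(pr, pos),
                            best_c = fit$best_c)
  }
  held <- do.call(rbind, rows)
  structure(list(variant = "group",
                 held_out = held,
                 mean_accuracy = mean(held$accuracy),
                 mean_auc = mean(held$auc, na.rm = TRUE),
                 n_trials = sum(vapply(features_list, nrow, 1L)),
                 best_c = NA_real_,
                 weights = NULL),
            class = "decoding_result")
}

#' Write a decoding result to JSON
#' @param result a `decoding_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_decoding_result <- function(result, path) {
  payload <- result[!vapply(result, is.null, logical(1))]
  class(payload) <- NULL
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}
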