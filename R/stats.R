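#' Permutation test of group-level decoding performance
#'
#' The observed statistic is the chosen metric (accuracy or AUC) of the
#' per-participant decision decoders averaged across participants. Each
#' permutation reassigns the "yes" labels uniformly at random within every
#' participant, preserving that participant's class counts exactly, reruns
#' the decoding, and averages the metric; the p-value uses the add-one
#' estimator `p = (1 + #(null >= observed)) / (1 + n_perm)`, which can never
#' return 0.
#'
#' By default each permutation reruns the full sparsity grid search
#' (conservative); `reuse_c = TRUE` reuses each participant's observed best
#' C, which is much faster and appropriate for calibration studies at
#' reduced `n_perm`.
#'
#' @param features_list list of per-participant feature tables.
#' @param metric "accuracy" or "auc".
#' @param n_perm number of permutations (default 1,000).
#' @param seed integer seed.
#' @param reuse_c reuse the observed best C inside permutations.
#' @param folds,repeats CV scheme passed through to the decoders.
#' @param cfg a [session_config()].
#' @return list of class `permutation_result`: `observed`, `null`
#'   (length `n_perm`), `p`, `metric`, `n_perm`.
#' @export
permutation_test <- function(features_list, metric = c("accuracy", "auc"),
                             n_perm = NULL, seed = 1L, reuse_c = FALSE,
                             folds = NULL, repeats = NULL,
                             cfg = session_config()) {
  metric <- match.arg(metric)
  n_perm <- n_perm %||% cfg$n_permutations
  if (n_perm < 1) stop("n_perm must be at least 1")
  folds <- folds %||% cfg$cv_folds
  repeats <- repeats %||% cfg$cv_repeats
  field <- if (metric == "accuracy") "mean_accuracy" else "mean_auc"

  observed_fits <- lapply(seq_along(features_list), function(p) {
    decode_decision(features_list[[p]], "both", seed = seed + p,
                    folds = folds, repeats = repeats, cfg = cfg)
  })
  observed <- mean(vapply(observed_fits, `[[`, 1, field))

  set.seed(seed)
  perm_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                  n_perm * length(features_list)),
                       nrow = n_perm)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    vals <- vapply(seq_along(features_list), function(p) {
      feats <- features_list[[p]]
      dat <- feats[feats$is_interest, , drop = FALSE]
      set.seed(perm_seeds[b, p])
      dat$decision <- sample(dat$decision)
      stopifnot(identical(table(dat$decision),
                          table(feats$decision[feats$is_interest])))
      if (reuse_c) {
        fm <- cross_validate(dat, dat$decision, "yes",
                             C = observed_fits[[p]]$best_c,
                             folds = folds, repeats = repeats,
                             seed = perm_seeds[b, p])
        mean(fm[[if (metric == "accuracy") "accuracy" else "auc"]],
             na.rm = TRUE)
      } else {
        fit <- grid_search_C(dat, dat$decision, "yes", folds = folds,
                             repeats = repeats, seed = perm_seeds[b, p],
                             cfg = cfg)
        fit[[field]]
      }
    }, numeric(1))
    null[b] <- mean(vals)
  }
  structure(list(observed = observed, null = null,
                 p = (1 + sum(null >= observed)) / (1 + n_perm),
                 metric = metric, n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s = %.4f, p = %.4g (%d permutations)\n",
              x$metric, x$observed, x$p, x$n_perm))
  invisible(x)
}

# JZS integrand: marginal likelihood ratio with the Zellner-Siow g-prior,
# g ~ inverse-gamma(1/2, r^2/2); one-dimensional integral over g.
jzs_bf10 <- function(t, n, rscale) {
  nu <- n - 1
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  f <- function(g) {
    (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      (rscale^2 / 2)^(1 / 2) / gamma(1 / 2) *
      g^(-3 / 2) * exp(-rscale^2 / (2 * g))
  }
  num <- integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  num / den
}

#' Bayesian paired-samples t-test (JZS Bayes factor)
#'
#' BF10 for the paired (one-sample) t-test under the Jeffreys-Zellner-Siow
#' prior: a Cauchy prior with scale `rscale` (default 0.707) on the
#' standardized effect size, computed by one-dimensional numerical
#' integration. Values above 1 favor the alternative; the conventional
#' evidence bands are 1-3 anecdotal, 3-10 moderate, above 10 strong.
#'
#' @param x numeric vector: differences, or first member of each pair.
#' @param y optional second member; when given, `x - y` is tested.
#' @param mu null value for the mean difference (default 0).
#' @param rscale Cauchy prior scale (default `sqrt(2)/2`).
#' @return list of class `bf_result`: `bf10`, `t`, `n`, `category`.
#' @export
paired_bf10 <- function(x, y = NULL, mu = 0, rscale = sqrt(2) / 2) {
  d <- if (is.null(y)) x else x - y
  d <- d - mu
  if (length(d) < 2) stop("need at least 2 pairs")
  if (any(!is.finite(d))) stop("values must be finite")
  if (sd(d) == 0) stop("zero-variance differences")
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  bf <- jzs_bf10(t, n, rscale)
  structure(list(bf10 = bf, t = t, n = n, category = bf_category(bf)),
            class = "bf_result")
}

#' Evidence category of a Bayes factor
#'
#' Band boundaries exactly at 1, 3 and 10: BF10 <= 1 "favors_null",
#' (1, 3] "anecdotal", (3, 10] "moderate", above 10 "strong".
#'
#' @param bf10 a positive Bayes factor.
#' @return character category.
#' @export
bf_category <- function(bf10) {
  stopifnot(bf10 > 0)
  if (bf10 <= 1) "favors_null"
  else if (bf10 <= 3) "anecdotal"
  else if (bf10 <= 10) "moderate"
  else "strong"
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("<bf_result> BF10 = %.4g (%s), t(%d) = %.3f\n",
              x$bf10, x$category, x$n - 1L, x$t))
  invisible(x)
}

#' Summaries of decoder weights across participants
#'
#' Per-feature mean weight with a JZS Bayes factor against 0; Pearson
#' correlation between the saccade-rate and pupil weights within each
#' period, across participants (flagged undefined when either column has
#' zero variance); and, when confidence-decoder results are supplied, the
#' per-participant correlation between the decision and confidence weight
#' vectors, averaged.
#'
#' @param results list of per-participant `decoding_result`s (decision).
#' @param conf_results optional matching list of confidence results
#'   (entries with `excluded = TRUE` are skipped).
#' @param rscale Cauchy prior scale for the Bayes factors.
#' @return list with `weights` (participants x 6 matrix), `per_feature`
#'   (mean, t, bf10, category per feature), `period_correlations` (r and
#'   bf10 of SacRate vs Pupil weight per period, with `undefined` flags),
#'   and optionally `decision_confidence_r` (per participant + mean).
#' @export
weight_summary <- function(results, conf_results = NULL,
                           rscale = sqrt(2) / 2) {
  if (length(results) < 3) stop("need at least 3 participants")
  W <- do.call(rbind, lapply(results, `[[`, "weights"))
  colnames(W) <- .feature_names
  per_feature <- lapply(seq_len(ncol(W)), function(j) {
    if (sd(W[, j]) == 0) {
      return(list(feature = colnames(W)[j], mean = mean(W[, j]),
                  t = NA_real_, bf10 = NA_real_, category = "undefined"))
    }
    bf <- paired_bf10(W[, j], rscale = rscale)
    list(feature = colnames(W)[j], mean = mean(W[, j]), t = bf$t,
         bf10 = bf$bf10, category = bf$category)
  })
  periods <- c("adapt", "isi", "target")
  period_correlations <- lapply(seq_along(periods), function(p) {
    a <- W[, p]; b <- W[, 3 + p]
    if (sd(a) == 0 || sd(b) == 0) {
      return(list(period = periods[p], r = NA_real_, undefined = TRUE))
    }
    list(period = periods[p], r = cor(a, b), undefined = FALSE)
  })
  out <- list(weights = W,
              per_feature = per_feature,
              period_correlations = period_correlations)
  if (!is.null(conf_results)) {
    rs <- vapply(seq_along(results), function(p) {
      cr <- conf_results[[p]]
      if (is.null(cr$weights) || isTRUE(cr$excluded)) return(NA_real_)
      a <- results[[p]]$weights; b <- cr$weights
      if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
      cor(a, b)
    }, numeric(1))
    out$decision_confidence_r <- list(per_participant = rs,
                                      mean = mean(rs, na.rm = TRUE))
  }
  out
}

#' Compare total blink duration between yes and no trials
#'
#' Per participant, the mean per-trial total blink duration is computed
#' separately for "yes" and "no" trials; the participant means are compared
#' with a paired t-test and the JZS Bayes factor. Participants missing one
#' of the two labels are skipped with a warning.
#'
#' @param features_list list of per-participant feature tables.
#' @param rscale Cauchy prior scale.
#' @return list with `mean_yes`, `mean_no` (s), `t`, `p`, `bf10`,
#'   `category`, `n` (participants used).
#' @export
blink_comparison <- function(features_list, rscale = sqrt(2) / 2) {
  rows <- lapply(seq_along(features_list), function(p) {
    f <- features_list[[p]]
    if (!all(c("yes", "no") %in% f$decision)) {
      warning("participant ", p, " skipped: a decision label is absent")
      return(NULL)
    }
    data.frame(yes = mean(f$blink_total[f$decision == "yes"]),
               no = mean(f$blink_total[f$decision == "no"]))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) < 2) {
    stop("need at least 2 participants with both labels")
  }
  tt <- t.test(rows$yes, rows$no, paired = TRUE)
  bf <- paired_bf10(rows$yes, rows$no, rscale = rscale)
  list(mean_yes = mean(rows$yes), mean_no = mean(rows$no),
       t = unname(tt$statistic), p = tt$p.value,
       bf10 = bf$bf10, category = bf$category, n = nrow(rows))
}
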