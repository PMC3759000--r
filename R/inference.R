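#' Bonferroni-corrected significance threshold
#'
#' `alpha / n_tests`; with the 13 connectivity features at alpha = 0.05
#' this is 0.05 / 13 = 0.0038 (to two significant digits).
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_tests number of tests, at least 1.
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Majority-class chance accuracy
#'
#' Accuracy (in percent) of always predicting the most frequent class,
#' after excluding any `"Disenrolled"` labels — the baseline against
#' which cross-validated accuracy is judged.
#'
#' @param labels character or factor vector of diagnosis labels.
#' @return Percentage in (0, 100].
#' @export
#' @examples
#' chance_accuracy(rep(c("Patient", "Control"), c(72, 74)))  # 50.7
chance_accuracy <- function(labels) {
  labels <- as.character(labels)
  labels <- labels[labels != "Disenrolled"]
  if (length(labels) == 0)
    stop("no usable labels after excluding Disenrolled", call. = FALSE)
  100 * max(table(labels)) / length(labels)
}

#' Per-feature Welch t-tests between groups
#'
#' Two-sided two-sample t-tests with unequal-variance (Welch) degrees of
#' freedom, one per feature column, with missing values omitted per
#' feature.  Significance is judged against the Bonferroni threshold
#' `alpha / n_features`.  A feature with fewer than 2 valid values in
#' either group, or with zero variance in both groups, is marked
#' untestable (`NA` statistics) rather than raising an error.
#'
#' @param features numeric matrix or data.frame of features
#'   (rows = subjects); an `fnc_features` object also works.
#' @param labels group labels aligned with the rows; `"Disenrolled"`
#'   rows are excluded.
#' @param alpha family-wise error rate; default 0.05.
#' @return An object of class `fnc_tests`: data.frame with one row per
#'   feature (means, SDs, t, df, p, significant, untestable) and
#'   attributes `threshold` and `alpha`.
#' @export
welch_t_tests <- function(features, labels, alpha = 0.05) {
  X <- feature_value_matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  keep <- labels != "Disenrolled"
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  groups <- sort(unique(labels))
  if (length(groups) != 2)
    stop("need exactly two groups after exclusion", call. = FALSE)
  thr <- bonferroni_threshold(alpha, ncol(X))
  rows <- lapply(colnames(X), function(f) {
    x1 <- X[labels == groups[1], f]; x1 <- x1[!is.na(x1)]
    x2 <- X[labels == groups[2], f]; x2 <- x2[!is.na(x2)]
    base <- data.frame(feature = f,
                       mean_1 = mean(x1), sd_1 = sd(x1),
                       mean_2 = mean(x2), sd_2 = sd(x2),
                       t = NA_real_, df = NA_real_, p = NA_real_,
                       significant = NA, untestable = TRUE,
                       stringsAsFactors = FALSE)
    if (length(x1) >= 2 && length(x2) >= 2 &&
        (sd(x1) > 0 || sd(x2) > 0)) {
      tt <- t.test(x1, x2)
      base$t <- unname(tt$statistic)
      base$df <- unname(tt$parameter)
      base$p <- tt$p.value
      base$significant <- tt$p.value < thr
      base$untestable <- FALSE
    }
    base
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("mean_", groups[1]), paste0("sd_", groups[1]),
                       paste0("mean_", groups[2]), paste0("sd_", groups[2]))
  attr(out, "threshold") <- thr
  attr(out, "alpha") <- alpha
  attr(out, "groups") <- groups
  class(out) <- c("fnc_tests", "data.frame")
  out
}

#' @export
`[.fnc_tests` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.fnc_tests <- function(x, digits = 4, ...) {
  cat(sprintf("Welch t-tests (%s vs %s), Bonferroni threshold %.4g\n",
              attr(x, "groups")[1], attr(x, "groups")[2],
              attr(x, "threshold")))
  df <- as.data.frame(x)
  df$p <- signif(df$p, digits)
  df$t <- signif(df$t, digits)
  print(df[, c("feature", "t", "df", "p", "significant")],
        row.names = FALSE)
  invisible(x)
}

feature_value_matrix <- function(features) {
  if (is.data.frame(features)) {
    num <- vapply(features, is.numeric, logical(1))
    X <- as.matrix(features[, num, drop = FALSE])
  } else {
    X <- as.matrix(features)
  }
  if (is.null(colnames(X)))
    colnames(X) <- paste0("feature_", seq_len(ncol(X)))
  X
}

#' Cross-validated SVM classification of the feature matrix
#'
#' Radial-basis-kernel support vector classification with default
#' hyperparameters (cost 1, kernel width `1 / n_features`) and k-fold
#' cross-validation.  Folds are assigned by a seeded random permutation
#' without stratification.  Inside each fold, missing feature values are
#' imputed by the training-fold median and features are standardized by
#' training-fold mean and SD only (no leakage into the held-out fold).
#' `"Disenrolled"` subjects are excluded up front.
#'
#' @param features numeric matrix / data.frame (rows = subjects) or
#'   `fnc_features` object.
#' @param labels diagnosis labels aligned with rows; must be binary after
#'   excluding `"Disenrolled"`.
#' @param folds number of cross-validation folds; default 10.
#' @param seed integer seed for the fold assignment.
#' @return An object of class `fnc_cv`: list with `accuracy` (overall
#'   cross-validated accuracy, percent, subject-weighted),
#'   `fold_accuracy`, `chance` (majority-class accuracy, percent),
#'   `folds`, `seed`, `kernel`, `cost`, `gamma`, `n`, `imputed` (count of
#'   imputed cells).
#' @export
svm_cross_validate <- function(features, labels, folds = 10L, seed = 1L) {
  X <- feature_value_matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  keep <- labels != "Disenrolled"
  X <- X[keep, , drop = FALSE]
  y <- factor(labels[keep])
  if (nlevels(y) != 2)
    stop("need binary labels after excluding Disenrolled", call. = FALSE)
  n <- nrow(X)
  folds <- as.integer(folds)
  if (folds < 2L || folds > n)
    stop("need 2 <= folds <= number of subjects", call. = FALSE)
  gamma <- 1 / ncol(X)

  run_cv <- function(fold_id) {
    fold_acc <- numeric(folds)
    correct <- 0L
    imputed <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f; te <- !tr
      ytr <- droplevels(y[tr])
      if (nlevels(ytr) < 2) return(NULL)
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      med <- apply(Xtr, 2, median, na.rm = TRUE)
      med[is.na(med)] <- 0
      for (jj in seq_len(ncol(X))) {
        miss_tr <- is.na(Xtr[, jj]); miss_te <- is.na(Xte[, jj])
        imputed <- imputed + sum(miss_tr) + sum(miss_te)
        Xtr[miss_tr, jj] <- med[jj]; Xte[miss_te, jj] <- med[jj]
      }
      mu <- colMeans(Xtr)
      sdev <- apply(Xtr, 2, sd)
      sdev[sdev == 0 | is.na(sdev)] <- 1
      Xtr <- scale(Xtr, center = mu, scale = sdev)
      Xte <- scale(Xte, center = mu, scale = sdev)
      fit <- e1071::svm(Xtr, y[tr], kernel = "radial", cost = 1,
                        gamma = gamma, scale = FALSE)
      pred <- predict(fit, Xte)
      hits <- sum(pred == y[te])
      fold_acc[f] <- 100 * hits / sum(te)
      correct <- correct + hits
    }
    list(fold_acc = fold_acc, accuracy = 100 * correct / n,
         imputed = imputed)
  }

  res <- with_seed(seed, {
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    out <- run_cv(fold_id)
    if (is.null(out)) {       # one retry with re-randomized folds
      fold_id <- sample(rep(seq_len(folds), length.out = n))
      out <- run_cv(fold_id)
    }
    out
  })
  if (is.null(res))
    stop("a training fold contained a single class twice in a row",
         call. = FALSE)
  structure(list(accuracy = res$accuracy, fold_accuracy = res$fold_acc,
                 chance = chance_accuracy(y), folds = folds, seed = seed,
                 kernel = "radial", cost = 1, gamma = gamma, n = n,
                 imputed = res$imputed),
            class = "fnc_cv")
}

#' @export
print.fnc_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated SVM (radial kernel, cost %g, gamma %.4g)\n",
              x$folds, x$cost, x$gamma))
  cat(sprintf("  accuracy %.1f%% over %d subjects (chance %.1f%%), seed %d\n",
              x$accuracy, x$n, x$chance, x$seed))
  invisible(x)
}
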