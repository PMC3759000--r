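#' Fit the full functional-network-connectivity analysis to a cohort
#'
#' The top-level pipeline: for each subject, the lagged cross-correlation
#' pseudo-distance matrix ([distance_matrix()]) is pruned into an
#' inverse-distance weighted graph ([prune_graph()]) and summarized by
#' the 13-feature connectivity fingerprint ([feature_vector()]); the
#' feature matrix is then compared between groups by Welch t-tests with
#' Bonferroni correction ([welch_t_tests()]) and classified by
#' cross-validated SVM ([svm_cross_validate()]).  `"Disenrolled"`
#' subjects contribute features but are excluded from both inference
#' stages.  Deterministic given `seed`.
#'
#' @param cohort an `fnc_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]), or a list of `fnc_subject`s with group labels.
#' @param max_lag lag bound for the cross-correlation stage; default 3
#'   timepoints.
#' @param k neighbours per vertex for pruning; default the
#'   [choose_k()] rule per subject.
#' @param ndim embedding dimension request; default `min(15, M - 1)` per
#'   subject.
#' @param weighted use weighted path metrics in the feature vector;
#'   default TRUE.
#' @param sw_reps Erdos-Renyi ensemble size for small-worldness; default
#'   5000.
#' @param folds cross-validation folds; default 10.
#' @param alpha family-wise error rate for the t-tests; default 0.05.
#' @param seed master seed for the small-world ensembles and fold
#'   assignment.
#' @param classify run the SVM stage (requires at least `folds` usable
#'   subjects); default TRUE.
#' @return An object of class `fnc_study`: list with `features` (an
#'   `fnc_features` data.frame: subject_id, diagnosis, 13 feature
#'   columns), `tests` (`fnc_tests`), `svm` (`fnc_cv` or NULL),
#'   `fragmented` (named logical per subject), `settings`.
#' @export
#' @examples
#' \donttest{
#' cfg <- fnc_sim_config(n_per_group = 6, M_range = c(10, 14), seed = 3)
#' fit <- fnc_study(simulate_cohort(cfg), sw_reps = 50, folds = 4)
#' summary(fit)
#' }
fnc_study <- function(cohort, max_lag = 3L, k = NULL, ndim = NULL,
                      weighted = TRUE, sw_reps = 5000L, folds = 10L,
                      alpha = 0.05, seed = 1L, classify = TRUE) {
  if (!inherits(cohort, "fnc_cohort")) {
    stopifnot(is.list(cohort), all(vapply(cohort, inherits, TRUE,
                                          "fnc_subject")))
    cohort <- structure(list(
      subjects = cohort,
      phenotype = data.frame(
        subject_id = vapply(cohort, `[[`, "", "subject_id"),
        diagnosis = vapply(cohort, function(s) s$group %||% NA_character_,
                           ""),
        stringsAsFactors = FALSE)),
      class = "fnc_cohort")
  }
  subjects <- cohort$subjects
  pheno <- cohort$phenotype
  n <- length(subjects)
  usable <- sum(pheno$diagnosis != "Disenrolled")
  if (classify && usable < folds)
    stop(sprintf("only %d usable subjects for %d folds", usable, folds),
         call. = FALSE)

  feats <- matrix(NA_real_, n, length(fnc_feature_names),
                  dimnames = list(NULL, fnc_feature_names))
  fragmented <- logical(n)
  for (i in seq_len(n)) {
    s <- subjects[[i]]
    g <- tryCatch(
      prune_graph(distance_matrix(s, max_lag = max_lag), k = k,
                  ndim = ndim),
      error = function(e)
        stop(sprintf("subject %s, graph stage: %s", s$subject_id,
                     conditionMessage(e)), call. = FALSE))
    fragmented[i] <- g$fragmented
    feats[i, ] <- feature_vector(g, weighted = weighted,
                                 sw_reps = sw_reps,
                                 sw_seed = subject_seed(seed, i))
  }
  names(fragmented) <- pheno$subject_id
  features <- cbind(pheno[, c("subject_id", "diagnosis")],
                    as.data.frame(feats, check.names = FALSE))
  class(features) <- c("fnc_features", "data.frame")

  tests <- welch_t_tests(features[, fnc_feature_names],
                         features$diagnosis, alpha = alpha)
  svm_res <- if (classify)
    svm_cross_validate(features[, fnc_feature_names],
                       features$diagnosis, folds = folds, seed = seed)
  else NULL

  structure(list(features = features, tests = tests, svm = svm_res,
                 fragmented = fragmented,
                 settings = list(max_lag = max_lag, k = k, ndim = ndim,
                                 weighted = weighted, sw_reps = sw_reps,
                                 folds = folds, alpha = alpha,
                                 seed = seed)),
            class = "fnc_study")
}

#' Extract the feature matrix of a fitted study
#' @param fit an `fnc_study`.
#' @return The `fnc_features` data.frame.
#' @export
fnc_features <- function(fit) {
  stopifnot(inherits(fit, "fnc_study"))
  fit$features
}

#' @export
print.fnc_study <- function(x, ...) {
  n <- nrow(x$features)
  tab <- table(x$features$diagnosis)
  cat("Functional network connectivity study\n")
  cat(sprintf("  %d subjects (%s); %d fragmented graph(s)\n", n,
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              sum(x$fragmented)))
  sig <- x$tests$feature[which(x$tests$significant)]
  cat(sprintf("  significant features at Bonferroni %.4g: %s\n",
              attr(x$tests, "threshold"),
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  if (!is.null(x$svm))
    cat(sprintf("  %d-fold SVM accuracy %.1f%% (chance %.1f%%)\n",
                x$svm$folds, x$svm$accuracy, x$svm$chance))
  invisible(x)
}

#' @export
summary.fnc_study <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$tests)
  if (!is.null(object$svm)) {
    cat("\n")
    print(object$svm)
  }
  invisible(object)
}

#' Boxplots of connectivity features by group
#'
#' @param x an `fnc_study`.
#' @param features which features to plot; default all 13.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.fnc_study <- function(x, features = fnc_feature_names, ...) {
  keep <- x$features$diagnosis != "Disenrolled"
  df <- x$features[keep, , drop = FALSE]
  features <- intersect(features, fnc_feature_names)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(features)),
                       mar = c(2, 3, 2, 0.5))
  on.exit(graphics::par(old))
  for (f in features)
    graphics::boxplot(df[[f]] ~ factor(df$diagnosis), main = f,
                      xlab = "", ylab = "", ...)
  invisible(x)
}

#' Write study artifacts to a directory
#'
#' Writes `features.csv` (subject_id, diagnosis, the 13 feature
#' columns), `tests.csv`, `classification.json` (plain-text report) and
#' `manifest.txt` (settings echo, seeds, fragmentation flags).
#'
#' @param fit an `fnc_study`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(fit, dir) {
  stopifnot(inherits(fit, "fnc_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(fit$features), file.path(dir, "features.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(fit$tests), file.path(dir, "tests.csv"),
            row.names = FALSE)
  if (!is.null(fit$svm)) {
    sv <- fit$svm
    json <- sprintf(
      paste0('{"folds": %d, "accuracy": %.6f, "chance": %.6f, ',
             '"fold_accuracy": [%s], "kernel": "%s", "cost": %g, ',
             '"gamma": %.8f, "seed": %d, "n": %d}'),
      sv$folds, sv$accuracy, sv$chance,
      paste(sprintf("%.6f", sv$fold_accuracy), collapse = ", "),
      sv$kernel, sv$cost, sv$gamma, sv$seed, sv$n)
    writeLines(json, file.path(dir, "classification.json"))
  }
  st <- fit$settings
  manifest <- c(
    sprintf("fncgraph %s", as.character(utils::packageVersion("fncgraph"))),
    sprintf("subjects: %d", nrow(fit$features)),
    sprintf("max_lag: %d", st$max_lag),
    sprintf("k: %s", if (is.null(st$k)) "auto (max(floor(M/10), 2))"
            else st$k),
    sprintf("ndim: %s", if (is.null(st$ndim)) "auto (min(15, M-1))"
            else st$ndim),
    sprintf("weighted: %s", st$weighted),
    sprintf("sw_reps: %d", st$sw_reps),
    sprintf("folds: %d", st$folds),
    sprintf("alpha: %g", st$alpha),
    sprintf("seed: %d", st$seed),
    sprintf("fragmented: %s",
            paste(names(fit$fragmented)[fit$fragmented], collapse = ", ")))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
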