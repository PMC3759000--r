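#' Configuration for synthetic FNC cohorts
#'
#' Defines the generative model for synthetic cohorts of per-subject
#' component timecourses.  Each subject gets `M` components (drawn
#' uniformly from `M_range`, emulating per-subject ICA model-order
#' selection), partitioned at random into `n_clusters` latent coupling
#' clusters.  One base signal per cluster is a zero-mean AR(1) series;
#' component `j` is a mixture
#' \deqn{x_j = \alpha \, b_{c(j)}(t - \ell_j) + \sqrt{1-\alpha^2}\, e_j(t)}
#' of its cluster base signal (shifted by an integer lag \eqn{\ell_j}
#' drawn uniformly from `0:max_true_lag`) and independent AR(1) noise,
#' where \eqn{\alpha} is the group coupling coefficient.  Columns are
#' standardized to zero mean and unit variance.
#'
#' @param n_per_group subjects per group.
#' @param T_len timepoints per subject; default 150 (a ~5 minute scan at
#'   TR = 2 s).
#' @param M_range inclusive integer range for the per-subject component
#'   count; default `c(15, 40)`.
#' @param n_clusters latent coupling clusters per subject.
#' @param coupling_control,coupling_patient coupling coefficients
#'   \eqn{\alpha \in [0, 1)} for the two groups.
#' @param ar_coef AR(1) coefficient in (-1, 1) shared by base signals and
#'   noise.
#' @param max_true_lag maximum planted lead/lag in timepoints; default 3,
#'   matching the lag window of the connectivity stage.
#' @param n_disenrolled extra subjects labelled `"Disenrolled"` in the
#'   phenotype table (they get timecourses, generated with the control
#'   coupling, but are excluded from inference).
#' @param seed integer master seed; per-subject substreams are derived
#'   from it by counter so cohorts are reproducible under reordering.
#' @return An object of class `fnc_sim_config`.
#' @seealso [simulate_cohort()], [simulate_subject()]
#' @export
#' @examples
#' cfg <- fnc_sim_config(n_per_group = 2, M_range = c(8, 10), seed = 1)
#' cohort <- simulate_cohort(cfg)
#' length(cohort$subjects)
fnc_sim_config <- function(n_per_group,
                           T_len = 150L,
                           M_range = c(15L, 40L),
                           n_clusters = 4L,
                           coupling_control = 0.8,
                           coupling_patient = 0.4,
                           ar_coef = 0.3,
                           max_true_lag = 3L,
                           n_disenrolled = 0L,
                           seed = 1L) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              T_len = as.integer(T_len),
              M_range = as.integer(M_range),
              n_clusters = as.integer(n_clusters),
              coupling_control = coupling_control,
              coupling_patient = coupling_patient,
              ar_coef = ar_coef,
              max_true_lag = as.integer(max_true_lag),
              n_disenrolled = as.integer(n_disenrolled),
              seed = as.integer(seed))
  class(cfg) <- "fnc_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "fnc_sim_config"))
  if (cfg$n_per_group < 1L)
    stop("invalid config: n_per_group must be >= 1", call. = FALSE)
  for (a in c(cfg$coupling_control, cfg$coupling_patient))
    if (!is.finite(a) || a < 0 || a >= 1)
      stop("invalid config: coupling coefficients must lie in [0, 1)",
           call. = FALSE)
  if (length(cfg$M_range) != 2L || cfg$M_range[1] > cfg$M_range[2])
    stop("invalid config: M_range must be an increasing pair", call. = FALSE)
  if (cfg$M_range[1] < 3L)
    stop("invalid config: M_range minimum must be >= 3", call. = FALSE)
  if (abs(cfg$ar_coef) >= 1)
    stop("invalid config: ar_coef must lie in (-1, 1)", call. = FALSE)
  if (cfg$max_true_lag < 0L)
    stop("invalid config: max_true_lag must be >= 0", call. = FALSE)
  if (cfg$T_len <= 10L * cfg$max_true_lag)
    stop("invalid config: T_len must exceed 10 * max_true_lag", call. = FALSE)
  if (cfg$n_disenrolled < 0L)
    stop("invalid config: n_disenrolled must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.fnc_sim_config <- function(x, ...) {
  cat("Synthetic FNC cohort configuration\n")
  cat(sprintf("  %d subjects/group, T = %d, M in [%d, %d], %d clusters\n",
              x$n_per_group, x$T_len, x$M_range[1], x$M_range[2],
              x$n_clusters))
  cat(sprintf("  coupling: control %.3g, patient %.3g; AR(1) coef %.3g; max lag %d\n",
              x$coupling_control, x$coupling_patient, x$ar_coef,
              x$max_true_lag))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# Stationary AR(1) with unit marginal variance: innovations scaled by
# sqrt(1 - phi^2) so the mixture weights alpha / sqrt(1 - alpha^2) act on
# equal-variance ingredients.
ar1_series <- function(n, phi) {
  innov <- rnorm(n) * sqrt(1 - phi^2)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# Substream seed for subject `counter` under master seed `seed`; kept
# within 32-bit integer range.
subject_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + counter * 104729) %% 2147483647)
}

#' Simulate one subject's component timecourses
#'
#' @param config an [fnc_sim_config()] object.
#' @param group `"Patient"`, `"Control"` or `"Disenrolled"` (the latter is
#'   generated with the control coupling coefficient).
#' @param counter integer index of the subject within the cohort; together
#'   with `config$seed` it determines the subject's private random
#'   substream.
#' @return An object of class `fnc_subject`: a list with `subject_id`,
#'   `values` (a T x M matrix, rows = timepoints, columns = components,
#'   each column standardized to mean 0 and SD 1), `group`, and the
#'   planted ground truth in `clusters` and `lags`.
#' @export
simulate_subject <- function(config, group = c("Control", "Patient",
                                               "Disenrolled"),
                             counter = 1L) {
  validate_sim_config(config)
  group <- match.arg(group)
  alpha <- if (group == "Patient") config$coupling_patient
           else config$coupling_control
  T_len <- config$T_len
  lag_max <- config$max_true_lag

  with_seed(subject_seed(config$seed, counter), {
    M <- config$M_range[1] +
      sample.int(config$M_range[2] - config$M_range[1] + 1L, 1L) - 1L
    clusters <- sample(config$n_clusters, M, replace = TRUE)
    lags <- sample(0:lag_max, M, replace = TRUE)
    # extra leading points so lagged reads stay inside the series
    base <- sapply(seq_len(config$n_clusters),
                   function(i) ar1_series(T_len + lag_max, config$ar_coef))
    x <- matrix(0, T_len, M)
    for (j in seq_len(M)) {
      shifted <- base[(1 + lag_max - lags[j]):(T_len + lag_max - lags[j]),
                      clusters[j]]
      noise <- ar1_series(T_len, config$ar_coef)
      x[, j] <- alpha * shifted + sqrt(1 - alpha^2) * noise
    }
    x <- scale(x)            # zero mean, unit (n-1) SD per column
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
    structure(list(subject_id = sprintf("S%04d", counter),
                   values = x, group = group,
                   clusters = clusters, lags = lags),
              class = "fnc_subject")
  })
}

#' @export
print.fnc_subject <- function(x, ...) {
  cat(sprintf("FNC subject %s (%s): %d timepoints x %d components\n",
              x$subject_id, x$group %||% "ungrouped",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a two-group cohort of component timecourses
#'
#' Generates `n_per_group` subjects per group (plus any disenrolled
#' subjects) and the matching phenotype table.  Deterministic given
#' `config$seed`: each subject draws from its own counter-indexed
#' substream, so the cohort is bit-identical across runs and stable under
#' subject reordering.
#'
#' @param config an [fnc_sim_config()] object.
#' @return An object of class `fnc_cohort`: list with `subjects` (list of
#'   [simulate_subject()] results), `phenotype` (data.frame with columns
#'   `subject_id`, `diagnosis`), and `config`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  groups <- c(rep("Control", config$n_per_group),
              rep("Patient", config$n_per_group),
              rep("Disenrolled", config$n_disenrolled))
  subjects <- lapply(seq_along(groups), function(i)
    simulate_subject(config, groups[i], counter = i))
  phenotype <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    diagnosis = groups,
    stringsAsFactors = FALSE)
  structure(list(subjects = subjects, phenotype = phenotype,
                 config = config),
            class = "fnc_cohort")
}

#' @export
print.fnc_cohort <- function(x, ...) {
  tab <- table(x$phenotype$diagnosis)
  cat(sprintf("FNC cohort: %d subjects (%s)\n", length(x$subjects),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
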