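#' Lagged cross-correlation between two timeseries
#'
#' For lag \eqn{l \ge 0},
#' \deqn{CCF(l) = \frac{1}{T} \sum_{t=1}^{T-l}
#'   \frac{(x_{t+l} - \bar x)(y_t - \bar y)}{s_x s_y}}
#' where \eqn{\bar x, \bar y} are full-series means and \eqn{s_x, s_y}
#' full-series standard deviations with divisor \eqn{T}; negative lags
#' swap the roles of `x` and `y`.  This matches the convention of
#' `stats::ccf()`: the value at lag `l` measures `x` lagging `y` by `l`
#' points.  Values are not strictly bounded by 1 in finite samples.
#'
#' @param x,y numeric vectors of equal length with nonzero variance.
#' @param max_lag lag bound `L >= 0`; the result covers lags `-L..L`.
#' @return Numeric vector of length `2 * max_lag + 1`, named by lag.
#' @export
#' @examples
#' x <- sin(seq(0, 4 * pi, length.out = 50))
#' cross_correlation(x, x, 0)       # 1 at lag 0
cross_correlation <- function(x, y, max_lag) {
  T_len <- length(x)
  if (length(y) != T_len)
    stop("timeseries lengths differ", call. = FALSE)
  max_lag <- as.integer(max_lag)
  if (max_lag < 0 || max_lag >= T_len)
    stop("invalid lag bound: need 0 <= max_lag < length(x)", call. = FALSE)
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  if (sx == 0 || sy == 0)
    stop("degenerate series: zero variance input", call. = FALSE)
  xc <- (x - mean(x)) / sx
  yc <- (y - mean(y)) / sy
  lags <- seq(-max_lag, max_lag)
  out <- vapply(lags, function(l) {
    if (l >= 0) sum(xc[(1 + l):T_len] * yc[1:(T_len - l)]) / T_len
    else        sum(yc[(1 - l):T_len] * xc[1:(T_len + l)]) / T_len
  }, numeric(1))
  names(out) <- lags
  out
}

#' Pseudo-distance between two timeseries
#'
#' One minus the maximal absolute lagged cross-correlation over lags
#' `-max_lag..max_lag`, clamped into `[0, 1]`.  A value of 0 means
#' perfectly coupled (including anti-coupled, since the absolute value is
#' taken); 1 means uncoupled.
#'
#' @inheritParams cross_correlation
#' @return A number in `[0, 1]`.
#' @export
pseudo_distance <- function(x, y, max_lag) {
  d <- 1 - max(abs(cross_correlation(x, y, max_lag)))
  min(max(d, 0), 1)
}

#' Per-subject connectivity pseudo-distance matrix
#'
#' Computes [pseudo_distance()] for every unordered pair of components of
#' one subject, mirrored into a symmetric M x M matrix with zero
#' diagonal.  Internally the computation is vectorized: columns are
#' standardized by full-series moments (divisor T) and the lagged
#' cross-products are formed by matrix multiplication, which is
#' arithmetically identical to the pairwise formula.
#'
#' @param subject an `fnc_subject`, or a plain T x M numeric matrix
#'   (rows = timepoints, columns = components).
#' @param max_lag lag bound in timepoints; default 3.
#' @return An object of class `fnc_dist`: list with `subject_id`, `D`
#'   (the M x M pseudo-distance matrix) and `max_lag`.
#' @export
distance_matrix <- function(subject, max_lag = 3L) {
  if (inherits(subject, "fnc_subject")) {
    values <- subject$values
    id <- subject$subject_id
  } else {
    values <- as.matrix(subject)
    id <- attr(subject, "subject_id") %||% "subject"
  }
  T_len <- nrow(values)
  M <- ncol(values)
  if (M < 3L)
    stop("need at least 3 components", call. = FALSE)
  max_lag <- as.integer(max_lag)
  if (max_lag < 0 || max_lag >= T_len)
    stop("invalid lag bound: need 0 <= max_lag < T", call. = FALSE)
  vars <- apply(values, 2, function(col) mean((col - mean(col))^2))
  if (any(vars == 0))
    stop(sprintf("zero-variance component column(s): %s",
                 paste(which(vars == 0), collapse = ", ")), call. = FALSE)
  z <- sweep(values, 2, colMeans(values))
  z <- sweep(z, 2, sqrt(vars), "/")
  # maxcc[i, j] accumulates max over lags of |CCF(x_i, x_j, l)|;
  # lag l >= 0 gives crossprod(z[(1+l):T, ], z[1:(T-l), ]) / T, and the
  # transpose covers the negative lags.
  maxcc <- abs(crossprod(z)) / T_len
  for (l in seq_len(max_lag)) {
    cc <- abs(crossprod(z[(1 + l):T_len, , drop = FALSE],
                        z[1:(T_len - l), , drop = FALSE])) / T_len
    maxcc <- pmax(maxcc, cc, t(cc))
  }
  D <- 1 - maxcc
  D[D < 0] <- 0
  D[D > 1] <- 1
  diag(D) <- 0
  D <- (D + t(D)) / 2          # exact symmetry against rounding
  structure(list(subject_id = id, D = D, max_lag = max_lag),
            class = "fnc_dist")
}

#' @export
print.fnc_dist <- function(x, ...) {
  cat(sprintf("FNC pseudo-distance matrix for %s: %d components, max lag %d\n",
              x$subject_id, nrow(x$D), x$max_lag))
  invisible(x)
}
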