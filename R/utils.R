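#' Principal component analysis on a numeric matrix
#'
#' Thin wrapper around [stats::prcomp()] that centres and scales columns,
#' checks the requested rank, and returns scores, loadings and explained
#' variance in one list. Used both for the mesic/xeric stand classification
#' and for ordination of pooled climate-growth correlations.
#'
#' @param x numeric matrix or data frame (observations in rows).
#' @param n_components number of components to return; defaults to the rank.
#' @param scale. logical, scale columns to unit variance (default `TRUE`).
#' @return list with `scores`, `loadings`, `sdev`, `explained` (proportion of
#'   variance per component) and `center`/`scale` vectors.
#' @export
run_pca <- function(x, n_components = NULL, scale. = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (anyNA(x)) stop("'x' must be complete (no NA)")
  sds <- apply(x, 2, stats::sd)
  if (scale. && any(sds == 0)) stop("zero-variance column(s): ",
                                    paste(colnames(x)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (is.null(n_components)) n_components <- rank
  if (n_components > rank) {
    stop("requested ", n_components, " components but matrix rank is ", rank)
  }
  keep <- seq_len(n_components)
  list(scores    = pc$x[, keep, drop = FALSE],
       loadings  = pc$rotation[, keep, drop = FALSE],
       sdev      = pc$sdev[keep],
       explained = pc$sdev[keep]^2 / sum(pc$sdev^2),
       center    = pc$center,
       scale     = if (scale.) pc$scale else rep(1, ncol(x)))
}

#' Gini coefficient of a non-negative distribution
#'
#' Mean absolute difference form, G = sum_ij |x_i - x_j| / (2 n^2 mu),
#' bounded in \[0, 1 - 1/n\]. Used for within-stand tree size (DBH) and age
#' inequality.
#'
#' @param x non-negative numeric vector, length >= 2.
#' @return Gini coefficient in \[0, 1).
#' @export
gini <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 finite values")
  if (any(x < 0)) stop("values must be non-negative")
  mu <- mean(x)
  if (mu == 0) stop("mean of 'x' is zero; Gini undefined")
  n <- length(x)
  xs <- sort(x)
  # identity: sum_ij |xi - xj| = 2 * sum_i (2i - n - 1) x_(i)
  g <- 2 * sum((2 * seq_len(n) - n - 1) * xs) / (2 * n^2 * mu)
  g
}

#' Tukey's biweight robust mean
#'
#' Iterated biweight location estimate with tuning constant `c = 9` on the
#' MAD scale, the standard aggregation for tree-ring chronologies. Falls
#' back to the common value when the MAD is zero.
#'
#' @param x numeric vector with at least one finite value.
#' @param c_tune tuning constant (default 9).
#' @param tol convergence tolerance on the location update.
#' @return robust mean, bounded between `min(x)` and `max(x)`.
#' @export
biweight_mean <- function(x, c_tune = 9, tol = 1e-8) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no finite values")
  if (length(x) == 1) return(x)
  m <- stats::median(x)
  s <- stats::mad(x, center = m, constant = 1)
  if (s == 0) return(m)
  for (i in 1:100) {
    u <- (x - m) / (c_tune * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(m)
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Frequency-cutoff smoothing spline
#'
#' Discrete cubic-smoothing-spline analogue built from a second-difference
#' roughness penalty. The smoothing parameter is solved analytically from
#' the amplitude criterion used in tree-ring standardization: a sinusoid of
#' period `nyrs` years is attenuated to fraction `f` (default 50%) of its
#' amplitude, i.e. lambda = ((1 - f)/f) / (2 sin(pi / nyrs))^4.
#'
#' @param y numeric series (regular annual spacing, no NA).
#' @param nyrs period (years) at which the frequency response equals `f`.
#' @param f frequency response at period `nyrs` (default 0.5).
#' @return fitted smooth values, same length as `y`.
#' @export
cps_spline <- function(y, nyrs = 10, f = 0.5) {
  if (anyNA(y)) stop("series contains NA")
  n <- length(y)
  if (n < 4) stop("series too short for spline fitting")
  if (nyrs <= 1) stop("'nyrs' must exceed 1 year")
  lambda <- ((1 - f) / f) / (2 * sin(pi / nyrs))^4
  # banded second-difference operator; penalized system solved sparsely
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  A <- Matrix::Diagonal(n) + lambda * Matrix::crossprod(D)
  as.numeric(Matrix::solve(A, y))
}
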