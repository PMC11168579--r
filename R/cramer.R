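#' Cramer (Baringhaus-Franz) two-sample statistic
#'
#' Multivariate two-sample statistic built from Euclidean distances: distances
#' between the two samples enter with positive weight, within-sample distances
#' with negative weight,
#' \deqn{T = \frac{mn}{m+n}\Big(\frac{1}{mn}\sum_{i,j}\phi(\|X_i-Y_j\|^2)
#'   - \frac{1}{2m^2}\sum_{i,j}\phi(\|X_i-X_j\|^2)
#'   - \frac{1}{2n^2}\sum_{i,j}\phi(\|Y_i-Y_j\|^2)\Big).}
#' With the default kernel \eqn{\phi(z) = \sqrt{z}/2} (half the Euclidean
#' distance, applied to squared distances) T is a scaled energy distance
#' between the empirical distributions: non-negative, and zero exactly when
#' the two empirical distributions coincide. Large values indicate a
#' difference between the distributions.
#'
#' @param x,y Numeric matrices (rows = observations) or vectors (treated as
#'   one-dimensional samples) of equal dimension.
#' @param kernel Function applied to squared Euclidean distances. Any positive
#'   multiple of the default rescales T but leaves bootstrap p-values
#'   unchanged.
#' @return The statistic, a single number.
#' @export
cramer_statistic <- function(x, y, kernel = kernel_cramer) {
  x <- as_sample_matrix(x)
  y <- as_sample_matrix(y)
  if (ncol(x) != ncol(y)) stop("`x` and `y` must share dimension", call. = FALSE)
  if (nrow(x) < 1 || nrow(y) < 1) stop("empty sample", call. = FALSE)
  K <- kernel(pooled_sqdist(rbind(x, y)))
  cramer_from_kernel(K, seq_len(nrow(x)), nrow(x) + seq_len(nrow(y)))
}

#' Default Cramer kernel: half the Euclidean distance
#' @param z Squared Euclidean distances.
#' @return `sqrt(z) / 2`.
#' @export
kernel_cramer <- function(z) sqrt(z) / 2

as_sample_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  x
}

pooled_sqdist <- function(z) {
  g <- tcrossprod(z)
  q <- diag(g)
  d2 <- outer(q, q, `+`) - 2 * g
  d2[d2 < 0] <- 0
  d2
}

cramer_from_kernel <- function(K, i, j) {
  m <- length(i); n <- length(j)
  (m * n / (m + n)) *
    (sum(K[i, j]) / (m * n) -
       sum(K[i, i]) / (2 * m^2) -
       sum(K[j, j]) / (2 * n^2))
}

#' Bootstrap two-sample Cramer test
#'
#' Computes the Cramer statistic for the observed split and estimates its
#' p-value by resampling. Under the default `"permutation"` mode the pooled
#' sample of size m+n is randomly re-split into groups of m and n — exact
#' under the exchangeability of the null hypothesis F = G. Under
#' `"ordinary_bootstrap"` the pooled sample is instead drawn m+n times with
#' replacement; with small samples of sparse high-dimensional vectors this
#' mode is markedly conservative, because duplicated draws inflate the
#' replicate statistics. The p-value is the plain proportion of
#' replicates with `T* >= T_obs`, with no +1 continuity correction, so an
#' observed statistic exceeding every replicate yields an estimated p of
#' exactly zero.
#'
#' @inheritParams cramer_statistic
#' @param B Number of resampling replicates (default 1000).
#' @param seed Integer seed making the replicate stream reproducible.
#' @param resampling `"permutation"` (default) or `"ordinary_bootstrap"`.
#' @return An object of class `cramer_test` with fields `statistic`,
#'   `p_value`, `m`, `n`, `B`, `seed`, `kernel`, `resampling`.
#' @export
cramer_test <- function(x, y, B = 1000, seed = NULL,
                        resampling = c("permutation", "ordinary_bootstrap"),
                        kernel = kernel_cramer) {
  resampling <- match.arg(resampling)
  if (!is.numeric(B) || length(B) != 1 || B < 1) {
    stop("`B` must be a positive integer", call. = FALSE)
  }
  B <- as.integer(B)
  x <- as_sample_matrix(x)
  y <- as_sample_matrix(y)
  if (ncol(x) != ncol(y)) stop("`x` and `y` must share dimension", call. = FALSE)
  m <- nrow(x); n <- nrow(y); N <- m + n
  K <- kernel(pooled_sqdist(rbind(x, y)))
  t_obs <- cramer_from_kernel(K, seq_len(m), m + seq_len(n))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  t_star <- numeric(B)
  for (b in seq_len(B)) {
    idx <- if (resampling == "ordinary_bootstrap") {
      sample.int(N, N, replace = TRUE)
    } else {
      sample.int(N)
    }
    t_star[b] <- cramer_from_kernel(K, idx[seq_len(m)], idx[m + seq_len(n)])
  }
  structure(
    list(statistic = t_obs,
         p_value = mean(t_star >= t_obs),
         m = m, n = n, B = B,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         kernel = deparse(substitute(kernel)),
         resampling = resampling),
    class = "cramer_test"
  )
}

#' @export
print.cramer_test <- function(x, ...) {
  cat("Cramer two-sample bootstrap test\n")
  cat(sprintf("  T = %.6g, p = %.4g (m = %d, n = %d, B = %d, %s)\n",
              x$statistic, x$p_value, x$m, x$n, x$B, x$resampling))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Cramer test result
#' @param x A `cramer_test`.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `p_value`, `m`, `n`, `B`,
#'   `resampling`.
#' @export
tidy.cramer_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 m = x$m, n = x$n, B = x$B, resampling = x$resampling)
}

#' @rdname tidy.cramer_test
#' @export
glance.cramer_test <- function(x, ...) tidy.cramer_test(x)

#' Compare two cohorts of a feature matrix
#'
#' Splits the proportion rows of a [feature_matrix()] by cohort label and runs
#' the bootstrap Cramer test on the two groups of feature vectors.
#'
#' @param matrix A [feature_matrix()] tibble with exactly two cohort labels.
#' @inheritParams cramer_test
#' @return A `cramer_test` object.
#' @export
compare_feature_cohorts <- function(matrix, B = 1000, seed = NULL,
                                    resampling = c("permutation",
                                                   "ordinary_bootstrap"),
                                    kernel = kernel_cramer) {
  labs <- unique(matrix$cohort)
  if (length(labs) != 2) {
    stop("feature matrix must contain exactly two cohorts, found ",
         length(labs), call. = FALSE)
  }
  cols <- fv_columns(matrix)
  x <- as.matrix(matrix[matrix$cohort == labs[1], cols])
  y <- as.matrix(matrix[matrix$cohort == labs[2], cols])
  cramer_test(x, y, B = B, seed = seed,
              resampling = match.arg(resampling), kernel = kernel)
}
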