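#' Construct a simple difference sequence of order m
#'
#' Builds the Yatchew "simple" difference sequence
#' \eqn{d_0 = \sqrt{m/(m+1)}}, \eqn{d_q = -1/\sqrt{m(m+1)}} for
#' \eqn{q = 1, \dots, m}.  Any valid difference sequence must have zero sum
#' (so that differencing annihilates locally constant signals, in particular
#' the smooth trend \eqn{f(t)}) and unit sum of squares (so that differencing
#' preserves the scale of white noise).  The simple sequence satisfies both
#' exactly; for `m = 3` it is
#' \eqn{(\sqrt{3/4}, -\sqrt{1/12}, -\sqrt{1/12}, -\sqrt{1/12})}.
#'
#' @param m Order of differencing, a positive integer.
#' @return An object of class `diff_sequence`: a list with elements `order`
#'   (integer) and `weights` (numeric vector of length `m + 1`).
#' @seealso [as_diff_sequence()] to validate user-supplied weights,
#'   [diff_matrix()] for the associated banded matrix.
#' @examples
#' diff_sequence(3)
#' @export
diff_sequence <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 || m != floor(m)) {
    stop("`m` must be a single positive integer (got ", deparse(m), ").",
         call. = FALSE)
  }
  m <- as.integer(m)
  w <- c(sqrt(m / (m + 1)), rep(-1 / sqrt(m * (m + 1)), m))
  new_diff_sequence(w, tol = 1e-12)
}

#' Validate user-supplied differencing weights
#'
#' Accepts a numeric weight vector \eqn{(d_0, \dots, d_m)} if and only if
#' \eqn{\sum_q d_q = 0} and \eqn{\sum_q d_q^2 = 1} hold within `tol`, and
#' returns the typed sequence.  Weights typed in from decimal literals are
#' accepted at the looser default tolerance.
#'
#' @param weights Numeric vector of length at least 2.
#' @param tol Absolute tolerance on both constraint residuals.
#' @return A `diff_sequence` object.
#' @examples
#' as_diff_sequence(c(1, -1) / sqrt(2))
#' @export
as_diff_sequence <- function(weights, tol = 1e-8) {
  if (!is.numeric(weights) || length(weights) < 2L || anyNA(weights)) {
    stop("`weights` must be a numeric vector of length >= 2 with no NAs.",
         call. = FALSE)
  }
  new_diff_sequence(as.numeric(weights), tol = tol)
}

new_diff_sequence <- function(weights, tol) {
  sum_resid <- abs(sum(weights))
  ssq_resid <- abs(sum(weights^2) - 1)
  if (sum_resid > tol) {
    stop("Invalid difference sequence: sum of weights must be 0 ",
         "(residual ", format(sum_resid), ").", call. = FALSE)
  }
  if (ssq_resid > tol) {
    stop("Invalid difference sequence: sum of squared weights must be 1 ",
         "(residual ", format(ssq_resid), ").", call. = FALSE)
  }
  structure(
    list(order = length(weights) - 1L, weights = as.numeric(weights)),
    class = "diff_sequence"
  )
}

#' @export
print.diff_sequence <- function(x, ...) {
  cat("<diff_sequence> order m =", x$order, "\n")
  cat("  weights:", paste(format(x$weights, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Banded differencing matrix
#'
#' Returns the \eqn{(n-m) \times n} matrix `D` whose row `i` carries the
#' weights \eqn{d_0, \dots, d_m} in columns `i` to `i + m` and zeros
#' elsewhere, so that `D %*% y` computes all differenced values
#' \eqn{\tilde y_i = \sum_q d_q y_{i+q}}.
#'
#' @param seq A `diff_sequence`.
#' @param n Number of observations; must exceed the order `m`.
#' @return A dense numeric matrix of dimension `(n - m) x n`.
#' @export
diff_matrix <- function(seq, n) {
  stopifnot(inherits(seq, "diff_sequence"))
  m <- seq$order
  if (!is.numeric(n) || length(n) != 1L || n != floor(n) || n <= m) {
    stop("`n` must be an integer greater than the differencing order m = ",
         m, ".", call. = FALSE)
  }
  n <- as.integer(n)
  D <- matrix(0, n - m, n)
  for (q in 0:m) {
    D[cbind(seq_len(n - m), seq_len(n - m) + q)] <- seq$weights[q + 1L]
  }
  D
}

# Banded application of a difference sequence to a vector or matrix,
# equivalent to diff_matrix(seq, n) %*% v without forming D.
difference_apply <- function(seq, v) {
  w <- seq$weights
  m <- seq$order
  if (is.matrix(v)) {
    out <- apply(v, 2, function(col) {
      as.vector(stats::embed(col, m + 1L) %*% rev(w))
    })
    if (nrow(v) - m == 1L) out <- matrix(out, nrow = 1L)
    out
  } else {
    as.vector(stats::embed(v, m + 1L) %*% rev(w))
  }
}

#' Apply differencing to a partially linear model dataset
#'
#' Computes the differenced response \eqn{\tilde y_i = \sum_q d_q y_{i+q}}
#' and covariates \eqn{\tilde x_i = \sum_q d_q x_{i+q}} of the reduced linear
#' model \eqn{\tilde Y = \tilde X \beta + \tilde e}.  Differencing removes
#' the smooth nonparametric component \eqn{f(t)} up to terms that vanish as
#' the design points tighten, which is what licenses ordinary least squares
#' on the differenced data.
#'
#' @param data A data frame with columns `t`, `y` and covariates
#'   `x1, ..., xd` (see [read_plm()] for the format).
#' @param seq A `diff_sequence`; defaults to the order-3 simple sequence.
#' @return A tibble with `n - m` rows and columns `y_tilde` and
#'   `x1_tilde, ..., xd_tilde`.
#' @examples
#' d <- simulate_plm(32, seed = 1)
#' apply_differencing(d)
#' @export
apply_differencing <- function(data, seq = diff_sequence(3)) {
  stopifnot(inherits(seq, "diff_sequence"))
  plm <- as_plm_data(data)
  if (plm$n <= seq$order) {
    stop("Need n > m rows to difference (n = ", plm$n, ", m = ", seq$order,
         ").", call. = FALSE)
  }
  y_tilde <- difference_apply(seq, plm$y)
  X_tilde <- difference_apply(seq, plm$X)
  out <- tibble::as_tibble(as.data.frame(X_tilde))
  names(out) <- paste0(colnames(plm$X), "_tilde")
  dplyr::bind_cols(tibble::tibble(y_tilde = y_tilde), out)
}

# Internal: validate and unpack a (t, y, x1..xd) data frame.
as_plm_data <- function(data) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame with columns t, y, x1, ...",
         call. = FALSE)
  }
  nms <- names(data)
  xcols <- grep("^x[0-9]+$", nms, value = TRUE)
  missing <- setdiff(c("t", "y"), nms)
  if (length(missing) > 0 || length(xcols) == 0) {
    stop("`data` must contain columns t, y and at least one covariate ",
         "column x1, x2, ...; missing: ",
         paste(c(missing, if (length(xcols) == 0) "x1"), collapse = ", "),
         ".", call. = FALSE)
  }
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  t <- as.numeric(data$t)
  y <- as.numeric(data$y)
  X <- as.matrix(data[xcols])
  storage.mode(X) <- "double"
  if (anyNA(t) || anyNA(y) || anyNA(X)) {
    stop("`data` contains missing or non-numeric values.", call. = FALSE)
  }
  if (any(t < 0 | t > 1)) {
    bad <- which(t < 0 | t > 1)[1]
    stop("`t` must lie in [0, 1]; row ", bad, " has t = ", t[bad], ".",
         call. = FALSE)
  }
  if (is.unsorted(t)) {
    stop("`t` must be nondecreasing; use read_plm() to reorder on input.",
         call. = FALSE)
  }
  list(t = t, y = y, X = X, n = length(y), d = ncol(X))
}
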