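# Refinement (two-scale) coefficients c_q with sum 2; phi has support
# [0, length(c) - 1].  Daubechies filters in the standard orthonormal
# normalization multiplied by sqrt(2).
daub_refinement <- list(
  "haar" = c(1, 1),
  "daubechies-2" = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / 4,
  "daubechies-3" = sqrt(2) * c(0.3326705529509569, 0.8068915093133388,
                               0.4598775021193313, -0.1350110200102546,
                               -0.0854412738822415, 0.0352262918821007)
)

#' Tabulate a compactly supported scaling function
#'
#' Evaluates the scaling function (father wavelet) \eqn{\phi} of a
#' multiresolution analysis on a dyadic grid of step `2^-refinement` over
#' its support by the cascade algorithm: the values at integers solve the
#' eigenproblem of the two-scale relation
#' \eqn{\phi(x) = \sum_q c_q \phi(2x - q)}, which is then iterated to
#' refine the grid.  Daubechies families are named by their number of
#' vanishing moments; `"haar"` (the indicator of `[0, 1)`) is provided as
#' an analytically tractable test family even though it lacks the
#' smoothness the asymptotic theory assumes.
#'
#' @param family One of `"daubechies-2"`, `"daubechies-3"`, `"haar"`.
#' @param refinement Dyadic refinement level `J`; the table has step
#'   `2^-J`.  At least 6 for Daubechies families.
#' @return An object of class `scaling_function` with elements `family`,
#'   `support` (c(0, L)), `grid`, `values`, `step`.
#' @examples
#' phi <- scaling_function("daubechies-2")
#' phi_eval(phi, c(0.5, 1, 1.5))
#' @export
scaling_function <- function(family = "daubechies-2", refinement = 10) {
  if (!family %in% names(daub_refinement)) {
    stop("Unknown scaling-function family '", family, "'. Supported: ",
         paste(names(daub_refinement), collapse = ", "), ".", call. = FALSE)
  }
  J <- as.integer(refinement)
  if (family != "haar" && J < 6) {
    stop("`refinement` must be >= 6 for Daubechies families.", call. = FALSE)
  }
  h <- daub_refinement[[family]]
  L <- length(h) - 1L
  if (family == "haar") {
    grid <- seq(0, 1, by = 2^-J)
    values <- as.numeric(grid < 1)
  } else {
    # Values at integers: eigenvector of M[j, i] = c_{2j - i} for
    # eigenvalue 1, normalized to sum 1 (partition of unity at integers).
    M <- matrix(0, L + 1L, L + 1L)
    for (j in 0:L) {
      for (i in 0:L) {
        q <- 2L * j - i
        if (q >= 0 && q <= L) M[j + 1L, i + 1L] <- h[q + 1L]
      }
    }
    ev <- eigen(M)
    k1 <- which.min(abs(ev$values - 1))
    v <- Re(ev$vectors[, k1])
    v <- v / sum(v)
    # Dyadic refinement: values on step 2^-j from step 2^-(j-1).
    for (j in seq_len(J)) {
      prev <- v
      len <- L * 2^j + 1L
      v <- numeric(len)
      for (q in 0:L) {
        idx <- seq_len(len) - 1L - q * 2^(j - 1L)
        ok <- idx >= 0 & idx <= L * 2^(j - 1L)
        v[ok] <- v[ok] + h[q + 1L] * prev[idx[ok] + 1L]
      }
    }
    grid <- seq(0, L, by = 2^-J)
    values <- v
  }
  # cumulative integral of the piecewise-linear interpolant (trapezoid is
  # exact for it); used for closed-form interval integration
  cumint <- c(0, cumsum((values[-1] + values[-length(values)]) / 2)) * 2^-J
  structure(
    list(family = family, support = c(0, L), grid = grid, values = values,
         step = 2^-J, cumint = cumint),
    class = "scaling_function"
  )
}

#' @export
print.scaling_function <- function(x, ...) {
  cat("<scaling_function>", x$family, " support [0,", x$support[2],
      "] step", format(x$step), "\n")
  invisible(x)
}

#' Evaluate a tabulated scaling function
#'
#' Linear interpolation between dyadic table points; zero outside the
#' support.  For a Lipschitz \eqn{\phi} the interpolation error is of the
#' order of the table step.
#'
#' @param phi A `scaling_function`.
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of \eqn{\phi(x)} values.
#' @export
phi_eval <- function(phi, x) {
  stopifnot(inherits(phi, "scaling_function"))
  out <- numeric(length(x))
  ok <- x > phi$support[1] & x < phi$support[2]
  if (phi$family == "haar") {
    ok <- x >= 0 & x < 1
    out[ok] <- 1
    return(out)
  }
  if (any(ok)) {
    xi <- x[ok] / phi$step
    lo <- floor(xi)
    frac <- xi - lo
    out[ok] <- phi$values[lo + 1L] * (1 - frac) + phi$values[lo + 2L] * frac
  }
  out
}

#' Resolution level from the sample size
#'
#' The multiresolution level \eqn{\tilde m} must satisfy
#' \eqn{2^{\tilde m} = O(n^{1/3})} for the smoother's variance and bias to
#' balance; the default rule is \eqn{\tilde m = \lfloor \log_2(n)/3 \rfloor}.
#'
#' @param n Sample size, at least 8.
#' @return Integer resolution level.
#' @examples
#' choose_resolution(128)
#' @export
choose_resolution <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 8) {
    stop("`n` must be a single number >= 8.", call. = FALSE)
  }
  as.integer(floor(log2(n) / 3))
}

#' Multiresolution reproducing kernel
#'
#' Bundles a scaling function with a resolution level \eqn{\tilde m},
#' defining the projection kernel of the space \eqn{V_{\tilde m}}:
#' \deqn{E_{\tilde m}(t, s) = 2^{\tilde m} \sum_k \phi(2^{\tilde m} t - k)
#'   \phi(2^{\tilde m} s - k).}
#'
#' @param phi A `scaling_function` (or a family name, which is tabulated at
#'   the default refinement).
#' @param resolution Nonnegative integer \eqn{\tilde m}.
#' @return An object of class `repro_kernel`.
#' @export
repro_kernel <- function(phi = scaling_function("daubechies-2"),
                         resolution) {
  if (is.character(phi)) phi <- scaling_function(phi)
  stopifnot(inherits(phi, "scaling_function"))
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      resolution < 0 || resolution != floor(resolution)) {
    stop("`resolution` must be a nonnegative integer.", call. = FALSE)
  }
  structure(list(phi = phi, resolution = as.integer(resolution)),
            class = "repro_kernel")
}

#' @export
print.repro_kernel <- function(x, ...) {
  cat("<repro_kernel>", x$phi$family, " resolution m~ =", x$resolution, "\n")
  invisible(x)
}

#' Evaluate the reproducing kernel
#'
#' Computes \eqn{E_{\tilde m}(t, s)} as a finite sum over the translates
#' `k` whose support overlaps both arguments.  The sum is symmetric in
#' `(t, s)` and vanishes when `|t - s|` exceeds the support width times
#' `2^-resolution` (locality).
#'
#' @param kernel A `repro_kernel`.
#' @param t,s Numeric vectors in `[0, 1]`, recycled to a common length.
#' @return Numeric vector of kernel values.
#' @export
kernel_eval <- function(kernel, t, s) {
  stopifnot(inherits(kernel, "repro_kernel"))
  if (any(t < 0 | t > 1) || any(s < 0 | s > 1)) {
    stop("`t` and `s` must lie in [0, 1].", call. = FALSE)
  }
  nmax <- max(length(t), length(s))
  t <- rep_len(t, nmax)
  s <- rep_len(s, nmax)
  phi <- kernel$phi
  L <- phi$support[2]
  two_m <- 2^kernel$resolution
  out <- numeric(nmax)
  tt <- two_m * t
  ss <- two_m * s
  klo <- ceiling(pmax(tt, ss) - L)
  khi <- floor(pmin(tt, ss))
  for (i in seq_len(nmax)) {
    if (khi[i] < klo[i]) next
    ks <- klo[i]:khi[i]
    out[i] <- two_m *
      sum(phi_eval(phi, tt[i] - ks) * phi_eval(phi, ss[i] - ks))
  }
  out
}

#' Uniform partition of the unit interval
#'
#' Breakpoints \eqn{s_i = i/n}, the partition used when design points are
#' the equispaced \eqn{t_i = i/n} (so that \eqn{t_i \in [s_{i-1}, s_i]}).
#'
#' @param n Number of intervals.
#' @return Numeric vector of `n + 1` breakpoints from 0 to 1.
#' @export
uniform_partition <- function(n) {
  (0:n) / n
}

#' Midpoint partition adapted to design points
#'
#' Breakpoints \eqn{s_0 = 0}, \eqn{s_i = (t_i + t_{i+1})/2},
#' \eqn{s_n = 1}; each \eqn{t_i} lies in its own interval for any
#' nondecreasing design.
#'
#' @param t Nondecreasing numeric vector in `[0, 1]`.
#' @return Numeric vector of `length(t) + 1` breakpoints.
#' @export
plm_breaks <- function(t) {
  n <- length(t)
  c(0, (t[-n] + t[-1]) / 2, 1)
}

check_partition <- function(breaks, t = NULL, C = 4) {
  n <- length(breaks) - 1L
  if (n < 1L || breaks[1] != 0 || abs(breaks[n + 1L] - 1) > 1e-12 ||
      is.unsorted(breaks, strictly = TRUE)) {
    stop("`breaks` must be strictly increasing from 0 to 1.", call. = FALSE)
  }
  if (max(diff(breaks)) > C / n) {
    stop("Partition mesh exceeds ", C, "/n; intervals must shrink at rate ",
         "O(1/n).", call. = FALSE)
  }
  if (!is.null(t)) {
    if (length(t) != n ||
        any(t < breaks[-(n + 1L)] - 1e-12 | t > breaks[-1] + 1e-12)) {
      stop("Each design point t_i must lie in its interval ",
           "[s_{i-1}, s_i].", call. = FALSE)
    }
  }
  invisible(breaks)
}

# Antiderivative of the tabulated piecewise-linear interpolant of phi,
# evaluated at x (vectorized); exact, clamped outside the support.
phi_antideriv <- function(phi, x) {
  if (phi$family == "haar") return(pmin(pmax(x, 0), 1))
  L <- phi$support[2]
  x <- pmin(pmax(x, 0), L)
  xi <- x / phi$step
  lo <- pmin(floor(xi), length(phi$values) - 2)
  d <- (xi - lo) * phi$step
  v0 <- phi$values[lo + 1L]
  v1 <- phi$values[lo + 2L]
  phi$cumint[lo + 1L] + v0 * d + (v1 - v0) / (2 * phi$step) * d^2
}

#' Interval-integrated kernel weights
#'
#' Computes \eqn{w_i(t) = \int_{A_i} E_{\tilde m}(t, s)\, ds} for every
#' interval \eqn{A_i = [s_{i-1}, s_i]} of the partition.  These are the
#' weights the nonparametric estimator applies to the parametric residuals.
#' The integral is evaluated in closed form: each translate contributes
#' \eqn{\phi(2^{\tilde m} t - k)} times an increment of the antiderivative
#' of the tabulated \eqn{\phi}, which integrates the piecewise-linear
#' interpolant exactly (for the Haar family this reduces to the
#' interval-overlap length times \eqn{2^{\tilde m}}).
#'
#' For interior `t` the weights sum to approximately 1 (the kernel
#' integrates to 1 in the limit); near the boundary mass is lost to
#' truncation of the translate sum.
#'
#' @param kernel A `repro_kernel`.
#' @param breaks Partition breakpoints `s_0 = 0 < ... < s_n = 1`.
#' @param t Evaluation point in `[0, 1]`.
#' @return Numeric vector of `length(breaks) - 1` weights.
#' @export
kernel_weights <- function(kernel, breaks, t) {
  stopifnot(inherits(kernel, "repro_kernel"))
  if (t < 0 || t > 1) stop("`t` must lie in [0, 1].", call. = FALSE)
  check_partition(breaks)
  n <- length(breaks) - 1L
  two_m <- 2^kernel$resolution
  phi <- kernel$phi
  L <- phi$support[2]
  if (phi$family == "haar") {
    # E(t, s) = 2^m on the dyadic bin of t, 0 elsewhere.
    bin <- min(floor(t * two_m), two_m - 1L)
    lo <- bin / two_m
    hi <- (bin + 1) / two_m
    over <- pmax(0, pmin(breaks[-1], hi) - pmax(breaks[-(n + 1L)], lo))
    return(two_m * over)
  }
  tt <- two_m * t
  ks <- seq.int(ceiling(tt - L), floor(tt))
  pk <- phi_eval(phi, tt - ks)
  ks <- ks[pk != 0]
  pk <- pk[pk != 0]
  w <- numeric(n)
  if (length(ks) == 0) return(w)
  # Phi table at all breakpoints for each active translate
  for (j in seq_along(ks)) {
    Phi_b <- phi_antideriv(phi, two_m * breaks - ks[j])
    w <- w + pk[j] * diff(Phi_b)
  }
  w
}

#' Wavelet reproducing-kernel estimate of the nonparametric component
#'
#' Given the DOLS estimate of \eqn{\beta}, estimates \eqn{f} by
#' \deqn{\hat f_n(t) = \sum_{i=1}^n (y_i - x_i^T \hat\beta_n)
#'   \int_{A_i} E_{\tilde m}(t, s)\, ds,}
#' i.e. a kernel-weighted sum of parametric residuals.  Values within one
#' kernel support width of the boundary are flagged: the translate sum is
#' truncated there and the raw estimate is reported unrenormalized.
#'
#' @param data A data frame with columns `t`, `y`, `x1, ..., xd`.
#' @param beta_hat Either a `dols_fit` or a numeric coefficient vector.
#'   Defaults to fitting DOLS with the order-3 simple sequence.
#' @param kernel A `repro_kernel`; default daubechies-2 at
#'   `choose_resolution(n)`.
#' @param breaks Partition breakpoints; default [plm_breaks()] on the
#'   design points.
#' @param grid Evaluation grid in `[0, 1]`; default 101 equispaced points.
#' @return An object of class `plm_smooth`: list with `estimate` (tibble
#'   with columns `t`, `f_hat`, `weight_sum`, `boundary`), `weights`
#'   (grid-by-n matrix), `kernel`, `residuals`.
#' @examples
#' d <- simulate_plm(128, seed = 1)
#' sm <- smooth_plm(d)
#' head(sm$estimate)
#' @export
smooth_plm <- function(data, beta_hat = NULL, kernel = NULL, breaks = NULL,
                       grid = seq(0, 1, length.out = 101)) {
  plm <- as_plm_data(data)
  if (is.null(beta_hat)) beta_hat <- dols(data)
  if (inherits(beta_hat, "dols_fit")) beta_hat <- beta_hat$beta_hat
  if (length(beta_hat) != plm$d) {
    stop("`beta_hat` must have length d = ", plm$d, ".", call. = FALSE)
  }
  if (is.null(kernel)) {
    kernel <- repro_kernel(scaling_function("daubechies-2"),
                           choose_resolution(plm$n))
  }
  if (is.null(breaks)) breaks <- plm_breaks(plm$t)
  check_partition(breaks, plm$t)
  if (any(grid < 0 | grid > 1)) {
    stop("`grid` points must lie in [0, 1].", call. = FALSE)
  }
  resid <- plm$y - drop(plm$X %*% beta_hat)
  W <- t(vapply(grid, function(tt) kernel_weights(kernel, breaks, tt),
                numeric(plm$n)))
  margin <- boundary_margin(kernel)
  est <- tibble::tibble(
    t = grid,
    f_hat = drop(W %*% resid),
    weight_sum = rowSums(W),
    boundary = grid < margin | grid > 1 - margin
  )
  structure(
    list(estimate = est, weights = W, kernel = kernel, residuals = resid,
         breaks = breaks),
    class = "plm_smooth"
  )
}

#' @export
print.plm_smooth <- function(x, ...) {
  cat("<plm_smooth>", x$kernel$phi$family, " m~ =", x$kernel$resolution,
      " grid points:", nrow(x$estimate), "\n")
  invisible(x)
}

#' Boundary margin of a reproducing kernel
#'
#' Distance from the interval edge within which the kernel's translate
#' sum is truncated, so the weights \eqn{w_i(t)} no longer integrate to 1.
#' A translate \eqn{\phi(2^{\tilde m} s - k)} contributes at `t` when
#' \eqn{2^{\tilde m} t - L < k < 2^{\tilde m} t} (support `[0, L]`); all
#' contributing translates lie inside `[0, 1]` exactly when `t` is at
#' least \eqn{(L - 1) 2^{-\tilde m}} from each edge.
#'
#' @param kernel A `repro_kernel`.
#' @return Nonnegative scalar margin.
#' @export
boundary_margin <- function(kernel) {
  stopifnot(inherits(kernel, "repro_kernel"))
  (kernel$phi$support[2] - 1) / 2^kernel$resolution
}

#' Pointwise variance of the wavelet estimator
#'
#' The limiting standardization of \eqn{\hat f_n(t)} uses
#' \eqn{\tau_t^2 = Var(\sum_i e_i \int_{A_i} E_{\tilde m}(t, s) ds)
#' = w^T Cov(e) w}.  Supply the error covariance as a scalar variance
#' (iid, giving \eqn{\sigma^2 \sum_i w_i^2}) or a full matrix.
#'
#' @param weights Numeric weight vector \eqn{w_i(t)}.
#' @param error_cov Scalar variance or `n x n` covariance matrix.
#' @return Nonnegative scalar \eqn{\tau_t^2}.
#' @export
tau2_t <- function(weights, error_cov) {
  if (!all(is.finite(weights))) {
    stop("`weights` must be finite.", call. = FALSE)
  }
  out <- if (is.matrix(error_cov)) {
    drop(crossprod(weights, error_cov %*% weights))
  } else {
    if (length(error_cov) != 1L) {
      stop("`error_cov` must be a scalar variance or a covariance matrix.",
           call. = FALSE)
    }
    error_cov * sum(weights^2)
  }
  if (out < -1e-10) {
    stop("tau2_t is negative; `error_cov` is not positive semidefinite.",
         call. = FALSE)
  }
  max(out, 0)
}
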