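#' Difference-based ordinary least squares for the partially linear model
#'
#' Fits the parametric component \eqn{\beta} of
#' \eqn{y_i = x_i^T \beta + f(t_i) + e_i} by applying a difference sequence
#' to remove \eqn{f} and running ordinary least squares on the reduced model
#' \eqn{\tilde Y = \tilde X \beta + \tilde e}, giving the closed form
#' \eqn{\hat\beta_n = \Sigma_n^{-1} \tilde X^T \tilde Y} with
#' \eqn{\Sigma_n = \tilde X^T \tilde X}.
#'
#' @param data A data frame with columns `t`, `y`, `x1, ..., xd`; `t`
#'   nondecreasing in `[0, 1]`.
#' @param m Differencing order used when `weights` is `NULL`; the simple
#'   sequence of that order is used.
#' @param weights Optional explicit differencing weights, validated by
#'   [as_diff_sequence()].
#' @return An object of class `dols_fit` with elements `beta_hat` (named
#'   numeric), `Sigma_n`, `residuals` (length `n - m`), `seq`, `y_tilde`,
#'   `X_tilde`, `n`, `d` and the original `data`.
#' @examples
#' d <- simulate_plm(128, beta = 5, seed = 1)
#' fit <- dols(d)
#' tidy(fit)
#' @export
dols <- function(data, m = 3, weights = NULL) {
  seq <- if (is.null(weights)) diff_sequence(m) else as_diff_sequence(weights)
  plm <- as_plm_data(data)
  if (plm$n <= seq$order + plm$d) {
    stop("Need n > m + d observations (n = ", plm$n, ", m = ", seq$order,
         ", d = ", plm$d, ").", call. = FALSE)
  }
  y_tilde <- difference_apply(seq, plm$y)
  X_tilde <- difference_apply(seq, plm$X)
  colnames(X_tilde) <- colnames(plm$X)
  core <- dols_core(y_tilde, X_tilde)
  structure(
    c(core,
      list(seq = seq, y_tilde = y_tilde, X_tilde = X_tilde,
           n = plm$n, d = plm$d, data = data)),
    class = "dols_fit"
  )
}

# Solve the differenced normal equations; shared by dols() and the study
# harness (which skips data-frame plumbing in its inner loop).
dols_core <- function(y_tilde, X_tilde) {
  Sigma_n <- crossprod(X_tilde)
  kap <- kappa(Sigma_n, exact = TRUE)
  if (!is.finite(kap) || kap > 1e12) {
    stop("Sigma_n = crossprod(X_tilde) is singular or near-singular ",
         "(condition number ", format(kap, digits = 3),
         "); the differenced design does not identify beta.", call. = FALSE)
  }
  beta_hat <- drop(solve(Sigma_n, crossprod(X_tilde, y_tilde)))
  names(beta_hat) <- colnames(X_tilde)
  resid <- y_tilde - drop(X_tilde %*% beta_hat)
  list(beta_hat = beta_hat, Sigma_n = Sigma_n, residuals = resid)
}

#' @export
print.dols_fit <- function(x, ...) {
  cat("<dols_fit> n =", x$n, " m =", x$seq$order, " d =", x$d, "\n")
  cat("  beta_hat:", paste(format(x$beta_hat, digits = 6), collapse = ", "),
      "\n")
  invisible(x)
}

#' Lag products of a difference sequence
#'
#' Returns \eqn{\gamma_k = \sum_{q=0}^{m-k} d_q d_{q+k}} for
#' \eqn{k = 1, \dots, m}.  For iid errors with variance \eqn{\sigma^2} the
#' differenced errors satisfy
#' \eqn{Cov(\tilde e_i, \tilde e_{i+k}) = \gamma_k \sigma^2} and are
#' uncorrelated beyond lag `m`.
#'
#' @param seq A `diff_sequence`.
#' @return Numeric vector of length `m` (lags 1 to m).
#' @export
lag_gamma <- function(seq) {
  stopifnot(inherits(seq, "diff_sequence"))
  w <- seq$weights
  m <- seq$order
  vapply(seq_len(m), function(k) {
    sum(w[seq_len(m - k + 1L)] * w[seq_len(m - k + 1L) + k])
  }, numeric(1))
}

new_beta_covariance <- function(tau2, method, lag_truncation) {
  tau2 <- (tau2 + t(tau2)) / 2
  structure(
    list(tau2 = tau2, method = method,
         lag_truncation = as.integer(lag_truncation)),
    class = "beta_covariance"
  )
}

#' @export
print.beta_covariance <- function(x, ...) {
  cat("<beta_covariance> method =", x$method,
      " lag =", x$lag_truncation, "\n")
  print(x$tau2)
  invisible(x)
}

#' Closed-form limiting covariance of the DOLS estimator under iid errors
#'
#' Under iid errors with variance `sigma2` the limiting covariance of the
#' standardized DOLS estimator is
#' \deqn{\tau^2_\beta = (n-m)^{-1} \{ \sum_i \tilde x_i \tilde x_i^T \sigma^2
#'   + 2 \sum_{k=1}^m \sum_i \tilde x_i \tilde x_{i+k}^T \gamma_k \sigma^2 \},}
#' with \eqn{\gamma_k} from [lag_gamma()]; differenced errors are
#' uncorrelated past lag `m`, so the outer sum stops there.
#'
#' @param seq The `diff_sequence` used for differencing.
#' @param X_tilde Differenced covariate matrix, `(n - m) x d`.
#' @param sigma2 Error variance, positive scalar.
#' @return A `beta_covariance` object with `method = "iid_closed_form"`.
#' @export
tau2_beta_iid <- function(seq, X_tilde, sigma2) {
  stopifnot(inherits(seq, "diff_sequence"))
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0) {
    stop("`sigma2` must be a positive scalar.", call. = FALSE)
  }
  X_tilde <- as.matrix(X_tilde)
  nm <- nrow(X_tilde)
  gam <- lag_gamma(seq)
  acc <- crossprod(X_tilde)
  for (k in seq_along(gam)) {
    if (nm - k < 1L) break
    i <- seq_len(nm - k)
    acc <- acc + 2 * gam[k] *
      crossprod(X_tilde[i, , drop = FALSE], X_tilde[i + k, , drop = FALSE])
  }
  new_beta_covariance(sigma2 * acc / nm, "iid_closed_form", seq$order)
}

#' HAC-type residual plug-in covariance for the DOLS estimator
#'
#' Empirical counterpart of the limiting covariance \eqn{\tau^2_\beta},
#' replacing the variances and covariances of the differenced errors by
#' residual products \eqn{\hat e_i \hat e_j} and truncating the double sum
#' at `|i - j| <= lag_truncation`:
#' \deqn{\hat\tau^2_\beta = (n-m)^{-1} \{ \sum_i \tilde x_i \tilde x_i^T
#'   \hat e_i^2 + 2 \sum_{k=1}^{L} \sum_i \tilde x_i \tilde x_{i+k}^T
#'   \hat e_i \hat e_{i+k} \}.}
#' For iid model errors the differenced-error autocovariance vanishes past
#' lag `m`; the default `m + 5` adds a small guard for dependence.
#'
#' @param fit A `dols_fit`.
#' @param lag_truncation Nonnegative truncation lag `L`, at most `n - m - 1`.
#' @return A `beta_covariance` with `method = "residual_plugin"`.  If the
#'   truncated sum is not positive semidefinite its negative eigenvalues are
#'   clipped at zero with a warning.
#' @export
tau2_beta_plugin <- function(fit, lag_truncation = fit$seq$order + 5) {
  stopifnot(inherits(fit, "dols_fit"))
  nm <- length(fit$residuals)
  L <- lag_truncation
  if (!is.numeric(L) || length(L) != 1L || L < 0 || L != floor(L) ||
      L > nm - 1L) {
    stop("`lag_truncation` must be an integer in [0, n - m - 1].",
         call. = FALSE)
  }
  r <- fit$residuals
  Xw <- fit$X_tilde * r  # rows x_i~ scaled by e_i^
  acc <- crossprod(Xw)
  for (k in seq_len(L)) {
    if (nm - k < 1L) break
    i <- seq_len(nm - k)
    acc <- acc + 2 * crossprod(Xw[i, , drop = FALSE], Xw[i + k, , drop = FALSE])
  }
  tau2 <- (acc + t(acc)) / (2 * nm)
  ev <- eigen(tau2, symmetric = TRUE)
  if (any(ev$values < 0)) {
    warning("Plug-in tau2_beta not positive semidefinite; negative ",
            "eigenvalues clipped at zero. Consider a smaller lag.",
            call. = FALSE)
    tau2 <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  }
  new_beta_covariance(tau2, "residual_plugin", L)
}

# Inverse symmetric square root with an eigenvalue floor.
inv_sqrtm <- function(S, floor = 1e-12) {
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(ev$values) <= floor) {
    stop("Covariance matrix is not positive definite (min eigenvalue ",
         format(min(ev$values), digits = 3),
         "); increase n or reduce the lag truncation.", call. = FALSE)
  }
  ev$vectors %*% (ev$values^(-0.5) * t(ev$vectors))
}

#' Standardized DOLS statistic
#'
#' Computes \eqn{M = (n-m)^{-1/2} \tau_\beta^{-1} \Sigma_n
#' (\hat\beta_n - \beta_0)}, where \eqn{\tau_\beta^{-1}} is the inverse
#' symmetric square root of the supplied covariance.  Under the model
#' assumptions `M` is asymptotically standard `d`-variate normal, which is
#' what the Monte-Carlo study harness checks.
#'
#' @param fit A `dols_fit`.
#' @param cov A `beta_covariance` (positive definite).
#' @param beta0 Hypothesized true parameter vector, length `d`.
#' @return Numeric vector of length `d`.
#' @export
standardize_beta <- function(fit, cov, beta0) {
  stopifnot(inherits(fit, "dols_fit"), inherits(cov, "beta_covariance"))
  if (length(beta0) != fit$d) {
    stop("`beta0` must have length d = ", fit$d, ".", call. = FALSE)
  }
  nm <- length(fit$residuals)
  drop(inv_sqrtm(cov$tau2) %*% (fit$Sigma_n %*% (fit$beta_hat - beta0))) /
    sqrt(nm)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DOLS fit
#'
#' One row per coefficient with plug-in standard errors: the covariance of
#' \eqn{\hat\beta_n} is estimated by
#' \eqn{(n-m) \Sigma_n^{-1} \hat\tau^2_\beta \Sigma_n^{-1}} with the
#' HAC-type residual plug-in of [tau2_beta_plugin()].
#'
#' @param x A `dols_fit`.
#' @param lag_truncation Passed to [tau2_beta_plugin()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`.
#' @method tidy dols_fit
#' @export
tidy.dols_fit <- function(x, lag_truncation = x$seq$order + 5, ...) {
  cov <- tau2_beta_plugin(x, lag_truncation)
  nm <- length(x$residuals)
  Sinv <- solve(x$Sigma_n)
  V <- nm * Sinv %*% cov$tau2 %*% Sinv
  se <- sqrt(pmax(diag(V), 0))
  tibble::tibble(
    term = names(x$beta_hat),
    estimate = unname(x$beta_hat),
    std.error = se,
    statistic = unname(x$beta_hat) / se
  )
}

#' Glance at a DOLS fit
#'
#' @param x A `dols_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `m`, `d`, `sigma2_tilde` (mean squared
#'   differenced residual) and `min_eigen_Sigma` (smallest eigenvalue of
#'   \eqn{\Sigma_n}, a finite-sample identifiability diagnostic).
#' @method glance dols_fit
#' @export
glance.dols_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    m = x$seq$order,
    d = x$d,
    sigma2_tilde = mean(x$residuals^2),
    min_eigen_Sigma = min(eigen(x$Sigma_n, symmetric = TRUE,
                                only.values = TRUE)$values)
  )
}
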