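# Shared fixed-design setup for the simulation studies: equispaced t,
# cosine covariate, sine trend, differenced design and exact error moments.
study_setup <- function(n, m, beta0, pmf, target_sum, center, error_model,
                        covariate_fn = function(t) cos(2 * pi * t),
                        f_fn = function(t) sin(2 * pi * t)) {
  t <- (1:n) / n
  X <- covariate_fn(t)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  if (ncol(X) != 1L || length(beta0) != 1L) {
    stop("The study harness covers the scalar-covariate design (d = 1).",
         call. = FALSE)
  }
  colnames(X) <- "x1"
  f <- f_fn(t)
  seq <- diff_sequence(m)
  X_tilde <- difference_apply(seq, X)
  colnames(X_tilde) <- "x1"
  f_tilde <- difference_apply(seq, f)
  if (error_model == "gaussian") {
    mom <- list(var = 1, cov = 0)
    tab <- NULL
  } else {
    mom <- nsd_moments(pmf, n, target_sum = target_sum, center = center)
    tab <- nsd_sum_table(pmf, n)
  }
  list(t = t, X = X, f = f, seq = seq, X_tilde = X_tilde, f_tilde = f_tilde,
       Sigma_n = crossprod(X_tilde), var = mom$var, cov = mom$cov,
       sigma_eff = mom$var - mom$cov, table = tab, n = n, m = m,
       beta0 = beta0, pmf = pmf, target_sum = target_sum, center = center,
       error_model = error_model)
}

draw_errors <- function(su) {
  if (su$error_model == "gaussian") {
    stats::rnorm(su$n)
  } else {
    sample_nsd(su$n, su$pmf, target_sum = su$target_sum, center = su$center,
               table = su$table)
  }
}

new_normality_report <- function(samples, statistic, n, reps, dropped,
                                 extra = list()) {
  N <- length(samples)
  srt <- sort(samples)
  structure(
    c(list(
      samples = samples,
      statistic = statistic,
      n = n, reps = reps, dropped = dropped,
      sample_mean = mean(samples),
      sample_var = stats::var(samples),
      ks_stat = ks_statistic(samples),
      ecdf = tibble::tibble(x = srt, F_hat = seq_len(N) / N),
      qq = tibble::tibble(theoretical = stats::qnorm((seq_len(N) - 0.5) / N),
                          empirical = srt)
    ), extra),
    class = "normality_report"
  )
}

#' @export
print.normality_report <- function(x, ...) {
  cat("<normality_report>", x$statistic, " n =", x$n, " reps =", x$reps,
      "\n")
  cat("  sample mean ", format(x$sample_mean, digits = 4),
      "  sample var ", format(x$sample_var, digits = 4),
      "  KS vs N(0,1) ", format(x$ks_stat, digits = 4), "\n")
  if (x$dropped > 0) cat("  dropped replications:", x$dropped, "\n")
  invisible(x)
}

#' @rdname run_beta_study
#' @method glance normality_report
#' @export
glance.normality_report <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, n = x$n, reps = x$reps,
    sample_mean = x$sample_mean, sample_var = x$sample_var,
    ks_stat = x$ks_stat, dropped = x$dropped
  )
}

#' @rdname run_beta_study
#' @method tidy normality_report
#' @export
tidy.normality_report <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$samples), statistic = x$samples)
}

#' Monte-Carlo normality study of the standardized DOLS estimator
#'
#' Replicates the reference simulation design (equispaced
#' \eqn{t_i = i/n}, \eqn{x_i = \cos(2\pi t_i)},
#' \eqn{f(t_i) = \sin(2\pi t_i)}, sum-conditioned NSD errors), fits DOLS
#' in each replication and standardizes
#' \eqn{M = (n-m)^{-1/2} \tau_\beta^{-1} \Sigma_n (\hat\beta_n - \beta_0)}.
#' The standardizing \eqn{\tau^2_\beta} is computed once from the exact
#' conditional error moments: the conditional law is exchangeable, and for
#' exchangeable errors the zero-sum differencing weights reduce the general
#' covariance to the iid closed form evaluated at the effective variance
#' \eqn{v - c} (marginal variance minus common pairwise covariance).  Under
#' the asymptotic theory the collected statistics approach N(0, 1); the
#' report carries their ECDF, normal QQ pairs and Kolmogorov-Smirnov
#' distance.
#'
#' A degenerate (zero-variance) error law makes every statistic zero and
#' the report reduces to a point mass (KS distance 0.5).
#'
#' @param n Sample size.
#' @param reps Number of Monte-Carlo replications (>= 100).
#' @param m Differencing order (simple sequence).
#' @param beta0 True scalar coefficient.
#' @param pmf Base `error_pmf` for the NSD construction.
#' @param error_model `"nsd"` (sum-conditioned pmf) or `"gaussian"`
#'   (iid standard normal, a sanity anchor: iid is an NSD special case).
#' @param target_sum,center Passed to [sample_nsd()].
#' @param seed Optional integer seed; the whole study is reproducible
#'   from it.
#' @return A `normality_report`; see [glance.normality_report()].  The
#'   element `beta_hat` holds the per-replication estimates.
#' @examples
#' \donttest{
#' rep <- run_beta_study(n = 64, reps = 200, seed = 1)
#' glance(rep)
#' }
#' @export
run_beta_study <- function(n = 128, reps = 1000, m = 3, beta0 = 5,
                           pmf = nsd_pmf(),
                           error_model = c("nsd", "gaussian"),
                           target_sum = n, center = TRUE, seed = NULL) {
  error_model <- match.arg(error_model)
  if (reps < 100) stop("`reps` must be at least 100.", call. = FALSE)
  run <- function() {
    su <- study_setup(n, m, beta0, pmf, target_sum, center, error_model)
    nm <- n - m
    degenerate <- su$sigma_eff < 1e-14
    scale_fac <- if (degenerate) NA_real_ else {
      tau2 <- tau2_beta_iid(su$seq, su$X_tilde, su$sigma_eff)$tau2
      1 / (sqrt(nm) * sqrt(drop(tau2)))
    }
    samples <- numeric(reps)
    betas <- numeric(reps)
    dropped <- 0L
    for (r in seq_len(reps)) {
      res <- tryCatch({
        e <- draw_errors(su)
        y_tilde <- drop(su$X_tilde) * beta0 + su$f_tilde +
          difference_apply(su$seq, e)
        fit <- dols_core(y_tilde, su$X_tilde)
        score <- drop(su$Sigma_n) * (fit$beta_hat - beta0)
        c(if (degenerate) 0 else score * scale_fac, fit$beta_hat)
      }, error = function(cnd) NULL)
      if (is.null(res)) {
        dropped <- dropped + 1L
        samples[r] <- NA_real_
        betas[r] <- NA_real_
      } else {
        samples[r] <- res[1]
        betas[r] <- res[2]
      }
    }
    if (dropped > 0.05 * reps) {
      stop("More than 5% of replications failed (", dropped, "/", reps,
           ").", call. = FALSE)
    }
    keep <- !is.na(samples)
    new_normality_report(samples[keep], "M_beta", n, reps, dropped,
                         extra = list(beta_hat = betas[keep],
                                      error_model = error_model))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Monte-Carlo normality study of the standardized wavelet estimator
#'
#' Runs the full pipeline per replication: DOLS for \eqn{\beta}, then the
#' reproducing-kernel estimate \eqn{\hat f_n(t^*)} at the interior
#' evaluation point, standardized by
#' \eqn{\tau_t = \sqrt{Var(\sum_i e_i w_i(t^*))}} computed from the exact
#' exchangeable error covariance (variance `v`, common pairwise covariance
#' `c`): \eqn{\tau_t^2 = (v - c) \sum_i w_i^2 + c (\sum_i w_i)^2}.  The
#' design uses the uniform partition \eqn{s_i = i/n}, matching the
#' equispaced design points.
#'
#' @inheritParams run_beta_study
#' @param family Scaling-function family for the kernel.
#' @param resolution Resolution level; default [choose_resolution()] of `n`.
#' @param t_eval Interior evaluation point \eqn{t^*}; must be outside the
#'   kernel's [boundary_margin()].
#' @return A `normality_report` with statistic `"M_f"`; element `f_hat`
#'   holds the per-replication estimates and `tau_t` the standardizer.
#' @examples
#' \donttest{
#' rep <- run_f_study(n = 64, reps = 200, seed = 1)
#' glance(rep)
#' }
#' @export
run_f_study <- function(n = 128, reps = 1000, m = 3, beta0 = 5,
                        pmf = nsd_pmf(), family = "daubechies-2",
                        resolution = NULL, t_eval = 0.5,
                        error_model = c("nsd", "gaussian"),
                        target_sum = n, center = TRUE, seed = NULL) {
  error_model <- match.arg(error_model)
  if (reps < 100) stop("`reps` must be at least 100.", call. = FALSE)
  run <- function() {
    su <- study_setup(n, m, beta0, pmf, target_sum, center, error_model)
    if (is.null(resolution)) resolution <- choose_resolution(n)
    kern <- repro_kernel(scaling_function(family), resolution)
    margin <- boundary_margin(kern)
    if (t_eval < margin || t_eval > 1 - margin) {
      stop("`t_eval` = ", t_eval, " is inside the kernel boundary margin (",
           format(margin, digits = 3), "); the weights there do not sum ",
           "to 1.", call. = FALSE)
    }
    w <- kernel_weights(kern, uniform_partition(n), t_eval)
    Sigma_e <- (su$var - su$cov) * diag(n) + su$cov
    tau2 <- tau2_t(w, Sigma_e)
    if (tau2 < 1e-14) {
      stop("tau_t = 0: the error law is noiseless, the standardized ",
           "statistic is undefined.", call. = FALSE)
    }
    tau_t <- sqrt(tau2)
    f_true <- sin(2 * pi * t_eval)
    samples <- numeric(reps)
    fhats <- numeric(reps)
    dropped <- 0L
    for (r in seq_len(reps)) {
      res <- tryCatch({
        e <- draw_errors(su)
        y <- drop(su$X) * beta0 + su$f + e
        y_tilde <- drop(su$X_tilde) * beta0 + su$f_tilde +
          difference_apply(su$seq, e)
        fit <- dols_core(y_tilde, su$X_tilde)
        fhat <- sum((y - drop(su$X) * fit$beta_hat) * w)
        c((fhat - f_true) / tau_t, fhat)
      }, error = function(cnd) NULL)
      if (is.null(res)) {
        dropped <- dropped + 1L
        samples[r] <- NA_real_
        fhats[r] <- NA_real_
      } else {
        samples[r] <- res[1]
        fhats[r] <- res[2]
      }
    }
    if (dropped > 0.05 * reps) {
      stop("More than 5% of replications failed (", dropped, "/", reps,
           ").", call. = FALSE)
    }
    keep <- !is.na(samples)
    new_normality_report(samples[keep], "M_f", n, reps, dropped,
                         extra = list(f_hat = fhats[keep], tau_t = tau_t,
                                      t_eval = t_eval,
                                      error_model = error_model))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Kolmogorov-Smirnov distance to a reference distribution
#'
#' Sup-distance between the empirical CDF of `x` and a continuous
#' reference CDF (standard normal by default), evaluated at both one-sided
#' limits of the ECDF steps.
#'
#' @param x Numeric sample of at least 2 values.
#' @param cdf Reference CDF function.
#' @return The KS statistic in `[0, 1]`.
#' @examples
#' ks_statistic(qnorm((1:1000 - 0.5) / 1000))
#' @export
ks_statistic <- function(x, cdf = stats::pnorm) {
  n <- length(x)
  if (n < 2) stop("Need at least 2 samples.", call. = FALSE)
  Fx <- cdf(sort(x))
  max(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n)
}

#' Monte-Carlo check of Rosenthal-type maximal moment bounds
#'
#' For mean-zero NSD (or iid) errors the partial-sum maximum satisfies
#' \deqn{E \max_k |\sum_{i \le k} e_i|^p \le 2^{3-p} \sum_i E|e_i|^p,
#'   \quad 1 < p \le 2,}
#' and the weighted (differenced) version with weights \eqn{c_q}
#' \deqn{E \max_k |\sum_{i \le k} \sum_q c_q e_{i+q}|^p \le
#'   4 m^{p-1} \sum_i \sum_q E|c_q e_{i+q}|^p.}
#' (For `p > 2` the corresponding bounds with the
#' \eqn{2 (15p/\ln p)^p} constants are used.)  The left side is estimated
#' by Monte Carlo; the right side is computed exactly from the marginal
#' law.  The returned ratio LHS/RHS should not exceed 1 beyond Monte-Carlo
#' error.
#'
#' @param p Moment exponent, greater than 1.
#' @param n Sequence length.
#' @param reps Monte-Carlo replications.
#' @param seq Optional `diff_sequence`; when supplied the weighted bound
#'   is checked with \eqn{c_q} equal to the differencing weights.
#' @param pmf Base `error_pmf`.
#' @param error_model `"nsd"` for sum-conditioned errors, `"iid"` for
#'   independent draws from the centered pmf.
#' @param target_sum Conditioning value for the NSD model.
#' @param seed Optional integer seed.
#' @return A one-row tibble with columns `p`, `n`, `m`, `ratio`, `se`
#'   (Monte-Carlo standard error of the ratio), `lhs`, `rhs`.
#' @export
check_moment_inequality <- function(p, n, reps = 2000, seq = NULL,
                                    pmf = nsd_pmf(),
                                    error_model = c("nsd", "iid"),
                                    target_sum = n, seed = NULL) {
  error_model <- match.arg(error_model)
  if (!is.numeric(p) || length(p) != 1L || p <= 1) {
    stop("`p` must be a single number greater than 1.", call. = FALSE)
  }
  run <- function() {
    if (error_model == "nsd") {
      if (n < 2) stop("NSD conditioning needs n >= 2.", call. = FALSE)
      mom <- nsd_moments(pmf, n, target_sum = target_sum, center = TRUE)
      shift <- target_sum / n
      marg_val <- mom$marginal$value - shift
      marg_prob <- mom$marginal$prob
      tab <- nsd_sum_table(pmf, n)
      sampler <- function() {
        sample_nsd(n, pmf, target_sum = target_sum, center = TRUE,
                   table = tab)
      }
    } else {
      mu <- sum(pmf$support * pmf$probs)
      marg_val <- pmf$support - mu
      marg_prob <- pmf$probs
      sampler <- function() {
        pmf$support[sample.int(length(pmf$probs), n, replace = TRUE,
                               prob = pmf$probs)] - mu
      }
    }
    abs_p <- sum(abs(marg_val)^p * marg_prob)
    var_e <- sum(marg_val^2 * marg_prob)
    if (is.null(seq)) {
      m <- NA_integer_
      lhs_draw <- function() max(abs(cumsum(sampler())))^p
      rhs <- if (p <= 2) {
        2^(3 - p) * n * abs_p
      } else {
        2 * (15 * p / log(p))^p * (n * abs_p + (n * var_e)^(p / 2))
      }
    } else {
      stopifnot(inherits(seq, "diff_sequence"))
      m <- seq$order
      if (n <= m) stop("Need n > m for the weighted bound.", call. = FALSE)
      wp <- sum(abs(seq$weights)^p)
      lhs_draw <- function() {
        max(abs(cumsum(difference_apply(seq, sampler()))))^p
      }
      rhs <- if (p <= 2) {
        4 * m^(p - 1) * n * wp * abs_p
      } else {
        2^(p + 1) * m^(p - 1) * (15 * p / log(p))^p *
          (n * wp * abs_p + (n * sum(seq$weights^2) * var_e)^(p / 2))
      }
    }
    lhs <- vapply(seq_len(reps), function(r) lhs_draw(), numeric(1))
    tibble::tibble(
      p = p, n = n, m = m,
      ratio = mean(lhs) / rhs,
      se = stats::sd(lhs) / sqrt(reps) / rhs,
      lhs = mean(lhs), rhs = rhs
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
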