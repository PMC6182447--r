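#' Base probability mass function for NSD errors
#'
#' The default is the three-point law \eqn{P(e = 0) = 0.4},
#' \eqn{P(e = 1) = 0.2}, \eqn{P(e = 2) = 0.4}.  An iid sample from this pmf
#' conditioned on its sum equaling `n` is a negatively superadditive
#' dependent (NSD) sequence: fixing the total makes large values in one
#' coordinate crowd out large values elsewhere.
#'
#' @param support Integer support points.
#' @param probs Probabilities, nonnegative, summing to 1.
#' @return An object of class `error_pmf`.
#' @examples
#' nsd_pmf()
#' @export
nsd_pmf <- function(support = c(0, 1, 2), probs = c(0.4, 0.2, 0.4)) {
  if (length(support) != length(probs) || length(support) < 1L) {
    stop("`support` and `probs` must have equal positive length.",
         call. = FALSE)
  }
  if (any(support != floor(support))) {
    stop("`support` must be integer-valued.", call. = FALSE)
  }
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-12) {
    stop("`probs` must be nonnegative and sum to 1 (residual ",
         format(abs(sum(probs) - 1)), ").", call. = FALSE)
  }
  o <- order(support)
  structure(list(support = as.integer(support[o]), probs = probs[o]),
            class = "error_pmf")
}

#' @export
print.error_pmf <- function(x, ...) {
  cat("<error_pmf>\n")
  print(stats::setNames(x$probs, x$support))
  invisible(x)
}

#' Exact distribution of partial sums
#'
#' Dynamic-programming convolution table of \eqn{P(S_k = s)} for
#' \eqn{k = 1, \dots, n}, where \eqn{S_k} is the sum of `k` iid draws from
#' the pmf.  Each row is renormalized to sum exactly 1.  This table is the
#' backbone of exact conditional sampling and of exact conditional moments.
#'
#' @param pmf An `error_pmf`.
#' @param n Number of summands.
#' @return An `n x (n * (max - min) + 1)` matrix; column `j` corresponds
#'   to the sum value `n * min(support) + j - 1` (see the `"offset"`
#'   attribute and column names).
#' @export
nsd_sum_table <- function(pmf, n) {
  stopifnot(inherits(pmf, "error_pmf"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop("`n` must be a positive integer.", call. = FALSE)
  }
  n <- as.integer(n)
  lo <- min(pmf$support)
  hi <- max(pmf$support)
  width <- n * (hi - lo) + 1L
  tab <- matrix(0, n, width)
  # Base pmf over offsets 0..(hi - lo).
  base <- numeric(hi - lo + 1L)
  base[pmf$support - lo + 1L] <- pmf$probs
  tab[1L, seq_along(base)] <- base
  if (n > 1L) {
    for (k in 2L:n) {
      prev <- tab[k - 1L, seq_len((k - 1L) * (hi - lo) + 1L)]
      cur <- numeric(k * (hi - lo) + 1L)
      for (a in seq_along(base)) {
        if (base[a] == 0) next
        idx <- seq_along(prev) + (a - 1L)
        cur[idx] <- cur[idx] + base[a] * prev
      }
      cur <- cur / sum(cur)
      tab[k, seq_along(cur)] <- cur
    }
  }
  colnames(tab) <- as.character(n * lo + seq_len(width) - 1L)
  attr(tab, "offset") <- n * lo
  tab
}

# P(S_k = s) lookup with out-of-range -> 0.
sum_prob <- function(tab, k, s) {
  off <- attr(tab, "offset")
  j <- s - off + 1L
  ok <- k >= 1L & j >= 1L & j <= ncol(tab)
  out <- numeric(length(s))
  out[ok] <- tab[cbind(rep_len(k, length(s))[ok], j[ok])]
  out
}

#' Exact draw from the sum-conditioned NSD law
#'
#' Samples \eqn{(e_1, \dots, e_n)} from the law of iid draws given
#' \eqn{S_n = } `target_sum`, by exact sequential sampling: the first
#' coordinate is drawn from
#' \eqn{P(e_1 = a \mid S_n = T) \propto p_a P(S_{n-1} = T - a)} and the
#' construction recurses on the remaining coordinates and the remaining
#' target.  Uncentered draws sum to `target_sum` exactly; with
#' `center = TRUE` (default) the conditional per-coordinate mean
#' `target_sum / n` is subtracted so the returned errors have mean-zero
#' marginals as assumed by the asymptotic theory.
#'
#' @param n Length of the error sequence.
#' @param pmf An `error_pmf`.
#' @param target_sum Conditioning value of the sum, default `n`; must be
#'   attainable.
#' @param center Subtract `target_sum / n` from each coordinate?
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @param table Optional precomputed [nsd_sum_table()] for this pmf and `n`
#'   (a speed-up when sampling repeatedly).
#' @return Numeric vector of length `n`.
#' @examples
#' sample_nsd(16, seed = 1)
#' @export
sample_nsd <- function(n, pmf = nsd_pmf(), target_sum = n, center = TRUE,
                       seed = NULL, table = NULL) {
  stopifnot(inherits(pmf, "error_pmf"))
  n <- as.integer(n)
  if (target_sum < n * min(pmf$support) || target_sum > n * max(pmf$support)) {
    stop("`target_sum` = ", target_sum, " is unattainable for n = ", n,
         " draws from this support.", call. = FALSE)
  }
  if (is.null(table)) table <- nsd_sum_table(pmf, n)
  if (sum_prob(table, n, target_sum) <= 0) {
    stop("`target_sum` = ", target_sum, " has probability zero under the ",
         "base pmf.", call. = FALSE)
  }
  draw <- function() {
    e <- integer(n)
    r <- as.integer(target_sum)
    for (i in seq_len(n)) {
      remaining <- n - i
      if (remaining == 0L) {
        e[i] <- r
        break
      }
      p <- pmf$probs * sum_prob(table, remaining, r - pmf$support)
      e[i] <- pmf$support[sample.int(length(p), 1L, prob = p)]
      r <- r - e[i]
    }
    e
  }
  e <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (center) e - target_sum / n else as.numeric(e)
}

#' Exact moments of the sum-conditioned error law
#'
#' Conditional per-coordinate mean, variance and (by exchangeability,
#' common) pairwise covariance of the NSD construction, computed exactly
#' from the partial-sum table:
#' \eqn{P(e_1 = a \mid S_n = T) \propto p_a P(S_{n-1} = T - a)} and
#' \eqn{P(e_1 = a, e_2 = b \mid S_n = T) \propto p_a p_b
#' P(S_{n-2} = T - a - b)}.  Because the sum is fixed, the covariance
#' satisfies \eqn{c = -v/(n - 1)} exactly; this identity is a useful
#' cross-check.
#'
#' @param pmf An `error_pmf`.
#' @param n Sequence length (at least 2).
#' @param target_sum Conditioning value, default `n`.
#' @param center If `TRUE` the mean is reported for centered errors
#'   (variance and covariance are unaffected by centering).
#' @return A list with `mean`, `var`, `cov` and the marginal table
#'   `marginal` (tibble with columns `value`, `prob`).
#' @export
nsd_moments <- function(pmf, n, target_sum = n, center = TRUE) {
  stopifnot(inherits(pmf, "error_pmf"))
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be at least 2.", call. = FALSE)
  tab <- nsd_sum_table(pmf, n)
  pT <- sum_prob(tab, n, target_sum)
  if (pT <= 0) {
    stop("`target_sum` has probability zero under the base pmf.",
         call. = FALSE)
  }
  a <- pmf$support
  # P(S_0 = s) is the point mass at zero (n = 2 pairwise case)
  pS <- function(k, s) {
    if (k == 0L) as.numeric(s == 0) else sum_prob(tab, k, s)
  }
  marg <- pmf$probs * pS(n - 1L, target_sum - a) / pT
  mu <- sum(a * marg)
  v <- sum(a^2 * marg) - mu^2
  # Pairwise: joint over (a, b).
  exy <- 0
  for (i in seq_along(a)) {
    pab <- pmf$probs[i] * pmf$probs *
      pS(n - 2L, target_sum - a[i] - a) / pT
    exy <- exy + sum(a[i] * a * pab)
  }
  cv <- exy - mu^2
  list(
    mean = if (center) mu - target_sum / n else mu,
    var = v,
    cov = cv,
    marginal = tibble::tibble(value = a, prob = marg)
  )
}

#' Simulate a partially linear model dataset
#'
#' Generates the design \eqn{t_i = i/n}, covariates
#' \eqn{x_i = \cos(2\pi t_i)}, trend \eqn{f(t_i) = \sin(2\pi t_i)} and
#' response \eqn{y_i = x_i^T \beta + f(t_i) + e_i} with NSD errors from the
#' sum-conditioned construction (defaults match the package's reference
#' simulation design, with \eqn{\beta = 5}).
#'
#' @param n Sample size, at least 8.
#' @param beta True coefficient vector (length matching the number of
#'   columns of `covariate_fn(t)`).
#' @param covariate_fn Function of `t` returning a vector or `n x d`
#'   matrix of covariates.
#' @param f_fn Function of `t` returning the trend values.
#' @param pmf An `error_pmf` for the base law.
#' @param target_sum,center Passed to [sample_nsd()].
#' @param seed Optional integer seed; identical seeds give identical
#'   datasets.
#' @return A tibble with columns `t`, `y`, `x1, ..., xd`.  The attribute
#'   `"truth"` holds `beta`, `f_fn` and the drawn errors, for recovery
#'   tests.
#' @examples
#' simulate_plm(64, seed = 7)
#' @export
simulate_plm <- function(n, beta = 5,
                         covariate_fn = function(t) cos(2 * pi * t),
                         f_fn = function(t) sin(2 * pi * t),
                         pmf = nsd_pmf(), target_sum = n, center = TRUE,
                         seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 8 || n != floor(n)) {
    stop("`n` must be a single integer >= 8.", call. = FALSE)
  }
  n <- as.integer(n)
  t <- (1:n) / n
  X <- covariate_fn(t)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  if (nrow(X) != n) stop("`covariate_fn` must return n rows.", call. = FALSE)
  if (ncol(X) != length(beta)) {
    stop("`beta` length must match the number of covariate columns.",
         call. = FALSE)
  }
  f <- f_fn(t)
  e <- sample_nsd(n, pmf, target_sum = target_sum, center = center,
                  seed = seed)
  y <- drop(X %*% beta) + f + e
  out <- tibble::as_tibble(as.data.frame(X))
  names(out) <- paste0("x", seq_len(ncol(X)))
  out <- dplyr::bind_cols(tibble::tibble(t = t, y = y), out)
  attr(out, "truth") <- list(beta = beta, f_fn = f_fn, errors = e)
  out
}

#' Monte-Carlo covariance of the conditioned error law
#'
#' Estimates the per-coordinate variance and the common pairwise
#' covariance of centered sum-conditioned errors from `reps` independent
#' draws, pooling across coordinates (the conditional law is
#' exchangeable, so a single off-diagonal value summarizes the
#' covariance).  [nsd_moments()] gives the exact values; this Monte-Carlo
#' counterpart is useful for error laws without a tractable table and as
#' an independent check.
#'
#' @param pmf An `error_pmf`.
#' @param n Sequence length.
#' @param reps Number of Monte-Carlo draws, at least 100.
#' @param target_sum,center Passed to [sample_nsd()].  With
#'   `condition = FALSE` the draws are iid from the base pmf (a control
#'   whose off-diagonal covariance is zero).
#' @param condition If `FALSE`, skip the conditioning (iid control).
#' @param seed Optional integer seed.
#' @return A one-row tibble with columns `variance`, `covariance`, `n`,
#'   `reps`.
#' @export
empirical_error_covariance <- function(pmf, n, reps = 1000, target_sum = n,
                                       center = TRUE, condition = TRUE,
                                       seed = NULL) {
  stopifnot(inherits(pmf, "error_pmf"))
  if (reps < 100) stop("`reps` must be at least 100.", call. = FALSE)
  run <- function() {
    if (condition) {
      tab <- nsd_sum_table(pmf, n)
      E <- t(vapply(seq_len(reps), function(r) {
        sample_nsd(n, pmf, target_sum = target_sum, center = center,
                   table = tab)
      }, numeric(n)))
    } else {
      E <- matrix(pmf$support[sample.int(length(pmf$probs), reps * n,
                                         replace = TRUE, prob = pmf$probs)],
                  reps, n)
      if (center) E <- E - sum(pmf$support * pmf$probs)
    }
    Ec <- scale(E, center = TRUE, scale = FALSE)
    v <- mean(colSums(Ec^2) / (reps - 1))
    # Pool adjacent pairs; under exchangeability every pair has the same
    # covariance.
    cv <- mean(colSums(Ec[, -n, drop = FALSE] * Ec[, -1, drop = FALSE]) /
                 (reps - 1))
    tibble::tibble(variance = v, covariance = cv, n = n, reps = reps)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
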