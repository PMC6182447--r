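test_that("haar scaling function is the unit indicator", {
  phi <- scaling_function("haar")
  expect_equal(phi_eval(phi, c(0, 0.25, 0.999)), c(1, 1, 1))
  expect_equal(phi_eval(phi, c(-0.1, 1, 1.5)), c(0, 0, 0))
})

test_that("daubechies tables integrate to one and form a partition of unity", {
  for (fam in c("daubechies-2", "daubechies-3")) {
    phi <- scaling_function(fam, refinement = 10)
    # trapezoid on the table (endpoint values are zero)
    integral <- sum(phi$values) * phi$step -
      (phi$values[1] + phi$values[length(phi$values)]) * phi$step / 2
    expect_lt(abs(integral - 1), 1e-6)
    L <- phi$support[2]
    xs <- seq(1, L, by = 1 / 64)  # interior window where all shifts overlap
    pou <- vapply(xs, function(x) {
      sum(phi_eval(phi, x - (-(L):L)))
    }, numeric(1))
    expect_lt(max(abs(pou - 1)), 1e-4)
    # compact support
    expect_equal(phi_eval(phi, c(-0.5, L + 0.5)), c(0, 0))
  }
  expect_error(scaling_function("sym4"), "Supported")
  expect_error(scaling_function("daubechies-2", refinement = 4), ">= 6")
})

test_that("resolution rule follows the cube-root growth law", {
  expect_identical(choose_resolution(64), 2L)
  expect_identical(choose_resolution(128), 2L)
  expect_identical(choose_resolution(8), 1L)
  expect_identical(choose_resolution(1024), 3L)
  expect_error(choose_resolution(4), ">= 8")
})

test_that("haar kernel is the dyadic-bin indicator times 2^m", {
  k <- repro_kernel(scaling_function("haar"), 2)
  # same quarter of [0,1): E = 4
  expect_equal(kernel_eval(k, 0.30, 0.55), 0)
  expect_equal(kernel_eval(k, 0.26, 0.49), 4)
  expect_equal(kernel_eval(k, 0.1, 0.2), 4)
  expect_equal(kernel_eval(k, 0.1, 0.3), 0)
  expect_error(kernel_eval(k, 1.2, 0.5), "\\[0, 1\\]")
})

test_that("kernel is symmetric, local, and uniformly bounded by O(2^m)", {
  phi <- scaling_function("daubechies-2")
  set.seed(8)
  for (m in c(1, 3)) {
    k <- repro_kernel(phi, m)
    ts <- runif(25)
    ss <- runif(25)
    expect_equal(kernel_eval(k, ts, ss), kernel_eval(k, ss, ts))
    # locality: support width 3 * 2^-m
    far <- abs(ts - ss) > 3 / 2^m
    expect_true(all(kernel_eval(k, ts, ss)[far] == 0))
  }
  # sup_s |E(t,s)| <= C * 2^m with a common constant across resolutions
  sgrid <- seq(0, 1, length.out = 801)
  for (m in 1:5) {
    k <- repro_kernel(phi, m)
    mx <- max(abs(kernel_eval(k, rep(0.5, length(sgrid)), sgrid)))
    expect_lt(mx / 2^m, 3)
  }
})

test_that("integrated absolute kernel stays bounded across resolutions", {
  phi <- scaling_function("daubechies-2")
  vals <- vapply(1:5, function(m) {
    k <- repro_kernel(phi, m)
    s <- seq(0, 1, length.out = 2001)
    v <- abs(kernel_eval(k, rep(0.5, length(s)), s))
    sum((v[-1] + v[-length(v)]) / 2) / 2000
  }, numeric(1))
  expect_true(all(vals < 3))
})

test_that("haar closed-form weights match quadrature and sum to one", {
  kh <- repro_kernel(scaling_function("haar"), 2)
  n <- 16  # divisible by 2^m
  br <- uniform_partition(n)
  w <- kernel_weights(kh, br, 0.3)
  # t = 0.3 lies in dyadic bin [0.25, 0.5): the 4 intervals there get 4/16
  expect_equal(w, c(rep(0, 4), rep(0.25, 4), rep(0, 8)))
  expect_equal(sum(w), 1)
})

test_that("interval weights match a knot-refined trapezoid oracle", {
  for (res in c(2, 3)) {
    k <- repro_kernel(scaling_function("daubechies-2"), res)
    br <- uniform_partition(40)
    w <- kernel_weights(k, br, 0.5)
    w_or <- vapply(seq_len(40), function(i) {
      trapz_kernel(k, 0.5, br[i], br[i + 1])
    }, numeric(1))
    expect_lt(max(abs(w - w_or)), 1e-8)
  }
})

test_that("interior weights approach total mass one as resolution grows", {
  phi <- scaling_function("daubechies-2")
  sums <- vapply(2:4, function(m) {
    k <- repro_kernel(phi, m)
    sum(kernel_weights(k, uniform_partition(256), 0.5))
  }, numeric(1))
  expect_true(all(abs(sums - 1) < 0.05))
  expect_equal(sums[2], 1, tolerance = 1e-10)
})

test_that("partition validation enforces mesh and membership", {
  expect_error(kernel_weights(repro_kernel(scaling_function("haar"), 1),
                              c(0, 0.1, 0.9), 0.5), "increasing from 0 to 1")
  expect_silent(diffplm:::check_partition(uniform_partition(10), (1:10) / 10))
  expect_error(diffplm:::check_partition(c(0, seq(0.9, 1, length.out = 10)),
                                         C = 4), "mesh")
})

test_that("constant residuals reproduce the constant at interior points", {
  n <- 64
  d <- tibble::tibble(t = (1:n) / n, y = rep(2.5, n), x1 = rep(0, n))
  k <- repro_kernel(scaling_function("daubechies-2"), 3)
  sm <- smooth_plm(d, beta_hat = 0, kernel = k,
                   breaks = uniform_partition(n), grid = c(0.4, 0.5, 0.6))
  expect_equal(sm$estimate$f_hat, rep(2.5, 3), tolerance = 2.5 * 0.01)
  expect_false(any(sm$estimate$boundary))
})

test_that("haar smoother is the dyadic bin average on a uniform design", {
  n <- 32
  set.seed(6)
  y <- rnorm(n)
  d <- tibble::tibble(t = (1:n) / n, y = y, x1 = rep(0, n))
  k <- repro_kernel(scaling_function("haar"), 2)
  sm <- smooth_plm(d, beta_hat = 0, kernel = k,
                   breaks = uniform_partition(n), grid = c(0.3))
  bin <- which((1:n) / n > 0.25 & (1:n) / n <= 0.5)
  expect_equal(sm$estimate$f_hat, mean(y[bin]), tolerance = 1e-10)
})

test_that("noiseless sup-error over the interior shrinks with n", {
  sup_err <- function(n) {
    t <- (1:n) / n
    d <- tibble::tibble(t = t, y = sin(2 * pi * t), x1 = rep(0, n))
    k <- repro_kernel(scaling_function("daubechies-2"), choose_resolution(n))
    grid <- seq(0.1, 0.9, length.out = 33)
    sm <- smooth_plm(d, beta_hat = 0, kernel = k,
                     breaks = uniform_partition(n), grid = grid)
    max(abs(sm$estimate$f_hat - sin(2 * pi * grid)))
  }
  errs <- vapply(c(64, 256, 1024), sup_err, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
})

test_that("tau2_t handles scalar, banded and degenerate error covariances", {
  w <- c(0.1, 0.4, 0.3, 0.2)
  expect_equal(tau2_t(w, 1), sum(w^2))
  expect_equal(tau2_t(rep(0, 4), 3), 0)
  # banded lag-1 covariance vs explicit double sum
  S <- diag(4) * 2
  S[cbind(1:3, 2:4)] <- -0.5
  S[cbind(2:4, 1:3)] <- -0.5
  oracle <- 0
  for (i in 1:4) for (j in 1:4) oracle <- oracle + w[i] * w[j] * S[i, j]
  expect_equal(tau2_t(w, S), oracle)
  expect_error(tau2_t(w, matrix(-1, 4, 4)), "positive semidefinite")
})

test_that("smooth_plm defaults run end to end on simulated data", {
  d <- simulate_plm(128, seed = 9)
  sm <- smooth_plm(d)
  expect_s3_class(sm$estimate, "tbl_df")
  expect_identical(nrow(sm$estimate), 101L)
  # interior fit tracks the true sine within the coarse-resolution error
  interior <- !sm$estimate$boundary
  rmse <- sqrt(mean((sm$estimate$f_hat[interior] -
                       sin(2 * pi * sm$estimate$t[interior]))^2))
  expect_lt(rmse, 0.6)
  expect_error(smooth_plm(d, grid = c(-0.1, 0.5)), "\\[0, 1\\]")
})
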