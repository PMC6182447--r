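test_that("default pmf solves the stated probability equalities", {
  p <- nsd_pmf()
  expect_equal(sum(p$probs), 1)
  expect_equal(p$probs[p$support == 1], 0.2)
  expect_equal(sum(p$support * p$probs), 1)  # unconditional mean
  expect_error(nsd_pmf(c(0, 1), c(0.5, 0.6)), "sum to 1")
  expect_error(nsd_pmf(c(0, 1.5), c(0.5, 0.5)), "integer")
})

test_that("partial-sum table rows are exact probability vectors", {
  p <- nsd_pmf()
  tab1 <- nsd_sum_table(p, 1)
  expect_equal(unname(tab1[1, 1:3]), p$probs)
  tab <- nsd_sum_table(p, 6)
  expect_equal(unname(rowSums(tab)), rep(1, 6))
  expect_true(all(tab >= 0))
  # P(S_2 = 2) = 0.4*0.4 + 0.2*0.2 + 0.4*0.4 = 0.36 by enumeration
  expect_equal(unname(tab[2, "2"]), 0.36)
  # cross-check the whole S_2 row against exhaustive enumeration
  enum <- sapply(0:4, function(s) {
    sum(outer(p$probs, p$probs)[outer(p$support, p$support, "+") == s])
  })
  expect_equal(unname(tab[2, 1:5]), enum)
})

test_that("uncentered draws hit the target sum exactly, centered have mean zero", {
  p <- nsd_pmf()
  for (n in c(8, 33)) {
    raw <- sample_nsd(n, p, center = FALSE, seed = n)
    expect_equal(sum(raw), n)
    expect_true(all(raw %in% p$support))
    cen <- sample_nsd(n, p, center = TRUE, seed = n)
    expect_equal(mean(cen), 0)
  }
  expect_error(sample_nsd(4, p, target_sum = 100), "unattainable")
  p0 <- nsd_pmf(c(0, 2), c(0.5, 0.5))
  expect_error(sample_nsd(3, p0, target_sum = 3), "probability zero")
})

test_that("sequential sampler matches exhaustive enumeration at n = 2", {
  p <- nsd_pmf()
  # P(e = (1,1) | S_2 = 2) = 0.04 / 0.36 = 1/9
  reps <- 10000
  draws <- withr::with_seed(12, {
    tab <- nsd_sum_table(p, 2)
    vapply(seq_len(reps), function(i) {
      all(sample_nsd(2, p, center = FALSE, table = tab) == c(1, 1))
    }, logical(1))
  })
  phat <- mean(draws)
  se <- sqrt((1 / 9) * (8 / 9) / reps)
  expect_lt(abs(phat - 1 / 9), 3 * se)
})

test_that("sampler distribution passes a goodness-of-fit test against enumeration", {
  p <- nsd_pmf()
  enum <- enumerate_conditional(p, 4, 4)
  reps <- 20000
  key <- apply(enum$outcomes, 1, paste, collapse = "")
  draws <- withr::with_seed(77, {
    tab <- nsd_sum_table(p, 4)
    vapply(seq_len(reps), function(i) {
      paste(sample_nsd(4, p, center = FALSE, table = tab), collapse = "")
    }, character(1))
  })
  counts <- table(factor(draws, levels = key))
  expect_identical(sum(counts), as.integer(reps))  # all draws are valid outcomes
  gof <- suppressWarnings(stats::chisq.test(counts, p = enum$probs))
  expect_gt(gof$p.value, 0.001)
})

test_that("conditional law is exchangeable by enumeration", {
  p <- nsd_pmf()
  enum <- enumerate_conditional(p, 3, 3)
  key <- apply(enum$outcomes, 1, function(r) paste(sort(r), collapse = ""))
  for (k in unique(key)) {
    pr <- enum$probs[key == k]
    expect_lt(diff(range(pr)), 1e-14)
  }
})

test_that("exact conditional moments obey the fixed-sum identity", {
  p <- nsd_pmf()
  for (n in c(2, 16, 128)) {
    mom <- nsd_moments(p, n)
    expect_equal(mom$mean, 0)  # centered
    expect_equal(mom$cov, -mom$var / (n - 1), tolerance = 1e-12)
    expect_equal(sum(mom$marginal$prob), 1)
  }
  # n = 2, target 2 against enumeration: outcomes (0,2),(1,1),(2,0)
  enum <- enumerate_conditional(p, 2, 2)
  mu <- sum(enum$outcomes[, 1] * enum$probs)
  v <- sum(enum$outcomes[, 1]^2 * enum$probs) - mu^2
  cv <- sum(enum$outcomes[, 1] * enum$outcomes[, 2] * enum$probs) - mu^2
  mom2 <- nsd_moments(p, 2)
  expect_equal(mom2$var, v)
  expect_equal(mom2$cov, cv)
})

test_that("monte-carlo covariance agrees with exact moments and iid control", {
  p <- nsd_pmf()
  est <- empirical_error_covariance(p, n = 16, reps = 4000, seed = 5)
  mom <- nsd_moments(p, 16)
  expect_lt(est$covariance, 0)  # conditioning induces negative dependence
  expect_lt(abs(est$variance - mom$var), 0.05)
  expect_lt(abs(est$covariance - mom$cov), 0.02)
  ctrl <- empirical_error_covariance(p, n = 16, reps = 4000,
                                     condition = FALSE, seed = 6)
  expect_lt(abs(ctrl$covariance), 0.02)  # iid: off-diagonal ~ 0
  expect_lt(abs(ctrl$variance - 0.8), 0.05)
  # n = 2 exact covariance within 3 MC standard errors
  est2 <- empirical_error_covariance(p, n = 2, reps = 4000, seed = 7)
  mom2 <- nsd_moments(p, 2)
  expect_lt(abs(est2$covariance - mom2$cov), 3 * mom2$var / sqrt(4000))
})

test_that("simulated datasets follow the reference design deterministically", {
  d <- simulate_plm(64, seed = 3)
  expect_named(d, c("t", "y", "x1"))
  expect_equal(d$t, (1:64) / 64)
  expect_equal(d$x1[32], cos(pi))  # t = 1/2
  d2 <- simulate_plm(64, seed = 3)
  expect_identical(d, d2)
  d3 <- simulate_plm(64, seed = 4)
  expect_false(identical(d$y, d3$y))
  # degenerate pmf at zero: y is exactly signal
  dn <- simulate_plm(32, pmf = nsd_pmf(0, 1), target_sum = 0, seed = 1)
  t <- (1:32) / 32
  expect_equal(dn$y, 5 * cos(2 * pi * t) + sin(2 * pi * t))
  # truth attribute supports recovery tests
  tr <- attr(d, "truth")
  expect_equal(d$y, 5 * d$x1 + tr$f_fn(d$t) + tr$errors)
})

test_that("rejection sampler agrees with the sequential sampler in distribution", {
  # independent oracle: draw iid, accept iff the sum hits the target
  p <- nsd_pmf()
  n <- 4
  reps <- 5000
  rej <- withr::with_seed(21, {
    out <- matrix(NA_real_, reps, n)
    filled <- 0
    while (filled < reps) {
      e <- sample(p$support, n, replace = TRUE, prob = p$probs)
      if (sum(e) == n) {
        filled <- filled + 1
        out[filled, ] <- e
      }
    }
    out
  })
  seqdraws <- withr::with_seed(22, {
    tab <- nsd_sum_table(p, n)
    t(vapply(seq_len(reps), function(i) {
      sample_nsd(n, p, center = FALSE, table = tab)
    }, numeric(n)))
  })
  # compare first-coordinate marginals (exchangeability already tested)
  for (a in p$support) {
    p1 <- mean(rej[, 1] == a)
    p2 <- mean(seqdraws[, 1] == a)
    se <- sqrt(p1 * (1 - p1) / reps + p2 * (1 - p2) / reps)
    expect_lt(abs(p1 - p2), 4 * se + 1e-12)
  }
})
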