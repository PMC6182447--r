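# Shared fixtures and independent oracles used across test files.

# The order-3 sequence of the reference simulation design.
paper_seq <- function() diff_sequence(3)

# Small fixed dataset (n = 8, d = 1) used for brute-force comparisons.
tiny_plm <- function() {
  tibble::tibble(
    t = (1:8) / 8,
    y = c(4.21, -1.37, 2.80, 0.55, -3.10, 1.95, 0.07, 2.66),
    x1 = c(0.9, -0.4, 0.7, 0.1, -0.8, 0.5, 0.0, 0.6)
  )
}

# Brute-force DOLS oracle: build the dense differencing matrix explicitly
# and solve the normal equations with qr.solve.
brute_dols <- function(data, seq) {
  n <- nrow(data)
  D <- diff_matrix(seq, n)
  xcols <- grep("^x[0-9]+$", names(data), value = TRUE)
  Xt <- D %*% as.matrix(data[xcols])
  yt <- D %*% data$y
  unname(drop(qr.solve(Xt, yt)))
}

# All length-n outcomes over a pmf support with a given total, and their
# conditional probabilities (exhaustive enumeration oracle).
enumerate_conditional <- function(pmf, n, target) {
  grids <- rep(list(pmf$support), n)
  all_out <- as.matrix(expand.grid(grids))
  keep <- rowSums(all_out) == target
  out <- all_out[keep, , drop = FALSE]
  lp <- apply(out, 1, function(row) {
    prod(pmf$probs[match(row, pmf$support)])
  })
  list(outcomes = out, probs = lp / sum(lp))
}

# Refined-trapezoid integral of E(t, s) over [a, b]: sample points include
# every knot of the tabulated kernel (lattice of step 2^-(J + m)), where
# the integrand is piecewise linear, so the rule is an independent exact
# oracle for the interval weights.
trapz_kernel <- function(kernel, t, a, b) {
  step <- kernel$phi$step / 2^kernel$resolution
  knots <- seq(ceiling(a / step), floor(b / step)) * step
  s <- sort(unique(c(a, knots, b)))
  v <- kernel_eval(kernel, t, s)
  sum((v[-1] + v[-length(v)]) / 2 * diff(s))
}
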