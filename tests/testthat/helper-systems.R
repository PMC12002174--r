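# Shared fixtures and small helpers for the test suite.

pd_matrix <- function() matrix(c(-3, 1, -5, -4), 2,
                               dimnames = list(c("C", "D"), c("C", "D")))

# random bounded systems with seeded positive rates, skipping systems whose
# off-diagonals sit within `margin` of a classification threshold
random_classifiable_systems <- function(n, margin = 1e-3, rate_seed_base = 10000,
                                        rate_range = c(0.2, 3)) {
  out <- list()
  s <- 0
  while (length(out) < n) {
    s <- s + 1
    sys <- sample_bounded_system(seed = s)
    r <- lvgames:::with_seed(rate_seed_base + s,
                             stats::runif(2, rate_range[1], rate_range[2]))
    sys <- eco_game_system(sys$A, r)
    b <- classification_boundaries(sys$A, r)
    if (abs(sys$A[2, 1] - b$a21_threshold) < margin) next
    if (abs(sys$A[1, 2] - b$a12_threshold) < margin) next
    out[[length(out) + 1]] <- sys
  }
  out
}

expect_unstable <- function(eq) {
  expect_true(eq$stability %in% c("UNSTABLE", "SADDLE"))
}

# central finite-difference Jacobian of the LV field
fd_jacobian <- function(sys, n, h = 1e-6) {
  m <- length(n)
  J <- matrix(0, m, m)
  for (k in seq_len(m)) {
    e <- numeric(m); e[k] <- h
    J[, k] <- (lv_derivative(sys, n + e) - lv_derivative(sys, n - e)) / (2 * h)
  }
  J
}
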