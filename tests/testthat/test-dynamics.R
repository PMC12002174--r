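test_that("lv_derivative matches the model equations", {
  s <- fixture_system("pd_equal")
  expect_equal(lv_derivative(s, c(0, 0)), c(0, 0))
  # boundary equilibrium of the resident type 2 sits at -r2/a22 = 1/4
  expect_equal(lv_derivative(s, c(0, 0.25)), c(0, 0))
  # interior equilibrium of the unequal-rate system from a 2x2 linear solve
  su <- fixture_system("pd_unequal")
  n_star <- solve(su$A, -su$r)
  expect_equal(unname(n_star), c(3 / 17, 5 / 17))
  expect_lt(max(abs(lv_derivative(su, n_star))), 1e-12)
  expect_error(lv_derivative(s, c(1, 2, 3)), "types")
})

test_that("LV integration converges to the predicted equilibria", {
  s <- fixture_system("pd_equal")
  tr <- integrate_lv(s, c(0.1, 0.1), t_end = 200)
  expect_lt(max(abs(tr$states[nrow(tr$states), ] - c(0, 0.25))), 1e-6)
  su <- fixture_system("pd_unequal")
  tru <- integrate_lv(su, c(0.1, 0.1), t_end = 200)
  expect_lt(max(abs(tru$states[nrow(tru$states), ] - c(3 / 17, 5 / 17))), 1e-6)
  # the empty state is a fixed point
  tr0 <- integrate_lv(s, c(0, 0), t_end = 10)
  expect_true(all(tr0$states == 0))
})

test_that("absent types remain structurally absent during integration", {
  ru <- fixture_system("rps_unequal")
  # an S-only start must never sprout R or P, even though both could invade
  tr <- integrate_lv(ru, c(0, 0, 1e-6), t_end = 500, n_out = 500)
  expect_true(all(tr$states[, c(1, 2)] == 0))
  expect_lt(abs(tr$states[nrow(tr$states), 3] - 1), 1e-6)
})

test_that("replicator_derivative implements x_i (f_i - f_bar)", {
  A <- pd_matrix()
  # vertices are fixed points
  expect_equal(replicator_derivative(A, c(1, 0)), c(0, 0))
  expect_equal(replicator_derivative(rps_matrix(1.3), rep(1 / 3, 3)),
               rep(0, 3))
  # hand arithmetic at the barycenter: f1 = -4, f2 = -1.5,
  # dx1/dt = 0.5 * (f1 - fbar) * ... = x1 x2 (f1 - f2) = -0.625
  d <- replicator_derivative(A, c(0.5, 0.5))
  expect_equal(d[1], -0.625)
  expect_equal(sum(d), 0, tolerance = 1e-14)
  tm <- dynamical_terms(A, c(0.5, 0.5), r = c(2, 1))
  expect_equal(tm$f, c(-4, -1.5))
  expect_equal(tm$f_bar, -2.75)
  expect_equal(tm$r_bar, 1.5)
})

test_that("dynamical terms stay within the range of their components", {
  A <- sample_bounded_system(seed = 5)$A
  for (x1 in seq(0.05, 0.95, by = 0.09)) {
    tm <- dynamical_terms(A, c(x1, 1 - x1), r = c(2, 0.5))
    expect_gte(tm$f_bar, min(tm$f)); expect_lte(tm$f_bar, max(tm$f))
    expect_gte(tm$r_bar, 0.5); expect_lte(tm$r_bar, 2)
  }
})

test_that("replicator integration keeps the simplex and finds the PD limit", {
  tr <- integrate_replicator(pd_matrix(), c(0.5, 0.5), t_end = 100)
  expect_lt(tr$diagnostics$max_simplex_defect, 1e-9)
  expect_lt(tr$states[nrow(tr$states), 1], 1e-10)   # defectors take over
  # a vertex start stays put
  trv <- integrate_replicator(pd_matrix(), c(0, 1), t_end = 50)
  expect_equal(max(abs(trv$states[, 1])), 0)
  expect_equal(max(abs(trv$states[, 2] - 1)), 0)
})

test_that("symmetric RPS replicator orbits are closed and conserve x_R x_P x_S", {
  x0 <- c(0.5, 0.3, 0.2)
  tr <- integrate_replicator(rps_matrix(1.3), x0, t_end = 100, n_out = 4000)
  expect_lt(tr$diagnostics$max_simplex_defect, 1e-9)
  # constant of motion along the orbit
  p <- apply(tr$states, 1, prod)
  expect_lt(max(abs(p - p[1])) / p[1], 1e-6)
  # the orbit returns within 1e-3 of its start
  d <- sqrt(rowSums((tr$states - matrix(x0, nrow(tr$states), 3,
                                        byrow = TRUE))^2))
  expect_lt(min(d[tr$times > 5]), 1e-3)
})

test_that("coupled frequency/total dynamics equals LV under change of variables", {
  for (nm in c("pd_equal", "pd_unequal", "rps_unequal")) {
    sys <- fixture_system(nm)
    m <- length(sys$r)
    n0 <- seq(0.1, 0.3, length.out = m)
    lv <- integrate_lv(sys, n0, t_end = 50, extinction_floor = 0)
    cp <- integrate_coupled(sys, n0 / sum(n0), sum(n0), t_end = 50)
    x_lv <- trajectory_frequencies(lv)
    expect_lt(max(abs(x_lv - cp$states[, seq_len(m)])), 1e-6, label = nm)
    expect_lt(max(abs(rowSums(lv$states) - cp$states[, m + 1])), 1e-6)
  }
  # the identity also holds for random systems and initial conditions
  for (seed in 1:10) {
    sys <- sample_bounded_system(seed = seed, r = c(1.7, 0.6))
    n0 <- lvgames:::with_seed(seed, stats::runif(2, 0.05, 1))
    lv <- integrate_lv(sys, n0, t_end = 40, extinction_floor = 0)
    cp <- integrate_coupled(sys, n0 / sum(n0), sum(n0), t_end = 40)
    expect_lt(max(abs(trajectory_frequencies(lv) - cp$states[, 1:2])), 1e-6)
  }
})

test_that("coupled dynamics pins a vertex and reduces N to logistic growth", {
  s <- fixture_system("pd_equal")
  cp <- integrate_coupled(s, c(0, 1), N0 = 0.05, t_end = 30)
  expect_equal(max(abs(cp$states[, 1])), 0)
  # single-type logistic: N -> -r2/a22 = 1/4
  expect_lt(abs(cp$states[nrow(cp$states), 3] - 0.25), 1e-6)
})

test_that("simplex conservation holds on long runs of all fixtures", {
  for (nm in c("pd_equal", "pd_unequal", "rps_equal", "rps_unequal")) {
    sys <- fixture_system(nm)
    m <- length(sys$r)
    x0 <- rep(1, m) / m
    tr <- integrate_replicator(sys$A, x0, t_end = 1000, n_out = 500)
    expect_lt(tr$diagnostics$max_simplex_defect, 1e-9, label = nm)
    cp <- integrate_coupled(sys, x0, N0 = 0.3, t_end = 200)
    expect_lt(max(abs(rowSums(cp$states[, seq_len(m), drop = FALSE]) - 1)),
              1e-9, label = nm)
  }
})

test_that("RPS abundances never blow up regardless of growth rates", {
  for (r in list(c(1, 1, 1), c(2.5, 1, 1), c(5, 0.2, 3))) {
    sys <- eco_game_system(rps_matrix(1.3), r)
    tr <- integrate_lv(sys, c(1, 1, 1), t_end = 200)
    expect_false(tr$unbounded)
    expect_lt(max(tr$states), max(max(r), 3) + 1)
  }
})

test_that("mutualism beyond the boundedness threshold is flagged unbounded", {
  sys <- eco_game_system(rbind(c(-0.5, 1), c(1, -0.5)), c(1, 1))
  tr <- integrate_lv(sys, c(1, 1), t_end = 100)
  expect_true(tr$unbounded)
})

test_that("frequency-dependent LV matches replicator under equal rates only", {
  se <- fixture_system("pd_equal")
  tr <- integrate_lv_freqdep(se, c(0.1, 0.1), t_end = 30, extinction_floor = 0)
  x <- trajectory_frequencies(tr)
  rp <- integrate_replicator(se$A, c(0.5, 0.5), t_end = 30)
  expect_lt(max(abs(x - rp$states)), 1e-6)
  # unequal rates: a sufficient growth advantage keeps the game's loser at a
  # stable interior frequency, while the replicator prediction is x1 -> 0
  s25 <- eco_game_system(se$A, c(2.5, 1))
  tru <- integrate_lv_freqdep(s25, c(0.1, 0.1), t_end = 25,
                              extinction_floor = 0)
  xu <- trajectory_frequencies(tru)
  expect_lt(abs(xu[nrow(xu), 1] - 1 / 6), 1e-3)
  rpu <- integrate_replicator(se$A, c(0.5, 0.5), t_end = 25)
  expect_lt(rpu$states[nrow(rpu$states), 1], 1e-6)
  # a type absent at the start stays absent
  tr0 <- integrate_lv_freqdep(se, c(0, 0.1), t_end = 10, extinction_floor = 0)
  expect_true(all(tr0$states[, 1] == 0))
})

test_that("check_equivalence separates equal from unequal growth rates", {
  eq <- check_equivalence(fixture_system("pd_equal"), c(0.1, 0.1), t_end = 100)
  expect_true(eq$equivalent)
  expect_lt(eq$max_orbit_deviation, 1e-6)
  ne <- check_equivalence(fixture_system("pd_unequal"), c(0.1, 0.1),
                          t_end = 100)
  expect_false(ne$equivalent)
  # LV frequencies converge to the interior ratio 3/8; replicator loses type 1
  expect_lt(abs(ne$x_lv[nrow(ne$x_lv), 1] - 3 / 8), 1e-6)
  expect_lt(ne$x_replicator[nrow(ne$x_replicator), 1], 1e-6)
  # a single-type system is trivially equivalent (both sides constant)
  s1 <- eco_game_system(matrix(-2), 1, labels = "only")
  expect_true(check_equivalence(s1, 0.3, t_end = 20)$equivalent)
})

test_that("trajectories round-trip losslessly through CSV", {
  tr <- integrate_lv(fixture_system("pd_unequal"), c(0.1, 0.1), t_end = 10,
                     n_out = 25)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_identical(back$dynamics_kind, "lv")
  expect_identical(back$times, tr$times)
  expect_identical(unname(back$states), unname(tr$states))
  unlink(f)
})
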