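#' Lotka-Volterra vector field
#'
#' Right-hand side of the generalized Lotka-Volterra equations
#' `dn_i/dt = n_i (r_i + sum_j a_ij n_j)` for any number of types.
#'
#' @param sys an [eco_game_system()].
#' @param n numeric vector of nonnegative abundances.
#' @return numeric vector of abundance rates of change.
#' @examples
#' lv_derivative(fixture_system("pd_equal"), c(0, 0.25))  # boundary fixed point
#' @export
lv_derivative <- function(sys, n) {
  sys <- as_system(sys)
  n <- as.numeric(n)
  if (length(n) != n_types(sys)) {
    stop("state has ", length(n), " entries but the system has ", n_types(sys), " types")
  }
  as.numeric(n * (sys$r + sys$A %*% n))
}

#' Replicator vector field and its building blocks
#'
#' `dynamical_terms()` evaluates the game fitnesses `f_i = sum_j a_ij x_j`,
#' their population mean `f_bar = sum_i x_i f_i` and (when growth rates are
#' supplied) the mean growth rate `r_bar = sum_i x_i r_i`.
#' `replicator_derivative()` returns the replicator vector field
#' `dx_i/dt = x_i (f_i - f_bar)`; its components always sum to zero.
#'
#' @param A square payoff/interaction matrix.
#' @param x frequency vector on the simplex (nonnegative, summing to 1).
#' @param r optional growth-rate vector for `r_bar`.
#' @return `dynamical_terms()`: list with `f`, `f_bar`, `r_bar` (NULL if `r`
#'   missing). `replicator_derivative()`: numeric vector of frequency rates.
#' @examples
#' replicator_derivative(rps_matrix(1.3), c(1, 1, 1) / 3)  # interior fixed point
#' @export
dynamical_terms <- function(A, x, r = NULL) {
  A <- as.matrix(A)
  x <- as.numeric(x)
  if (length(x) != nrow(A)) stop("frequency vector does not match matrix dimension")
  f <- as.numeric(A %*% x)
  out <- list(f = f, f_bar = sum(x * f), r_bar = NULL)
  if (!is.null(r)) {
    if (length(r) != length(x)) stop("growth-rate vector does not match dimension")
    out$r_bar <- sum(x * r)
  }
  out
}

#' @rdname dynamical_terms
#' @export
replicator_derivative <- function(A, x) {
  terms <- dynamical_terms(A, x)
  as.numeric(x * (terms$f - terms$f_bar))
}

check_simplex <- function(x, tol = 1e-8) {
  if (any(x < -tol)) stop("frequencies must be nonnegative")
  if (abs(sum(x) - 1) > tol) stop("frequencies must sum to 1 (defect ", abs(sum(x) - 1), ")")
  invisible(x)
}

new_trajectory <- function(times, states, dynamics_kind, labels, sys = NULL,
                           unbounded = FALSE, diagnostics = list()) {
  states <- as.matrix(states)
  colnames(states) <- labels
  structure(list(times = as.numeric(times), states = states,
                 dynamics_kind = dynamics_kind, labels = labels,
                 system = sys, unbounded = unbounded,
                 diagnostics = diagnostics),
            class = "lv_trajectory")
}

#' @export
print.lv_trajectory <- function(x, ...) {
  cat("<lv_trajectory> kind=", x$dynamics_kind, ", ", length(x$times),
      " points, t in [", format(min(x$times)), ", ", format(max(x$times)),
      "]\n", sep = "")
  if (isTRUE(x$unbounded)) cat("flagged UNBOUNDED (abundance ceiling reached)\n")
  cat("final state:\n")
  print(x$states[nrow(x$states), ])
  invisible(x)
}

final_state <- function(traj) traj$states[nrow(traj$states), ]

# Shared deSolve driver. Returns matrix of states at `times`; flags blow-up
# past `ceiling` instead of erroring.
ode_drive <- function(func, y0, times, rtol, atol, ceiling = NULL) {
  sol <- tryCatch(
    deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                 method = "lsoda", rtol = rtol, atol = atol, maxsteps = 50000),
    warning = function(w) {
      res <- suppressWarnings(
        deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                     method = "lsoda", rtol = rtol, atol = atol, maxsteps = 50000))
      attr(res, "ode_warning") <- conditionMessage(w)
      res
    })
  st <- unname(sol[, -1, drop = FALSE])
  tt <- sol[, 1]
  out <- list(times = tt, states = st, unbounded = FALSE,
              warning = attr(sol, "ode_warning"))
  if (!is.null(ceiling)) {
    over <- rowSums(!is.finite(st) | st > ceiling) > 0
    if (any(over)) {
      k <- which(over)[1]
      out$times <- tt[seq_len(k)]
      out$states <- st[seq_len(k), , drop = FALSE]
      out$unbounded <- TRUE
    }
  }
  if (!is.null(out$warning) && !out$unbounded && nrow(out$states) < length(times)) {
    stop("integration failed near t = ", max(out$times), ": ", out$warning)
  }
  out
}

#' Integrate Lotka-Volterra abundance dynamics
#'
#' Adaptive integration of `dn_i/dt = n_i (r_i + sum_j a_ij n_j)`. Abundances
#' below the extinction floor at the *end* of the run are clamped to exactly
#' zero (never mid-step, which would distort near-boundary excursions such as
#' heteroclinic-like cycles). Trajectories exceeding the abundance ceiling
#' are truncated and flagged `unbounded` rather than raising an error.
#'
#' @param sys an [eco_game_system()].
#' @param n0 initial abundances (nonnegative).
#' @param t_end end time (> 0).
#' @param tol relative tolerance of the integrator.
#' @param atol absolute tolerance.
#' @param n_out number of equally spaced output times.
#' @param extinction_floor final-state clamping threshold.
#' @param ceiling abundance above which the run is flagged unbounded.
#' @param times optional explicit output times (overrides `t_end`/`n_out`).
#' @return An `lv_trajectory` (elements `times`, `states`, `dynamics_kind`,
#'   `unbounded`).
#' @examples
#' traj <- integrate_lv(fixture_system("pd_equal"), c(0.1, 0.1), t_end = 50)
#' traj
#' @export
integrate_lv <- function(sys, n0, t_end, tol = 1e-10, atol = 1e-12,
                         n_out = 400, extinction_floor = 1e-9,
                         ceiling = 1e6, times = NULL) {
  sys <- as_system(sys)
  n0 <- as.numeric(n0)
  if (any(n0 < 0)) stop("initial abundances must be nonnegative")
  if (is.null(times)) {
    stopifnot(t_end > 0)
    times <- seq(0, t_end, length.out = n_out)
  }
  # Absent types stay structurally absent: n_i = 0 is invariant in exact
  # arithmetic, but solver dust (~atol) in a zero component would be
  # amplified whenever that type could invade, so only the subsystem of
  # initially present types is integrated.
  supp <- which(n0 > 0)
  if (length(supp) == 0) {
    st <- matrix(0, length(times), length(n0))
    return(new_trajectory(times, st, "lv", sys$labels, sys))
  }
  A <- sys$A[supp, supp, drop = FALSE]; r <- sys$r[supp]
  rhs <- function(t, n, p) list(n * (r + as.numeric(A %*% n)))
  res <- ode_drive(rhs, n0[supp], times, tol, atol, ceiling = ceiling)
  st <- matrix(0, length(res$times), length(n0))
  st[, supp] <- res$states
  st[st < 0] <- 0
  st[nrow(st), st[nrow(st), ] < extinction_floor] <- 0
  new_trajectory(res$times, st, "lv", sys$labels, sys, unbounded = res$unbounded)
}

#' Integrate replicator frequency dynamics
#'
#' Adaptive integration of `dx_i/dt = x_i (f_i - f_bar)` on the simplex.
#' Output states are renormalized; the pre-normalization defect is recorded
#' in `diagnostics$max_simplex_defect` and must stay tiny for a healthy run.
#'
#' @param A square payoff matrix.
#' @param x0 initial frequencies on the simplex.
#' @inheritParams integrate_lv
#' @param labels optional type names.
#' @return An `lv_trajectory` with `dynamics_kind = "replicator"`.
#' @examples
#' integrate_replicator(rps_matrix(1.3), c(0.5, 0.3, 0.2), t_end = 10)
#' @export
integrate_replicator <- function(A, x0, t_end, tol = 1e-10, atol = 1e-12,
                                 n_out = 400, labels = NULL, times = NULL) {
  A <- as.matrix(A)
  x0 <- check_simplex(as.numeric(x0))
  if (is.null(labels)) labels <- colnames(A)
  if (is.null(labels)) labels <- paste0("T", seq_len(nrow(A)))
  if (is.null(times)) {
    stopifnot(t_end > 0)
    times <- seq(0, t_end, length.out = n_out)
  }
  # fitness terms are evaluated on the normalized state: the simplex is
  # invariant but not attracting for the raw field, so integration error in
  # sum(x) would otherwise be amplified; with normalization the sum is an
  # exact invariant of the extended field
  rhs <- function(t, x, p) {
    z <- x / sum(x)
    f <- as.numeric(A %*% z)
    list(x * (f - sum(z * f)))
  }
  res <- ode_drive(rhs, x0, times, tol, atol)
  st <- res$states
  defect <- max(abs(rowSums(st) - 1))
  st[st < 0] <- 0
  st <- st / rowSums(st)
  new_trajectory(res$times, st, "replicator", labels,
                 diagnostics = list(max_simplex_defect = defect))
}

#' Integrate the coupled frequency/total-abundance system
#'
#' The change of variables `x_i = n_i / N`, `N = sum_i n_i` turns the
#' Lotka-Volterra equations into the exactly equivalent coupled system
#' `dx_i/dt = x_i ((r_i - r_bar) + N (f_i - f_bar))`,
#' `dN/dt = N (r_bar + N f_bar)`. For two types this is the single equation
#' `dx1/dt = N x1 x2 ((r1 - r2)/N + f1 - f2)` plus the total-abundance
#' equation. When all growth rates are equal the bracket loses its `1/N`
#' term and the frequency part reduces to replicator dynamics up to a time
#' rescaling by the positive factor `N`.
#'
#' @param sys an [eco_game_system()].
#' @param x0 initial frequencies on the simplex.
#' @param N0 initial total abundance (> 0).
#' @inheritParams integrate_lv
#' @return An `lv_trajectory` with `dynamics_kind = "coupled"`; state columns
#'   are the frequencies followed by `N`.
#' @examples
#' integrate_coupled(fixture_system("pd_unequal"), c(0.5, 0.5), N0 = 0.2, t_end = 50)
#' @export
integrate_coupled <- function(sys, x0, N0, t_end, tol = 1e-10, atol = 1e-12,
                              n_out = 400, ceiling = 1e6, times = NULL) {
  sys <- as_system(sys)
  x0 <- check_simplex(as.numeric(x0))
  stopifnot(N0 > 0)
  if (is.null(times)) {
    stopifnot(t_end > 0)
    times <- seq(0, t_end, length.out = n_out)
  }
  A <- sys$A; r <- sys$r; m <- n_types(sys)
  rhs <- function(t, y, p) {
    x <- y[seq_len(m)]; N <- y[m + 1]
    z <- x / sum(x)  # normalized in the field; keeps sum(x) exactly invariant
    f <- as.numeric(A %*% z)
    f_bar <- sum(z * f); r_bar <- sum(z * r)
    list(c(x * ((r - r_bar) + N * (f - f_bar)),
           N * (r_bar + N * f_bar)))
  }
  res <- ode_drive(rhs, c(x0, N0), times, tol, atol, ceiling = ceiling)
  st <- res$states
  xs <- st[, seq_len(m), drop = FALSE]
  xs[xs < 0] <- 0
  xs <- xs / rowSums(xs)
  st <- cbind(xs, st[, m + 1])
  new_trajectory(res$times, st, "coupled", c(sys$labels, "N"), sys,
                 unbounded = res$unbounded)
}

#' Integrate frequency-dependent Lotka-Volterra dynamics
#'
#' Variant in which interactions act on frequencies rather than densities:
#' `dn_i/dt = n_i (r_i + sum_j a_ij x_j)` with `x_j = n_j / sum_k n_k`. With
#' equal growth rates its frequency dynamics coincides with replicator
#' dynamics of `A` (no state-dependent time rescaling); with unequal rates
#' the two predictions part ways just as in the density-dependent model.
#'
#' @inheritParams integrate_lv
#' @return An `lv_trajectory` with `dynamics_kind = "lv_freqdep"`.
#' @export
integrate_lv_freqdep <- function(sys, n0, t_end, tol = 1e-10, atol = 1e-12,
                                 n_out = 400, extinction_floor = 1e-9,
                                 ceiling = 1e6, times = NULL) {
  sys <- as_system(sys)
  n0 <- as.numeric(n0)
  if (any(n0 < 0)) stop("initial abundances must be nonnegative")
  if (sum(n0) <= 0) stop("total abundance must be positive")
  if (is.null(times)) {
    stopifnot(t_end > 0)
    times <- seq(0, t_end, length.out = n_out)
  }
  supp <- which(n0 > 0)  # absent types stay structurally absent (see integrate_lv)
  A <- sys$A[supp, supp, drop = FALSE]; r <- sys$r[supp]
  rhs <- function(t, n, p) {
    N <- sum(n)
    if (N <= 0) return(list(0 * n))
    x <- n / N
    list(n * (r + as.numeric(A %*% x)))
  }
  res <- ode_drive(rhs, n0[supp], times, tol, atol, ceiling = ceiling)
  st <- matrix(0, length(res$times), length(n0))
  st[, supp] <- res$states
  st[st < 0] <- 0
  st[nrow(st), st[nrow(st), ] < extinction_floor] <- 0
  new_trajectory(res$times, st, "lv_freqdep", sys$labels, sys,
                 unbounded = res$unbounded)
}

#' Frequencies carried by an abundance trajectory
#'
#' @param traj an `lv_trajectory` of abundances.
#' @return matrix of frequencies `n_i / sum n`, one row per time point.
#' @export
trajectory_frequencies <- function(traj) {
  st <- traj$states
  if (traj$dynamics_kind == "coupled") {
    return(st[, -ncol(st), drop = FALSE])
  }
  tot <- rowSums(st)
  if (any(tot <= 0)) stop("total abundance hit zero; frequencies undefined")
  st / tot
}

#' Do abundance and replicator dynamics agree?
#'
#' Integrates the Lotka-Volterra system from `n0`, extracts the frequency
#' trajectory, and compares it to the replicator trajectory of the same
#' matrix started at the same initial frequencies after rescaling time by
#' the total abundance (`dtau/dt = N(t)`, `tau(0) = 0`). The rescaled clock
#' `tau` is integrated alongside the abundances, so it carries the same
#' accuracy as the trajectory itself. When all growth rates are equal the
#' two frameworks are dynamically identical and the deviation is at the
#' level of integration error; when they differ the frequency dynamics is
#' not autonomous and no replicator equation reproduces it.
#'
#' @param sys an [eco_game_system()].
#' @param n0 initial abundances with positive total.
#' @param t_end comparison horizon in Lotka-Volterra time.
#' @param tol integration tolerance.
#' @param n_out number of comparison points.
#' @param deviation_tol deviation below which the two are declared
#'   equivalent.
#' @return list with `max_orbit_deviation`, `equivalent`, and the two
#'   frequency trajectories (`x_lv`, `x_replicator`, both at `times`).
#' @examples
#' check_equivalence(fixture_system("pd_equal"), c(0.1, 0.1), t_end = 20)$equivalent
#' @export
check_equivalence <- function(sys, n0, t_end, tol = 1e-10, n_out = 400,
                              deviation_tol = 1e-6) {
  sys <- as_system(sys)
  n0 <- as.numeric(n0)
  if (sum(n0) <= 0) stop("total abundance must be positive")
  m <- n_types(sys)
  A <- sys$A; r <- sys$r
  times <- seq(0, t_end, length.out = n_out)
  # LV trajectory augmented with the rescaled clock tau, dtau/dt = N(t)
  rhs <- function(t, y, p) {
    n <- y[seq_len(m)]
    list(c(n * (r + as.numeric(A %*% n)), sum(n)))
  }
  res <- ode_drive(rhs, c(n0, 0), times, tol, 1e-12)
  nst <- res$states[, seq_len(m), drop = FALSE]
  tau <- res$states[, m + 1]
  tot <- rowSums(nst)
  x_lv <- nst / tot
  x0 <- n0 / sum(n0)
  # replicator trajectory sampled exactly at the rescaled times tau(t_k)
  rep_traj <- integrate_replicator(A, x0, tol = tol, times = tau,
                                   labels = sys$labels)
  dev <- max(abs(x_lv - rep_traj$states))
  list(max_orbit_deviation = dev,
       equivalent = dev < deviation_tol,
       times = times,
       x_lv = x_lv,
       x_replicator = rep_traj$states)
}
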