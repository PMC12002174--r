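#' Jacobian of the Lotka-Volterra vector field
#'
#' `J[i, k] = delta_ik (r_i + sum_j a_ij n_j) + n_i a_ik`. At an interior
#' equilibrium the growth term vanishes and the Jacobian reduces to
#' `diag(n) %*% A`; at the origin it is `diag(r)`.
#'
#' @param sys an [eco_game_system()].
#' @param n abundance vector at which to linearize.
#' @return square numeric matrix.
#' @export
lv_jacobian <- function(sys, n) {
  sys <- as_system(sys)
  n <- as.numeric(n)
  m <- n_types(sys)
  if (length(n) != m) stop("state dimension mismatch")
  growth <- as.numeric(sys$r + sys$A %*% n)
  diag(growth, m, m) + n * sys$A
}

stability_label <- function(eigenvalues, tol = 1e-8) {
  re <- Re(eigenvalues)
  if (max(re) < -tol) return("STABLE")
  if (abs(max(re)) <= tol) return("NEUTRAL")
  if (min(re) < -tol) return("SADDLE")
  "UNSTABLE"
}

new_equilibrium <- function(n, support, eigenvalues, stability, residual, labels) {
  names(n) <- labels
  structure(list(n = n, support = support, eigenvalues = eigenvalues,
                 stability = stability, residual = residual, labels = labels),
            class = "lv_equilibrium")
}

#' @export
print.lv_equilibrium <- function(x, ...) {
  supp <- if (length(x$support)) paste(x$labels[x$support], collapse = ",") else "(empty)"
  cat("<lv_equilibrium> support {", supp, "} ", x$stability, "\n", sep = "")
  print(x$n)
  cat("eigenvalue real parts: ", paste(format(Re(x$eigenvalues), digits = 4),
                                       collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Enumerate the fixed points of a Lotka-Volterra system
#'
#' For every subset `S` of types, solves the linear system
#' `r_i + sum_{j in S} a_ij n_j = 0` restricted to `S` and keeps solutions
#' that are strictly positive on `S` (and zero elsewhere). The origin is
#' always included. Each equilibrium carries the eigenvalues of the full
#' Jacobian and a stability label: `STABLE` if every real part is below
#' `-stab_tol`, `NEUTRAL` if the largest real part sits within `stab_tol` of
#' zero (the hallmark of closed-orbit dynamics such as the symmetric cyclic
#' community), `SADDLE`/`UNSTABLE` otherwise.
#'
#' @param sys an [eco_game_system()] with at most 10 types (support
#'   enumeration is exponential in the number of types).
#' @param stab_tol tolerance on eigenvalue real parts.
#' @return list of `lv_equilibrium` objects.
#' @examples
#' fixed_points(fixture_system("pd_equal"))
#' @export
fixed_points <- function(sys, stab_tol = 1e-8) {
  sys <- as_system(sys)
  m <- n_types(sys)
  if (m > 10) stop("support enumeration is limited to 10 types (2^m subsets)")
  out <- list()
  for (mask in 0:(2^m - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    n <- numeric(m)
    if (length(S) > 0) {
      sol <- tryCatch(solve(sys$A[S, S, drop = FALSE], -sys$r[S]),
                      error = function(e) NULL)
      if (is.null(sol)) next  # singular support system: skipped
      if (any(sol <= 0)) next
      n[S] <- sol
    }
    J <- lv_jacobian(sys, n)
    ev <- eigen(J, only.values = TRUE)$values
    resid <- max(abs(lv_derivative(sys, n)))
    out[[length(out) + 1]] <- new_equilibrium(
      n, S, ev, stability_label(ev, stab_tol), resid, sys$labels)
  }
  out
}

#' Invasion fitness of a rare type
#'
#' Per-capita growth rate of a rare invader at a resident community's
#' equilibrium: `r_inv + sum_j a_inv,j n_hat_j`. A positive value means the
#' invader grows deterministically from any low inoculum; a negative value
#' means it is repelled.
#'
#' @param sys an [eco_game_system()] containing both residents and invader.
#' @param resident_eq an `lv_equilibrium` (or bare abundance vector) whose
#'   support excludes the invader.
#' @param invader index (or label) of the invading type.
#' @return scalar invasion growth rate.
#' @examples
#' eq <- fixed_points(fixture_system("rps_equal"))
#' # resident Rock alone sits at abundance 1; Paper invades at rate +alpha
#' @export
invasion_fitness <- function(sys, resident_eq, invader) {
  sys <- as_system(sys)
  if (is.character(invader)) invader <- match(invader, sys$labels)
  if (is.na(invader) || invader < 1 || invader > n_types(sys)) {
    stop("unknown invader index/label")
  }
  n <- if (inherits(resident_eq, "lv_equilibrium")) resident_eq$n else as.numeric(resident_eq)
  if (n[invader] > 0) stop("invader is already present in the resident community")
  as.numeric(sys$r[invader] + sum(sys$A[invader, ] * n))
}
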