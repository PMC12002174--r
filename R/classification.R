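outcome_levels <- c("DOMINANCE_1", "DOMINANCE_2", "COEXISTENCE", "BISTABILITY",
                    "EXTINCTION_BOTH", "UNBOUNDED")

#' Is a two-type system bounded?
#'
#' A two-type system has bounded trajectories when each type limits itself
#' (`a11 < 0`, `a22 < 0`) and the cross-interactions cannot fuel runaway
#' mutual growth. The classical inequality `a12 * a21 < a11 * a22` is what
#' rules out blow-up; it can only fail dangerously when the off-diagonal
#' product is positive with at least one positive entry (mutualistic
#' feedback). When both cross-effects are nonpositive (pure competition)
#' each abundance is capped by its own logistic envelope and the system is
#' bounded regardless of the product inequality, even though its interior
#' equilibrium is then a saddle (bistability).
#'
#' @param sys an [eco_game_system()] with 2 types (or a 2x2 matrix).
#' @param strict if `TRUE`, require the literal inequality
#'   `a12 * a21 < a11 * a22` in all sign quadrants (the sufficient
#'   condition); the default also admits purely competitive systems that
#'   violate it but cannot blow up.
#' @return logical.
#' @examples
#' is_bounded(fixture_system("pd_equal"))
#' @export
is_bounded <- function(sys, strict = FALSE) {
  A <- if (inherits(sys, "eco_game_system")) sys$A else as.matrix(sys)
  if (!all(dim(A) == c(2, 2))) stop("boundedness test is defined for 2 types")
  if (A[1, 1] >= 0 || A[2, 2] >= 0) return(FALSE)
  if (A[1, 2] * A[2, 1] < A[1, 1] * A[2, 2]) return(TRUE)
  if (strict) return(FALSE)
  # competitive cross-effects cannot drive divergence
  A[1, 2] <= 0 && A[2, 1] <= 0
}

#' Classify the game played by a two-type matrix
#'
#' The equal-growth-rate (replicator) classification by the signs of
#' `a21 - a11` and `a12 - a22`, stated for matrices in canonical order
#' `a11 >= a22` (applied automatically; the permutation is reported):
#' \describe{
#'   \item{PRISONERS_DILEMMA}{`a21 > a11` and `a12 < a22`: type 2 dominates.}
#'   \item{HARMONY}{`a21 < a11` and `a12 > a22`: type 1 dominates.}
#'   \item{COEXISTENCE_GAME}{both differences positive (e.g. Hawk-Dove /
#'     Snowdrift): stable interior mixture.}
#'   \item{COORDINATION}{both negative (e.g. Stag-Hunt): bistability.}
#' }
#'
#' @param A 2x2 interaction/payoff matrix.
#' @param tol ties within `tol` of either boundary are flagged degenerate
#'   and left unclassified.
#' @return list with `game_class` (or `NA` when degenerate), `degenerate`,
#'   `swapped`, `perm`.
#' @examples
#' classify_game(fixture_system("pd_equal")$A)$game_class
#' @export
classify_game <- function(A, tol = 1e-9) {
  A <- if (inherits(A, "eco_game_system")) A$A else as.matrix(A)
  co <- canonical_order(A)
  B <- co$A
  d1 <- B[2, 1] - B[1, 1]   # a21 - a11
  d2 <- B[1, 2] - B[2, 2]   # a12 - a22
  degenerate <- abs(d1) <= tol || abs(d2) <= tol || co$tie
  cls <- if (degenerate) NA_character_
  else if (d1 > 0 && d2 < 0) "PRISONERS_DILEMMA"
  else if (d1 < 0 && d2 > 0) "HARMONY"
  else if (d1 > 0 && d2 > 0) "COEXISTENCE_GAME"
  else "COORDINATION"
  list(game_class = cls, degenerate = degenerate,
       swapped = co$swapped, perm = co$perm)
}

#' Classify the ecological interaction type
#'
#' By the signs of the cross-effects `(a12, a21)`: both positive is
#' mutualism, both negative is competition, mixed signs are exploitation
#' (predation/parasitism); a zero lands on the neutral edge between
#' quadrants.
#'
#' @param A 2x2 interaction matrix (or system).
#' @return one of `"MUTUALISM"`, `"COMPETITION"`, `"EXPLOITATION"`,
#'   `"NEUTRAL_EDGE"`.
#' @examples
#' classify_ecology(fixture_system("pd_equal")$A)  # (-5, +1): exploitation
#' @export
classify_ecology <- function(A) {
  A <- if (inherits(A, "eco_game_system")) A$A else as.matrix(A)
  if (!all(dim(A) == c(2, 2))) stop("ecological classification is defined for 2 types")
  a12 <- A[1, 2]; a21 <- A[2, 1]
  if (a12 == 0 || a21 == 0) return("NEUTRAL_EDGE")
  if (a12 > 0 && a21 > 0) return("MUTUALISM")
  if (a12 < 0 && a21 < 0) return("COMPETITION")
  "EXPLOITATION"
}

#' Growth-rate-shifted classification boundaries
#'
#' With equal growth rates the two-type outcome regions in the
#' `(a12, a21)` plane are bounded by the lines `a21 = a11` and `a12 = a22`.
#' Unequal (positive) rates move them: the `a21` threshold becomes
#' `a11 * r2 / r1` and the `a12` threshold becomes `a22 * r1 / r2`. Each
#' threshold is the point at which the rare type's growth rate at the other
#' type's single-species equilibrium changes sign.
#'
#' @param A 2x2 interaction matrix.
#' @param r growth-rate vector with both entries positive.
#' @return list with `a21_threshold` and `a12_threshold`.
#' @examples
#' classification_boundaries(fixture_system("pd_growth_shift")$A, c(1.5, 1))
#' @export
classification_boundaries <- function(A, r) {
  A <- if (inherits(A, "eco_game_system")) A$A else as.matrix(A)
  r <- as.numeric(r)
  if (!all(dim(A) == c(2, 2)) || length(r) != 2) stop("defined for 2 types")
  if (any(r <= 0)) stop("boundary formulas hold only for positive growth rates")
  list(a21_threshold = A[1, 1] * r[2] / r[1],
       a12_threshold = A[2, 2] * r[1] / r[2])
}

#' Classify the dynamical outcome of a bounded two-type system
#'
#' The full classification that accounts for unequal intrinsic growth
#' rates. For positive rates the verdict follows from mutual invasibility:
#' type 2 invades type 1's single-species equilibrium iff
#' `a21 > a11 * r2 / r1`, and type 1 invades type 2's iff
#' `a12 > a22 * r1 / r2`. Both hold: coexistence; neither: bistability;
#' exactly one: dominance of the invader. When one rate is positive and the
#' other nonpositive, only the positive-rate type can stand alone, so the
#' outcome is coexistence (if the other type invades) or dominance of the
#' viable type; when neither rate is positive, both types die out. Unbounded
#' systems are reported as such, not classified.
#'
#' @param sys a 2-type [eco_game_system()].
#' @param tol comparisons within `tol` of a threshold are flagged
#'   degenerate.
#' @return list with `outcome` (one of `DOMINANCE_1`, `DOMINANCE_2`,
#'   `COEXISTENCE`, `BISTABILITY`, `EXTINCTION_BOTH`, `UNBOUNDED`),
#'   `degenerate`, `boundaries` (when defined) and `details` (the signed
#'   invasion margins used).
#' @examples
#' classify_outcome(fixture_system("pd_unequal"))$outcome  # coexistence
#' @export
classify_outcome <- function(sys, tol = 1e-9) {
  sys <- as_system(sys)
  if (n_types(sys) != 2) stop("outcome classification is defined for 2 types")
  A <- sys$A; r <- sys$r
  res <- list(outcome = NA_character_, degenerate = FALSE,
              boundaries = NULL, details = list())
  if (!is_bounded(sys)) {
    res$outcome <- "UNBOUNDED"
    return(res)
  }
  if (any(abs(r) <= tol)) res$degenerate <- TRUE  # r_i = 0: cannot persist alone
  pos <- r > tol
  if (all(pos)) {
    # mutual invasibility margins; margin_i > 0 means type i invades the other
    margin2 <- A[2, 1] - A[1, 1] * r[2] / r[1]
    margin1 <- A[1, 2] - A[2, 2] * r[1] / r[2]
    scale2 <- max(abs(c(A[2, 1], A[1, 1] * r[2] / r[1], 1)))
    scale1 <- max(abs(c(A[1, 2], A[2, 2] * r[1] / r[2], 1)))
    if (abs(margin2) <= tol * scale2 || abs(margin1) <= tol * scale1) {
      res$degenerate <- TRUE
    }
    res$boundaries <- classification_boundaries(A, r)
    res$details <- list(invades_1_margin = margin1, invades_2_margin = margin2)
    res$outcome <-
      if (margin1 > 0 && margin2 > 0) "COEXISTENCE"
      else if (margin1 < 0 && margin2 < 0) "BISTABILITY"
      else if (margin2 > 0) "DOMINANCE_2"
      else "DOMINANCE_1"
    return(res)
  }
  if (any(pos)) {
    i <- which(pos); j <- which(!pos)
    n_hat <- -r[i] / A[i, i]
    lambda <- as.numeric(r[j] + A[j, i] * n_hat)
    if (abs(lambda) <= tol) res$degenerate <- TRUE
    res$details <- list(resident = i, resident_abundance = as.numeric(n_hat),
                        invader_growth = lambda)
    res$outcome <- if (lambda > 0) "COEXISTENCE"
                   else if (i == 1) "DOMINANCE_1" else "DOMINANCE_2"
    return(res)
  }
  res$outcome <- "EXTINCTION_BOTH"
  res
}

#' Critical growth rate turning dominance into coexistence
#'
#' For a matrix in which type 1 cannot invade at equal rates
#' (`a12 < a22 < 0`, a dominance-of-type-2 scenario), the invasion condition
#' `a12 > a22 * r1 / r2` is equivalent to `r1 > r2 * a12 / a22`. The
#' returned value is that threshold: the infimum of growth rates `r1` at
#' which the two types coexist. `method = "bisection"` instead locates the
#' threshold numerically as the point where a feasible, linearly stable
#' interior equilibrium appears (via [fixed_points()]), providing an
#' independent check on the closed form.
#'
#' @param A 2x2 interaction matrix with `a22 < 0` and `a12 < a22`.
#' @param r2 growth rate of the resident type 2 (> 0).
#' @param method `"formula"` (closed form) or `"bisection"`.
#' @param tol bisection convergence tolerance on `r1`.
#' @return scalar critical value of `r1`.
#' @examples
#' critical_r1(fixture_system("pd_equal")$A, r2 = 1)  # 5/4
#' @export
critical_r1 <- function(A, r2, method = c("formula", "bisection"), tol = 1e-8) {
  A <- if (inherits(A, "eco_game_system")) A$A else as.matrix(A)
  method <- match.arg(method)
  if (!all(dim(A) == c(2, 2))) stop("defined for 2 types")
  if (A[2, 2] >= 0) stop("requires self-limitation of type 2 (a22 < 0)")
  if (r2 <= 0) stop("requires a positive resident growth rate r2")
  if (A[1, 2] > A[2, 2]) {
    stop("requires a12 < a22 (type 1 unable to invade at equal rates)")
  }
  if (method == "formula") {
    return(r2 * A[1, 2] / A[2, 2])
  }
  has_stable_interior <- function(r1) {
    eqs <- fixed_points(eco_game_system(A, c(r1, r2)))
    any(vapply(eqs, function(e) length(e$support) == 2 && e$stability == "STABLE",
               logical(1)))
  }
  lo <- r2                       # equal rates: dominance of 2, no interior
  hi <- 2 * r2
  for (k in 1:60) {
    if (has_stable_interior(hi)) break
    lo <- hi
    hi <- 2 * hi
    if (hi > 1e8) stop("no coexistence found while expanding the bracket")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (has_stable_interior(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Which outcomes can growth rates produce for a fixed matrix?
#'
#' Scans the growth-rate plane through the sign-regime and threshold
#' structure of [classify_outcome()] and reports every reachable outcome
#' together with one concrete witness pair `(r1, r2)`. Dominance of either
#' type is always reachable (make the other type's intrinsic rate
#' sufficiently negative), extinction of both is always reachable (both
#' rates negative), coexistence is reachable exactly when
#' `a12 * a21 < a11 * a22`, and bistability is reachable exactly when both
#' cross-effects are negative with `a12 * a21 > a11 * a22`. Every witness is
#' verified through [classify_outcome()] before being returned.
#'
#' @param A 2x2 interaction matrix with `a11 < 0`, `a22 < 0`, excluding
#'   matrices that are unbounded for every choice of rates.
#' @return data frame with columns `outcome`, `r1`, `r2`.
#' @examples
#' achievable_outcomes(fixture_system("pd_equal")$A)
#' @export
achievable_outcomes <- function(A) {
  A <- if (inherits(A, "eco_game_system")) A$A else as.matrix(A)
  if (!all(dim(A) == c(2, 2))) stop("defined for 2 types")
  a11 <- A[1, 1]; a12 <- A[1, 2]; a21 <- A[2, 1]; a22 <- A[2, 2]
  if (a11 >= 0 || a22 >= 0) stop("requires self-limitation (a11 < 0, a22 < 0)")
  if (a12 > 0 && a21 > 0 && a12 * a21 >= a11 * a22) {
    stop("matrix is unbounded for every choice of growth rates")
  }
  wit <- list(EXTINCTION_BOTH = c(-1, -2))
  # rho = r2 / r1 in the positive-rate regime; margins:
  #   type 2 invades iff rho > a21/a11 (automatic when a21 >= 0)
  #   type 1 invades iff rho < a22/a12 (automatic when a12 >= 0)
  lo <- if (a21 < 0) a21 / a11 else 0
  hi <- if (a12 < 0) a22 / a12 else Inf
  if (lo < hi) {  # mutual invasibility window exists <=> a12*a21 < a11*a22
    rho <- if (is.infinite(hi)) lo + 1 else (lo + hi) / 2
    wit$COEXISTENCE <- c(1, rho)
  } else if (a12 < 0 && a21 < 0) {  # both invasions can fail simultaneously
    rho <- (hi + lo) / 2            # here hi = a22/a12 < rho < a21/a11 = lo
    wit$BISTABILITY <- c(1, rho)
  }
  # dominance of 2: either only-2-invades in the positive regime (needs a12<0),
  # or r1 negative enough that type 1 cannot persist at 2's equilibrium
  if (a12 < 0) {
    rho <- 2 * max(1, lo, a22 / a12)
    wit$DOMINANCE_2 <- c(1, rho)
  } else {
    wit$DOMINANCE_2 <- c(-1 - a12 * (-1 / a22), 1)
  }
  if (a21 < 0) {
    rho <- 0.5 * min(1, if (is.finite(hi)) hi else 1, a21 / a11)
    wit$DOMINANCE_1 <- c(1, rho)
  } else {
    wit$DOMINANCE_1 <- c(1, -1 - a21 * (-1 / a11))
  }
  out <- data.frame(outcome = names(wit),
                    r1 = vapply(wit, `[`, numeric(1), 1),
                    r2 = vapply(wit, `[`, numeric(1), 2),
                    row.names = NULL, stringsAsFactors = FALSE)
  chk <- vapply(seq_len(nrow(out)), function(k) {
    classify_outcome(eco_game_system(A, c(out$r1[k], out$r2[k])))$outcome
  }, character(1))
  if (!identical(chk, out$outcome)) {
    stop("internal error: witness verification failed for ",
         paste(out$outcome[chk != out$outcome], collapse = ", "))
  }
  out[order(match(out$outcome, outcome_levels)), , drop = FALSE]
}

#' Long-run simulation verdict for a two-type system
#'
#' Independent numerical oracle for [classify_outcome()]: integrates the
#' Lotka-Volterra dynamics from several initial conditions (each boundary
#' equilibrium perturbed by a small inoculum of the missing type, plus two
#' interior starts) until the trajectory has demonstrably converged onto
#' one of the enumerated fixed points, and reads the outcome off the
#' pattern of reached supports: interior convergence from every start is
#' coexistence, convergence to the same boundary from every start is
#' dominance, start-dependent boundary convergence is bistability, and
#' universal convergence to the origin is extinction of both. Chunks of
#' integration time grow geometrically, so systems with near-threshold
#' (hence slow) invasion dynamics are followed as long as it takes to
#' resolve the verdict; the convergence tolerance adapts to the minimum
#' separation between fixed points so that a genuinely tiny interior
#' component is not mistaken for an extinction in progress.
#'
#' @param sys a 2-type [eco_game_system()].
#' @param starts optional list of initial abundance vectors.
#' @param t_max hard cap on integration time per start.
#' @param tol integrator relative tolerance.
#' @param delta inoculum used for the boundary-perturbed starts.
#' @return list with `outcome` and `support_per_start`.
#' @export
simulate_outcome <- function(sys, starts = NULL, t_max = 1e6, tol = 1e-8,
                             delta = 1e-4) {
  sys <- as_system(sys)
  if (n_types(sys) != 2) stop("simulation verdict is defined for 2 types")
  A <- sys$A; r <- sys$r
  if (is.null(starts)) {
    starts <- list(c(0.1, 0.1), c(1, 1))
    if (r[1] > 0) starts <- c(starts, list(c(-r[1] / A[1, 1], delta)))
    if (r[2] > 0) starts <- c(starts, list(c(delta, -r[2] / A[2, 2])))
  }
  eqs <- fixed_points(sys)
  eq_states <- lapply(eqs, function(e) unname(e$n))
  # convergence radius: well below the closest pair of fixed points
  minsep <- Inf
  for (i in seq_along(eq_states)) {
    for (j in seq_len(i - 1)) {
      minsep <- min(minsep, max(abs(eq_states[[i]] - eq_states[[j]])))
    }
  }
  conv_tol <- max(min(1e-3, 0.3 * minsep), 1e-9)
  supports <- vapply(starts, function(n0) {
    n <- n0
    t_done <- 0
    chunk <- 200
    repeat {
      traj <- integrate_lv(sys, n, t_end = chunk, tol = tol, atol = 1e-12,
                           n_out = 40, extinction_floor = 0)
      n <- final_state(traj)
      t_done <- t_done + chunk
      chunk <- min(2 * chunk, 1e5)
      if (isTRUE(traj$unbounded)) return("unbounded")
      d <- vapply(eq_states, function(e) max(abs(n - e)), numeric(1))
      if (min(d) < conv_tol && max(abs(lv_derivative(sys, n))) < 1e-10) {
        return(paste(eqs[[which.min(d)]]$support, collapse = ""))
      }
      if (t_done >= t_max) return("indeterminate")
    }
  }, character(1))
  outcome <-
    if (any(supports == "unbounded")) "UNBOUNDED"
    else if (all(supports == "12")) "COEXISTENCE"
    else if (all(supports == "1")) "DOMINANCE_1"
    else if (all(supports == "2")) "DOMINANCE_2"
    else if (all(supports == "")) "EXTINCTION_BOTH"
    else if (all(supports %in% c("1", "2"))) "BISTABILITY"
    else "INDETERMINATE"
  list(outcome = outcome, support_per_start = supports)
}
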