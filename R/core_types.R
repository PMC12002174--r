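#' Construct an ecological game system
#'
#' Bundles an interaction matrix `A` and a growth-rate vector `r` into the
#' single object that every dynamical, classification and assembly routine
#' consumes. Entry `A[i, j]` is the per-capita effect of type `j` on the
#' growth rate of type `i` (row = affected type, column = acting type); in
#' abundance dynamics its units are 1/(time x abundance), in frequency
#' dynamics it plays the role of a dimensionless payoff. `r[i]` is the
#' intrinsic per-capita growth rate of type `i` when rare and free of all
#' interactions (units 1/time).
#'
#' @param A square numeric matrix of interaction coefficients; all entries
#'   must be finite.
#' @param r numeric vector of intrinsic growth rates, one per type.
#' @param labels optional character vector of type names; defaults to the
#'   dimnames of `A` or `T1, T2, ...`.
#' @return An object of class `eco_game_system` with elements `A`, `r`,
#'   `labels`.
#' @examples
#' sys <- eco_game_system(matrix(c(-3, 1, -5, -4), 2), r = c(1, 1))
#' sys
#' @export
eco_game_system <- function(A, r, labels = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) {
    stop("interaction matrix must be square, got ", nrow(A), "x", ncol(A))
  }
  if (!is.numeric(A) || any(!is.finite(A))) {
    stop("interaction matrix entries must all be finite numbers")
  }
  r <- as.numeric(r)
  if (any(!is.finite(r))) stop("growth rates must all be finite")
  m <- nrow(A)
  if (length(r) != m) {
    stop("growth-rate vector has length ", length(r),
         " but the matrix has ", m, " types")
  }
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(A))) rownames(A) else paste0("T", seq_len(m))
  }
  labels <- as.character(labels)
  if (length(labels) != m) stop("need exactly one label per type")
  if (anyDuplicated(labels)) stop("type labels must be unique")
  dimnames(A) <- list(labels, labels)
  names(r) <- labels
  structure(list(A = A, r = r, labels = labels), class = "eco_game_system")
}

#' @export
print.eco_game_system <- function(x, ...) {
  cat("<eco_game_system> ", length(x$labels), " types: ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  cat("interaction matrix (row = affected, column = acting):\n")
  print(x$A)
  cat("intrinsic growth rates:\n")
  print(x$r)
  invisible(x)
}

#' @export
dim.eco_game_system <- function(x) dim(x$A)

n_types <- function(sys) nrow(sys$A)

as_system <- function(x) {
  if (inherits(x, "eco_game_system")) return(x)
  stop("expected an eco_game_system; got ", class(x)[1])
}

#' Hawk-Dove interaction matrix
#'
#' The classical two-strategy conflict game: two Doves split a benefit
#' `b > 0`; a Dove meeting a Hawk retreats (payoff 0) and yields the whole
#' benefit; two Hawks fight, for an expected payoff of `(b - c)/2 < 0`, where
#' the cost of escalated conflict satisfies `c > b`.
#'
#' @param b benefit of the contested resource, `b > 0`.
#' @param c cost of escalated conflict, `c > b`.
#' @return 2x2 matrix with rows/columns labelled `Hawk`, `Dove`:
#'   `rbind(c((b - c)/2, b), c(0, b/2))`.
#' @examples
#' hawk_dove_matrix(b = 2, c = 4)
#' @export
hawk_dove_matrix <- function(b, c) {
  if (!is.numeric(b) || length(b) != 1 || !is.finite(b) || b <= 0) {
    stop("benefit b must be a single positive number")
  }
  if (!is.numeric(c) || length(c) != 1 || !is.finite(c) || c <= b) {
    stop("cost c must exceed the benefit b (c > b > 0)")
  }
  m <- rbind(c((b - c) / 2, b),
             c(0,           b / 2))
  dimnames(m) <- list(c("Hawk", "Dove"), c("Hawk", "Dove"))
  m
}

#' Rock-Paper-Scissors interaction matrix
#'
#' Fully symmetric cyclic game with self-limitation: every entry carries a
#' baseline of -1 (bounded growth of each type on its own), winning an
#' encounter adds `+alpha` and losing adds `-alpha`. Rock beats Scissors,
#' Scissors beats Paper, Paper beats Rock.
#'
#' @param alpha strength of cyclic dominance, `alpha > 0`.
#' @return 3x3 matrix in row order `R`, `P`, `S` with diagonal -1, entries
#'   `-1 + alpha` against the strategy each row beats and `-1 - alpha`
#'   against the strategy it loses to.
#' @examples
#' rps_matrix(1.3)
#' @export
rps_matrix <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0) {
    stop("alpha must be a single positive number")
  }
  m <- matrix(-1, 3, 3)
  # row = affected: R is hurt by P (loses) and helped... R beats S: gains +alpha from S
  m[1, 2] <- -1 - alpha; m[1, 3] <- -1 + alpha
  m[2, 1] <- -1 + alpha; m[2, 3] <- -1 - alpha
  m[3, 1] <- -1 - alpha; m[3, 2] <- -1 + alpha
  dimnames(m) <- list(c("R", "P", "S"), c("R", "P", "S"))
  m
}

#' Built-in example systems
#'
#' Named parameter sets used throughout the documentation and tests. The
#' `pd_*` family shares one Prisoner's-Dilemma-ranked interaction matrix
#' (`a11 = -3`, `a12 = -5`, `a21 = 1`, `a22 = -4`, ranking
#' `a21 > a11 > a22 > a12`) under different growth-rate regimes; the `rps_*`
#' pair is the cyclic community of [rps_matrix()] with `alpha = 1.3` under
#' equal and unequal growth rates.
#'
#' @param name one of `"pd_equal"` (r = (1, 1)), `"pd_growth_shift"`
#'   (r = (1.5, 1)), `"pd_prey_advantage"` (r = (1, -1)), `"pd_decline"`
#'   (r = (-0.5, -1)), `"pd_unequal"` (r = (2, 1)), `"rps_equal"`
#'   (r = (1, 1, 1)), `"rps_unequal"` (r = (2.5, 1, 1)).
#' @return An [eco_game_system()].
#' @examples
#' fixture_system("pd_equal")
#' @export
fixture_system <- function(name) {
  pd <- matrix(c(-3, 1, -5, -4), 2,
               dimnames = list(c("C", "D"), c("C", "D")))
  switch(
    match.arg(name, c("pd_equal", "pd_growth_shift", "pd_prey_advantage",
                      "pd_decline", "pd_unequal", "rps_equal", "rps_unequal")),
    pd_equal          = eco_game_system(pd, c(1, 1)),
    pd_growth_shift   = eco_game_system(pd, c(1.5, 1)),
    pd_prey_advantage = eco_game_system(pd, c(1, -1)),
    pd_decline        = eco_game_system(pd, c(-0.5, -1)),
    pd_unequal        = eco_game_system(pd, c(2, 1)),
    rps_equal         = eco_game_system(rps_matrix(1.3), c(1, 1, 1)),
    rps_unequal       = eco_game_system(rps_matrix(1.3), c(2.5, 1, 1))
  )
}

#' @rdname fixture_system
#' @export
fixture_names <- function() {
  c("pd_equal", "pd_growth_shift", "pd_prey_advantage", "pd_decline",
    "pd_unequal", "rps_equal", "rps_unequal")
}

#' Canonical ordering of a two-type matrix
#'
#' Game classification is stated for matrices with `a11 >= a22` (type 1 gets
#' at least as much from its own type as type 2 does). This helper reorders
#' the two types when needed and records the permutation so that outcome
#' labels can be mapped back to the user's original ordering.
#'
#' @param A 2x2 interaction matrix.
#' @return list with `A` (possibly reordered), `perm` (integer permutation
#'   applied to the original indices), `swapped` (logical) and `tie`
#'   (logical; `a11 == a22`, user's order kept).
#' @export
canonical_order <- function(A) {
  A <- as.matrix(A)
  if (!all(dim(A) == c(2, 2))) stop("canonical ordering is defined for 2x2 matrices")
  if (A[1, 1] >= A[2, 2]) {
    list(A = A, perm = 1:2, swapped = FALSE, tie = A[1, 1] == A[2, 2])
  } else {
    list(A = A[2:1, 2:1, drop = FALSE], perm = 2:1, swapped = TRUE, tie = FALSE)
  }
}

# Seed handling: run `code` under a fixed seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample a random bounded two-type system
#'
#' Rejection-samples a two-type system whose trajectories stay bounded:
#' self-limitation on the diagonal (`a11 < 0`, `a22 < 0`, drawn uniformly
#' from `diag_range`) and cross-interaction product below the
#' self-limitation product (`a12 * a21 < a11 * a22`, off-diagonals drawn
#' uniformly from `offdiag_range`). Types are returned in canonical order
#' (`a11 >= a22`). The same seed always yields the same system.
#'
#' @param seed integer seed; required for reproducibility.
#' @param r optional growth-rate vector (default `c(1, 1)`).
#' @param diag_range,offdiag_range sampling intervals for diagonal and
#'   off-diagonal entries.
#' @param max_tries rejection-sampling budget before giving up.
#' @return An [eco_game_system()] satisfying `is_bounded()`.
#' @examples
#' sys <- sample_bounded_system(seed = 42)
#' is_bounded(sys)
#' @export
sample_bounded_system <- function(seed, r = c(1, 1),
                                  diag_range = c(-5, -0.5),
                                  offdiag_range = c(-5, 5),
                                  max_tries = 1000L) {
  stopifnot(length(seed) == 1, is.finite(seed))
  A <- with_seed(as.integer(seed), {
    for (k in seq_len(max_tries)) {
      d <- stats::runif(2, diag_range[1], diag_range[2])
      o <- stats::runif(2, offdiag_range[1], offdiag_range[2])
      cand <- matrix(c(d[1], o[2], o[1], d[2]), 2)
      if (cand[1, 2] * cand[2, 1] < cand[1, 1] * cand[2, 2]) break
      cand <- NULL
    }
    if (is.null(cand)) stop("could not sample a bounded system in ", max_tries, " tries")
    cand
  })
  A <- canonical_order(A)$A
  eco_game_system(A, r, labels = c("T1", "T2"))
}
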