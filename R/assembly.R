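#' Parameters of the stepwise assembly protocol
#'
#' @param inoculum abundance at which a new type is introduced (default
#'   1e-6); must exceed the extinction floor.
#' @param extinction_floor abundance below which a type is pruned after
#'   relaxation (default 1e-9).
#' @param relax_time ecological relaxation horizon per introduction step
#'   (default 500 time units, with one doubling retry if neither a steady
#'   state nor a cycle is detected).
#' @param cycle_window trailing time window used for cycle detection
#'   (default 100).
#' @param tol integrator relative tolerance.
#' @return list of class `assembly_params`.
#' @export
assembly_params <- function(inoculum = 1e-6, extinction_floor = 1e-9,
                            relax_time = 500, cycle_window = 100,
                            tol = 1e-10) {
  stopifnot(inoculum > extinction_floor, extinction_floor > 0,
            relax_time > cycle_window, cycle_window > 0, tol > 0)
  structure(list(inoculum = inoculum, extinction_floor = extinction_floor,
                 relax_time = relax_time, cycle_window = cycle_window,
                 tol = tol),
            class = "assembly_params")
}

# Steady-state test: derivative sup-norm below thr at every sample in the
# last `window` time units.
is_steady <- function(sys, traj, thr = 1e-8, window = 5) {
  tt <- traj$times
  idx <- which(tt >= max(tt) - window)
  all(vapply(idx, function(k) {
    max(abs(lv_derivative(sys, traj$states[k, ]))) < thr
  }, logical(1)))
}

# Cycle test on the trailing window: every supported type keeps oscillating
# with non-decaying amplitude while staying above the floor.
looks_cyclic <- function(traj, support, window, floor) {
  tt <- traj$times
  idx <- which(tt >= max(tt) - window)
  if (length(idx) < 20) return(FALSE)
  st <- traj$states[idx, support, drop = FALSE]
  if (any(st <= floor)) return(FALSE)
  half <- seq_len(floor(length(idx) / 2))
  for (j in seq_len(ncol(st))) {
    a1 <- diff(range(st[half, j]))
    a2 <- diff(range(st[-half, j]))
    if (a2 < 1e-4 * max(st[, j])) return(FALSE)  # flat: converging, not cycling
    if (a2 < 0.5 * a1) return(FALSE)             # decaying envelope
  }
  TRUE
}

#' Relax a community to its ecological attractor
#'
#' Integrates the Lotka-Volterra dynamics until a steady state is detected
#' (derivative sup-norm below 1e-8 sustained over 5 time units) or
#' `relax_time` elapses, then prunes types below the extinction floor.
#' Non-steady endings are inspected for sustained oscillation over the
#' trailing `cycle_window`; if neither verdict fits, the run is retried once
#' with a doubled horizon and otherwise reported `INDETERMINATE`.
#'
#' @param sys an [eco_game_system()].
#' @param n0 initial abundances.
#' @param params an [assembly_params()].
#' @return list with `community` (final abundances, pruned), `support`
#'   (indices above the floor), `regime` (`"FIXED_POINT"`, `"CYCLE"`,
#'   `"EXTINCT"` or `"INDETERMINATE"`), and the final `trajectory`.
#' @examples
#' relax(fixture_system("pd_equal"), c(0.1, 0.1))
#' @export
relax <- function(sys, n0, params = assembly_params()) {
  sys <- as_system(sys)
  n0 <- as.numeric(n0)
  horizon <- params$relax_time
  for (attempt in 1:2) {
    n_out <- max(400, ceiling(horizon))
    traj <- integrate_lv(sys, n0, t_end = horizon, tol = params$tol,
                         n_out = n_out,
                         extinction_floor = params$extinction_floor)
    if (isTRUE(traj$unbounded)) {
      stop("unbounded growth during relaxation (abundance ceiling reached)")
    }
    n_end <- final_state(traj)
    support <- unname(which(n_end > params$extinction_floor))
    if (length(support) == 0) {
      return(list(community = n_end * 0, support = integer(0),
                  regime = "EXTINCT", trajectory = traj))
    }
    if (is_steady(sys, traj)) {
      n_end[-support] <- 0
      return(list(community = n_end, support = support,
                  regime = "FIXED_POINT", trajectory = traj))
    }
    if (looks_cyclic(traj, support, params$cycle_window,
                     params$extinction_floor)) {
      return(list(community = n_end, support = support,
                  regime = "CYCLE", trajectory = traj))
    }
    horizon <- 2 * horizon
  }
  list(community = n_end, support = support, regime = "INDETERMINATE",
       trajectory = traj)
}

#' Stepwise community assembly
#'
#' Builds a community one type at a time: each type in `order` arrives at
#' the inoculum abundance into the fully relaxed resident community, the
#' system relaxes, and types that fell below the extinction floor are
#' pruned. Invasion fitness is recorded against fixed-point residents (it is
#' `NA` against a cycling resident, whose invasibility is decided by the
#' simulation itself). Mutations/migrations are rare: strictly one
#' introduction per relaxed state.
#'
#' @param sys an [eco_game_system()] describing the full species pool.
#' @param order integer indices or labels giving the introduction sequence
#'   (a subset of the pool, each type at most once).
#' @param params an [assembly_params()].
#' @return list of class `assembly_record` with `steps` (data frame:
#'   `introduced`, `invasion_fitness`, `regime`, `support` as
#'   comma-separated labels), `final_support`, `final_regime`,
#'   `final_community`.
#' @examples
#' assemble(fixture_system("rps_equal"), c("R", "P", "S"))
#' @export
assemble <- function(sys, order, params = assembly_params()) {
  sys <- as_system(sys)
  m <- n_types(sys)
  if (is.character(order)) order <- match(order, sys$labels)
  order <- as.integer(order)
  if (any(is.na(order)) || anyDuplicated(order) ||
      any(order < 1) || any(order > m)) {
    stop("order must list distinct types from the pool")
  }
  n <- numeric(m)
  regime <- "EXTINCT"
  steps <- vector("list", length(order))
  for (k in seq_along(order)) {
    i <- order[k]
    fit <- if (regime %in% c("EXTINCT", "FIXED_POINT")) {
      invasion_fitness(sys, n, i)
    } else NA_real_
    n[i] <- params$inoculum
    rel <- relax(sys, n, params)
    n <- rel$community
    regime <- rel$regime
    steps[[k]] <- data.frame(
      introduced = sys$labels[i],
      invasion_fitness = fit,
      regime = regime,
      support = paste(sys$labels[rel$support], collapse = ","),
      stringsAsFactors = FALSE)
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(introduced = character(0), invasion_fitness = numeric(0),
               regime = character(0), support = character(0))
  structure(list(steps = steps,
                 final_support = unname(which(n > params$extinction_floor)),
                 final_regime = regime,
                 final_community = n,
                 labels = sys$labels),
            class = "assembly_record")
}

#' @export
print.assembly_record <- function(x, ...) {
  cat("<assembly_record> ", nrow(x$steps), " introduction(s)\n", sep = "")
  print(x$steps)
  cat("final regime: ", x$final_regime, "; final support: {",
      paste(x$labels[x$final_support], collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Can a target community be assembled stepwise?
#'
#' Tries every introduction order of the species pool and reports the first
#' whose final support contains the target set. With an exhaustive failure
#' the target community cannot be reached by rare sequential invasions.
#'
#' @param sys an [eco_game_system()] (pool of at most 8 types).
#' @param target_support indices or labels of the community to reach.
#' @param params an [assembly_params()].
#' @return list with `possible`, `witness_order` (labels, or `NULL`),
#'   `record` (the successful [assemble()] record, or `NULL`) and
#'   `orders_tried`.
#' @examples
#' can_assemble(fixture_system("rps_unequal"), c("R", "P", "S"))$possible
#' @export
can_assemble <- function(sys, target_support, params = assembly_params()) {
  sys <- as_system(sys)
  m <- n_types(sys)
  if (m > 8) stop("exhaustive order search is limited to pools of 8 types")
  if (is.character(target_support)) {
    target_support <- match(target_support, sys$labels)
  }
  target_support <- sort(as.integer(target_support))
  if (any(is.na(target_support))) stop("unknown type in target support")
  perms <- all_permutations(seq_len(m))
  tried <- 0L
  for (ord in perms) {
    tried <- tried + 1L
    rec <- assemble(sys, ord, params)
    if (all(target_support %in% rec$final_support)) {
      return(list(possible = TRUE, witness_order = sys$labels[ord],
                  record = rec, orders_tried = tried))
    }
  }
  list(possible = FALSE, witness_order = NULL, record = NULL,
       orders_tried = tried)
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (k in seq_along(v)) {
    for (rest in all_permutations(v[-k])) {
      out[[length(out) + 1]] <- c(v[k], rest)
    }
  }
  out
}
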