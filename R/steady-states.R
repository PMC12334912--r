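#' Find fixed points of a circuit at a constant input
#'
#' Multi-start root finding on the rate equations: starting points are
#' drawn uniformly inside the model's plausible state box (plus any
#' candidates from the model's one-dimensional steady-state reduction and
#' user-supplied `extra_starts`), converged with a Gauss-Newton solver,
#' filtered to non-negative residual-zero roots, and merged at 1e-6
#' relative tolerance. Stability is read off the sign of the largest real
#' part of the Jacobian eigenvalues (central differences).
#'
#' @param model A `circuit_model`.
#' @param input_value Constant external input (signal level or scanned
#'   activity, e.g. ATF2).
#' @param n_starts Number of random starting points.
#' @param seed Optional RNG seed for the starts.
#' @param extra_starts Optional matrix of additional starting states
#'   (rows).
#' @return A tibble with one row per fixed point: the species columns,
#'   `stable` (logical) and `max_re_eig`.
#' @export
find_steady_states <- function(model, input_value = 0, n_starts = 30,
                               seed = NULL, extra_starts = NULL) {
  stopifnot(inherits(model, "circuit_model"))
  if (!is.null(seed)) withr::local_seed(seed)
  ns <- length(model$species)
  f <- function(x) as.numeric(model$derivs(0, x, input_value, model$params))

  starts <- matrix(runif(n_starts * ns), ncol = ns)
  starts <- sweep(starts, 2, model$state_upper * 1.2, `*`)
  if (!is.null(model$steady_state_starts)) {
    cand <- model$steady_state_starts(input_value)
    if (!is.null(cand)) starts <- rbind(cand, starts)
  }
  if (!is.null(extra_starts)) starts <- rbind(as.matrix(extra_starts), starts)

  solve_from <- function(x0) {
    if (ns == 1) {
      # univariate: exhaustive sign-change scan plus refinement
      g <- seq(0, model$state_upper * 1.5 + 1, length.out = 500)
      v <- vapply(g, f, 0)
      i <- which(v[-1] * v[-length(v)] < 0)[1]
      if (is.na(i)) {
        z <- which(abs(v) < 1e-12)[1]
        if (is.na(z)) return(NULL)
        return(g[z])
      }
      return(stats::uniroot(f, c(g[i], g[i + 1]), tol = 1e-12)$root)
    }
    tryCatch(suppressWarnings(pracma::fsolve(f, x0, tol = 1e-12))$x,
             error = function(e) NULL)
  }

  roots <- list()
  for (i in seq_len(nrow(starts))) {
    x <- solve_from(as.numeric(starts[i, ]))
    if (is.null(x) || anyNA(x)) next
    if (max(abs(f(x))) > 1e-7) next
    if (any(x < -1e-7)) next
    roots[[length(roots) + 1]] <- pmax(x, 0)
  }
  if (!length(roots))
    stop("no fixed point found from any start", call. = FALSE)

  uniq <- list()
  for (x in roots) {
    dup <- any(vapply(uniq, function(y)
      max(abs(x - y) / pmax(1, abs(y))) < 1e-6, TRUE))
    if (!dup) uniq[[length(uniq) + 1]] <- x
  }

  rows <- purrr::map_dfr(uniq, function(x) {
    J <- numeric_jacobian(f, x)
    ev <- eigen(J, only.values = TRUE)$values
    mre <- max(Re(ev))
    out <- as.list(setNames(x, model$species))
    out$stable <- mre < 0
    out$max_re_eig <- mre
    tibble::as_tibble(out)
  })
  dplyr::arrange(rows, .data[[model$species[1]]])
}

numeric_jacobian <- function(f, x, h = NULL) {
  n <- length(x)
  if (is.null(h)) h <- 1e-6 * pmax(1, abs(x))
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- h[j]
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h[j])
  }
  J
}

count_states <- function(model, value, n_starts, extra_starts = NULL) {
  ss <- find_steady_states(model, value, n_starts = n_starts,
                           extra_starts = extra_starts)
  list(n = nrow(ss), states = ss)
}

#' Scan a parameter and assemble a bifurcation diagram
#'
#' Tracks the model's fixed points across a grid of the scanned input
#' (e.g. ATF2 activity), brackets each saddle-node (fold) bifurcation by
#' bisection on the fixed-point count to `1e-4` of the grid span, and
#' issues the reversibility verdict: switching is *irreversible* when the
#' left fold lies outside the physically admissible input range (e.g. at
#' negative ATF2 activity), because a cell driven onto the low branch can
#' then never be brought back by an admissible input.
#'
#' @param model A `circuit_model` (input-scanned form).
#' @param grid Strictly increasing numeric grid of input values, dense
#'   enough that the fixed-point count changes at most once between
#'   neighbours (the scan refines locally and errors if a neighbour pair
#'   still hides two transitions).
#' @param physical_range Admissible input interval (default `[0, Inf)`).
#' @param n_starts Random starts per grid value for
#'   [find_steady_states()].
#' @param seed RNG seed for the scan.
#' @param fold_tol Bracketing tolerance; default `1e-4 * diff(range(grid))`.
#' @param parameter Name of the scanned parameter (for labels/summaries).
#' @return An object of class `bifurcation_diagram`: list with `points`
#'   (tibble: `param`, species columns, `stable`), `counts` (tibble:
#'   `param`, `n_fixed`), `folds` (sorted numeric), `bistable_range`,
#'   `reversibility` (`"reversible"`/`"irreversible"`), `physical_range`
#'   and `parameter`.
#' @export
scan_bifurcation <- function(model, grid, physical_range = c(0, Inf),
                             n_starts = 24, seed = 1, fold_tol = NULL,
                             parameter = "input") {
  stopifnot(inherits(model, "circuit_model"), length(grid) >= 2,
            all(diff(grid) > 0))
  if (!is.null(seed)) withr::local_seed(seed)
  span <- diff(range(grid))
  if (is.null(fold_tol)) fold_tol <- 1e-4 * span

  prev_states <- NULL
  res <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cs <- count_states(model, grid[i], n_starts,
                       extra_starts = prev_states)
    res[[i]] <- cs
    prev_states <- as.matrix(cs$states[, model$species])
  }
  counts <- vapply(res, `[[`, 0L, "n")

  # refine neighbour pairs hiding more than one transition
  jumps <- which(abs(diff(counts)) > 2)
  depth <- 0
  while (length(jumps) && depth < 4) {
    for (j in rev(jumps)) {
      mid <- (grid[j] + grid[j + 1]) / 2
      cs <- count_states(model, mid, n_starts,
                         extra_starts = as.matrix(
                           res[[j]]$states[, model$species]))
      grid <- append(grid, mid, after = j)
      res <- append(res, list(cs), after = j)
    }
    counts <- vapply(res, `[[`, 0L, "n")
    jumps <- which(abs(diff(counts)) > 2)
    depth <- depth + 1
  }
  if (length(jumps))
    stop("fixed-point count changes by more than 2 between neighbouring ",
         "grid values after refinement; supply a denser grid",
         call. = FALSE)

  points <- purrr::map2_dfr(res, grid, function(cs, g)
    dplyr::mutate(cs$states, param = g, .before = 1))

  folds <- numeric()
  for (j in which(diff(counts) != 0)) {
    lo <- grid[j]; hi <- grid[j + 1]
    n_lo <- counts[j]; n_hi <- counts[j + 1]
    seeds_states <- rbind(as.matrix(res[[j]]$states[, model$species]),
                          as.matrix(res[[j + 1]]$states[, model$species]))
    while (hi - lo > fold_tol) {
      mid <- (lo + hi) / 2
      n_mid <- count_states(model, mid, n_starts, seeds_states)$n
      if (n_mid == n_lo) lo <- mid else hi <- mid
    }
    folds <- c(folds, (lo + hi) / 2)
  }
  folds <- sort(folds)

  bistable <- grid[counts >= 3]
  bistable_range <- if (length(bistable)) range(bistable) else NULL

  reversibility <- "reversible"
  left_fold <- NA_real_
  if (!is.null(bistable_range)) {
    below <- folds[folds < bistable_range[1]]
    if (length(below)) {
      left_fold <- max(below)
      if (left_fold < physical_range[1]) reversibility <- "irreversible"
    } else if (min(bistable) <= min(grid) + fold_tol) {
      # bistable all the way to the scan's lower edge: the left fold lies
      # below everything scanned, hence outside the physical range when
      # the scan already starts at its lower bound
      if (min(grid) <= physical_range[1]) reversibility <- "irreversible"
    }
  }

  structure(
    list(parameter = parameter,
         points = points,
         counts = tibble::tibble(param = grid, n_fixed = counts),
         folds = folds, left_fold = left_fold,
         bistable_range = bistable_range,
         reversibility = reversibility,
         physical_range = physical_range),
    class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf(
    "<bifurcation_diagram> %s: %d grid points, %d fold(s)%s, %s\n",
    x$parameter, nrow(x$counts), length(x$folds),
    if (length(x$folds))
      paste0(" at ", paste(signif(x$folds, 4), collapse = ", ")) else "",
    x$reversibility))
  invisible(x)
}

#' Quasi-static hysteresis sweep
#'
#' Steps the scanned input up through `grid` and back down, integrating
#' the model for `dwell` time units at each step with the state carried
#' over, and records the plateau level of each species. The up-switching
#' threshold is the input at which the first species (SOX10) leaves its
#' high (ON) branch, the down-threshold the input at which it returns;
#' their difference is the hysteresis loop width, which matches the fold
#' separation of [scan_bifurcation()] within the grid resolution. A
#' monostable circuit gives loop width ~0.
#'
#' @param model A `circuit_model`.
#' @param grid Increasing input grid for the up sweep (reversed for the
#'   down sweep).
#' @param dwell Integration time per step; must exceed the slowest
#'   relaxation (plateaus are checked and the dwell extended up to 4x,
#'   with a warning if still unsettled).
#' @param species Species whose branch occupancy defines the thresholds.
#' @return A list with `sweep` (tibble: `direction`, `param`, one column
#'   per species), `up_threshold`, `down_threshold`, `loop_width`, and
#'   `no_transition` (`TRUE` when the state never switched in range).
#' @export
hysteresis_sweep <- function(model, grid, dwell = 40, species = NULL) {
  stopifnot(inherits(model, "circuit_model"), length(grid) >= 2,
            all(diff(grid) > 0))
  if (is.null(species)) species <- model$species[1]

  settle <- function(state, value) {
    t_total <- 0; max_t <- dwell * 4
    repeat {
      tr <- simulate_circuit(model, signal_profile(numeric(), value),
                             t_end = dwell, initial_state = pmax(state, 0),
                             n_out = 201)
      state <- as.numeric(tr[nrow(tr), model$species])
      t_total <- t_total + dwell
      pw <- plateau_window(tr, species, 0, dwell)
      if (pw$ok || t_total >= max_t) {
        if (!pw$ok)
          warning("plateau not settled at input ", signif(value, 4),
                  "; increase dwell", call. = FALSE)
        return(state)
      }
    }
  }

  ss0 <- find_steady_states(model, grid[1], n_starts = 20, seed = 1)
  state <- as.numeric(ss0[which.max(ss0[[species]]), model$species])

  record <- function(direction, params_seq, state) {
    rows <- vector("list", length(params_seq))
    for (i in seq_along(params_seq)) {
      state <- settle(state, params_seq[i])
      rows[[i]] <- tibble::as_tibble(
        c(list(direction = direction, param = params_seq[i]),
          as.list(setNames(state, model$species))))
    }
    list(rows = dplyr::bind_rows(rows), state = state)
  }
  up <- record("up", grid, state)
  down <- record("down", rev(grid), up$state)
  sweep_tbl <- dplyr::bind_rows(up$rows, down$rows)

  on_level <- up$rows[[species]][1]
  off_level <- up$rows[[species]][nrow(up$rows)]
  mid <- (on_level + off_level) / 2
  up_cross <- which(up$rows[[species]] < mid)[1]
  down_cross <- which(down$rows[[species]] > mid)[1]
  no_transition <- is.na(up_cross) || is.na(down_cross) ||
    abs(on_level - off_level) <
    0.05 * max(abs(on_level), abs(off_level), 1e-12)

  up_threshold <- if (is.na(up_cross)) NA_real_ else up$rows$param[up_cross]
  down_threshold <- if (is.na(down_cross)) NA_real_
                    else down$rows$param[down_cross]
  loop_width <- if (no_transition) 0 else up_threshold - down_threshold

  list(sweep = sweep_tbl, up_threshold = up_threshold,
       down_threshold = down_threshold, loop_width = loop_width,
       no_transition = no_transition)
}

#' Per-interval phenotype calls along a trajectory
#'
#' For each constant-signal interval of a trajectory, takes the plateau
#' (final 10%) mean of the MITF readout and classifies it with a
#' [phenotype_map()] -- e.g. the three-state
#' mesenchymal/intermediate/melanocytic map for toggle-switch replays.
#'
#' @param traj A `circuit_trajectory`.
#' @param map A [phenotype_map()].
#' @param species Readout column; defaults to the last species whose name
#'   contains `"MITF"`.
#' @return A tibble with columns `interval`, `t_start`, `t_end`,
#'   `mitf_level`, `phenotype`.
#' @export
phase_report <- function(traj, map, species = NULL) {
  stopifnot(inherits(traj, "circuit_trajectory"),
            inherits(map, "phenotype_map"))
  if (is.null(species)) {
    cand <- grep("MITF", names(traj), value = TRUE)
    if (!length(cand)) stop("no MITF readout column found", call. = FALSE)
    species <- cand[length(cand)]
  }
  sig <- attr(traj, "signal")
  bounds <- unique(c(0, sig$breakpoints[sig$breakpoints < max(traj$time)],
                     max(traj$time)))
  purrr::map_dfr(seq_len(length(bounds) - 1), function(i) {
    pw <- plateau_window(traj, species, bounds[i], bounds[i + 1])
    tibble::tibble(interval = i, t_start = bounds[i], t_end = bounds[i + 1],
                   mitf_level = pw$mean,
                   phenotype = classify_phenotype(pw$mean, map))
  })
}
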