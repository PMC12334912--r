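#' Piecewise-constant input signal
#'
#' A signal that holds `levels[1]` on `[0, breakpoints[1])`, `levels[2]` on
#' the next interval, and so on; `length(levels)` must be
#' `length(breakpoints) + 1`. Used to drive circuits through signal
#' phases (e.g. miR-155 induction turned off and on again).
#'
#' @param breakpoints Strictly increasing positive times (may be empty for
#'   a constant signal).
#' @param levels Non-negative signal values, one per interval.
#' @return An object of class `signal_profile`.
#' @export
signal_profile <- function(breakpoints = numeric(), levels = 1) {
  stopifnot(length(levels) == length(breakpoints) + 1,
            all(levels >= 0))
  if (length(breakpoints))
    stopifnot(all(breakpoints > 0), all(diff(breakpoints) > 0))
  structure(list(breakpoints = as.numeric(breakpoints),
                 levels = as.numeric(levels)),
            class = "signal_profile")
}

#' @rdname signal_profile
#' @param signal A `signal_profile`.
#' @param t Time(s) at which to evaluate the signal.
#' @export
signal_at <- function(signal, t) {
  stopifnot(inherits(signal, "signal_profile"))
  signal$levels[findInterval(t, signal$breakpoints) + 1L]
}

#' Simulate a circuit model under a piecewise-constant signal
#'
#' Integrates the model ODEs with `deSolve::lsoda`, restarting the
#' integrator at every signal breakpoint so discontinuous inputs are
#' handled exactly. States remain non-negative (within solver tolerance)
#' for non-negative initial conditions.
#'
#' @param model A `circuit_model`.
#' @param signal A [signal_profile()] giving the external input over time.
#' @param t_end End time (> 0).
#' @param initial_state Numeric vector of initial species levels (>= 0);
#'   defaults to all zeros.
#' @param n_out Approximate number of output time points.
#' @param rtol,atol Solver tolerances.
#' @return A `circuit_trajectory`: a tibble with a `time` column and one
#'   column per species, carrying the model, signal and tolerances as
#'   attributes.
#' @export
simulate_circuit <- function(model, signal = signal_profile(), t_end,
                             initial_state = NULL, n_out = 2001,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "circuit_model"),
            inherits(signal, "signal_profile"), t_end > 0)
  ns <- length(model$species)
  if (is.null(initial_state)) initial_state <- rep(0, ns)
  stopifnot(length(initial_state) == ns)
  if (any(initial_state < 0))
    stop("initial_state must be non-negative", call. = FALSE)

  bps <- signal$breakpoints[signal$breakpoints < t_end]
  bounds <- c(0, bps, t_end)
  grid <- seq(0, t_end, length.out = n_out)

  state <- setNames(as.numeric(initial_state), model$species)
  pieces <- vector("list", length(bounds) - 1)
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    u <- signal_at(signal, t0)
    times <- unique(c(t0, grid[grid > t0 & grid < t1], t1))
    rhs <- function(t, y, parms) list(model$derivs(t, y, u, model$params))
    sol <- tryCatch(
      deSolve::lsoda(y = state, times = times, func = rhs, parms = NULL,
                     rtol = rtol, atol = atol),
      warning = function(w) {
        stop("solver difficulty in [", signif(t0, 4), ", ", signif(t1, 4),
             "]: ", conditionMessage(w), call. = FALSE)
      })
    sol <- as.data.frame(sol)
    state <- setNames(as.numeric(sol[nrow(sol), -1]), model$species)
    if (i > 1) sol <- sol[-1, , drop = FALSE]  # drop duplicated junction
    pieces[[i]] <- sol
  }
  out <- tibble::as_tibble(dplyr::bind_rows(pieces))
  names(out) <- c("time", model$species)
  structure(out, class = c("circuit_trajectory", class(out)),
            model = model, signal = signal, rtol = rtol, atol = atol)
}

plateau_window <- function(traj, species, t_lo, t_hi, frac = 0.1,
                           cv_limit = 0.01) {
  w0 <- t_hi - frac * (t_hi - t_lo)
  x <- traj[[species]][traj$time >= w0 & traj$time <= t_hi]
  m <- mean(x)
  # near-zero plateaus: judge variability against 1% of the species'
  # dynamic range rather than the vanishing mean
  span <- diff(range(traj[[species]]))
  scale <- max(abs(m), span * 0.01, 1e-12)
  cv <- stats::sd(x) / scale
  list(mean = m, cv = cv, ok = cv < cv_limit)
}

#' Measure a species' response delay after a signal transition
#'
#' The delay is the time from `transition_time` until the species first
#' crosses the midpoint between its pre- and post-transition steady
#' levels. Steady levels are estimated from plateau windows: the final 10%
#' of the signal interval before the transition and of the interval after
#' it, each required to have a coefficient of variation below 1% (an
#' error asks for a longer `t_end` otherwise).
#'
#' @param traj A `circuit_trajectory` spanning the transition.
#' @param species Species (column) name.
#' @param transition_time Time of the signal step.
#' @param post_end End of the post-transition interval; defaults to the
#'   next signal breakpoint after `transition_time`, or the trajectory
#'   end.
#' @return Delay (time units), with the pre/post levels as attributes.
#' @export
measure_response_delay <- function(traj, species, transition_time,
                                   post_end = NULL) {
  stopifnot(inherits(traj, "circuit_trajectory"),
            species %in% names(traj))
  sig <- attr(traj, "signal")
  bps <- c(0, sig$breakpoints, max(traj$time))
  pre_lo <- max(bps[bps < transition_time - 1e-9])
  if (is.null(post_end)) {
    after <- bps[bps > transition_time + 1e-9]
    post_end <- min(after)
  }
  pre <- plateau_window(traj, species, pre_lo, transition_time)
  post <- plateau_window(traj, species, transition_time, post_end)
  if (!pre$ok || !post$ok)
    stop("no steady plateau detected around the transition; ",
         "increase t_end or the interval lengths", call. = FALSE)
  mid <- (pre$mean + post$mean) / 2
  seg <- traj[traj$time >= transition_time & traj$time <= post_end, ]
  x <- seg[[species]]
  rising <- post$mean > pre$mean
  crossed <- if (rising) x >= mid else x <= mid
  i <- which(crossed)[1]
  if (is.na(i))
    stop("species never crossed the midpoint; increase t_end",
         call. = FALSE)
  t_cross <- if (i == 1) seg$time[1] else {
    # linear interpolation between the bracketing samples
    t0 <- seg$time[i - 1]; t1 <- seg$time[i]
    x0 <- x[i - 1]; x1 <- x[i]
    t0 + (mid - x0) / (x1 - x0) * (t1 - t0)
  }
  structure(t_cross - transition_time,
            pre_level = pre$mean, post_level = post$mean)
}

#' Transient-pulse rejection of a feedforward circuit
#'
#' Holds the signal at `baseline_level` long enough to reach steady state,
#' applies an opposite-level pulse of each requested duration, and
#' measures the MITF protein excursion relative to the circuit's full
#' dynamic range (the distance between the steady MITF levels under
#' sustained baseline and sustained pulse-level signal). An AND-gate
#' persistence detector rejects pulses shorter than the SOX10 arm's
#' threshold-crossing time (excursion below `epsilon`); an OR gate
#' responds even to short pulses.
#'
#' @param model An FFL `circuit_model`.
#' @param pulse_durations Numeric vector of pulse lengths (> 0 allowed;
#'   a zero duration trivially gives zero excursion).
#' @param baseline_level,pulse_level Signal levels outside/during the
#'   pulse.
#' @param epsilon Response threshold as a fraction of the dynamic range.
#' @param species Readout species.
#' @param settle Time allowed to reach the baseline steady state before
#'   the pulse; also the post-pulse observation window.
#' @return A list with `results` (tibble: `duration`, `excursion`,
#'   `responds`), `min_responding_duration` (smallest duration whose
#'   excursion exceeds `epsilon`; `Inf` if none), `epsilon` and
#'   `dynamic_range`.
#' @export
pulse_rejection <- function(model, pulse_durations, baseline_level = 1,
                            pulse_level = 0, epsilon = 0.05,
                            species = "MITF_protein", settle = 15) {
  stopifnot(inherits(model, "circuit_model"))
  if (!length(pulse_durations)) stop("empty pulse-duration grid",
                                     call. = FALSE)
  stopifnot(all(pulse_durations >= 0))

  ss_of <- function(level) {
    tr <- simulate_circuit(model, signal_profile(numeric(), level),
                           t_end = settle * 4, n_out = 401)
    as.numeric(tr[nrow(tr), model$species])
  }
  base_ss <- ss_of(baseline_level)
  alt_ss <- ss_of(pulse_level)
  i_sp <- match(species, model$species)
  dynamic_range <- abs(alt_ss[i_sp] - base_ss[i_sp])
  if (dynamic_range <= 0)
    stop("readout species has no dynamic range between signal levels",
         call. = FALSE)

  excursion <- vapply(pulse_durations, function(d) {
    if (d == 0) return(0)
    sig <- signal_profile(c(settle, settle + d),
                          c(baseline_level, pulse_level, baseline_level))
    tr <- simulate_circuit(model, sig, t_end = settle + d + settle,
                           initial_state = pmax(base_ss, 0))
    seg <- tr[[species]][tr$time >= settle]
    max(abs(seg - base_ss[i_sp])) / dynamic_range
  }, 0)

  results <- tibble::tibble(duration = pulse_durations,
                            excursion = excursion,
                            responds = excursion > epsilon)
  min_resp <- if (any(results$responds))
    min(results$duration[results$responds]) else Inf
  list(results = results, min_responding_duration = min_resp,
       epsilon = epsilon, dynamic_range = dynamic_range)
}

#' Leaky-transcript clearance with and without miRNA support
#'
#' Models the hypoxia scenario: before `hypoxia_time` the circuit sits at
#' steady state with MITF mRNA transcribed and no miR-155; at
#' `hypoxia_time` transcription shuts off (the HIF-mediated arm) and
#' miR-155 is induced, adding `lambda * [miR]` to the mRNA decay rate.
#' Two runs are compared -- with the miRNA degradation arm (`lambda`) and
#' without (`lambda = 0`, decay by intrinsic half-life only) -- and the
#' residual-transcript burden is summarized by the area under the mRNA
#' curve after shutoff and the times to decay to 50% and 10% of the
#' shutoff level.
#'
#' @param params FFL parameters ([ffl_params()]); `beta_m`, `delta_m`,
#'   `beta_r`, `delta_r` and `lambda` are used.
#' @param lambda miRNA-enhanced degradation rate for the "with" run
#'   (default `params$lambda`).
#' @param hypoxia_time Onset of hypoxia.
#' @param t_end End of simulation.
#' @param mirna_level If given, miR-155 is held at this constant level
#'   after onset instead of following its induction kinetics (gives exact
#'   exponential decay at rate `delta_r + lambda * mirna_level`).
#' @return A list with `trajectories` (long tibble: `run`, `time`,
#'   `species`, `level`) and `metrics` (tibble: `run`, `lambda`, `auc`,
#'   `t50`, `t10`).
#' @export
leaky_transcript_comparison <- function(params = ffl_params(),
                                        lambda = params$lambda,
                                        hypoxia_time = 5, t_end = 25,
                                        mirna_level = NULL) {
  stopifnot(lambda >= 0, t_end > hypoxia_time)
  run_one <- function(lam, label) {
    derivs <- function(t, state, u, p) {
      M <- if (is.null(mirna_level)) state[1] else mirna_level * u
      dM <- if (is.null(mirna_level)) p$beta_m * u - p$delta_m * state[1]
            else 0
      c(dM, p$beta_r * (1 - u) - (p$delta_r + lam * M) * state[2])
    }
    model <- circuit_model(c("MIR155", "MITF_mRNA"), derivs, params,
                           kind = "leak")
    r0 <- params$beta_r / params$delta_r
    tr <- simulate_circuit(model, signal_profile(hypoxia_time, c(0, 1)),
                           t_end = t_end, initial_state = c(0, r0),
                           n_out = 4001)
    seg <- tr[tr$time >= hypoxia_time, ]
    lvl <- seg$MITF_mRNA
    auc <- pracma::trapz(seg$time, lvl)
    tt <- function(frac) {
      i <- which(lvl <= frac * lvl[1])[1]
      if (is.na(i)) NA_real_ else seg$time[i] - hypoxia_time
    }
    list(traj = dplyr::mutate(tidyr::pivot_longer(
           tibble::as_tibble(tr), -"time", names_to = "species",
           values_to = "level"), run = label),
         metrics = tibble::tibble(run = label, lambda = lam, auc = auc,
                                  t50 = tt(0.5), t10 = tt(0.1)))
  }
  with_mir <- run_one(lambda, "with_mirna")
  without <- run_one(0, "without_mirna")
  list(trajectories = dplyr::bind_rows(with_mir$traj, without$traj),
       metrics = dplyr::bind_rows(with_mir$metrics, without$metrics))
}

#' mRNA clearance metrics across a miRNA-strength grid
#'
#' Convenience wrapper running [leaky_transcript_comparison()] over a grid
#' of `lambda` values; the area under the post-shutoff mRNA curve is
#' strictly decreasing in `lambda`.
#'
#' @inheritParams leaky_transcript_comparison
#' @param lambdas Numeric vector of miRNA-enhanced degradation rates.
#' @return Tibble with columns `lambda`, `auc`, `t50`, `t10`.
#' @export
leak_suppression_curve <- function(params = ffl_params(), lambdas,
                                   hypoxia_time = 5, t_end = 25) {
  purrr::map_dfr(lambdas, function(lam) {
    m <- leaky_transcript_comparison(params, lambda = lam,
                                     hypoxia_time = hypoxia_time,
                                     t_end = t_end)$metrics
    dplyr::filter(m, .data$run == "with_mirna")[
      c("lambda", "auc", "t50", "t10")]
  })
}
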