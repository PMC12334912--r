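#' Hill regulation terms
#'
#' Standard activating and repressing Hill functions used by all circuit
#' models: `hill_act(x, k, n) = x^n / (k^n + x^n)` and
#' `hill_rep(x, k, n) = k^n / (k^n + x^n)`.
#'
#' @param x Regulator level (>= 0).
#' @param k Half-effect constant (> 0).
#' @param n Hill coefficient (>= 1).
#' @return Numeric in `[0, 1]`.
#' @export
hill_act <- function(x, k, n) {
  if (is.infinite(k)) return(rep(0, length(x)))
  x^n / (k^n + x^n)
}

#' @rdname hill_act
#' @export
hill_rep <- function(x, k, n) {
  # k = Inf disables the repression arm entirely
  if (is.infinite(k)) return(rep(1, length(x)))
  k^n / (k^n + x^n)
}

#' Construct a circuit ODE model
#'
#' Low-level constructor used by [build_ffl_model()], [build_fbl_model()]
#' and [simple_gene_model()]. A model bundles species names, a derivative
#' function `derivs(t, state, u, params)` (with `u` the external input:
#' signal level or scanned activity), parameters, and optional helpers for
#' steady-state work.
#'
#' @param species Character vector of species names.
#' @param derivs Function `(t, state, u, params) -> named numeric vector`.
#' @param params Named list of positive rates and constants.
#' @param kind Short tag (`"ffl"`, `"fbl"`, `"gene"`).
#' @param state_upper Numeric vector of plausible upper bounds per species
#'   (used to draw multi-start points for root finding).
#' @param steady_state_starts Optional function `(u) -> matrix` of
#'   candidate fixed-point states (rows), used to seed the multi-start
#'   solver; typically derived from a one-dimensional steady-state
#'   reduction.
#' @param ... Extra fields stored on the model (e.g. `gate`,
#'   `logic_mode`).
#' @return An object of class `circuit_model`.
#' @export
circuit_model <- function(species, derivs, params, kind = "custom",
                          state_upper = NULL, steady_state_starts = NULL,
                          ...) {
  stopifnot(is.character(species), is.function(derivs), is.list(params))
  if (is.null(state_upper)) state_upper <- rep(1, length(species))
  structure(
    list(species = species, derivs = derivs, params = params, kind = kind,
         state_upper = state_upper,
         steady_state_starts = steady_state_starts, ...),
    class = "circuit_model")
}

#' @export
print.circuit_model <- function(x, ...) {
  cat(sprintf("<circuit_model> %s: species %s\n", x$kind,
              paste(x$species, collapse = ", ")))
  invisible(x)
}

check_params <- function(params, required) {
  missing <- setdiff(required, names(params))
  if (length(missing))
    stop("missing circuit parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- required[vapply(params[required], function(v)
    !is.numeric(v) || length(v) != 1 || is.na(v), TRUE)]
  if (length(bad))
    stop("non-numeric circuit parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(params)
}

#' Default parameters for the miR-155--SOX10--MITF feedforward circuit
#'
#' All rates are order one in arbitrary concentration/time units. The
#' signal drives miR-155 production; miR-155 represses SOX10; SOX10
#' activates MITF transcription; miR-155 additionally acts on MITF mRNA
#' (enhanced degradation, rate `lambda` per miRNA unit) and on MITF
#' translation (Hill repression). The miRNA arm is made fast
#' (`delta_m = 3`) relative to SOX10 (`delta_s = 0.8`) so that the
#' SOX10-mediated arm is the slow one -- the asymmetry behind
#' sign-sensitive delay and persistence detection.
#'
#' `theta_s` and `theta_m` are the activation/repression thresholds used in
#' `"threshold"` logic mode (absolute levels: SOX10 must exceed `theta_s`
#' and miR-155 stay below `theta_m` for the AND gate to transcribe MITF).
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of parameters.
#' @export
ffl_params <- function(...) {
  p <- list(
    beta_m = 3, delta_m = 3,        # signal -> miR-155
    beta_s = 1, delta_s = 0.8,      # miR-155 -| SOX10
    k_ms = 0.3, n_ms = 2,
    beta_r = 1, delta_r = 1,        # SOX10 -> MITF mRNA
    k_sr = 0.8, n_sr = 2,
    k_mr = 0.4, n_mr = 2,           # miR-155 -| MITF mRNA (direct arm)
    lambda = 1,                     # miRNA-enhanced mRNA degradation
    beta_p = 2, delta_p = 2,        # MITF mRNA -> protein
    k_mp = 0.4, n_mp = 2,           # miR-155 -| MITF translation
    theta_s = 0.8, theta_m = 0.5)   # gate thresholds (threshold mode)
  utils::modifyList(p, list(...))
}

#' Build the miR-155--SOX10--MITF coherent feedforward loop model
#'
#' Species: `MIR155` (signal-driven), `SOX10` (repressed by miR-155),
#' `MITF_mRNA` and `MITF_protein`. MITF transcription combines the
#' SOX10-activation arm and the direct miR-155-repression arm through a
#' gate:
#' \describe{
#'   \item{threshold mode}{literal truth tables -- AND: production at
#'     `beta_r` iff `SOX10 > theta_s` and `MIR155 < theta_m`; OR: iff
#'     `SOX10 > theta_s` or `MIR155 < theta_m`. The miRNA's direct arm is
#'     carried by the gate, so the continuous repression arms are off.}
#'   \item{continuous mode}{AND: product of the normalized Hill terms;
#'     OR: probabilistic sum. `mirna_action` then selects whether miR-155
#'     represses translation (Hill factor on protein production), enhances
#'     mRNA degradation (`delta_r + lambda * MIR155`), or both.}
#' }
#'
#' @param params Parameter list from [ffl_params()].
#' @param gate `"AND"` or `"OR"`.
#' @param logic_mode `"threshold"` (truth-table semantics, the surface for
#'   phase-pattern analyses) or `"continuous"` (smooth Hill semantics).
#' @param mirna_action `"both"`, `"translational_repression"` or
#'   `"enhanced_degradation"` (continuous mode only).
#' @return A `circuit_model`.
#' @export
build_ffl_model <- function(params = ffl_params(), gate = c("AND", "OR"),
                            logic_mode = c("threshold", "continuous"),
                            mirna_action = c("both",
                                             "translational_repression",
                                             "enhanced_degradation")) {
  gate <- match.arg(gate)
  logic_mode <- match.arg(logic_mode)
  mirna_action <- match.arg(mirna_action)
  check_params(params, names(ffl_params()))

  use_deg <- logic_mode == "continuous" &&
    mirna_action %in% c("both", "enhanced_degradation")
  use_trl <- logic_mode == "continuous" &&
    mirna_action %in% c("both", "translational_repression")

  derivs <- function(t, state, u, p) {
    M <- state[1]; S <- state[2]; R <- state[3]; P <- state[4]
    prod_r <- if (logic_mode == "threshold") {
      on <- if (gate == "AND") (S > p$theta_s) && (M < p$theta_m)
            else               (S > p$theta_s) || (M < p$theta_m)
      p$beta_r * as.numeric(on)
    } else {
      act <- hill_act(S, p$k_sr, p$n_sr)
      rep <- hill_rep(M, p$k_mr, p$n_mr)
      reg <- if (gate == "AND") act * rep else act + rep - act * rep
      p$beta_r * reg
    }
    deg_r <- p$delta_r + if (use_deg) p$lambda * M else 0
    trl <- if (use_trl) hill_rep(M, p$k_mp, p$n_mp) else 1
    c(p$beta_m * u - p$delta_m * M,
      p$beta_s * hill_rep(M, p$k_ms, p$n_ms) - p$delta_s * S,
      prod_r - deg_r * R,
      p$beta_p * R * trl - p$delta_p * P)
  }

  circuit_model(
    species = c("MIR155", "SOX10", "MITF_mRNA", "MITF_protein"),
    derivs = derivs, params = params, kind = "ffl",
    state_upper = with(params, c(beta_m / delta_m, beta_s / delta_s,
                                 beta_r / delta_r,
                                 beta_p * beta_r / (delta_p * delta_r))),
    gate = gate, logic_mode = logic_mode, mirna_action = mirna_action)
}

#' Default parameters for the miR-204--SOX10--ATF2 positive feedback circuit
#'
#' SOX10 activates miR-204 transcription; miR-204 represses ATF2 activity
#' post-transcriptionally; ATF2 represses SOX10 -- a cycle of sign product
#' `(+)(-)(-) = +1`, i.e. a positive (toggle-switch) loop. MITF is a
#' SOX10-driven reporter outside the loop. Both repressive arms default to
#' Hill coefficient 2: cooperativity is required for bistability. With
#' these defaults the bistable window sits at external ATF2 activity
#' roughly 2.6--5.4. `atf2_basal` adds constant ATF2 activity on top of
#' the scanned input; raising it slides the bistable window left, pushing
#' the left fold below zero activity (the irreversible-switch regime).
#' Setting `k_ma = Inf` removes miR-204's hold on ATF2 and opens the loop.
#'
#' @param ... Named overrides.
#' @return Named list of parameters.
#' @export
fbl_params <- function(...) {
  p <- list(
    beta_s = 2, delta_s = 1,      # ATF2 -| SOX10
    k_as = 1, n_as = 2,
    beta_mir = 2, delta_mir = 1,  # SOX10 -> miR-204
    k_sm = 1, n_sm = 2,
    k_ma = 0.5, n_ma = 2,         # miR-204 -| ATF2 activity
    beta_p = 1, delta_p = 1,      # SOX10 -> MITF reporter
    k_sp = 1, n_sp = 2,
    atf2_basal = 0,
    delta_a = 2)                  # ATF2 relaxation (dynamic variant only)
  utils::modifyList(p, list(...))
}

#' Build the miR-204--SOX10--ATF2 positive feedback loop model
#'
#' By default ATF2 is a *scanned input*: the external input `u` is ATF2
#' activity, modulated post-transcriptionally by miR-204
#' (`A_eff = max(u + atf2_basal, 0) * hill_rep(MIR204, k_ma, n_ma)`), and
#' the dynamic species are `SOX10`, `MIR204` and the `MITF` reporter.
#' With `atf2_dynamic = TRUE`, ATF2 is a fourth species relaxing toward
#' the miR-modulated input at rate `delta_a`, for time-course replays.
#' A warning is issued when neither repressive arm has Hill coefficient
#' >= 2, since the loop then cannot be bistable.
#'
#' @param params Parameter list from [fbl_params()].
#' @param atf2_dynamic Treat ATF2 as a dynamic species instead of a
#'   scanned input.
#' @return A `circuit_model` with a `cycle_signs` field recording the
#'   loop's edge signs.
#' @export
build_fbl_model <- function(params = fbl_params(), atf2_dynamic = FALSE) {
  check_params(params, setdiff(names(fbl_params()), "k_ma"))
  if (!"k_ma" %in% names(params))
    stop("missing circuit parameter(s): k_ma", call. = FALSE)
  if (params$n_as < 2 && params$n_ma < 2)
    warning("no repressive arm has hill_n >= 2; the loop cannot be bistable",
            call. = FALSE)

  a_eff <- function(u, m, p)
    max(u + p$atf2_basal, 0) * hill_rep(m, p$k_ma, p$n_ma)

  if (!atf2_dynamic) {
    derivs <- function(t, state, u, p) {
      S <- state[1]; m <- state[2]; P <- state[3]
      A <- a_eff(u, m, p)
      c(p$beta_s * hill_rep(A, p$k_as, p$n_as) - p$delta_s * S,
        p$beta_mir * hill_act(S, p$k_sm, p$n_sm) - p$delta_mir * m,
        p$beta_p * hill_act(S, p$k_sp, p$n_sp) - p$delta_p * P)
    }
    species <- c("SOX10", "MIR204", "MITF")
    upper <- with(params, c(beta_s / delta_s, beta_mir / delta_mir,
                            beta_p / delta_p))
  } else {
    derivs <- function(t, state, u, p) {
      S <- state[1]; m <- state[2]; P <- state[3]; A <- state[4]
      c(p$beta_s * hill_rep(A, p$k_as, p$n_as) - p$delta_s * S,
        p$beta_mir * hill_act(S, p$k_sm, p$n_sm) - p$delta_mir * m,
        p$beta_p * hill_act(S, p$k_sp, p$n_sp) - p$delta_p * P,
        p$delta_a * (a_eff(u, m, p) - A))
    }
    species <- c("SOX10", "MIR204", "MITF", "ATF2")
    upper <- with(params, c(beta_s / delta_s, beta_mir / delta_mir,
                            beta_p / delta_p, 10))
  }

  # 1-D steady-state reduction in SOX10, used to seed the root finder
  starts_fun <- NULL
  if (!atf2_dynamic) {
    starts_fun <- function(u) {
      p <- params
      g <- function(S) {
        m <- p$beta_mir * hill_act(S, p$k_sm, p$n_sm) / p$delta_mir
        A <- a_eff(u, m, p)
        p$beta_s * hill_rep(A, p$k_as, p$n_as) / p$delta_s - S
      }
      Sg <- seq(0, params$beta_s / params$delta_s * 1.05,
                length.out = 400)
      v <- vapply(Sg, g, 0)
      roots <- c()
      for (i in seq_len(length(Sg) - 1)) {
        if (is.finite(v[i]) && is.finite(v[i + 1]) && v[i] * v[i + 1] < 0)
          roots <- c(roots,
                     stats::uniroot(g, c(Sg[i], Sg[i + 1]),
                                    tol = 1e-12)$root)
      }
      if (!length(roots)) return(NULL)
      t(vapply(roots, function(S) {
        m <- p$beta_mir * hill_act(S, p$k_sm, p$n_sm) / p$delta_mir
        P <- p$beta_p * hill_act(S, p$k_sp, p$n_sp) / p$delta_p
        c(S, m, P)
      }, numeric(3)))
    }
  }

  circuit_model(
    species = species, derivs = derivs, params = params, kind = "fbl",
    state_upper = upper, steady_state_starts = starts_fun,
    atf2_dynamic = atf2_dynamic,
    cycle_signs = c(sox10_to_mir204 = 1L, mir204_to_atf2 = -1L,
                    atf2_to_sox10 = -1L))
}

#' Sign product of a model's regulatory cycle
#'
#' @param model A `circuit_model` carrying a `cycle_signs` field.
#' @return `+1` or `-1`.
#' @export
cycle_sign_product <- function(model) {
  stopifnot(inherits(model, "circuit_model"), !is.null(model$cycle_signs))
  prod(model$cycle_signs)
}

#' Single constitutive gene model
#'
#' One species produced at `beta * u(t)` and degraded at `delta`, the
#' textbook first-order gene whose step response is
#' `beta/delta * (1 - exp(-delta * t))` -- used as a closed-form solver
#' check and as a building block in examples.
#'
#' @param beta Production rate.
#' @param delta Degradation rate.
#' @param name Species name.
#' @return A `circuit_model`.
#' @export
simple_gene_model <- function(beta = 1, delta = 1, name = "X") {
  check_params(list(beta = beta, delta = delta), c("beta", "delta"))
  circuit_model(
    species = name,
    derivs = function(t, state, u, p) p$beta * u - p$delta * state[1],
    params = list(beta = beta, delta = delta),
    kind = "gene", state_upper = beta / delta * 1.5)
}
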