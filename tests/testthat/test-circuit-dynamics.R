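test_that("single-gene step response matches the closed form", {
  m <- simple_gene_model(beta = 2, delta = 0.7)
  tr <- simulate_circuit(m, signal_profile(numeric(), 1), t_end = 10)
  exact <- 2 / 0.7 * (1 - exp(-0.7 * tr$time))
  expect_lt(max(abs(tr$X - exact)), 1e-6 * 2 / 0.7)

  # zero production from a zero state stays identically zero
  tr0 <- simulate_circuit(m, signal_profile(numeric(), 0), t_end = 5)
  expect_true(all(tr0$X == 0))
})

test_that("piecewise signals restart the integrator at breakpoints", {
  m <- simple_gene_model(beta = 1, delta = 1)
  sig <- signal_profile(c(2, 4), c(1, 0, 1))
  expect_equal(signal_at(sig, c(0, 2, 3, 4, 9)), c(1, 0, 0, 1, 1))
  tr <- simulate_circuit(m, sig, t_end = 6)
  x2 <- tr$X[which.min(abs(tr$time - 2))]
  exact2 <- 1 - exp(-2)
  expect_lt(abs(x2 - exact2), 1e-6)
  # decay phase follows x(2) * exp(-(t-2))
  x4 <- tr$X[which.min(abs(tr$time - 4))]
  expect_lt(abs(x4 - exact2 * exp(-2)), 1e-6)
})

test_that("halving tolerances leaves steady levels unchanged to 1e-6", {
  m <- build_ffl_model(logic_mode = "continuous")
  run <- function(rtol, atol)
    simulate_circuit(m, signal_profile(numeric(), 1), t_end = 30,
                     rtol = rtol, atol = atol)
  a <- run(1e-8, 1e-10)
  b <- run(5e-9, 5e-11)
  fin_a <- as.numeric(a[nrow(a), -1])
  fin_b <- as.numeric(b[nrow(b), -1])
  expect_lt(max(abs(fin_a - fin_b) / pmax(abs(fin_b), 1e-6)), 1e-6)
})

test_that("states stay non-negative across randomized parameter draws", {
  withr::local_seed(99)
  for (i in 1:5) {
    p <- ffl_params(delta_m = runif(1, 1, 4), delta_s = runif(1, 0.5, 1.5),
                    delta_r = runif(1, 0.5, 2), delta_p = runif(1, 1, 3),
                    lambda = runif(1, 0, 2))
    m <- build_ffl_model(p, gate = sample(c("AND", "OR"), 1),
                         logic_mode = "continuous")
    sig <- signal_profile(c(5, 10), c(1, 0, 1))
    tr <- simulate_circuit(m, sig, t_end = 15,
                           initial_state = runif(4, 0, 1))
    expect_gt(min(as.matrix(tr[, -1])), -1e-9)
  }
})

test_that("gate truth tables hold at the rate-law level", {
  p <- ffl_params()
  and <- build_ffl_model(p, "AND", "threshold")
  or <- build_ffl_model(p, "OR", "threshold")
  rate_r <- function(model, S, M)
    model$derivs(0, c(M, S, 0, 0), 0, model$params)[3]
  # below the SOX10 threshold the AND gate never transcribes
  expect_equal(rate_r(and, p$theta_s * 0.5, 0), 0)
  expect_equal(rate_r(and, p$theta_s * 0.5, p$theta_m * 2), 0)
  # both conditions met: full production
  expect_equal(rate_r(and, p$theta_s * 2, p$theta_m * 0.1), p$beta_r)
  # OR transcribes when either condition holds
  expect_equal(rate_r(or, p$theta_s * 2, p$theta_m * 2), p$beta_r)
  expect_equal(rate_r(or, p$theta_s * 0.5, p$theta_m * 0.1), p$beta_r)
  expect_equal(rate_r(or, p$theta_s * 0.5, p$theta_m * 2), 0)
})

test_that("removing the miRNA reduces the loop to a two-gene cascade", {
  p <- ffl_params(lambda = 0)
  m <- build_ffl_model(p, "AND", "continuous")
  tr <- simulate_circuit(m, signal_profile(numeric(), 0), t_end = 60)
  fin <- as.numeric(tr[nrow(tr), -1])
  # no signal: no miRNA; SOX10 at beta_s/delta_s; MITF follows the cascade
  S <- p$beta_s / p$delta_s
  R <- p$beta_r * hill_act(S, p$k_sr, p$n_sr) / p$delta_r
  P <- p$beta_p * R / p$delta_p
  expect_equal(fin, c(0, S, R, P), tolerance = 1e-5)
})

test_that("response delay recovers the first-order half-life", {
  m <- simple_gene_model(beta = 1, delta = 0.9)
  sig <- signal_profile(10, c(0, 1))
  tr <- simulate_circuit(m, sig, t_end = 40, n_out = 8001)
  d <- measure_response_delay(tr, "X", 10)
  expect_lt(abs(as.numeric(d) - log(2) / 0.9), 0.02 * log(2) / 0.9)
  expect_error(measure_response_delay(
    simulate_circuit(m, sig, t_end = 10.5, n_out = 2001), "X", 10),
    "plateau|midpoint")
})

test_that("the AND gate delays MITF on signal removal, the OR gate on onset",
{
  d_and <- ffl_delay_metrics(build_ffl_model(gate = "AND"))
  expect_gt(d_and$off_delay_difference, 0)
  expect_gt(d_and$off_delay_difference, d_and$on_delay_difference)
  d_or <- ffl_delay_metrics(build_ffl_model(gate = "OR"))
  expect_gt(d_or$on_delay_difference, 0)
  expect_gt(d_or$on_delay_difference, d_or$off_delay_difference)
  # the OFF-step asymmetry is specific to the AND gate
  expect_lt(d_or$off_delay_difference, d_and$off_delay_difference)
})

test_that("pulse rejection separates AND and OR persistence behaviour", {
  and <- build_ffl_model(gate = "AND")
  or <- build_ffl_model(gate = "OR")
  pr_and <- pulse_rejection(and, c(0, 0.6, 2, 4))
  pr_or <- pulse_rejection(or, c(0, 0.6, 2, 4))
  expect_equal(pr_and$results$excursion[1], 0)  # zero pulse, zero response
  expect_false(pr_and$results$responds[2])      # short pulse rejected
  expect_true(pr_or$results$responds[2])        # OR responds to the same
  expect_true(all(diff(pr_and$results$excursion) >= -1e-9))  # monotone
  expect_lt(pr_or$min_responding_duration, pr_and$min_responding_duration)
  expect_error(pulse_rejection(and, numeric()), "empty")
})

test_that("leaky-transcript decay matches the enhanced-degradation rate", {
  p <- ffl_params(delta_r = 0.8)
  # constant miRNA level: decay is exactly exponential at delta + lambda*m
  cmp <- leaky_transcript_comparison(p, lambda = 1.5, mirna_level = 0.9,
                                     hypoxia_time = 4, t_end = 30)
  m <- cmp$metrics
  t50_with <- m$t50[m$run == "with_mirna"]
  t50_without <- m$t50[m$run == "without_mirna"]
  expect_lt(abs(t50_with - log(2) / (0.8 + 1.5 * 0.9)),
            0.02 * log(2) / (0.8 + 1.5 * 0.9))
  expect_lt(abs(t50_without - log(2) / 0.8), 0.02 * log(2) / 0.8)
  expect_lt(m$auc[m$run == "with_mirna"], m$auc[m$run == "without_mirna"])
})

test_that("transcript burden decreases monotonically with miRNA strength", {
  curve <- leak_suppression_curve(lambdas = c(0.3, 0.8, 1.5), t_end = 20)
  expect_true(all(diff(curve$auc) < 0))
  expect_true(all(diff(curve$t10) < 0))
})

test_that("steady-state finding is exact for a decoupled gene", {
  m <- simple_gene_model(beta = 2, delta = 1)
  ss <- find_steady_states(m, input_value = 1, seed = 1)
  expect_equal(nrow(ss), 1)
  expect_equal(ss$X, 2, tolerance = 1e-8)
  expect_true(ss$stable)
})

test_that("the feedback loop is monostable without cooperativity", {
  suppressWarnings(m1 <- build_fbl_model(fbl_params(n_as = 1, n_ma = 1)))
  for (a in seq(0, 6, length.out = 7)) {
    ss <- find_steady_states(m1, a, seed = 2)
    expect_equal(nrow(ss), 1)
  }
})

test_that("the cooperative feedback loop is bistable in its window", {
  m <- build_fbl_model()
  ss <- find_steady_states(m, 4, seed = 3)
  expect_equal(nrow(ss), 3)
  expect_equal(ss$stable, c(TRUE, FALSE, TRUE))  # sorted by SOX10 level
  # count agrees with the independent dense-grid oracle
  expect_equal(nrow(ss), oracle_fbl_root_count(m$params, 4))
  expect_equal(nrow(find_steady_states(m, 1, seed = 3)),
               oracle_fbl_root_count(m$params, 1))
  # the reporter rises with SOX10 across fixed points
  expect_true(all(diff(ss$MITF) > 0))
})

test_that("the constructed loop is positive and opens when an arm is cut", {
  m <- build_fbl_model()
  expect_equal(cycle_sign_product(m), 1)
  open <- build_fbl_model(fbl_params(k_ma = Inf))
  for (a in seq(0, 6, length.out = 5))
    expect_equal(nrow(find_steady_states(open, a, seed = 4)), 1)
  expect_warning(build_fbl_model(fbl_params(n_as = 1, n_ma = 1)),
                 "bistable")
  expect_error(build_ffl_model(params = list(beta_m = 1)), "missing")
})

test_that("bifurcation scans find folds matching hysteresis thresholds", {
  m <- build_fbl_model()
  grid <- seq(0, 6, by = 0.15)
  bd <- scan_bifurcation(m, grid, parameter = "atf2")
  expect_equal(length(bd$folds), 2)
  expect_equal(bd$reversibility, "reversible")
  # counts per grid value match the independent 1-D oracle
  for (i in seq(1, nrow(bd$counts), by = 8)) {
    expect_equal(bd$counts$n_fixed[i],
                 oracle_fbl_root_count(m$params, bd$counts$param[i]))
  }
  hs <- hysteresis_sweep(m, seq(0.5, 6.5, by = 0.25), dwell = 40)
  expect_gt(hs$loop_width, 0)
  expect_lt(abs(hs$up_threshold - max(bd$folds)), 2 * 0.25)
  expect_lt(abs(hs$down_threshold - min(bd$folds)), 2 * 0.25)
})

test_that("monostable scans report no folds and no hysteresis", {
  suppressWarnings(m1 <- build_fbl_model(fbl_params(n_as = 1, n_ma = 1)))
  bd <- scan_bifurcation(m1, seq(0, 6, by = 0.3))
  expect_equal(length(bd$folds), 0)
  expect_equal(bd$reversibility, "reversible")
  hs <- hysteresis_sweep(m1, seq(0.5, 6.5, by = 0.5), dwell = 30)
  expect_lt(abs(hs$loop_width), 2 * 0.5 + 1e-9)
})

test_that("basal ATF2 activity makes the switch irreversible", {
  m <- build_fbl_model(fbl_params(atf2_basal = 3))
  bd <- scan_bifurcation(m, seq(0, 6, by = 0.15))
  expect_equal(bd$reversibility, "irreversible")
})

test_that("phase reports classify plateau MITF levels", {
  m <- build_fbl_model()
  sig <- signal_profile(c(25, 50, 75), c(3, 6, 3, 1))
  ss <- find_steady_states(m, 3, seed = 5)
  init <- as.numeric(ss[which.max(ss$SOX10), m$species])
  tr <- simulate_circuit(m, sig, t_end = 100, initial_state = init)
  rep <- phase_report(tr, melanoma_state_map(c(0, 1)))
  expect_equal(rep$phenotype,
               c("melanocytic", "mesenchymal", "mesenchymal",
                 "melanocytic"))
  # a trajectory pinned at zero MITF sits in the lowest zone throughout
  zero <- simulate_circuit(simple_gene_model(name = "MITF"),
                           signal_profile(numeric(), 0), t_end = 10)
  rep0 <- phase_report(zero, melanoma_state_map(c(0, 1)))
  expect_true(all(rep0$phenotype == "mesenchymal"))
})
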