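test_that("clamp at a channel's reversal potential passes no current", {
  p <- default_parameters()
  # K+ channels only, clamped at E_K
  E_K <- nernst(1, p$initial$K_i, p$external$K_o)
  proto <- clamp_protocol(holding = E_K, steps = E_K, hold_ms = 100,
                          step_ms = 500, channels = c("Kv", "BK"))
  res <- run_voltage_clamp(proto, p, record_stride = 50L)
  expect_lt(max(abs(res$traces[[1]]$I_total_mem)), 1e-6)
})

test_that("clamped Markov occupancies match the matrix-exponential oracle", {
  p <- default_parameters()
  specs <- channel_specs(p)
  st <- initial_state(p, V0 = -80)
  ca <- free_calcium(p$initial$Ca_total, p$buffers)
  proto <- clamp_protocol(holding = -80, steps = -20, hold_ms = 10,
                          step_ms = 500)
  res <- run_voltage_clamp(proto, p, record_stride = 10L)
  tr <- res$traces[[1]]
  last <- nrow(tr)
  dur <- tr$t[last] - proto$hold_ms
  for (id in c("CaL", "BK", "Na")) {
    Q <- build_generator(specs[[id]], -20, ca)
    # propagate the hold-equilibrated occupancy through the step window
    p_exact <- expm_propagate(Q, st[[paste0("p_", id)]], dur)
    po_exact <- open_probability(p_exact, specs[[id]])
    expect_equal(tr[[paste0("Po_", id)]][last], po_exact, tolerance = 2e-3,
                 info = id)
  }
})

test_that("whole-cell clamp behaviour matches the recorded phenomenology", {
  p <- default_parameters()
  # outward current does not inactivate: at the end of a 2000 ms step the
  # current is at least 90 % of its within-step maximum for steps >= -20 mV
  proto <- clamp_protocol(holding = -70, steps = c(-20, 0, 20),
                          hold_ms = 1000, step_ms = 2000)
  res <- run_voltage_clamp(proto, p, record_stride = 100L)
  for (i in seq_along(proto$steps)) {
    tr <- res$traces[[i]]
    iseg <- tr$I_total_mem[tr$t > proto$hold_ms]
    expect_gte(iseg[length(iseg)], 0.9 * max(iseg))
  }
  # whole-cell steady-state I-V is monotone increasing over -60..+20 mV
  proto2 <- clamp_protocol(holding = -80, steps = seq(-60, 20, by = 10),
                           hold_ms = 500, step_ms = 4000)
  res2 <- run_voltage_clamp(proto2, p, record_stride = 100L)
  expect_true(all(diff(res2$summary$I_end) > 0))
})

test_that("I-V normalization is exact arithmetic and scale invariant", {
  expect_equal(normalize_iv(c(-10, -50, -25)), c(-0.2, -1, -0.5))
  x <- c(3, -7, 2)
  expect_equal(normalize_iv(17.3 * x), normalize_iv(x))
  expect_equal(max(abs(normalize_iv(x))), 1)
  expect_error(normalize_iv(c(0, 0)), "all-zero")
})

test_that("calcium-free condition zeroes E_Ca and is idempotent", {
  p <- apply_ca_free(default_parameters())
  expect_equal(p$external$Ca_o, 1e-13)
  expect_equal(nernst(2, 1e-13, p$external$Ca_o), 0)
  expect_identical(apply_ca_free(p), p)
})

test_that("sensitivity sweep handles degenerate input and bad knobs", {
  p <- default_parameters()
  tab <- sensitivity_sweep(p, targets = c("G_Kv", "G_BK"), fraction = 0,
                           duration = 30000, burn_in = 10000)
  dcols <- grep("^d_", names(tab), value = TRUE)
  expect_true(all(abs(as.matrix(tab[, dcols])) < 1e-12))
  expect_error(sensitivity_sweep(p, targets = "G_Nope", fraction = 0.5,
                                 duration = 30000, burn_in = 10000),
               "unknown conductance")
  expect_error(jsmc:::vary_knob(p, "Qux", 1.3, "kinetics", "activation"),
               "unknown kinetics")
})

test_that("L-type I-V under EGTA has the fitted bell shape", {
  p <- default_parameters()
  proto <- clamp_protocol(holding = -80, steps = seq(-60, 30, by = 10),
                          hold_ms = 200, step_ms = 300, channels = "CaL",
                          egta = TRUE)
  res <- run_voltage_clamp(proto, p, record_stride = 10L)
  niv <- normalize_iv(res$summary$I_peak)
  # inward current that activates above threshold, peaks, then declines
  # toward the reversal potential
  expect_lt(min(niv), -0.99)
  pk <- which.min(niv)
  expect_gt(pk, 1)
  expect_lt(pk, length(niv))
  expect_true(all(diff(niv[1:pk]) <= 0))
  expect_true(all(diff(niv[pk:length(niv)]) >= 0))
})
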