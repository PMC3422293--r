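test_that("generators have zero column sums and nonnegative rates", {
  p <- default_parameters()
  specs <- channel_specs(p)
  set.seed(11)
  for (sp in specs) {
    for (i in 1:6) {
      V <- runif(1, -100, 60)
      ca <- 10^runif(1, -8, -2)
      Q <- build_generator(sp, V, ca)
      expect_lt(max(abs(colSums(Q))), 1e-12)
      off <- Q - diag(diag(Q))
      expect_true(all(off >= 0))
    }
  }
  expect_error(build_generator(specs$CaL, Inf, 1e-4), "finite")
  bad <- specs$Na
  bad$edges$a[1] <- -1
  expect_error(build_generator(bad, -60, 1e-4), "negative")
})

test_that("toy reversible chain matches its detailed-balance closed form", {
  fx <- generate_fixtures(7)
  sp <- fx$toy_chain$spec
  Q <- build_generator(sp, 0, 1e-4)
  expect_equal(stationary_distribution(Q), fx$toy_chain$stationary,
               tolerance = 1e-12)
  # long implicit integration reaches the same distribution
  pv <- c(1, 0, 0)
  for (i in seq_len(5000)) pv <- advance_markov(pv, Q, 1)
  expect_equal(pv, fx$toy_chain$stationary, tolerance = 1e-9)
})

test_that("backward-Euler stepping preserves occupancy invariants", {
  p <- default_parameters()
  sp <- bk_spec(p$markov$BK)
  Q <- build_generator(sp, -30, 5e-4)
  # zero generator: identity
  p0 <- rep(1 / 10, 10)
  expect_equal(advance_markov(p0, matrix(0, 10, 10), 0.1), p0)
  # stationary distribution is a fixed point of the implicit step
  ps <- stationary_distribution(Q)
  expect_equal(advance_markov(ps, Q, 0.1), ps, tolerance = 1e-10)
  # sums stay exactly 1 and entries nonnegative under stiff stepping
  pv <- c(1, rep(0, 9))
  for (i in seq_len(2000)) {
    pv <- advance_markov(pv, Q, 0.1)
    expect_equal(sum(pv), 1, tolerance = 1e-12)
    expect_true(all(pv >= 0))
  }
  expect_equal(pv, ps, tolerance = 1e-8)
})

test_that("stationary distributions match the eigen-solver oracle on a (V, Ca) grid", {
  p <- default_parameters()
  specs <- channel_specs(p)
  Vs <- seq(-80, 20, length.out = 5)
  cas <- 10^seq(-5, -3, length.out = 5)
  for (sp in specs) {
    for (V in Vs) for (ca in cas) {
      Q <- build_generator(sp, V, ca)
      expect_equal(stationary_distribution(Q), eigen_stationary(Q),
                   tolerance = 1e-8,
                   info = sprintf("%s V=%g ca=%g", sp$id, V, ca))
    }
  }
})

test_that("open probability sums open-state occupancy", {
  p <- default_parameters()
  sp <- nav_spec(p$markov$Na)
  pv <- rep(0, 6); pv[sp$open_states] <- 1
  expect_equal(open_probability(pv, sp), 1)
  pv <- rep(0, 6); pv[1] <- 1
  expect_equal(open_probability(pv, sp), 0)
})

test_that("BK open probability increases with calcium and shifts left", {
  p <- default_parameters()
  sp <- bk_spec(p$markov$BK)
  po_at <- function(V, ca) {
    open_probability(stationary_distribution(build_generator(sp, V, ca)), sp)
  }
  # stationary open probability nondecreasing in Ca at fixed V, 100-1000 nM
  for (V in c(-60, -20, 20, 60)) {
    po <- vapply(seq(1e-4, 1e-3, length.out = 7), po_at, numeric(1), V = V)
    expect_true(all(diff(po) >= 0), info = paste("V =", V))
  }
  # equilibrium activation curve is left-shifted at 1000 vs 100 nM:
  # at every voltage the high-Ca curve is at least as activated
  Vs <- seq(-60, 60, by = 20)
  lo <- vapply(Vs, po_at, numeric(1), ca = 1e-4)
  hi <- vapply(Vs, po_at, numeric(1), ca = 1e-3)
  expect_true(all(hi > lo))
})

test_that("EGTA mode freezes calcium dependence and is idempotent", {
  p <- default_parameters()
  sp <- cal_spec(p$markov$CaL)
  e1 <- egta_mode(sp)
  expect_true(all(e1$edges$cad == 0))
  po <- function(s, ca) {
    open_probability(stationary_distribution(build_generator(s, -10, ca)), s)
  }
  expect_equal(po(e1, 1e-4), po(e1, 1e-3), tolerance = 1e-14)
  expect_identical(egta_mode(e1), e1)
  expect_warning(egta_mode(nav_spec(p$markov$Na)), "no Ca2\\+-dependent")
})
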