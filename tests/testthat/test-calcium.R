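test_that("free calcium solves the buffering mass-conservation equation", {
  p <- default_parameters()
  expect_equal(free_calcium(0, p$buffers), 0)
  nobuf <- list(CaM = list(B_total = 1e-300, K_d = 1e-3),
                CRT = list(B_total = 1e-300, K_d = 5e-3))
  expect_equal(free_calcium(2e-3, nobuf), 2e-3, tolerance = 1e-12)

  # agreement with a brute-force bisection oracle on random draws
  set.seed(99)
  for (i in 1:50) {
    tot <- 10^runif(1, -5, -2)
    buf <- list(A = list(B_total = 10^runif(1, -3, -1), K_d = 10^runif(1, -4, -2)),
                B = list(B_total = 10^runif(1, -3, -1), K_d = 10^runif(1, -4, -2)))
    f <- function(x) x + sum(vapply(buf, function(b) b$B_total * x / (b$K_d + x),
                                    numeric(1))) - tot
    lo <- 0; hi <- tot
    for (k in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    expect_lt(abs(free_calcium(tot, buf) - (lo + hi) / 2), 1e-12)  # mM
  }

  # strict monotonicity in total calcium
  tots <- seq(1e-5, 5e-3, length.out = 200)
  frees <- free_calcium(tots, p$buffers)
  expect_true(all(diff(frees) > 0))
})

test_that("concentration derivatives follow the stoichiometric bookkeeping", {
  p <- default_parameters()
  st <- initial_state(p)
  zero <- structure(as.list(setNames(rep(0, 10),
    c("I_CaL", "I_CaT", "I_Kv", "I_BK", "I_Na", "I_NaK", "I_NCX",
      "I_NaLeak", "I_KLeak", "I_total"))), class = "jsmc_currents")
  expect_equal(unname(concentration_derivatives(st, zero, p)), c(0, 0, 0))

  denom <- p$physical$F * p$physical$V_c / 1e-15
  one <- function(which, val = 1) {
    cur <- zero; cur[[which]] <- val; cur
  }
  # each current contributes to exactly one pool with its stoichiometric
  # factor (Ca valence 2; pump 3 Na out / 2 K in; NCX 3 Na in / 1 Ca out)
  cases <- list(
    list("I_CaL", c(-1 / (2 * denom), 0, 0)),
    list("I_CaT", c(-1 / (2 * denom), 0, 0)),
    list("I_Na", c(0, -1 / denom, 0)),
    list("I_NaLeak", c(0, -1 / denom, 0)),
    list("I_Kv", c(0, 0, -1 / denom)),
    list("I_BK", c(0, 0, -1 / denom)),
    list("I_KLeak", c(0, 0, -1 / denom)),
    list("I_NaK", c(0, -3 / denom, 2 / denom)),
    list("I_NCX", c(1 / denom, -3 / denom, 0))
  )
  for (cs in cases) {
    expect_equal(unname(concentration_derivatives(st, one(cs[[1]]), p)),
                 cs[[2]], info = cs[[1]], tolerance = 1e-15)
  }

  # a pure inward Ca2+ current of 1 pA for 1 ms raises total Ca2+ by
  # 1e-15 C / (2 F V_c): hand unit conversion
  d <- concentration_derivatives(st, one("I_CaL", -1), p)
  expect_equal(unname(d["dCa_total"]),
               1e-15 / (2 * 96.4867 * p$physical$V_c), tolerance = 1e-6)

  # doubling the cell volume halves all derivative magnitudes
  p2 <- p; p2$physical$V_c <- 2 * p$physical$V_c
  d1 <- concentration_derivatives(st, one("I_Kv", 5), p)
  d2 <- concentration_derivatives(st, one("I_Kv", 5), p2)
  expect_equal(unname(d1["dK"]), 2 * unname(d2["dK"]))
})

test_that("stoichiometry table is internally consistent", {
  s <- stoichiometry()
  expect_equal(s$ca_valence, 2)
  expect_equal(s$nak_na, 3)
  expect_equal(s$nak_k, -2)
  expect_equal(s$ncx_na, 3)
  expect_equal(s$ncx_ca, -2)
  # net charge per NaK cycle: 3 Na out - 2 K in = +1 unit
  expect_equal(s$nak_na + s$nak_k, 1)
  # net charge per NCX cycle: 3 Na in - 1 Ca(2+) out = +1 unit inward
  expect_equal(s$ncx_na + s$ncx_ca, 1)
})
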