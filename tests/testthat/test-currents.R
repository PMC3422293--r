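test_that("Nernst potential matches its closed form", {
  expect_equal(nernst(1, 10, 10), 0)
  # doubling valence halves the magnitude
  expect_equal(nernst(2, 5.4, 140), nernst(1, 5.4, 140) / 2)
  # K+ at defaults against a direct recomputation
  RTF <- 8.314 * 310 / 96.4867
  expect_equal(nernst(1, 150, 5.4, T = 310), RTF * log(5.4 / 150),
               tolerance = 1e-12)
  expect_error(nernst(1, -1, 10), "positive")
  expect_error(nernst(0, 1, 10), "valence")
})

test_that("ohmic channel current is linear with the expected zeros", {
  expect_equal(channel_current(2, 0.5, -50, -50), 0)
  expect_equal(channel_current(2, 0, -10, -80), 0)
  expect_equal(channel_current(4, 0.3, -10, -80),
               2 * channel_current(2, 0.3, -10, -80))
})

test_that("leak current reverses at 0 mV and respects the 45-fold bound", {
  p <- default_parameters()
  expect_equal(unname(leak_current(0, p)), c(0, 0))
  lk <- leak_current(-60, p)
  expect_lt(sum(lk), 0)  # inward at rest
  expect_lte(p$conductances$G_NaLeak + p$conductances$G_KLeak,
             p$conductances$G_Kv / 45)
})

test_that("NaK pump current saturates and matches the reference transcription", {
  p <- default_parameters()
  # zero scale, positivity at rest
  p0 <- p; p0$pumps$P_NaK <- 1e-300
  expect_equal(nak_current(-60, 10, 5.4, p0), 0, tolerance = 1e-290)
  expect_gt(nak_current(-60, 10, 5.4, p), 0)
  # monotone nondecreasing in Na_i
  nai <- seq(1, 40, by = 1)
  vals <- vapply(nai, function(x) nak_current(-60, x, 5.4, p), numeric(1))
  expect_true(all(diff(vals) > 0))
  # duplicate-implementation oracle on random operating points
  ops <- generate_fixtures(3)$operating_points
  for (i in seq_len(nrow(ops))) {
    expect_equal(nak_current(ops$V[i], ops$Na_i[i], 5.4, p),
                 oracle_nak(ops$V[i], ops$Na_i[i], 5.4, p$pumps$P_NaK,
                            p$pumps$K_mK, p$pumps$K_mNa, 8.314 * 310 / 96.4867),
                 tolerance = 1e-10)
  }
})

test_that("NCX current has the ten Tusscher form and extrusion behaviour", {
  p <- default_parameters()
  p0 <- p; p0$pumps$k_NCX <- 1e-300
  expect_equal(ncx_current(-60, 10, 1e-4, p0), 0, tolerance = 1e-290)
  # raising Ca 10x moves the current toward Ca-extrusion (more negative)
  expect_lt(ncx_current(-60, 10, 1e-3, p), ncx_current(-60, 10, 1e-4, p))
  # equals an independent transcription on 20 random operating points
  ops <- generate_fixtures(5)$operating_points
  for (i in seq_len(nrow(ops))) {
    expect_equal(
      ncx_current(ops$V[i], ops$Na_i[i], ops$Ca_free[i], p),
      oracle_ncx(ops$V[i], ops$Na_i[i], ops$Ca_free[i], p$pumps$k_NCX,
                 p$pumps$gamma_NCX, p$pumps$K_mNai, p$pumps$K_mCa,
                 p$pumps$k_sat, p$pumps$alpha_NCX,
                 p$external$Na_o, p$external$Ca_o, 8.314 * 310 / 96.4867),
      tolerance = 1e-10)
  }
})

test_that("current breakdown sums to the total and vanishes with zero scales", {
  p <- default_parameters()
  st <- initial_state(p)
  set.seed(42)
  for (i in 1:5) {
    st$V_m <- runif(1, -80, 0)
    st$Na_i <- runif(1, 5, 15)
    cur <- total_ionic_current(st, p)
    comps <- unlist(cur[setdiff(names(cur), "I_total")])
    expect_equal(sum(comps), cur$I_total, tolerance = 1e-9)
  }
  pz <- p
  for (g in names(pz$conductances)) pz$conductances[[g]] <- 1e-300
  pz$pumps$P_NaK <- 1e-300
  pz$pumps$k_NCX <- 1e-300
  stz <- initial_state(pz)
  expect_equal(total_ionic_current(stz, pz)$I_total, 0, tolerance = 1e-280)
})
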