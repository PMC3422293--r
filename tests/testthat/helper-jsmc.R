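# Shared fixtures and independent oracles for the test suite.

# cache expensive simulations across test files (testthat keeps helpers in
# one session per run)
.jsmc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .jsmc_cache)) {
    assign(key, force(expr), envir = .jsmc_cache)
  }
  get(key, envir = .jsmc_cache)
}

# the default 180 s free run used by several morphology checks
default_run <- function() {
  cached("default_run", run_free(default_parameters(), duration = 180000))
}

default_metrics <- function() {
  cached("default_metrics", analyze_trace(default_run()))
}

# independent stationary-distribution oracle: eigen-decomposition of the
# generator (column convention), normalised null vector of the zero eigenvalue
eigen_stationary <- function(Q) {
  e <- eigen(Q)
  i <- which.min(abs(e$values))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# independent propagation oracle: matrix exponential of the clamped generator
expm_propagate <- function(Q, p0, t_ms) {
  as.numeric(Matrix::expm(Matrix::Matrix(Q * t_ms)) %*% p0)
}

# independent transcription of the ten Tusscher NaK/NCX expressions, written
# directly from their published functional forms (duplicate-implementation
# oracle for the currents module)
oracle_nak <- function(V, Na_i, K_o, P, K_mK, K_mNa, RTF) {
  P * (K_o / (K_o + K_mK)) * (Na_i / (Na_i + K_mNa)) /
    (1 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF))
}

oracle_ncx <- function(V, Na_i, Ca_i, k, gam, K_mNai, K_mCa, k_sat, alph,
                       Na_o, Ca_o, RTF) {
  vf <- V / RTF
  k * (exp(gam * vf) * Na_i^3 * Ca_o -
         exp((gam - 1) * vf) * Na_o^3 * Ca_i * alph) /
    ((K_mNai^3 + Na_o^3) * (K_mCa + Ca_o) *
       (1 + k_sat * exp((gam - 1) * vf)))
}
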