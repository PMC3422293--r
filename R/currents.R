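#' Nernst equilibrium potential
#'
#' @param z Ionic valence (nonzero integer).
#' @param c_in Intracellular concentration, mM (> 0).
#' @param c_out Extracellular concentration, mM (> 0).
#' @param T Temperature, K.
#' @param R Gas constant, mJ/(mmol K).
#' @param F Faraday constant, C/mmol.
#' @return Equilibrium potential, mV.
#' @export
nernst <- function(z, c_in, c_out, T = 310, R = 8.314, F = 96.4867) {
  if (any(c_in <= 0) || any(c_out <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (z == 0) stop("valence must be nonzero", call. = FALSE)
  (R * T / (z * F)) * log(c_out / c_in)
}

#' Ohmic channel current
#'
#' I = G * Po * (V - E); outward currents are positive.
#'
#' @param G Maximum conductance, nS (>= 0).
#' @param Po Open probability in \[0, 1\].
#' @param V Membrane potential, mV.
#' @param E Reversal potential, mV.
#' @return Current, pA.
#' @export
channel_current <- function(G, Po, V, E) G * Po * (V - E)

#' Non-selective leak current components
#'
#' Linear Na+ and K+ leak components, both reversing at 0 mV. Their summed
#' conductance is at least 45-fold smaller than G_Kv (validated on load).
#'
#' @param V Membrane potential, mV.
#' @param params A `jsmc_params` object.
#' @return Named vector `c(I_NaLeak, I_KLeak)`, pA.
#' @export
leak_current <- function(V, params) {
  c(I_NaLeak = params$conductances$G_NaLeak * V,
    I_KLeak  = params$conductances$G_KLeak * V)
}

#' NaK pump current (ten Tusscher formulation)
#'
#' Outward-positive, saturating in intracellular Na+ and extracellular K+;
#' the 3 Na+ : 2 K+ stoichiometry is applied in the concentration equations,
#' not here.
#'
#' @param V Membrane potential, mV.
#' @param Na_i Intracellular Na+, mM.
#' @param K_o Extracellular K+, mM.
#' @param params A `jsmc_params` object.
#' @return Pump current, pA.
#' @export
nak_current <- function(V, Na_i, K_o, params) {
  pm <- params$pumps
  vf <- V / rtf_mV(params)
  pm$P_NaK * (K_o / (K_o + pm$K_mK)) * (Na_i / (Na_i + pm$K_mNa)) /
    (1 + 0.1245 * exp(-0.1 * vf) + 0.0353 * exp(-vf))
}

#' Na+/Ca2+ exchanger current (ten Tusscher formulation)
#'
#' Positive (outward) in Ca2+-entry (reverse) mode, negative in the
#' physiological Ca2+-extrusion mode where 3 Na+ enter per Ca2+ extruded.
#'
#' @param V Membrane potential, mV.
#' @param Na_i Intracellular Na+, mM.
#' @param Ca_free Free intracellular Ca2+, mM.
#' @param params A `jsmc_params` object.
#' @return Exchanger current, pA.
#' @export
ncx_current <- function(V, Na_i, Ca_free, params) {
  pm <- params$pumps
  ex <- params$external
  vf <- V / rtf_mV(params)
  num <- exp(pm$gamma_NCX * vf) * Na_i^3 * ex$Ca_o -
    exp((pm$gamma_NCX - 1) * vf) * ex$Na_o^3 * Ca_free * pm$alpha_NCX
  den <- (pm$K_mNai^3 + ex$Na_o^3) * (pm$K_mCa + ex$Ca_o) *
    (1 + pm$k_sat * exp((pm$gamma_NCX - 1) * vf))
  pm$k_NCX * num / den
}

#' Full membrane current breakdown at one state snapshot
#'
#' Evaluates all eight membrane current terms from a single state: the five
#' channel currents (L-type and T-type Ca2+, Kv, BK, Nav1.5), the NaK pump,
#' the NCX exchanger and the two leak components. Reversal potentials are
#' recomputed from the tracked intracellular concentrations at every call.
#' Sign convention: outward positive.
#'
#' @param state A `jsmc_state` object (see [initial_state()]).
#' @param params A `jsmc_params` object.
#' @param specs Channel specs from [channel_specs()] (rebuilt if omitted).
#' @return Named list of class `jsmc_currents` with the component currents
#'   (pA) and their sum `I_total`.
#' @export
total_ionic_current <- function(state, params, specs = channel_specs(params)) {
  g <- params$conductances
  ex <- params$external
  ph <- params$physical
  Ca_free <- state_ca_free(state, params)
  E_Na <- nernst(1, state$Na_i, ex$Na_o, ph$T, ph$R, ph$F)
  E_K  <- nernst(1, state$K_i,  ex$K_o,  ph$T, ph$R, ph$F)
  E_Ca <- nernst(2, Ca_free, ex$Ca_o, ph$T, ph$R, ph$F)
  V <- state$V_m
  lk <- leak_current(V, params)
  out <- list(
    I_CaL = channel_current(g$G_CaL, open_probability(state$p_CaL, specs$CaL), V, E_Ca),
    I_CaT = channel_current(g$G_CaT, state$m_CaT * state$h_CaT, V, E_Ca),
    I_Kv  = channel_current(g$G_Kv,  state$x_Kv * state$y_Kv, V, E_K),
    I_BK  = channel_current(g$G_BK,  open_probability(state$p_BK, specs$BK), V, E_K),
    I_Na  = channel_current(g$G_Na,  open_probability(state$p_Na, specs$Na), V, E_Na),
    I_NaK = nak_current(V, state$Na_i, ex$K_o, params),
    I_NCX = ncx_current(V, state$Na_i, Ca_free, params),
    I_NaLeak = unname(lk["I_NaLeak"]),
    I_KLeak  = unname(lk["I_KLeak"])
  )
  out$I_total <- sum(unlist(out))
  class(out) <- "jsmc_currents"
  out
}
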