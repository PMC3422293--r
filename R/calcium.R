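#' Free intracellular Ca2+ from total Ca2+ and buffering equilibrium
#'
#' Calmodulin (CaM) and calreticulin (CRT) buffer cytosolic Ca2+. Buffering
#' is treated as an instantaneous equilibrium, so conservation of mass gives
#' Ca_total = Ca_free + sum_b B_tot_b * Ca_free/(K_d_b + Ca_free), whose
#' left side is strictly increasing in Ca_free; the unique root in
#' \[0, Ca_total\] is found with a safeguarded root-finder.
#'
#' @param Ca_total Total intracellular Ca2+, mM (>= 0); vectorised.
#' @param buffers Buffer list, e.g. `params$buffers` (per buffer: `B_total`
#'   and `K_d`, mM).
#' @return Free Ca2+, mM; strictly increasing in `Ca_total`.
#' @export
free_calcium <- function(Ca_total, buffers) {
  vapply(Ca_total, function(tot) {
    if (tot < 0) stop("Ca_total must be >= 0", call. = FALSE)
    if (tot == 0) return(0)
    fn <- function(x) {
      x + sum(vapply(buffers, function(b) b$B_total * x / (b$K_d + x),
                     numeric(1))) - tot
    }
    stats::uniroot(fn, c(0, tot), tol = 1e-18)$root
  }, numeric(1))
}

state_ca_free <- function(state, params) {
  if (isTRUE(params$flags$ca_free)) return(1e-13)
  free_calcium(state$Ca_total, params$buffers)
}

#' Intracellular concentration derivatives
#'
#' Balance equations for total Ca2+, Na+ and K+. Each membrane current is
#' assigned to exactly one species pool with its stoichiometric factor:
#' Ca2+ valence 2; NaK pump 3 Na+ out and 2 K+ in per unit charge; NCX
#' 3 Na+ per Ca2+ (so 3x its charge for Na+, -2x for Ca2+). Inward
#' (negative, outward-positive convention) cation current raises the
#' corresponding intracellular concentration. The pA * ms -> mmol charge
#' scale is 1e-15 C per pA ms.
#'
#' @param state A `jsmc_state` object.
#' @param currents A `jsmc_currents` breakdown from [total_ionic_current()].
#' @param params A `jsmc_params` object.
#' @return Named vector `c(dCa_total, dNa, dK)`, mM/ms.
#' @export
concentration_derivatives <- function(state, currents, params) {
  s <- stoichiometry()
  denom <- params$physical$F * params$physical$V_c / 1e-15  # pA ms / mM
  cur <- currents
  dCa <- -(cur$I_CaL + cur$I_CaT + s$ncx_ca * cur$I_NCX) / (s$ca_valence * denom)
  dNa <- -(cur$I_Na + cur$I_NaLeak + s$nak_na * cur$I_NaK +
             s$ncx_na * cur$I_NCX) / denom
  dK  <- -(cur$I_Kv + cur$I_BK + cur$I_KLeak + s$nak_k * cur$I_NaK) / denom
  c(dCa_total = dCa, dNa = dNa, dK = dK)
}

#' Stoichiometric factors of the concentration balance
#'
#' Centralised so that the current-to-pool assignments can be enumerated and
#' tested in one place.
#'
#' @return Named list of stoichiometric factors.
#' @export
stoichiometry <- function() {
  list(
    ca_valence = 2,   # charges per Ca2+ ion
    nak_na = 3,       # Na+ extruded per unit NaK pump charge
    nak_k  = -2,      # K+ imported per unit NaK pump charge (opposes charge)
    ncx_na = 3,       # Na+ imported per unit NCX charge
    ncx_ca = -2       # Ca2+ charge moved per unit NCX charge (1 Ca2+ out per
                      # 3 Na+ in; valence 2, direction opposite the net charge)
  )
}
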