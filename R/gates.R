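#' Hodgkin-Huxley gate kinetics
#'
#' The T-type Ca2+ channel (gates m, h) and the voltage-dependent K+ channel
#' (gates x, y) use classical Hodgkin-Huxley first-order kinetics
#' dg/dt = (g_inf(V) - g)/tau(V). Steady states are Boltzmann sigmoids and
#' time constants are Gaussian bells of voltage; both are stored as
#' coefficient tables in the parameter set (`params$gates`) rather than as
#' code, so a corrected fit is a configuration change.
#'
#' @param spec A single gate coefficient list, e.g. `params$gates$m_CaT`,
#'   with fields `type` ("act" or "inact"), `v_half`, `slope` (mV) and the
#'   `tau_*` coefficients (ms).
#' @param V Membrane potential, mV.
#' @return `gate_steady_state()`: the equilibrium open fraction in \[0, 1\].
#' @export
gate_steady_state <- function(spec, V) {
  s <- if (identical(spec$type, "inact")) 1 else -1
  1 / (1 + exp(s * (V - spec$v_half) / spec$slope))
}

#' @rdname gate_steady_state
#' @return `gate_tau()`: the relaxation time constant, ms (> 0).
#' @export
gate_tau <- function(spec, V) {
  spec$tau_min + spec$tau_amp * exp(-((V - spec$tau_v) / spec$tau_w)^2)
}

#' Advance a gate one forward-Euler step
#'
#' @param g Current gate value in \[0, 1\].
#' @param spec Gate coefficient list (see [gate_steady_state()]).
#' @param V Membrane potential, mV.
#' @param dt Time step, ms (> 0).
#' @return Updated gate value; remains in \[0, 1\] whenever `dt <= tau(V)`.
#' @export
advance_gate <- function(g, spec, V, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  g + dt * (gate_steady_state(spec, V) - g) / gate_tau(spec, V)
}
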