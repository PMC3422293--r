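#' ICC slow-wave stimulus parameters
#'
#' The interstitial cells of Cajal (ICC) are not modelled biophysically; the
#' SMC sees a prescribed, periodic ICC membrane potential coupled through a
#' constant gap-junction conductance. The waveform rises from the ICC
#' resting potential to rest + amplitude during a short upstroke, holds a
#' decaying plateau and returns smoothly to rest at the end of the period
#' T = t_up + t_plat. Three shape constants control the waveform: `s_up`
#' (upstroke rise steepness), `plateau_frac` (sustained fraction of the
#' amplitude early in the plateau) and `tau_plat`/`w_fall` (early plateau
#' decay and terminal repolarisation width).
#'
#' @param params A `jsmc_params` object supplying defaults.
#' @param ... Named overrides of individual stimulus fields.
#' @return A list of class `jsmc_stimulus`.
#' @export
icc_stimulus <- function(params = default_parameters(), ...) {
  sp <- params$stimulus
  over <- list(...)
  bad <- setdiff(names(over), names(sp))
  if (length(bad)) stop("unknown stimulus field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  sp[names(over)] <- over
  if (sp$t_up <= 0 || sp$t_plat <= 0) {
    stop("t_up and t_plat must be positive", call. = FALSE)
  }
  class(sp) <- "jsmc_stimulus"
  sp
}

#' ICC membrane potential at time t
#'
#' Periodic with period `t_up + t_plat`; equals the ICC resting potential
#' before `t_start`; the maximum over a period is the peak potential
#' rest + amplitude (reached at the end of the upstroke) and the minimum is
#' the resting potential.
#'
#' @param t Time, ms (vectorised).
#' @param sp A `jsmc_stimulus` object.
#' @return ICC potential, mV.
#' @export
icc_voltage <- function(t, sp) {
  period <- sp$t_up + sp$t_plat
  v <- rep(sp$V_ICCrest, length(t))
  on <- t >= sp$t_start
  tp <- (t[on] - sp$t_start) %% period
  up <- tp < sp$t_up
  amp <- sp$V_ICCamp
  # saturating-exponential upstroke, normalised to reach exactly rest + amp
  # at t_up
  rise <- (1 - exp(-sp$s_up * tp[up] / sp$t_up)) / (1 - exp(-sp$s_up))
  w <- numeric(length(tp))
  w[up] <- rise
  s <- tp[!up] - sp$t_up
  # plateau: early decay toward plateau_frac * amp, then a smooth terminal
  # fall that is within 1 mV of rest by the end of the period
  sust <- sp$plateau_frac + (1 - sp$plateau_frac) * exp(-s / sp$tau_plat)
  s_off <- min(sp$t_fall, sp$t_plat - 2 * sp$w_fall)
  w[!up] <- sust / (1 + exp((s - s_off) / sp$w_fall))
  v[on] <- sp$V_ICCrest + amp * w
  v
}

#' Gap-junction stimulus current
#'
#' I_stim = G_couple * (V_icc - V_m), defined positive-inward: a depolarised
#' ICC produces a positive stimulus that depolarises the SMC (the membrane
#' equation is dV/dt = -(I_ion - I_stim)/C_m).
#'
#' @param V_icc ICC potential, mV.
#' @param V_m SMC membrane potential, mV.
#' @param G_couple Coupling conductance, nS.
#' @return Stimulus current, pA.
#' @export
stimulus_current <- function(V_icc, V_m, G_couple) G_couple * (V_icc - V_m)

#' 2-APB stimulus variant
#'
#' 50 uM 2-APB slows ICC slow waves to 4.90 cycles per minute, lengthens the
#' time to peak by 19.7 % and reduces the amplitude by 32.9 %. The variant
#' sets the period to 60000/4.9 ms, scales the upstroke duration by 1.197
#' and the amplitude by (1 - 0.329); custom factors allow intermediate drug
#' effects.
#'
#' @param sp A `jsmc_stimulus` object.
#' @param freq_cpm Target frequency, cycles per minute.
#' @param t_up_factor Upstroke duration scale.
#' @param amp_factor Amplitude scale.
#' @return Modified `jsmc_stimulus`.
#' @export
variant_2apb <- function(sp, freq_cpm = 4.90, t_up_factor = 1.197,
                         amp_factor = 1 - 0.329) {
  period <- 60000 / freq_cpm
  sp$t_up <- sp$t_up * t_up_factor
  sp$t_plat <- period - sp$t_up
  sp$V_ICCamp <- sp$V_ICCamp * amp_factor
  sp
}

#' Hwang-matched stimulus variant
#'
#' Human intestinal slow waves recorded by Hwang et al ran at 7.5 cycles per
#' minute with a larger amplitude (31 mV) and a more negative resting
#' potential (-64 mV) than the 6-cpm recordings the default stimulus
#' matches. The variant sets the period to 60000/7.5 = 8000 ms and moves the
#' ICC rest/amplitude to the configured Hwang-side values; the waveform
#' shape constants are preserved.
#'
#' @param sp A `jsmc_stimulus` object.
#' @return Modified `jsmc_stimulus`.
#' @export
variant_hwang <- function(sp) {
  period <- 60000 / 7.5
  sp$t_plat <- period - sp$t_up
  sp$V_ICCrest <- sp$hwang_rest
  sp$V_ICCamp <- sp$hwang_amp
  sp
}
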