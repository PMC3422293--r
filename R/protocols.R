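#' Define a voltage-clamp protocol
#'
#' The default values follow the whole-cell characterisation of freshly
#' isolated human jejunal myocytes: steps from -80 to +20 mV in 5 mV
#' increments, 2000 ms long, from a conditioning holding potential.
#'
#' @param holding Holding potential, mV.
#' @param steps Step potentials, mV.
#' @param hold_ms Conditioning time at the holding potential before each
#'   step, ms.
#' @param step_ms Step duration, ms.
#' @param channels `"all"` for the whole cell, or a subset of
#'   `c("CaL", "CaT", "Kv", "BK", "Na")` to isolate channels (other
#'   conductances and both transporters are zeroed).
#' @param egta Replicate a 2 mM EGTA pipette: Ca2+-dependent Markov
#'   transitions are frozen at a vanishing Ca2+ level.
#' @param evolve_conc Let intracellular concentrations evolve during the
#'   clamp. Default `FALSE`, matching pipette-dialysed cells.
#' @return A list of class `jsmc_clamp_protocol`.
#' @export
clamp_protocol <- function(holding = -80, steps = seq(-80, 20, by = 5),
                           hold_ms = 2000, step_ms = 2000,
                           channels = "all", egta = FALSE,
                           evolve_conc = FALSE) {
  if (step_ms <= 0) stop("step duration must be positive", call. = FALSE)
  rng <- range(c(holding, steps))
  if (rng[1] < -120 || rng[2] > 60) {
    stop("clamp potentials must lie within [-120, 60] mV", call. = FALSE)
  }
  structure(list(holding = holding, steps = steps, hold_ms = hold_ms,
                 step_ms = step_ms, channels = channels, egta = egta,
                 evolve_conc = evolve_conc),
            class = "jsmc_clamp_protocol")
}

channel_subset_params <- function(params, channels) {
  if (identical(channels, "all")) return(params)
  known <- c("CaL", "CaT", "Kv", "BK", "Na")
  bad <- setdiff(channels, known)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (ch in setdiff(known, channels)) {
    params$conductances[[paste0("G_", ch)]] <- 1e-12
  }
  params$conductances$G_NaLeak <- 1e-12
  params$conductances$G_KLeak <- 1e-12
  params$pumps$P_NaK <- 1e-12
  params$pumps$k_NCX <- 1e-12
  params
}

#' Run a voltage-clamp experiment
#'
#' The membrane potential is forced to the protocol waveform (conditioning
#' hold, then one step per configured potential); gates and Markov
#' occupancies evolve freely while intracellular concentrations are frozen
#' by default. Returns per-step current traces plus peak and end-of-step
#' summaries of the clamped whole-cell (or channel-subset) current.
#'
#' @param protocol A `jsmc_clamp_protocol`.
#' @param params A `jsmc_params` object.
#' @param dt Time step, ms.
#' @param record_stride Recording stride, steps.
#' @return List of class `jsmc_clamp_result`: `summary` (data frame with
#'   `step_mV`, `I_peak`, `I_end`, pA) and `traces` (one `jsmc_trace` per
#'   step, clamped current in column `I_total_mem`).
#' @export
run_voltage_clamp <- function(protocol, params = default_parameters(),
                              dt = 0.1, record_stride = 1L) {
  params <- channel_subset_params(params, protocol$channels)
  specs <- channel_specs(params)
  if (protocol$egta) {
    specs$CaL <- egta_mode(specs$CaL)
    specs$BK <- egta_mode(specs$BK)
  }
  init <- initial_state(params, V0 = max(min(protocol$holding, 20), -100))
  traces <- list()
  summary <- data.frame(step_mV = protocol$steps, I_peak = NA_real_,
                        I_end = NA_real_)
  n_hold <- round(protocol$hold_ms / dt)
  n_step <- round(protocol$step_ms / dt)
  for (i in seq_along(protocol$steps)) {
    cl <- list(t = c(0, protocol$hold_ms),
               v = c(protocol$holding, protocol$steps[i]))
    res <- simulate_cpp(pack_par(params, NULL, specs),
                        state_to_vector(init), n_hold + n_step, dt,
                        as.integer(record_stride), cl,
                        !protocol$evolve_conc)
    tr <- make_trace(res, params, dt, record_stride, "voltage_clamp", 0)
    # total membrane current carried by channels and transporters
    tr$I_total_mem <- rowSums(tr[, c("I_CaL", "I_CaT", "I_Kv", "I_BK",
                                     "I_Na", "I_NaK", "I_NCX", "I_NaLeak",
                                     "I_KLeak")])
    during <- tr$t > protocol$hold_ms
    iseg <- tr$I_total_mem[during]
    base <- tr$I_total_mem[which(!during)[sum(!during)]]
    summary$I_peak[i] <- iseg[which.max(abs(iseg - base))]
    summary$I_end[i] <- iseg[length(iseg)]
    traces[[i]] <- tr
  }
  structure(list(summary = summary, traces = traces, protocol = protocol),
            class = "jsmc_clamp_result")
}

#' Normalize an I-V relation
#'
#' Divides each peak current by the maximum absolute value, so the largest
#' magnitude is exactly 1 and the sign pattern is preserved.
#'
#' @param peaks Per-step peak (or steady-state) currents, pA.
#' @return Normalized currents, dimensionless.
#' @export
normalize_iv <- function(peaks) {
  m <- max(abs(peaks))
  if (!is.finite(m) || m == 0) {
    stop("all-zero currents cannot be normalized", call. = FALSE)
  }
  peaks / m
}

#' Apply the near-calcium-free recording condition
#'
#' Sets intra- and extracellular Ca2+ to 0.0001 nM (1e-13 mM). All
#' Ca2+-dependent machinery sees that value and E_Ca becomes exactly 0 mV
#' (equal concentrations). Idempotent.
#'
#' @param params A `jsmc_params` object.
#' @return Modified parameters.
#' @export
apply_ca_free <- function(params) {
  params$external$Ca_o <- 1e-13
  params$initial$Ca_total <- 1e-13
  params$flags$ca_free <- TRUE
  params
}

#' Sensitivity sweep over conductances or kinetics
#'
#' Runs the free-running protocol for the baseline and for +/-`fraction`
#' variants of each requested knob, and tabulates slow-wave metrics and
#' their deltas. Conductance knobs scale a maximum conductance. Kinetics
#' knobs scale the voltage-linked activation (or inactivation) parameters
#' of one of the four main channels: the half-activation voltage and slope
#' of an HH gate, or the voltage-sensitivity exponents of the
#' activation/deactivation (inactivation/recovery) edges of a Markov
#' channel.
#'
#' @param params A `jsmc_params` object.
#' @param stimulus A `jsmc_stimulus` (default: from `params`).
#' @param targets Conductance names (e.g. `c("G_CaL", "G_Kv", "G_BK",
#'   "G_Na")`) or channel names (`c("CaL", "Kv", "BK", "Na")`) for kinetics.
#' @param fraction Relative variation in (0, 1]; 0 returns zero deltas.
#' @param kind `"conductance"` or `"kinetics"`.
#' @param mode For kinetics: vary `"activation"` or `"inactivation"`
#'   parameters.
#' @param duration,burn_in Simulation length and discarded transient, ms.
#' @param dt Time step, ms.
#' @return Data frame: one row per variant (and the baseline) with the
#'   slow-wave metrics and deltas relative to baseline.
#' @export
sensitivity_sweep <- function(params = default_parameters(), stimulus = NULL,
                              targets = c("G_CaL", "G_Kv", "G_BK", "G_Na"),
                              fraction = 0.5,
                              kind = c("conductance", "kinetics"),
                              mode = c("activation", "inactivation"),
                              duration = 150000, burn_in = 60000, dt = 0.1) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(stimulus)) stimulus <- icc_stimulus(params)
  run_metrics <- function(p) {
    analyze_trace(run_free(p, stimulus, duration = duration, dt = dt,
                           burn_in = burn_in))
  }
  base <- run_metrics(params)
  rows <- list(cbind(data.frame(knob = "baseline", direction = 0L),
                     metrics_row(base)))
  for (tg in targets) {
    for (dir in c(-1, 1)) {
      p2 <- vary_knob(params, tg, 1 + dir * fraction, kind, mode)
      m <- if (fraction == 0) base else run_metrics(p2)
      rows[[length(rows) + 1]] <-
        cbind(data.frame(knob = tg, direction = dir), metrics_row(m))
    }
  }
  out <- do.call(rbind, rows)
  for (cl in c("resting_potential", "peak_potential", "plateau_potential",
               "amplitude", "frequency", "ca_min", "ca_max")) {
    out[[paste0("d_", cl)]] <- out[[cl]] - out[[cl]][1]
  }
  rownames(out) <- NULL
  out
}

metrics_row <- function(m) {
  data.frame(resting_potential = m$resting_potential,
             peak_potential = m$peak_potential,
             plateau_potential = m$plateau_potential, amplitude = m$amplitude,
             frequency = m$frequency, ca_min = m$ca_min, ca_max = m$ca_max)
}

vary_knob <- function(params, target, factor, kind, mode) {
  if (kind == "conductance") {
    if (!target %in% names(params$conductances)) {
      stop("unknown conductance knob: ", target, call. = FALSE)
    }
    params$conductances[[target]] <- params$conductances[[target]] * factor
    return(params)
  }
  scale_gate <- function(g) {
    g$v_half <- g$v_half * factor
    g$slope <- g$slope * factor
    g
  }
  scale_edges_coef <- function(coef, keys) {
    for (k in keys) coef[[k]] <- coef[[k]] * factor
    coef
  }
  act <- identical(mode, "activation")
  if (target == "Kv") {
    gate <- if (act) "x_Kv" else "y_Kv"
    params$gates[[gate]] <- scale_gate(params$gates[[gate]])
  } else if (target == "CaT") {
    gate <- if (act) "m_CaT" else "h_CaT"
    params$gates[[gate]] <- scale_gate(params$gates[[gate]])
  } else if (target == "CaL") {
    keys <- if (act) c("act_k", "deact_k") else c("inact_k", "rec_k")
    params$markov$CaL <- scale_edges_coef(params$markov$CaL, keys)
  } else if (target == "BK") {
    if (!act) stop("BK has no inactivation kinetics to vary", call. = FALSE)
    params$markov$BK <- scale_edges_coef(params$markov$BK,
                                         c("open_k", "close_k"))
  } else if (target == "Na") {
    keys <- if (act) c("act_k", "deact_k") else
      c("inact_o_k", "rec_o_k", "inact_c_k", "rec_c_k")
    params$markov$Na <- scale_edges_coef(params$markov$Na, keys)
  } else {
    stop("unknown kinetics knob: ", target, call. = FALSE)
  }
  params
}
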