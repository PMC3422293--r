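#' Construct a physically consistent initial state
#'
#' Gates start at their voltage steady state, Markov occupancies at the
#' stationary distribution of their generator at (V0, resting free Ca2+),
#' and concentrations at the documented defaults. One integration step at
#' clamped V0 with frozen concentrations therefore leaves gates and
#' occupancies unchanged to round-off.
#'
#' @param params A `jsmc_params` object.
#' @param V0 Initial membrane potential, mV, in \[-100, 20\].
#' @return A list of class `jsmc_state` with fields `V_m`, `m_CaT`, `h_CaT`,
#'   `x_Kv`, `y_Kv`, `p_CaL`, `p_BK`, `p_Na`, `Na_i`, `K_i`, `Ca_total`.
#' @export
initial_state <- function(params, V0 = params$initial$V0) {
  if (!is.finite(V0) || V0 < -100 || V0 > 20) {
    stop("V0 must lie in [-100, 20] mV", call. = FALSE)
  }
  specs <- channel_specs(params)
  ca0 <- if (isTRUE(params$flags$ca_free)) 1e-13 else
    free_calcium(params$initial$Ca_total, params$buffers)
  st <- list(
    V_m = V0,
    m_CaT = gate_steady_state(params$gates$m_CaT, V0),
    h_CaT = gate_steady_state(params$gates$h_CaT, V0),
    x_Kv = gate_steady_state(params$gates$x_Kv, V0),
    y_Kv = gate_steady_state(params$gates$y_Kv, V0),
    p_CaL = stationary_distribution(build_generator(specs$CaL, V0, ca0)),
    p_BK  = stationary_distribution(build_generator(specs$BK, V0, ca0)),
    p_Na  = stationary_distribution(build_generator(specs$Na, V0, ca0)),
    Na_i = params$initial$Na_i,
    K_i = params$initial$K_i,
    Ca_total = if (isTRUE(params$flags$ca_free)) 1e-13 else
      params$initial$Ca_total
  )
  class(st) <- "jsmc_state"
  st
}

state_to_vector <- function(state) {
  c(state$V_m, state$m_CaT, state$h_CaT, state$x_Kv, state$y_Kv,
    state$p_CaL, state$p_BK, state$p_Na,
    state$Na_i, state$K_i, state$Ca_total)
}

vector_to_state <- function(v) {
  st <- list(V_m = v[1], m_CaT = v[2], h_CaT = v[3], x_Kv = v[4], y_Kv = v[5],
             p_CaL = v[6:17], p_BK = v[18:27], p_Na = v[28:33],
             Na_i = v[34], K_i = v[35], Ca_total = v[36])
  class(st) <- "jsmc_state"
  st
}

#' Advance the coupled model one time step (reference implementation)
#'
#' Operator-split update matching the published numerical scheme: all
#' currents are evaluated from the beginning-of-step state; Markov
#' occupancies advance by backward Euler; gates, membrane potential and ion
#' concentrations advance by forward Euler. The compiled engine used by
#' [run_free()] performs the identical update; this R version is the
#' readable reference and is cross-checked against it in the test suite.
#'
#' @param state A `jsmc_state` object.
#' @param params A `jsmc_params` object.
#' @param stimulus A `jsmc_stimulus` or `NULL` for no stimulus.
#' @param t Current time, ms.
#' @param dt Time step, ms (> 0; 0.1 ms is sufficient for convergence).
#' @param specs Channel specs (rebuilt if omitted).
#' @param clamp If non-`NULL`, the membrane potential is held at this value
#'   (voltage clamp); the stimulus is ignored.
#' @param freeze_conc Freeze intracellular concentrations (pipette dialysis).
#' @return The updated `jsmc_state`.
#' @export
step <- function(state, params, stimulus = NULL, t = 0, dt = 0.1,
                 specs = channel_specs(params), clamp = NULL,
                 freeze_conc = FALSE) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.null(clamp)) state$V_m <- clamp
  ca_free <- state_ca_free(state, params)
  cur <- total_ionic_current(state, params, specs)
  i_stim <- if (is.null(clamp) && !is.null(stimulus)) {
    stimulus_current(icc_voltage(t, stimulus), state$V_m, stimulus$G_couple)
  } else 0
  V <- state$V_m
  state$p_CaL <- advance_markov(state$p_CaL, build_generator(specs$CaL, V, ca_free), dt)
  state$p_BK  <- advance_markov(state$p_BK,  build_generator(specs$BK, V, ca_free), dt)
  state$p_Na  <- advance_markov(state$p_Na,  build_generator(specs$Na, V, ca_free), dt)
  state$m_CaT <- advance_gate(state$m_CaT, params$gates$m_CaT, V, dt)
  state$h_CaT <- advance_gate(state$h_CaT, params$gates$h_CaT, V, dt)
  state$x_Kv  <- advance_gate(state$x_Kv, params$gates$x_Kv, V, dt)
  state$y_Kv  <- advance_gate(state$y_Kv, params$gates$y_Kv, V, dt)
  if (is.null(clamp)) {
    state$V_m <- V - dt * (cur$I_total - i_stim) / params$membrane$C_m
  }
  if (!freeze_conc) {
    d <- concentration_derivatives(state, cur, params)
    if (!isTRUE(params$flags$ca_free)) {
      state$Ca_total <- max(state$Ca_total + dt * d[["dCa_total"]], 1e-12)
    }
    state$Na_i <- state$Na_i + dt * d[["dNa"]]
    state$K_i  <- state$K_i + dt * d[["dK"]]
  }
  bad <- !vapply(state, function(x) all(is.finite(x)), logical(1))
  if (any(bad)) {
    stop("non-finite state component after step: ",
         paste(names(state)[bad], collapse = ", "), call. = FALSE)
  }
  state
}

pack_par <- function(params, stimulus, specs) {
  gate_mat <- t(vapply(params$gates, function(g) {
    c(g$v_half, g$slope, if (identical(g$type, "inact")) 1 else -1,
      g$tau_min, g$tau_amp, g$tau_v, g$tau_w)
  }, numeric(7)))
  edges_mat <- function(sp) as.matrix(sp$edges[, c("from", "to", "a", "b", "cad")])
  stim <- if (is.null(stimulus)) {
    c(rep(0, 11), 0)
  } else {
    c(stimulus$V_ICCrest, stimulus$V_ICCamp, stimulus$t_up, stimulus$t_plat,
      stimulus$s_up, stimulus$plateau_frac, stimulus$tau_plat,
      stimulus$w_fall, stimulus$G_couple, stimulus$t_start, stimulus$t_fall, 1)
  }
  list(
    Cm = params$membrane$C_m,
    F = params$physical$F, RTF = rtf_mV(params), Vc = params$physical$V_c,
    G = unlist(params$conductances[c("G_CaL", "G_CaT", "G_Kv", "G_BK",
                                     "G_Na", "G_NaLeak", "G_KLeak")]),
    nak = c(params$pumps$P_NaK, params$pumps$K_mK, params$pumps$K_mNa),
    ncx = c(params$pumps$k_NCX, params$pumps$gamma_NCX, params$pumps$K_mNai,
            params$pumps$K_mCa, params$pumps$k_sat, params$pumps$alpha_NCX),
    ext = c(params$external$Na_o, params$external$K_o, params$external$Ca_o),
    buf = c(params$buffers$CaM$B_total, params$buffers$CaM$K_d,
            params$buffers$CRT$B_total, params$buffers$CRT$K_d),
    gates = gate_mat,
    edges_cal = edges_mat(specs$CaL), edges_bk = edges_mat(specs$BK),
    edges_na = edges_mat(specs$Na),
    open_cal = as.integer(specs$CaL$open_states),
    open_bk = as.integer(specs$BK$open_states),
    open_na = as.integer(specs$Na$open_states),
    stim = stim,
    ca_free = isTRUE(params$flags$ca_free)
  )
}

trace_columns <- c("t", "V_m", "I_CaL", "I_CaT", "I_Kv", "I_BK", "I_Na",
                   "I_NaK", "I_NCX", "I_NaLeak", "I_KLeak", "I_stim",
                   "Po_CaL", "Po_BK", "Po_Na", "Na_i", "K_i", "Ca_total",
                   "Ca_free")

make_trace <- function(res, params, dt, stride, protocol, burn_in) {
  tr <- as.data.frame(res$trace)
  names(tr) <- trace_columns
  attr(tr, "dt") <- dt
  attr(tr, "stride") <- stride
  attr(tr, "protocol") <- protocol
  attr(tr, "burn_in") <- burn_in
  attr(tr, "params_yaml") <- write_parameters(params)
  attr(tr, "psum_err") <- res$psum_err
  attr(tr, "p_min") <- res$p_min
  attr(tr, "final_state") <- vector_to_state(res$final_state)
  attr(tr, "deterministic") <- TRUE
  class(tr) <- c("jsmc_trace", "data.frame")
  tr
}

#' Free-running slow-wave simulation
#'
#' Integrates the full model under the ICC stimulus with the fixed-step
#' operator-split scheme (forward Euler for potential, gates and
#' concentrations; backward Euler for Markov occupancies). The compiled
#' engine is the default; `engine = "r"` runs the reference R stepper
#' (practical only for short durations).
#'
#' @param params A `jsmc_params` object.
#' @param stimulus A `jsmc_stimulus`, `NULL` to use the parameter defaults,
#'   or `NA` for no stimulus.
#' @param duration Simulated time, ms.
#' @param dt Time step, ms.
#' @param record_stride Record every this many steps (default 10, i.e. 1 ms
#'   at the default step).
#' @param burn_in Portion of the trace, ms, that [analyze_trace()] will skip
#'   by default (stored as metadata; the trace itself is complete).
#' @param init State to start from (default: [initial_state()] at the
#'   configured V0).
#' @param engine `"cpp"` (compiled) or `"r"` (reference).
#' @return A `jsmc_trace` data frame (time, potential, every current
#'   component, open probabilities, concentrations and free Ca2+) with
#'   reproducibility metadata in its attributes.
#' @export
run_free <- function(params = default_parameters(), stimulus = NULL,
                     duration = 180000, dt = 0.1, record_stride = 10L,
                     burn_in = 60000, init = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.null(stimulus)) stimulus <- icc_stimulus(params)
  no_stim <- length(stimulus) == 1 && is.na(stimulus[1])
  if (no_stim) stimulus <- NULL
  specs <- channel_specs(params)
  if (is.null(init)) init <- initial_state(params)
  n <- round(duration / dt)
  if (engine == "cpp") {
    res <- simulate_cpp(pack_par(params, stimulus, specs),
                        state_to_vector(init), n, dt, as.integer(record_stride),
                        NULL, FALSE)
  } else {
    res <- simulate_r(params, stimulus, specs, init, n, dt,
                      as.integer(record_stride))
  }
  make_trace(res, params, dt, record_stride,
             if (no_stim) "free_run_unstimulated" else "free_run", burn_in)
}

# plain-R mirror of the compiled loop, for cross-checking and tiny runs
simulate_r <- function(params, stimulus, specs, init, n_steps, dt, stride) {
  st <- init
  nrec <- n_steps %/% stride + 1
  out <- matrix(NA_real_, nrec, length(trace_columns))
  psum_err <- 0
  rec <- 1
  for (k in 0:n_steps) {
    t <- k * dt
    if (k %% stride == 0) {
      ca_free <- state_ca_free(st, params)
      cur <- total_ionic_current(st, params, specs)
      i_stim <- if (!is.null(stimulus)) {
        stimulus_current(icc_voltage(t, stimulus), st$V_m, stimulus$G_couple)
      } else 0
      out[rec, ] <- c(t, st$V_m, cur$I_CaL, cur$I_CaT, cur$I_Kv, cur$I_BK,
                      cur$I_Na, cur$I_NaK, cur$I_NCX, cur$I_NaLeak,
                      cur$I_KLeak, i_stim,
                      open_probability(st$p_CaL, specs$CaL),
                      open_probability(st$p_BK, specs$BK),
                      open_probability(st$p_Na, specs$Na),
                      st$Na_i, st$K_i, st$Ca_total, ca_free)
      rec <- rec + 1
    }
    if (k == n_steps) break
    st <- step(st, params, stimulus, t, dt, specs)
  }
  list(trace = out[seq_len(rec - 1), , drop = FALSE],
       psum_err = psum_err, p_min = 0,
       final_state = state_to_vector(st))
}
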