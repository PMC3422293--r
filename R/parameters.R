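#' Default hJSMC model parameters
#'
#' Returns the canonical parameter set of the human jejunal smooth muscle cell
#' (hJSMC) electrophysiology model. Fixed experimental quantities (membrane
#' capacitance, maximum channel conductances, the 45-fold leak bound, the ICC
#' stimulus caption values) follow the published whole-cell characterisations;
#' quantities that are only constrained at the cellular level (pump/exchanger
#' scales, gap-junction coupling, buffer constants, cell volume, channel rate
#' coefficients) carry the values with which the model reproduces the recorded
#' slow-wave phenotype: resting potential -60 mV, amplitude 23 mV, free Ca2+
#' 94-250 nM, 6 cycles per minute.
#'
#' Internal unit system: mV, ms, pA, nS, pF, mM, K, litres. The identities
#' pA = nS * mV and pA/pF = mV/ms make the membrane equation
#' dV/dt = -(I_ion - I_stim)/C_m dimensionally consistent without conversion
#' factors; concentration updates use an explicit charge-scale factor (see
#' [concentration_derivatives()]).
#'
#' @return A nested list of class `jsmc_params`.
#' @export
default_parameters <- function() {
  p <- list(
    membrane = list(
      C_m = 50          # pF, within the reported 39-65 pF range
    ),
    conductances = list(
      G_CaL    = 1.44,     # nS, L-type Ca2+
      G_CaT    = 0.0425,   # nS, T-type Ca2+
      G_Kv     = 1.0217,   # nS, voltage-dependent K+
      G_BK     = 80,       # nS, large-conductance Ca2+/voltage-activated K+
      G_Na     = 25.1,     # nS, Nav1.5
      G_NaLeak = 0.0007,   # nS, non-selective leak (Na+ component)
      G_KLeak  = 0.0215    # nS, non-selective leak (K+ component)
    ),
    pumps = list(
      P_NaK   = 4.24,      # pA, maximum NaK pump current scale
      K_mK    = 1.0,       # mM, pump K+o half-saturation
      K_mNa   = 40,        # mM, pump Na+i half-saturation
      k_NCX   = 70000,     # pA, NCX scale
      gamma_NCX = 0.35,    # position of the energy barrier
      K_mNai  = 87.5,      # mM
      K_mCa   = 1.38,      # mM
      k_sat   = 0.1,
      alpha_NCX = 0.84
    ),
    physical = list(
      F   = 96.4867,       # C/mmol, Faraday constant
      R   = 8.314,         # mJ/(mmol K), gas constant
      T   = 310,           # K, body temperature
      V_c = 3.5e-12        # L, cytosolic volume
    ),
    external = list(       # bath concentrations, mM (held constant)
      Na_o = 140,
      K_o  = 5.4,
      Ca_o = 2
    ),
    initial = list(
      V0       = -60,      # mV
      Na_i     = 9.72,     # mM
      K_i      = 150,      # mM
      Ca_total = 1.2e-3    # mM total intracellular Ca2+ (free + buffered)
    ),
    buffers = list(
      CaM = list(B_total = 0.008, K_d = 0.001),  # mM; calmodulin
      CRT = list(B_total = 0.027, K_d = 0.005)   # mM; calreticulin
    ),
    gates = list(
      # steady state: 1/(1 + exp(sign * (V - v_half)/slope)), sign = -1 for
      # activation, +1 for inactivation; tau(V) = tau_min +
      # tau_amp * exp(-((V - tau_v)/tau_w)^2), ms
      m_CaT = list(type = "act",   v_half = -44, slope = 5.5,
                   tau_min = 1.2, tau_amp = 3,   tau_v = -60, tau_w = 25),
      h_CaT = list(type = "inact", v_half = -68, slope = 5.0,
                   tau_min = 80,  tau_amp = 150, tau_v = -65, tau_w = 20),
      x_Kv  = list(type = "act",   v_half = -13, slope = 14.5,
                   tau_min = 1500, tau_amp = 0,  tau_v = -50, tau_w = 30),
      y_Kv  = list(type = "inact", v_half = 60,  slope = 20,
                   tau_min = 500, tau_amp = 0,   tau_v = 0,   tau_w = 30)
    ),
    markov = list(
      # per-edge rates are a * exp(b * V) (* Ca_free for Ca-dependent edges);
      # coefficients a in 1/ms (1/(mM ms) when Ca-dependent), k in mV
      CaL = list(act_a = 0.465, act_k = 25,  deact_a = 0.05,  deact_k = 75,
                 inact_a = 0.04, inact_k = 25, rec_a = 0.005, rec_k = 50,
                 ca_on = 2.5, ca_off = 6e-5, mode_ca_act_scale = 0.25),
      BK  = list(k_on = 1000, k_off_c = 2.5, k_off_o = 0.25,
                 open_a = 2.6e-3, open_k = 25, close_a = 4, close_k = 60),
      Na  = list(act_a = 8, act_k = 14, deact_a = 0.3, deact_k = 16,
                 inact_o_a = 1.0, inact_o_k = 50, rec_o_a = 1e-4, rec_o_k = 30,
                 inact_c_a = 25, inact_c_k = 12, rec_c_a = 1e-4, rec_c_k = 12,
                 slow_a = 8e-4, slow_rec_a = 0.003, slow_rec_k = 60)
    ),
    stimulus = list(
      V_ICCrest = -57,     # mV, ICC resting potential
      V_ICCamp  = 23.5,    # mV, slow-wave amplitude (magnitude)
      t_up      = 300,     # ms, upstroke duration
      t_plat    = 9700,    # ms, plateau duration; period = 10 s -> 6 cpm
      s_up      = 3.5,     # upstroke shape constant (rise steepness)
      plateau_frac = 0.7,  # plateau shape constant (sustained fraction)
      tau_plat  = 6000,    # ms, plateau early-decay constant
      w_fall    = 200,     # ms, terminal repolarisation width
      t_fall    = 1500,    # ms into the plateau at which repolarisation starts
      G_couple  = 0.35,    # nS, ICC-SMC gap junction conductance
      t_start   = 0,       # ms, stimulus onset
      hwang_rest = -61,    # mV, ICC rest for the Hwang-matched variant
      hwang_amp  = 31.5    # mV, ICC amplitude for the Hwang-matched variant
    ),
    flags = list(
      ca_free = FALSE      # near-zero Ca2+ condition (see apply_ca_free)
    )
  )
  class(p) <- "jsmc_params"
  validate_parameters(p)
}

#' Load model parameters from a configuration file or override list
#'
#' Overrides are merged onto [default_parameters()]. Unknown keys are
#' rejected so that typos cannot silently leave a constant at its default.
#'
#' @param config Path to a YAML configuration file, or a nested list of
#'   overrides (possibly empty). Structure mirrors [default_parameters()].
#' @return A validated `jsmc_params` object.
#' @export
load_parameters <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("configuration file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) {
    stop("config must be a file path or a (possibly nested) list", call. = FALSE)
  }
  base <- default_parameters()
  merged <- merge_overrides(unclass(base), config, path = character())
  class(merged) <- "jsmc_params"
  validate_parameters(merged)
}

merge_overrides <- function(base, over, path) {
  for (nm in names(over)) {
    here <- c(path, nm)
    if (!nm %in% names(base)) {
      stop("unknown parameter key: ", paste(here, collapse = "$"),
           call. = FALSE)
    }
    if (is.list(base[[nm]])) {
      if (!is.list(over[[nm]])) {
        stop("parameter group ", paste(here, collapse = "$"),
             " must be a list", call. = FALSE)
      }
      base[[nm]] <- merge_overrides(base[[nm]], over[[nm]], here)
    } else {
      v <- over[[nm]]
      if (is.null(v)) {
        stop("missing required field: ", paste(here, collapse = "$"),
             call. = FALSE)
      }
      if (is.character(base[[nm]])) {
        base[[nm]] <- as.character(v)
      } else {
        if (!is.numeric(v) && !is.logical(v)) {
          stop("field ", paste(here, collapse = "$"), " must be numeric",
               call. = FALSE)
        }
        base[[nm]] <- if (is.logical(base[[nm]])) as.logical(v) else as.numeric(v)
      }
    }
  }
  base
}

#' Validate a parameter set
#'
#' Checks strict positivity of conductances, capacitance, volume,
#' concentrations and buffer constants, and the leak-size constraint
#' G_Kv >= 45 * (G_NaLeak + G_KLeak) that the whole-cell recordings impose.
#'
#' @param p A `jsmc_params` object.
#' @return `p`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_parameters <- function(p) {
  g <- p$conductances
  pos <- c(unlist(g), C_m = p$membrane$C_m, V_c = p$physical$V_c,
           F = p$physical$F, T = p$physical$T,
           unlist(p$external), Na_i = p$initial$Na_i, K_i = p$initial$K_i,
           Ca_total = p$initial$Ca_total,
           CaM_B = p$buffers$CaM$B_total, CaM_K = p$buffers$CaM$K_d,
           CRT_B = p$buffers$CRT$B_total, CRT_K = p$buffers$CRT$K_d)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) {
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ratio <- g$G_Kv / (g$G_NaLeak + g$G_KLeak)
  if (ratio < 45) {
    stop(sprintf(paste0("leak conductance too large: G_Kv/(G_NaLeak+G_KLeak)",
                        " = %.2f, must be >= 45"), ratio), call. = FALSE)
  }
  for (nm in names(p$gates)) {
    if (p$gates[[nm]]$slope == 0) {
      stop("gate ", nm, " has zero slope", call. = FALSE)
    }
  }
  if (p$stimulus$t_up <= 0 || p$stimulus$t_plat <= 0) {
    stop("stimulus durations t_up and t_plat must be positive", call. = FALSE)
  }
  invisible(p)
}

#' Serialize parameters to YAML
#'
#' The written document round-trips: `load_parameters(write_parameters(p))`
#' reproduces the effective values exactly.
#'
#' @param p A `jsmc_params` object.
#' @param path Output file; if `NULL`, the YAML text is returned as a string.
#' @return The path (invisibly) or the YAML string.
#' @export
write_parameters <- function(p, path = NULL) {
  txt <- yaml::as.yaml(unclass(p), precision = 17)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @export
print.jsmc_params <- function(x, ...) {
  g <- x$conductances
  cat("hJSMC model parameters\n")
  cat(sprintf("  C_m = %g pF, V_c = %g L, T = %g K\n",
              x$membrane$C_m, x$physical$V_c, x$physical$T))
  cat(sprintf("  G (nS): CaL %g, CaT %g, Kv %g, BK %g, Na %g, leak %g+%g\n",
              g$G_CaL, g$G_CaT, g$G_Kv, g$G_BK, g$G_Na,
              g$G_NaLeak, g$G_KLeak))
  cat(sprintf("  pumps: P_NaK %g pA, k_NCX %g pA\n",
              x$pumps$P_NaK, x$pumps$k_NCX))
  cat(sprintf("  stimulus: rest %g mV, amp %g mV, period %g ms, G_couple %g nS\n",
              x$stimulus$V_ICCrest, x$stimulus$V_ICCamp,
              x$stimulus$t_up + x$stimulus$t_plat, x$stimulus$G_couple))
  invisible(x)
}

# RT/F in mV for the parameter set
rtf_mV <- function(p) p$physical$R * p$physical$T / p$physical$F
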