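#' Markov-state channel model specifications
#'
#' Three membrane channels use deterministic continuous-time Markov chains:
#' the L-type Ca2+ channel (a Faber-style two-mode topology with Ca2+-driven
#' mode switching), the BK channel (a Cox-style allosteric topology with
#' cooperative Ca2+ binding to the four alpha subunits of the homotetramer)
#' and the Nav1.5 channel (six states). Every transition rate has the Eyring
#' form a * exp(b * V), optionally multiplied by the free Ca2+ concentration
#' (mM) for ligand-binding edges; coefficients live in `params$markov`.
#'
#' @param coef Coefficient list for the channel, e.g.
#'   `default_parameters()$markov$CaL`.
#' @return A list of class `jsmc_markov_spec` with fields `id`, `n_states`,
#'   `open_states`, `edges` (data.frame: `from`, `to`, `a`, `b`, `cad`,
#'   `role`) and `egta` (logical).
#' @name markov_specs
NULL

edge_row <- function(from, to, a, b, cad, role) {
  data.frame(from = from, to = to, a = a, b = b, cad = cad, role = role,
             stringsAsFactors = FALSE)
}

new_markov_spec <- function(id, n_states, open_states, edges) {
  if (any(edges$a < 0)) {
    bad <- which(edges$a < 0)[1]
    stop(sprintf("negative rate coefficient on edge %d -> %d of %s",
                 edges$from[bad], edges$to[bad], id), call. = FALSE)
  }
  structure(list(id = id, n_states = n_states, open_states = open_states,
                 edges = edges, egta = FALSE),
            class = "jsmc_markov_spec")
}

#' @rdname markov_specs
#' @details `cal_spec()`: 12 states. 1-4 closed C0-C3, 5 open O, 6 voltage
#'   inactivated IV (mode normal); 7-12 the same tier with Ca2+ bound (mode
#'   Ca), in which opening is scaled down by `mode_ca_act_scale` and state 11
#'   does not conduct, which is the model's Ca2+-dependent inactivation.
#'   Mode entry (Ca2+ binding) edges are the Ca2+-dependent edges frozen by
#'   [egta_mode()].
#' @export
cal_spec <- function(coef) {
  a  <- coef$act_a;  ka <- 1 / coef$act_k
  b  <- coef$deact_a; kb <- -1 / coef$deact_k
  mult_f <- c(4, 3, 2, 1); mult_b <- c(1, 2, 3, 4)
  chain <- function(off, act_scale) {
    rbind(
      edge_row(off + 1:4, off + 2:5, act_scale * mult_f * a, ka, 0, "act"),
      edge_row(off + 2:5, off + 1:4, mult_b * b, kb, 0, "deact")
    )
  }
  e <- rbind(
    chain(0, 1),
    chain(6, coef$mode_ca_act_scale),
    edge_row(c(5, 11), c(6, 12), coef$inact_a, 1 / coef$inact_k, 0, "inact"),
    edge_row(c(6, 12), c(5, 11), coef$rec_a, -1 / coef$rec_k, 0, "rec"),
    edge_row(1:6, 7:12, coef$ca_on, 0, 1, "ca_on"),
    edge_row(7:12, 1:6, coef$ca_off, 0, 0, "ca_off")
  )
  new_markov_spec("CaL", 12L, 5L, e)
}

#' @rdname markov_specs
#' @details `bk_spec()`: 10 states. 1-5 closed with 0-4 Ca2+ bound, 6-10 open
#'   with 0-4 Ca2+ bound. Horizontal edges bind/unbind Ca2+ with closed- and
#'   open-tier dissociation constants `k_off_c/k_on` and `k_off_o/k_on`;
#'   vertical closed-open edges are voltage dependent with allosteric factor
#'   f = sqrt(k_off_c/k_off_o) per bound Ca2+, which preserves detailed
#'   balance around every square of the topology.
#' @export
bk_spec <- function(coef) {
  f <- sqrt(coef$k_off_c / coef$k_off_o)
  i <- 0:3
  e <- rbind(
    edge_row(1:4, 2:5, (4 - i) * coef$k_on, 0, 1, "ca_on"),
    edge_row(2:5, 1:4, (i + 1) * coef$k_off_c, 0, 0, "ca_off"),
    edge_row(6:9, 7:10, (4 - i) * coef$k_on, 0, 1, "ca_on"),
    edge_row(7:10, 6:9, (i + 1) * coef$k_off_o, 0, 0, "ca_off"),
    edge_row(1:5, 6:10, coef$open_a * f^(0:4), 1 / coef$open_k, 0, "act"),
    edge_row(6:10, 1:5, coef$close_a * f^(-(0:4)), -1 / coef$close_k, 0, "deact")
  )
  new_markov_spec("BK", 10L, 6:10, e)
}

#' @rdname markov_specs
#' @details `nav_spec()`: 6 states. 1-3 closed C3-C1, 4 open, 5 fast
#'   inactivated I1 (reachable from both the open and the last closed state,
#'   giving steep closed-state inactivation), 6 slow inactivated I2. No
#'   Ca2+-dependent edges.
#' @export
nav_spec <- function(coef) {
  e <- rbind(
    edge_row(1:3, 2:4, c(3, 2, 1) * coef$act_a, 1 / coef$act_k, 0, "act"),
    edge_row(2:4, 1:3, c(1, 2, 3) * coef$deact_a, -1 / coef$deact_k, 0, "deact"),
    edge_row(4, 5, coef$inact_o_a, 1 / coef$inact_o_k, 0, "inact"),
    edge_row(5, 4, coef$rec_o_a, -1 / coef$rec_o_k, 0, "rec"),
    edge_row(3, 5, coef$inact_c_a, 1 / coef$inact_c_k, 0, "inact"),
    edge_row(5, 3, coef$rec_c_a, -1 / coef$rec_c_k, 0, "rec"),
    edge_row(5, 6, coef$slow_a, 0, 0, "inact"),
    edge_row(6, 5, coef$slow_rec_a, -1 / coef$slow_rec_k, 0, "rec")
  )
  new_markov_spec("Na", 6L, 4L, e)
}

#' Channel specs for a parameter set
#'
#' @param params A `jsmc_params` object.
#' @return Named list with elements `CaL`, `BK`, `Na`.
#' @export
channel_specs <- function(params) {
  list(CaL = cal_spec(params$markov$CaL),
       BK  = bk_spec(params$markov$BK),
       Na  = nav_spec(params$markov$Na))
}

#' Build the generator (rate) matrix of a channel at fixed voltage and Ca2+
#'
#' Column convention: dp/dt = Q p, so `Q[j, i]` is the rate from state i to
#' state j and every column sums to zero.
#'
#' @param spec A `jsmc_markov_spec`.
#' @param V Membrane potential, mV.
#' @param Ca_free Free intracellular Ca2+, mM (> 0).
#' @return An `n_states` x `n_states` matrix, 1/ms.
#' @export
build_generator <- function(spec, V, Ca_free) {
  if (!is.finite(V) || !is.finite(Ca_free) || Ca_free <= 0) {
    stop("V must be finite and Ca_free finite and > 0", call. = FALSE)
  }
  n <- spec$n_states
  e <- spec$edges
  r <- e$a * exp(e$b * V) * ifelse(e$cad == 1, Ca_free, 1)
  if (any(r < 0)) {
    bad <- which(r < 0)[1]
    stop(sprintf("negative transition rate on edge %d -> %d of %s",
                 e$from[bad], e$to[bad], spec$id), call. = FALSE)
  }
  Q <- matrix(0, n, n)
  for (k in seq_len(nrow(e))) {
    Q[e$to[k], e$from[k]] <- Q[e$to[k], e$from[k]] + r[k]
    Q[e$from[k], e$from[k]] <- Q[e$from[k], e$from[k]] - r[k]
  }
  Q
}

#' Backward-Euler step for a Markov occupancy vector
#'
#' Solves the implicit system (I - dt Q) p' = p by dense direct
#' factorisation (state counts are at most 12), clamps negative round-off to
#' zero and renormalises to sum exactly 1, which prevents drift over the
#' ~1.8e7 steps of a 30-minute run.
#'
#' @param p Occupancy vector (sums to 1).
#' @param Q Generator matrix from [build_generator()].
#' @param dt Time step, ms (> 0).
#' @return Updated occupancy vector.
#' @export
advance_markov <- function(p, Q, dt) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  n <- length(p)
  pnew <- tryCatch(solve(diag(n) - dt * Q, p),
                   error = function(e) stop("singular backward-Euler system: ",
                                            conditionMessage(e), call. = FALSE))
  pnew[pnew < 0] <- 0
  pnew / sum(pnew)
}

#' Open probability of a channel
#'
#' @param p Occupancy vector.
#' @param spec A `jsmc_markov_spec`.
#' @return Sum of occupancies over the spec's open states, in \[0, 1\].
#' @export
open_probability <- function(p, spec) sum(p[spec$open_states])

#' Stationary distribution of a generator matrix
#'
#' Solves Q p = 0 subject to sum(p) = 1 by replacing one balance equation
#' with the normalisation constraint. Errors if the chain is reducible
#' (non-unique stationary distribution).
#'
#' @param Q Generator matrix (column convention).
#' @return Stationary occupancy vector.
#' @export
stationary_distribution <- function(Q) {
  n <- nrow(Q)
  if (qr(Q)$rank < n - 1) {
    stop("reducible chain: stationary distribution is not unique",
         call. = FALSE)
  }
  A <- rbind(Q[-n, , drop = FALSE], rep(1, n))
  p <- solve(A, c(rep(0, n - 1), 1))
  p[p < 0] <- 0
  p / sum(p)
}

#' Freeze the Ca2+ dependence of a channel (EGTA pipette condition)
#'
#' Heavy pipette Ca2+ buffering (2 mM EGTA) clamps the free Ca2+ seen by the
#' channel to a fixed, vanishingly small value. The returned spec has its
#' Ca2+-dependent edges frozen at that value so that the open probability no
#' longer depends on `Ca_free`.
#'
#' @param spec A `jsmc_markov_spec`.
#' @param ca_fixed Frozen Ca2+ concentration, mM.
#' @return Modified spec; a no-op with a warning if the channel has no
#'   Ca2+-dependent edges. Idempotent.
#' @export
egta_mode <- function(spec, ca_fixed = 1e-7) {
  if (isTRUE(spec$egta)) return(spec)
  dep <- spec$edges$cad == 1
  if (!any(dep)) {
    warning("channel ", spec$id, " has no Ca2+-dependent edges; egta_mode is a no-op")
    return(spec)
  }
  spec$edges$a[dep] <- spec$edges$a[dep] * ca_fixed
  spec$edges$cad[dep] <- 0
  spec$egta <- TRUE
  spec
}
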