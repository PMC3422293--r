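#' Deterministic test fixtures
#'
#' Builds the small synthetic inputs the test-suite oracles need: a
#' three-state reversible Markov chain whose stationary distribution has a
#' detailed-balance closed form, a synthetic slow-wave trace with prescribed
#' metrics, and random operating points for the current-formula oracles.
#' The same seed always yields an identical bundle.
#'
#' @param seed Integer seed.
#' @return List with elements `toy_chain` (fields `edges`, `stationary`,
#'   `spec`), `synthetic_trace` (a `jsmc_trace`-shaped data frame with
#'   prescribed `rest`, `amplitude`, `freq_cpm`) and `operating_points`
#'   (data frame of V, Na_i, Ca_free draws).
#' @export
generate_fixtures <- function(seed = 1L) {
  set.seed(seed)

  # reversible 3-state chain 1 <-> 2 <-> 3: detailed balance gives
  # pi proportional to (1, k12/k21, k12*k23/(k21*k32))
  k <- stats::runif(4, 0.2, 2)  # k12, k21, k23, k32
  w <- c(1, k[1] / k[2], k[1] * k[3] / (k[2] * k[4]))
  edges <- data.frame(from = c(1, 2, 2, 3), to = c(2, 1, 3, 2),
                      a = k, b = 0, cad = 0, role = "toy")
  spec <- structure(list(id = "toy", n_states = 3L, open_states = 3L,
                         edges = edges, egta = FALSE),
                    class = "jsmc_markov_spec")
  toy <- list(edges = edges, stationary = w / sum(w), spec = spec)

  # square-ish slow wave with exactly known rest/amplitude/frequency
  rest <- -60; amp <- 23; freq <- 6
  period <- 60000 / freq
  t <- seq(0, 180000, by = 10)
  phase <- (t %% period) / period
  shape <- sin(pi * pmin(pmax((phase - 0.05) / 0.4, 0), 1))^0.25
  v <- rest + amp * shape
  trace <- data.frame(t = t, V_m = v, Ca_free = 94e-6 +
                        156e-6 * (v - rest) / amp)
  for (cl in setdiff(trace_columns, names(trace))) trace[[cl]] <- 0
  trace <- trace[, trace_columns]
  attr(trace, "burn_in") <- 0
  attr(trace, "dt") <- 10
  attr(trace, "stride") <- 1L
  attr(trace, "protocol") <- "synthetic"
  class(trace) <- c("jsmc_trace", "data.frame")

  ops <- data.frame(V = stats::runif(20, -90, 20),
                    Na_i = stats::runif(20, 4, 20),
                    Ca_free = 10^stats::runif(20, -5, -3))

  list(toy_chain = toy,
       synthetic_trace = trace,
       synthetic_metrics = list(rest = rest, amplitude = amp,
                                freq_cpm = freq),
       operating_points = ops)
}
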