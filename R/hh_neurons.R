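# Single-neuron dynamics: two-compartment cortical PY/IN neurons and
# one-compartment thalamic TC/RE neurons with Hodgkin-Huxley kinetics.
# The production integrator lives in src/; the functions here expose the
# closed-form pieces (temperature scaling, gating relaxation, I_h
# activation) and a single-neuron front end to the compiled stepper.

#' Temperature scaling factor for gating kinetics
#'
#' `Q^((T - 23) / 10)`; all gating time constants are divided by this
#' factor.  With `Q = 2.3` and `T = 36` (deg C) the factor is 2.9529.
#'
#' @param Q dimensionless temperature coefficient, `> 0`.
#' @param T temperature in degrees Celsius.
#' @return dimensionless scaling factor.
#' @export
temperature_factor <- function(Q = 2.3, T = 36) {
  if (!is.numeric(Q) || any(Q <= 0)) stop("Q must be positive")
  Q^((T - 23) / 10)
}

#' Gating-variable state
#'
#' Bundles a gating variable with its voltage-dependent rate functions
#' `alpha(V)` and `beta(V)` (ms^-1).  Between voltage changes the
#' variable relaxes toward `x_inf = alpha/(alpha+beta)` with time
#' constant `tau = 1/((alpha+beta) * QT)`.
#'
#' @param x0 initial value in \[0, 1\].
#' @param alpha,beta rate functions of voltage (each `function(V)`, ms^-1).
#' @export
gating_state <- function(x0, alpha, beta) {
  stopifnot(is.function(alpha), is.function(beta), x0 >= 0, x0 <= 1)
  structure(list(x = x0, alpha = alpha, beta = beta), class = "gating_state")
}

#' Advance a gating variable by one step
#'
#' Exact exponential update of `dx/dt = -(x - x_inf)/tau` at fixed
#' voltage: `x <- x_inf + (x - x_inf) * exp(-dt/tau)` with
#' `tau = 1/((alpha+beta) * QT)` and `x_inf = alpha/(alpha+beta)`.
#'
#' @param state a [gating_state()].
#' @param V membrane voltage (mV).
#' @param dt time step (ms), `> 0`.
#' @param QT temperature factor (see [temperature_factor()]).
#' @return the updated `gating_state`.
#' @export
gating_step <- function(state, V, dt, QT = temperature_factor()) {
  stopifnot(inherits(state, "gating_state"), dt > 0)
  a <- state$alpha(V)
  b <- state$beta(V)
  if (a + b <= 0) stop("degenerate gating rates: alpha + beta must be positive")
  x_inf <- a / (a + b)
  tau <- 1 / ((a + b) * QT)
  state$x <- x_inf + (state$x - x_inf) * exp(-dt / tau)
  state
}

#' Steady-state activation of the h-current
#'
#' `m_inf(V) = 1 / (1 + exp((V + 75 + HA_gh) / 5.5))`.  The
#' hyperpolarization-activated mixed cation current is expressed in TC
#' neurons only; histamine level enters as the shift `HA_gh` (mV) of the
#' activation curve (lower histamine during sleep shifts the curve back
#' toward its unmodulated position).
#'
#' @param V membrane voltage (mV).
#' @param HA_gh activation-curve shift (mV).
#' @return activation in (0, 1), decreasing in `V`.
#' @export
ih_steady_state <- function(V, HA_gh = 0) {
  1 / (1 + exp((V + 75 + HA_gh) / 5.5))
}

#' Simulate an isolated model neuron
#'
#' Runs one neuron of the network model (disconnected, no minis) under a
#' DC current step, using the compiled fixed-step integrator.  Intended
#' for characterising intrinsic dynamics: resting state, f-I curves,
#' low-threshold rebound bursts.
#'
#' @param kind `"PY"`, `"IN"`, `"TC"`, or `"RE"`.
#' @param dc amplitude of the injected DC current (nA equivalent;
#'   positive = depolarizing).
#' @param dc_on,dc_off onset and offset of the current step (ms).
#' @param duration total simulated time (ms).
#' @param dt integration step (ms).
#' @param state arousal state name (`"awake"` or `"N3"`) or an
#'   [arousal_state()] object; sets the neuromodulatory scalars.
#' @param record_dt sampling interval of the voltage trace (ms).
#' @param params biophysical parameters (see [sim_params()]).
#' @return list with `trace` (data.frame: time, V — somatic voltage for
#'   cortical kinds) and `spikes` (numeric vector of spike times, ms).
#' @export
simulate_neuron <- function(kind = c("PY", "IN", "TC", "RE"),
                            dc = 0, dc_on = 0, dc_off = Inf,
                            duration = 1000, dt = 0.02,
                            state = "awake", record_dt = 0.5,
                            params = sim_params()) {
  kind <- match.arg(kind)
  if (is.character(state)) state <- arousal_state(state)
  stopifnot(inherits(state, "arousal_state"), dt > 0, duration > 0)
  res <- cpp_simulate_neuron(kind, as.numeric(dc), as.numeric(dc_on),
                             as.numeric(min(dc_off, duration)),
                             as.numeric(duration), as.numeric(dt),
                             state_scalars(state), as.numeric(record_dt),
                             params)
  if (any(!is.finite(res$V)))
    stop("numerical blow-up in single-neuron simulation (", kind, ")")
  list(trace = data.frame(time = res$t, V = res$V), spikes = res$spikes)
}
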