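# Synaptic kinetics and plasticity rules.
#
# The plastic layer of the model is the cortical PY->PY AMPA projection;
# everything here is written so the same closed-form rules drive both the
# compiled network core and the (slower, reference) R implementations used
# throughout the test-suite oracles.

#' STDP parameter set
#'
#' Parameters of the exponential spike-timing-dependent plasticity kernel
#' and its coupling to miniature-EPSP amplitudes.  Defaults give the
#' balanced rule used during testing and sleep; `phase = "training"`
#' halves the depression amplitude (`a_minus = 0.001`), biasing the rule
#' toward potentiation as during attentive wakefulness.  The biased-sleep
#' variants (`"ltd_biased"`, `"ltp_biased"`) perturb `a_plus` to
#' 0.0019 or 0.0021 while keeping `a_minus = 0.002`.
#'
#' @param a_plus maximal potentiation amplitude (dimensionless, applied
#'   as a fraction of `g_max`).
#' @param a_minus maximal depression amplitude.
#' @param tau_plus,tau_minus decay constants of the kernel (ms).
#' @param f coupling factor of STDP onto miniature-EPSP amplitudes.
#' @param g_max upper weight bound (uS).
#' @param phase convenience presets: `"balanced"`, `"training"`,
#'   `"ltd_biased"`, `"ltp_biased"`.
#' @return an object of class `stdp_params`.
#' @export
stdp_params <- function(a_plus = 0.002, a_minus = 0.002,
                        tau_plus = 20, tau_minus = 20,
                        f = 0.01, g_max = 0.15,
                        phase = c("balanced", "training",
                                  "ltd_biased", "ltp_biased")) {
  phase <- match.arg(phase)
  if (phase == "training") a_minus <- 0.001
  if (phase == "ltd_biased") a_plus <- 0.0019
  if (phase == "ltp_biased") a_plus <- 0.0021
  stopifnot(a_plus >= 0, a_minus >= 0, tau_plus > 0, tau_minus > 0,
            f >= 0, g_max > 0)
  structure(list(a_plus = a_plus, a_minus = a_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus,
                 f = f, g_max = g_max, phase = phase),
            class = "stdp_params")
}

#' STDP kernel
#'
#' Weight-change factor as a function of the post-minus-pre spike-time
#' difference: `A+ * exp(-|dt|/tau+)` for `dt > 0` and
#' `-A- * exp(-|dt|/tau-)` for `dt < 0`.  The measure-zero exact tie
#' `dt == 0` produces no update.
#'
#' @param delta_t post-minus-pre spike time difference(s), ms.
#' @param params an [stdp_params()] object.
#' @return dimensionless weight-change factor(s), same length as `delta_t`.
#' @export
stdp_kernel <- function(delta_t, params = stdp_params()) {
  stopifnot(inherits(params, "stdp_params"), is.numeric(delta_t))
  out <- numeric(length(delta_t))
  pos <- delta_t > 0
  neg <- delta_t < 0
  out[pos] <- params$a_plus * exp(-abs(delta_t[pos]) / params$tau_plus)
  out[neg] <- -params$a_minus * exp(-abs(delta_t[neg]) / params$tau_minus)
  out
}

#' Apply one STDP pairing to a synapse
#'
#' Updates the synaptic weight by `g_max * F(dt)` (clipped to
#' `[0, g_max]`) and the miniature-EPSP amplitude by
#' `f * a_py_py * F(dt)` (floored at 0), where `a_py_py` is the resting
#' mini amplitude of the PY->PY projection.
#'
#' @param weight current AMPA weight (uS), in `[0, g_max]`.
#' @param mini_amplitude current miniature-EPSP amplitude (uS).
#' @param delta_t post-minus-pre spike-time difference (ms).
#' @param params an [stdp_params()] object.
#' @param a_py_py baseline PY->PY mini conductance (uS).
#' @return list with elements `weight` and `mini_amplitude`.
#' @export
apply_stdp <- function(weight, mini_amplitude, delta_t,
                       params = stdp_params(), a_py_py = 0.03) {
  stopifnot(weight >= 0, weight <= params$g_max)
  dF <- stdp_kernel(delta_t, params)
  list(weight = min(max(weight + params$g_max * dF, 0), params$g_max),
       mini_amplitude = max(mini_amplitude + params$f * a_py_py * dF, 0))
}

#' Short-term depression parameters
#'
#' Resource-depletion model of intracortical AMPA synapses: a fraction
#' `U` of available resources is consumed per presynaptic action
#' potential and recovers with time constant `tau_rec`.
#'
#' @param U fraction of synaptic resources used per spike.
#' @param tau_rec recovery time constant (ms).
#' @export
depression_params <- function(U = 0.073, tau_rec = 700) {
  stopifnot(U >= 0, U < 1, tau_rec > 0)
  structure(list(U = U, tau_rec = tau_rec), class = "depression_params")
}

#' Available synaptic resources after a presynaptic event
#'
#' `D = 1 - (1 - D_i * (1 - U)) * exp(-elapsed / tau_rec)`, where `D_i`
#' is the resource level immediately before the previous event and
#' `elapsed` the time since it.  `D` recovers monotonically to 1.
#'
#' @param D_i resource level at the previous presynaptic event, in (0, 1].
#' @param elapsed time since the previous event (ms), `>= 0`.
#' @param params a [depression_params()] object.
#' @return resource level in (0, 1].
#' @export
depression_update <- function(D_i, elapsed, params = depression_params()) {
  stopifnot(all(D_i > 0), all(D_i <= 1))
  if (any(elapsed < 0)) stop("elapsed time must be non-negative")
  1 - (1 - D_i * (1 - params$U)) * exp(-elapsed / params$tau_rec)
}

#' Instantaneous miniature-release rate
#'
#' Rate (per ms) of the inhomogeneous Poisson process generating
#' spontaneous miniature PSPs, `t0` being the last presynaptic spike:
#' `(2 / (1 + exp(-(t - t0)/upsilon)) - 1) / 250`.  The rate is 0 at
#' `t = t0` and saturates at `1/250` per ms (4 Hz).
#'
#' @param t current time(s), ms, `>= t0`.
#' @param t0 time of the last presynaptic spike (ms).
#' @param upsilon shape parameter of the recovery sigmoid (ms scale).
#' @return release rate(s) in events/ms.
#' @export
mini_rate <- function(t, t0, upsilon = 30) {
  stopifnot(all(t >= t0))
  (2 / (1 + exp(-(t - t0) / upsilon)) - 1) / 250
}

#' Sample miniature-release times
#'
#' Draws release times of the mini process on `[t0, t_end]` by thinning
#' against the saturation rate `1/250` per ms, with hazard [mini_rate()].
#' Uses the current R random-number stream.
#'
#' @param t0 time of the last presynaptic spike (ms).
#' @param t_end end of the sampling window (ms).
#' @param upsilon sigmoid shape parameter.
#' @return numeric vector of release times (possibly empty).
#' @export
mini_release_times <- function(t0, t_end, upsilon = 30) {
  stopifnot(t_end >= t0)
  rmax <- 1 / 250
  out <- numeric(0)
  t <- t0
  repeat {
    t <- t + rexp(1, rmax)
    if (t > t_end) break
    if (runif(1) < mini_rate(t, t0, upsilon) / rmax) out <- c(out, t)
  }
  out
}

#' Postsynaptic current through a ligand-gated channel
#'
#' `I = scale * g_syn * O * (V - E_syn)` where `O` is the open-channel
#' fraction and `scale` the neuromodulatory gain (`ACh_AMPA` for AMPA,
#' `gamma_GABAA` for GABA-A; see [arousal_state()]).  Reversal
#' potentials: 0 mV for AMPA/NMDA, -70 mV for GABA-A.
#'
#' @param g_syn maximal synaptic conductance (uS).
#' @param O open-channel fraction in \[0, 1\].
#' @param V postsynaptic membrane potential (mV).
#' @param E_syn channel reversal potential (mV).
#' @param modulation_scale dimensionless neuromodulatory gain.
#' @return current (nA); negative values depolarize in the membrane
#'   equation convention used here (currents are subtracted).
#' @export
synaptic_current <- function(g_syn, O, V, E_syn = 0, modulation_scale = 1) {
  stopifnot(all(O >= 0), all(O <= 1))
  modulation_scale * g_syn * O * (V - E_syn)
}

#' Advance first-order channel kinetics through a presynaptic event train
#'
#' Reference implementation of the open-fraction dynamics used by the
#' network core: `O` decays exponentially with time constant `tau_decay`
#' and jumps by `release * (1 - O)` at each presynaptic release, where
#' `release` is the product of the synaptic weight (normalised by
#' `g_max`) and, when depression is enabled, the available resources at
#' the event.
#'
#' @param events sorted presynaptic event times (ms).
#' @param t_grid evaluation grid (ms), sorted.
#' @param tau_decay decay constant of the open fraction (ms).
#' @param weight synaptic weight (uS).
#' @param g_max normalising maximal conductance (uS).
#' @param depression `NULL` or a [depression_params()] object.
#' @return data.frame with columns `time` and `O`.
#' @export
advance_channel_kinetics <- function(events, t_grid, tau_decay = 2,
                                     weight = 0.1, g_max = 0.15,
                                     depression = NULL) {
  if (is.unsorted(events)) stop("presynaptic events must be time-sorted")
  O <- 0
  D <- 1
  t_last_ev <- -Inf
  t_prev <- min(c(events, t_grid), 0)
  out <- numeric(length(t_grid))
  ev <- 1
  for (k in seq_along(t_grid)) {
    tk <- t_grid[k]
    while (ev <= length(events) && events[ev] <= tk) {
      te <- events[ev]
      O <- O * exp(-(te - t_prev) / tau_decay)
      rel <- weight / g_max
      if (!is.null(depression)) {
        if (is.finite(t_last_ev)) D <- depression_update(D, te - t_last_ev, depression)
        rel <- rel * D
        t_last_ev <- te
      }
      O <- O + rel * (1 - O)
      t_prev <- te
      ev <- ev + 1
    }
    O <- O * exp(-(tk - t_prev) / tau_decay)
    t_prev <- tk
    out[k] <- O
  }
  data.frame(time = t_grid, O = out)
}
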