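# Arousal-state switching, stimulation schedules and experiment
# orchestration.

#' Arousal state (neuromodulation scalars)
#'
#' Bundles the neuromodulatory scaling constants of a named arousal
#' state.  Going from awake to N3 (slow-wave) sleep, GABA-A scaling
#' doubles (`gamma_gabaa_in` 0.22 -> 0.44 for IN-sourced synapses,
#' `gamma_gabaa_re` 0.6 -> 1.2 for RE-sourced), cortical AMPA scaling
#' rises 0.133 -> 0.4332 (`ach_ampa_py`, PY->PY) and thalamocortical
#' AMPA 0.6 -> 1.2 (`ach_ampa_tc`), the potassium-leak scale
#' (`ach_gkl_*`, reflecting reduced acetylcholine) rises, and the
#' histamine shift of the TC h-current activation curve (`ha_gh`, mV)
#' relaxes from -8 to 0.  The printed GABA/AMPA constants are fixed by
#' the model; the `ach_gkl_*` scales and `ha_gh` are calibrated so that
#' the network meets its dynamical contracts (awake asynchronous
#' firing; N3 slow oscillation below 1 Hz).
#'
#' @param name `"awake"` or `"N3"`.
#' @param ... named overrides of individual scalars.
#' @return an object of class `arousal_state`.
#' @export
arousal_state <- function(name = c("awake", "N3"), ...) {
  name <- match.arg(name)
  base <- if (name == "awake") {
    list(gamma_gabaa_in = 0.22, gamma_gabaa_re = 0.6,
         ach_ampa_py = 0.133, ach_ampa_tc = 0.6,
         ach_gkl_py = 0.6, ach_gkl_in = 0.6,
         ach_gkl_tc = 0.5, ach_gkl_re = 0.5,
         ha_gh = -8)
  } else {
    list(gamma_gabaa_in = 0.44, gamma_gabaa_re = 1.2,
         ach_ampa_py = 0.4332, ach_ampa_tc = 1.2,
         ach_gkl_py = 0.25, ach_gkl_in = 0.25,
         ach_gkl_tc = 2.5, ach_gkl_re = 1.0,
         ha_gh = 0)
  }
  ov <- list(...)
  bad <- setdiff(names(ov), names(base))
  if (length(bad)) stop("unknown arousal scalar(s): ", paste(bad, collapse = ", "))
  structure(c(list(name = name), modifyList(base, ov)),
            class = "arousal_state")
}

#' @rdname arousal_state
#' @param state an `arousal_state` object.
#' @return `state_scalars()`: the scalars as the flat numeric vector
#'   consumed by the compiled core.
#' @export
state_scalars <- function(state) {
  stopifnot(inherits(state, "arousal_state"))
  as.numeric(unlist(state[c("gamma_gabaa_in", "gamma_gabaa_re",
                            "ach_ampa_py", "ach_ampa_tc",
                            "ach_gkl_py", "ach_gkl_in",
                            "ach_gkl_tc", "ach_gkl_re", "ha_gh")]))
}

#' Biophysical simulation parameters
#'
#' All intrinsic-current conductances, synaptic kinetics, miniature-PSP
#' and short-term-depression constants of the network model, as a named
#' list.  Cortical conductances are absolute (uS, capacitance nF);
#' thalamic conductances are densities (mS/cm2 with 1 uF/cm2).  Any
#' entry can be overridden through the `params` field of
#' [experiment_config()].
#'
#' @param ... named overrides.
#' @return named list of parameters.
#' @export
sim_params <- function(...) {
  p <- list(
    # cortical PY dendrite / soma
    py_cm_d = 0.124, py_g_couple = 0.1,
    py_gna_d = 0.25, py_gnap_d = 0.002, py_gkm = 0.02, py_gkca = 0.03,
    py_ghva = 0.006, py_gkl = 0.004, py_gl = 0.0055,
    py_gna_s = 3.0, py_gk_s = 1.0, py_gnap_s = 0.003,
    # cortical IN (no persistent Na)
    in_cm_d = 0.124, in_g_couple = 0.1,
    in_gna_d = 0.25, in_gkm = 0.01, in_gkca = 0.03,
    in_ghva = 0.01, in_gkl = 0.0045, in_gl = 0.0055,
    in_gna_s = 2.5, in_gk_s = 1.0,
    # reversal potentials (mV)
    e_na = 50, e_k = -95, e_ca = 140, e_cl = -62, e_h = -40,
    # dendritic calcium pool (uM)
    ca_tau = 200, ca_inf = 0.01, ca_gain = 0.2,
    # thalamic TC / RE
    tc_cm = 1.0, tc_gna = 90, tc_gk = 12, tc_gt = 2.2, tc_gh = 0.02,
    tc_gkl = 0.014, tc_gl = 0.01, tc_el = -70, tc_vt = -50,
    re_cm = 1.0, re_gna = 100, re_gk = 10, re_gt = 2.3,
    re_gkl = 0.014, re_gl = 0.05, re_el = -70, re_vt = -55,
    # synaptic kinetics (ms) and reversals (mV)
    tau_ampa = 3, tau_nmda = 100, tau_gabaa = 7,
    gabab_tau_r = 90, gabab_tau_d = 160,
    e_ampa = 0, e_gabaa = -70, e_gabab = -95,
    mg_vhalf = -25, mg_k = 12.5,
    qt = temperature_factor(2.3, 36),
    # miniature PSPs (uS; upsilon in ms; ceiling rate per ms)
    mini_py_py = 0.03, mini_py_in = 0.02, mini_in_py = 0.02,
    mini_upsilon = 30, mini_max_rate = 1 / 250,
    # short-term depression of intracortical AMPA
    dep_U = 0.073, dep_tau = 700,
    # spike detection
    spike_thresh = 0, refrac = 2
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p <- modifyList(p, ov)
  }
  p
}

#' Sequence specification
#'
#' An ordered "word" of "letters", each letter naming a group of PY
#' neurons activated in order during training.
#'
#' @param label sequence label (e.g. `"S1"`).
#' @param groups named list of integer vectors of PY-local neuron ids
#'   (1-based); names are the letters, list order is activation order.
#' @param pulse_ms duration of each group's DC pulse (ms).
#' @param gap_ms delay between subsequent group pulses (ms).
#' @param period_ms trial period (ms).
#' @return an object of class `sequence_spec`.
#' @export
sequence_spec <- function(label, groups, pulse_ms = 10, gap_ms = 5,
                          period_ms = 1000) {
  stopifnot(is.list(groups), length(groups) >= 2, !is.null(names(groups)))
  if (anyDuplicated(names(groups))) stop("duplicate letters in sequence")
  structure(list(label = label, groups = groups, letters = names(groups),
                 pulse_ms = pulse_ms, gap_ms = gap_ms,
                 period_ms = period_ms),
            class = "sequence_spec")
}

#' Reverse a sequence (same neurons, opposite activation order)
#' @param seq a [sequence_spec()].
#' @param label label of the reversed sequence (default appends `*`).
#' @export
reverse_sequence <- function(seq, label = paste0(seq$label, "*")) {
  sequence_spec(label, rev(seq$groups), seq$pulse_ms, seq$gap_ms,
                seq$period_ms)
}

#' Full-scale default sequences
#'
#' S1: groups A-E over PY neurons 201-250 (ids 1-based); S2: the
#' non-linear word W-V-X-Y-Z over PY 351-400; S1*: S1 reversed.
#' @return named list of [sequence_spec()] objects.
#' @export
default_sequences <- function() {
  s1 <- sequence_spec("S1", list(A = 201:210, B = 211:220, C = 221:230,
                                 D = 231:240, E = 241:250))
  s2 <- sequence_spec("S2", list(W = 361:370, V = 351:360, X = 371:380,
                                 Y = 381:390, Z = 391:400))
  list(S1 = s1, S2 = s2, `S1*` = reverse_sequence(s1))
}

.empty_schedule <- function() {
  data.frame(onset = numeric(0), offset = numeric(0),
             letter = character(0), seq = character(0),
             trial = integer(0), group_index = integer(0))
}

.schedule_row <- function(seq, k, onset) {
  data.frame(onset = onset, offset = onset + seq$pulse_ms,
             letter = seq$letters[k], seq = seq$label,
             trial = NA_integer_, group_index = k)
}

#' Sequence-training stimulation schedule
#'
#' Each trial activates the sequence's groups in order with a
#' `pulse_ms` DC pulse per group and `gap_ms` between pulse onsets'
#' ends (onset-to-onset spacing `pulse_ms + gap_ms`); trials repeat
#' every `period_ms`.
#'
#' @param seq a [sequence_spec()].
#' @param t0 schedule start time (ms).
#' @param duration schedule duration (ms), at least one trial period.
#' @return data.frame with one row per group pulse: `onset`, `offset`,
#'   `letter`, `seq`, `trial`, `group_index`.
#' @export
training_schedule <- function(seq, t0 = 0, duration = seq$period_ms) {
  stopifnot(inherits(seq, "sequence_spec"))
  if (duration < seq$period_ms)
    stop("duration must cover at least one trial period")
  trials <- floor(duration / seq$period_ms)
  step <- seq$pulse_ms + seq$gap_ms
  out <- do.call(rbind, lapply(seq_len(trials), function(tr) {
    base <- t0 + (tr - 1) * seq$period_ms
    rows <- do.call(rbind, lapply(seq_along(seq$groups), function(k)
      .schedule_row(seq, k, base + (k - 1) * step)))
    rows$trial <- tr
    rows
  }))
  rownames(out) <- NULL
  out
}

#' First-letter test schedule
#'
#' One pulse to the sequence's first group per trial period; recall of
#' the remaining letters is read from the network response.
#' @inheritParams training_schedule
#' @export
test_schedule <- function(seq, t0 = 0, duration = seq$period_ms) {
  stopifnot(inherits(seq, "sequence_spec"))
  if (duration < seq$period_ms)
    stop("duration must cover at least one trial period")
  trials <- floor(duration / seq$period_ms)
  out <- do.call(rbind, lapply(seq_len(trials), function(tr) {
    r <- .schedule_row(seq, 1L, t0 + (tr - 1) * seq$period_ms)
    r$trial <- tr
    r
  }))
  rownames(out) <- NULL
  out
}

#' Per-letter probe schedule
#'
#' Stimulates every group of the sequence independently, one group per
#' trial period, repeated `repeats` times; used for response-delay
#' analysis.
#' @inheritParams training_schedule
#' @param repeats number of probe repetitions per group.
#' @export
probe_schedule <- function(seq, t0 = 0, repeats = 1) {
  stopifnot(inherits(seq, "sequence_spec"))
  G <- length(seq$groups)
  out <- do.call(rbind, lapply(seq_len(repeats), function(r) {
    rows <- do.call(rbind, lapply(seq_len(G), function(k) {
      rr <- .schedule_row(seq, k,
                          t0 + ((r - 1) * G + (k - 1)) * seq$period_ms)
      rr$trial <- (r - 1L) * G + k
      rr
    }))
    rows
  }))
  rownames(out) <- NULL
  out
}

#' Interleaved training schedule
#'
#' Alternating single training trials of two sequences (odd trials
#' `seqA`, even trials `seqB`), time-sorted and non-overlapping.
#' @param seqA,seqB [sequence_spec()] objects.
#' @inheritParams training_schedule
#' @export
interleaved_schedule <- function(seqA, seqB, t0 = 0,
                                 duration = 2 * seqA$period_ms) {
  stopifnot(inherits(seqA, "sequence_spec"), inherits(seqB, "sequence_spec"),
            seqA$period_ms == seqB$period_ms)
  trials <- floor(duration / seqA$period_ms)
  step_a <- seqA$pulse_ms + seqA$gap_ms
  step_b <- seqB$pulse_ms + seqB$gap_ms
  out <- do.call(rbind, lapply(seq_len(trials), function(tr) {
    sq <- if (tr %% 2 == 1) seqA else seqB
    stp <- if (tr %% 2 == 1) step_a else step_b
    base <- t0 + (tr - 1) * sq$period_ms
    rows <- do.call(rbind, lapply(seq_along(sq$groups), function(k)
      .schedule_row(sq, k, base + (k - 1) * stp)))
    rows$trial <- tr
    rows
  }))
  rownames(out) <- NULL
  out[order(out$onset), , drop = FALSE]
}

#' Experiment phase
#'
#' @param kind `"test"`, `"train"`, `"interleaved-train"`, `"probe"`,
#'   `"sleep"`, or `"spontaneous"` (awake, no stimulation).
#' @param seq sequence label (character; two labels for interleaved
#'   training); `NULL` for sleep/spontaneous.
#' @param duration_s phase duration in seconds of biological time.
#' @param label phase label (defaults to `kind-seq`).
#' @param stdp STDP preset for the phase (see [stdp_params()]);
#'   defaults: `"training"` during training, `"balanced"` otherwise.
#' @param stdp_enabled logical; STDP can be switched off entirely.
#' @param stim_amp optional phase-specific stimulation amplitude (nA)
#'   overriding the configuration default.  Training pulses must fire
#'   their group against the feed-forward inhibition of the preceding
#'   pulse and therefore need a larger amplitude than the single
#'   first-letter test pulse.
#' @export
phase <- function(kind = c("test", "train", "interleaved-train", "probe",
                           "sleep", "spontaneous"),
                  seq = NULL, duration_s = 10, label = NULL,
                  stdp = NULL, stdp_enabled = TRUE, stim_amp = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("sleep", "spontaneous") && !is.null(seq))
    stop("no stimulation is delivered in ", kind, " phases")
  if (kind %in% c("test", "train", "probe") && is.null(seq))
    stop(kind, " phase requires a sequence label")
  if (kind == "interleaved-train" && length(seq) != 2)
    stop("interleaved training requires two sequence labels")
  if (is.null(stdp))
    stdp <- if (kind %in% c("train", "interleaved-train")) "training" else "balanced"
  state <- if (kind == "sleep") "N3" else "awake"
  if (is.null(label))
    label <- if (is.null(seq)) kind else paste(kind, paste(seq, collapse = "+"), sep = "-")
  structure(list(kind = kind, seq = seq, duration_s = duration_s,
                 state = state, stdp = stdp, stdp_enabled = stdp_enabled,
                 label = label, stim_amp = stim_amp),
            class = "experiment_phase")
}

#' Experiment configuration
#'
#' The single source of truth for a run: network layout and
#' connectivity, initial weights, sequences, ordered phases, integrator
#' settings and seeds.
#'
#' @param layout a [population_layout()].
#' @param projections projection table ([default_projections()]).
#' @param sequences named list of [sequence_spec()] objects.
#' @param phases list of [phase()] objects, executed in order.
#' @param weights list: `mean`, `sd`, `g_max` of the initial Gaussian
#'   PY->PY weights (uS).
#' @param dt integration step (ms).
#' @param seed master integer seed; connectivity, weights, initial
#'   conditions and the mini processes draw sub-seeds from it.
#' @param stim_amp amplitude of the training/testing DC pulses (nA).
#' @param params named overrides of [sim_params()].
#' @param states optional named list of [arousal_state()] objects
#'   (`awake`, `N3`) overriding the default neuromodulation constants.
#' @param warmup_s settling time (s) simulated before the first phase in
#'   that phase's arousal state, with plasticity off and no recording,
#'   so that phase statistics start from a settled network.
#' @param stdp_g_max upper bound of plastic weights; defaults to
#'   `weights$g_max`.
#' @param initial_weights optional `weight_matrix` (e.g. a snapshot of a
#'   previous run loaded with [load_weights()]) used instead of a fresh
#'   Gaussian initialisation; its mask must match the connectivity
#'   drawn from the seed.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(layout = population_layout(),
                              projections = default_projections(),
                              sequences = default_sequences(),
                              phases = list(),
                              weights = list(mean = 0.075, sd = 0.0075,
                                             g_max = 0.15),
                              dt = 0.02, seed = 1L, stim_amp = 0.45,
                              params = list(), states = list(),
                              stdp_g_max = NULL, warmup_s = 0.5,
                              initial_weights = NULL) {
  stopifnot(inherits(layout, "population_layout"), dt > 0)
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > 2^28) stop("seed must be a modest integer")
  for (ph in phases) stopifnot(inherits(ph, "experiment_phase"))
  for (sq in sequences) {
    ids <- unlist(sq$groups)
    if (any(ids < 1) || any(ids > layout$n[["PY"]]))
      stop("sequence ", sq$label, " references neurons outside the PY population")
  }
  if (is.null(stdp_g_max)) stdp_g_max <- weights$g_max
  st <- list(awake = arousal_state("awake"), N3 = arousal_state("N3"))
  for (nm in names(states)) {
    stopifnot(inherits(states[[nm]], "arousal_state"))
    st[[nm]] <- states[[nm]]
  }
  structure(list(layout = layout, projections = projections,
                 sequences = sequences, phases = phases,
                 weights = weights, dt = dt, seed = seed,
                 stim_amp = stim_amp, params = do.call(sim_params, params),
                 states = st, stdp_g_max = stdp_g_max,
                 warmup_s = warmup_s, initial_weights = initial_weights),
            class = "experiment_config")
}

# Build the per-phase stimulation schedule (data.frame of group pulses)
phase_schedule <- function(config, ph, t0) {
  dur <- ph$duration_s * 1000
  if (ph$kind %in% c("sleep", "spontaneous")) return(.empty_schedule())
  if (ph$kind == "interleaved-train") {
    sa <- config$sequences[[ph$seq[1]]]
    sb <- config$sequences[[ph$seq[2]]]
    return(interleaved_schedule(sa, sb, t0, dur))
  }
  sq <- config$sequences[[ph$seq]]
  if (is.null(sq)) stop("unknown sequence label: ", ph$seq)
  switch(ph$kind,
         train = training_schedule(sq, t0, dur),
         test = test_schedule(sq, t0, dur),
         probe = probe_schedule(sq, t0,
                                repeats = max(1, floor(dur / (length(sq$groups) * sq$period_ms)))))
}

# Expand a group-pulse schedule into per-neuron stimulus rows for the core
expand_stim <- function(config, sched, amp = NULL) {
  if (is.null(amp)) amp <- config$stim_amp
  if (!nrow(sched))
    return(list(neuron = integer(0), onset = numeric(0),
                offset = numeric(0), amp = numeric(0)))
  rows <- lapply(seq_len(nrow(sched)), function(r) {
    sq <- config$sequences[[sched$seq[r]]]
    ids <- sq$groups[[sched$group_index[r]]]
    data.frame(neuron = ids - 1L, onset = sched$onset[r],
               offset = sched$offset[r], amp = amp)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$onset), , drop = FALSE]
  list(neuron = as.integer(out$neuron), onset = out$onset,
       offset = out$offset, amp = out$amp)
}

# Assemble the compiled-core projection list
.core_projections <- function(config, conn, wm) {
  layout <- config$layout
  popidx <- c(PY = 0L, IN = 1L, TC = 2L, RE = 3L)
  pr <- config$projections
  out <- vector("list", nrow(pr))
  for (k in seq_len(nrow(pr))) {
    e <- conn$edges[[pr$name[k]]]
    src_local <- e$src - layout$range[[pr$source[k]]][1]
    dst_local <- e$dst - layout$range[[pr$target[k]]][1]
    plastic <- pr$plastic[k]
    w <- if (plastic) wm$w[cbind(src_local + 1, dst_local + 1)]
         else rep(pr$strength[k], nrow(e))
    depressing <- pr$source[k] == "PY" && pr$receptor[k] == "AMPA" &&
      pr$target[k] %in% c("PY", "IN")
    minis <- pr$name[k] %in% c("PY_PY_AMPA", "PY_IN_AMPA", "IN_PY_GABAA")
    mini_amp <- switch(pr$name[k],
                       PY_PY_AMPA = config$params$mini_py_py,
                       PY_IN_AMPA = config$params$mini_py_in,
                       IN_PY_GABAA = config$params$mini_in_py, 0)
    gain <- if ("gain" %in% names(pr)) pr$gain[k] else 1
    out[[k]] <- list(name = pr$name[k],
                     src_pop = popidx[[pr$source[k]]],
                     dst_pop = popidx[[pr$target[k]]],
                     receptor = pr$receptor[k],
                     plastic = plastic, depressing = depressing,
                     minis = minis, mini_amp = mini_amp,
                     gain = gain,
                     src = as.integer(src_local), dst = as.integer(dst_local),
                     w = as.numeric(w))
  }
  out
}

.stdp_list <- function(config, ph) {
  sp <- stdp_params(g_max = config$stdp_g_max, phase = ph$stdp)
  list(enabled = isTRUE(ph$stdp_enabled),
       a_plus = sp$a_plus, a_minus = sp$a_minus,
       tau_plus = sp$tau_plus, tau_minus = sp$tau_minus,
       f = sp$f, g_max = sp$g_max, mini_base = config$params$mini_py_py)
}

#' Run an experiment
#'
#' Builds the network from the configuration, then executes the
#' configured phases in order on a single persistent network state,
#' recording all spikes and snapshotting the plastic weight matrix
#' after every weight-relevant phase (training, interleaved training,
#' sleep).  Fully deterministic given the configuration seed.
#'
#' @param config an [experiment_config()].
#' @param record_v optional vector of global neuron ids (1-based) whose
#'   voltage is recorded at 1 ms resolution (for diagnostics).
#' @return object of class `experiment_result`: list with `spikes`
#'   (named list of per-phase [spike_record()] data.frames, absolute
#'   times in ms), `snapshots` (named list of `weight_matrix`),
#'   `schedules` (per-phase stimulation tables), `conn`, `config`,
#'   and `log` (per-phase timing/event counts).
#' @export
run_experiment <- function(config, record_v = integer(0)) {
  stopifnot(inherits(config, "experiment_config"))
  conn <- build_connectivity(config$layout, config$projections,
                             seed = config$seed * 13L + 1L)
  mask <- pypy_mask(conn)
  wm0 <- if (!is.null(config$initial_weights)) {
    if (!identical(which(config$initial_weights$mask), which(mask)))
      stop("initial_weights mask does not match the drawn connectivity")
    config$initial_weights
  } else {
    init_weights(mask, mean = config$weights$mean,
                 sd = config$weights$sd, g_max = config$weights$g_max,
                 seed = config$seed * 13L + 2L,
                 meta = list(phase = "baseline", seed = config$seed))
  }
  rng <- local_rng(config$seed * 13L + 3L)
  jit <- rng$rnorm(config$layout$total, 0, 2)
  ptr <- cpp_network_create(as.integer(config$layout$n),
                            .core_projections(config, conn, wm0),
                            config$params, jit,
                            config$seed * 13L + 4L)
  phase_labels <- make.unique(vapply(config$phases, `[[`, "", "label"))
  spikes <- list(); snapshots <- list(baseline = wm0)
  schedules <- list()
  log <- data.frame(phase = character(0), kind = character(0),
                    t_start = numeric(0), duration_s = numeric(0),
                    n_stim_events = integer(0), n_spikes = integer(0),
                    wall_s = numeric(0))
  t_now <- 0
  if (length(config$phases) && config$warmup_s > 0) {
    ph1 <- config$phases[[1]]
    wres <- cpp_network_run(ptr, config$warmup_s * 1000, config$dt,
                            state_scalars(config$states[[ph1$state]]),
                            list(enabled = FALSE, a_plus = 0, a_minus = 0,
                                 tau_plus = 20, tau_minus = 20, f = 0,
                                 g_max = config$stdp_g_max,
                                 mini_base = config$params$mini_py_py),
                            list(neuron = integer(0), onset = numeric(0),
                                 offset = numeric(0), amp = numeric(0)),
                            integer(0), 1.0)
    t_now <- wres$t_now
  }
  for (i in seq_along(config$phases)) {
    ph <- config$phases[[i]]
    lab <- phase_labels[i]
    sched <- phase_schedule(config, ph, t_now)
    stim <- expand_stim(config, sched, ph$stim_amp)
    mod <- state_scalars(config$states[[ph$state]])
    wall <- system.time(
      res <- cpp_network_run(ptr, ph$duration_s * 1000, config$dt, mod,
                             .stdp_list(config, ph), stim,
                             as.integer(record_v - 1L), 1.0)
    )[["elapsed"]]
    rec <- spike_record(res$spike_t, res$spike_id + 1L, config$layout,
                        phase = lab, t_start = t_now,
                        t_end = t_now + ph$duration_s * 1000)
    if (length(record_v)) {
      attr(rec, "voltage") <- matrix(res$v, ncol = length(record_v),
                                     byrow = TRUE,
                                     dimnames = list(NULL, record_v))
      attr(rec, "voltage_t") <- res$v_t
    }
    spikes[[lab]] <- rec
    schedules[[lab]] <- sched
    cw <- cpp_get_weights(ptr)
    W <- matrix(0, nrow(mask), ncol(mask))
    W[cbind(cw$src + 1L, cw$dst + 1L)] <- cw$w
    snap_lab <- paste0("post-", switch(ph$kind,
                       sleep = "sleep",
                       train = paste(ph$seq, collapse = "+"),
                       `interleaved-train` = paste(ph$seq, collapse = "+"),
                       lab))
    snap_lab <- make.unique(c(names(snapshots), snap_lab))[length(snapshots) + 1]
    snapshots[[snap_lab]] <- weight_matrix(mask, pmin(pmax(W, 0), config$stdp_g_max),
                                           g_max = config$stdp_g_max,
                                           phase = snap_lab, time = res$t_now,
                                           seed = config$seed)
    log <- rbind(log, data.frame(phase = lab, kind = ph$kind,
                                 t_start = t_now, duration_s = ph$duration_s,
                                 n_stim_events = nrow(sched),
                                 n_spikes = length(res$spike_t),
                                 wall_s = wall))
    t_now <- res$t_now
  }
  structure(list(spikes = spikes, snapshots = snapshots,
                 schedules = schedules, conn = conn, config = config,
                 log = log),
            class = "experiment_result")
}

#' Calibrate the stimulation amplitude
#'
#' Bisects for the smallest DC amplitude that makes an isolated PY
#' neuron spike during every pulse of a short awake-state pulse train,
#' then applies a safety factor.  The training pulses must activate a
#' group reliably without being so strong as to distort the dynamics.
#'
#' @param pulse_ms pulse width (ms).
#' @param safety multiplicative head-room on the threshold amplitude.
#' @param lo,hi bracketing amplitudes (nA).
#' @param tol bisection tolerance (nA).
#' @return calibrated amplitude (nA).
#' @export
calibrate_stim_amplitude <- function(pulse_ms = 10, safety = 1.5,
                                     lo = 0.01, hi = 5, tol = 0.01) {
  spikes_at <- function(amp) {
    r <- simulate_neuron("PY", dc = amp, dc_on = 200, dc_off = 200 + pulse_ms,
                         duration = 250, dt = 0.02, state = "awake")
    sum(r$spikes > 200 & r$spikes <= 200 + pulse_ms + 3) >= 1
  }
  if (!spikes_at(hi)) stop("upper bracket does not elicit a spike")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  hi * safety
}
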