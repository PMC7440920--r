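# Reduced-scale preset experiments.
#
# The desk-scale network divides every population by five
# (100 PY / 20 IN / 20 TC / 20 RE) while keeping the sequence geometry
# of the full model: groups of 10 PY neurons and the PY->PY radius of
# 20, so each neuron still reaches the two flanking letter groups.
# Cross-population radii are rescaled to the reduced target sizes while
# preserving full topographic coverage.

#' Reduced-scale population layout
#' @param factor integer reduction factor applied to every population.
#' @export
reduced_layout <- function(factor = 5) {
  population_layout(n_py = 500 / factor, n_in = 100 / factor,
                    n_tc = 100 / factor, n_re = 100 / factor)
}

#' Reduced-scale projection table
#'
#' [default_projections()] with radii adapted to the reduced layout:
#' the intracortical radii keep their full-scale values (the sequence
#' groups keep their full-scale size), thalamic and thalamocortical
#' radii shrink with their target populations but never below full
#' topographic coverage.
#' @inheritParams default_projections
#' @export
reduced_projections <- function(strengths = NULL, gains = NULL) {
  default_projections(
    radii = c(TC_RE_AMPA = 2, RE_TC_GABAA = 2, RE_TC_GABAB = 2,
              RE_RE_GABAA = 1, PY_PY_AMPA = 20, PY_PY_NMDA = 5,
              PY_IN_AMPA = 1, PY_IN_NMDA = 1, IN_PY_GABAA = 15,
              TC_PY_AMPA = 3, TC_IN_AMPA = 1, PY_TC_AMPA = 2,
              PY_RE_AMPA = 2),
    strengths = strengths, gains = gains)
}

#' Reduced-scale sequences
#'
#' S1: letters A-E, groups of 10 PY neurons over the region 26-75;
#' S1*: the same neurons in reverse order; S2 (for the two-region
#' protocol): smaller 5-neuron groups over the region 76-100 so that
#' the two trained regions are disjoint.
#' @export
reduced_sequences <- function() {
  s1 <- sequence_spec("S1", list(A = 26:35, B = 36:45, C = 46:55,
                                 D = 56:65, E = 66:75))
  s2 <- sequence_spec("S2", list(W = 81:85, V = 76:80, X = 86:90,
                                 Y = 91:95, Z = 96:100))
  list(S1 = s1, S2 = s2, `S1*` = reverse_sequence(s1))
}

#' Preset experiment configurations
#'
#' Named reduced-scale protocols:
#' \describe{
#'   \item{`"n3-spontaneous"`}{N3 sleep, no stimulation — slow
#'     oscillation between Up and Down states.}
#'   \item{`"awake-spontaneous"`}{awake, no stimulation — asynchronous
#'     irregular firing.}
#'   \item{`"sequence-overlap"`}{baseline tests, S1 training, tests,
#'     S1* training (same neurons, reversed), tests, N3 sleep, tests —
#'     the interference/consolidation protocol.}
#'   \item{`"two-region"`}{S1 and S2 trained in disjoint regions,
#'     then sleep.}
#'   \item{`"interleaved"`}{alternating S1/S1* training instead of
#'     sleep.}
#' }
#'
#' @param name preset name.
#' @param seed master seed.
#' @param durations optional named list overriding phase durations (s):
#'   `test`, `train1`, `train2`, `sleep`.
#' @param projections,sequences optional overrides of the reduced-scale
#'   defaults.
#' @param stim_amp_train amplitude (nA) of the training pulses (test
#'   pulses use the configuration default `stim_amp`).  A second
#'   element, when given, sets the amplitude of the second (interfering)
#'   training phase: that phase acts on an already-potentiated region,
#'   where slightly weaker pulses still activate every group reliably.
#' @param ... passed to [experiment_config()].
#' @return an [experiment_config()].
#' @export
preset_config <- function(name = c("n3-spontaneous", "awake-spontaneous",
                                   "sequence-overlap", "two-region",
                                   "interleaved"),
                          seed = 1, durations = list(),
                          projections = reduced_projections(),
                          sequences = reduced_sequences(),
                          stim_amp_train = c(0.7, 0.6), ...) {
  name <- tryCatch(match.arg(name),
                   error = function(e)
                     stop("unknown preset '", name[1], "'; available: ",
                          "n3-spontaneous, awake-spontaneous, ",
                          "sequence-overlap, two-region, interleaved"))
  d <- modifyList(list(test = 15, train1 = 100, train2 = 100, sleep = 30),
                  durations)
  phases <- switch(
    name,
    "n3-spontaneous" = list(phase("sleep", duration_s = d$sleep)),
    "awake-spontaneous" = list(phase("spontaneous", duration_s = d$test)),
    "sequence-overlap" = list(
      phase("test", "S1", d$test, label = "test-S1-baseline"),
      phase("test", "S1*", d$test, label = "test-S1s-baseline"),
      phase("train", "S1", d$train1, stim_amp = stim_amp_train[1]),
      phase("test", "S1", d$test, label = "test-S1-postS1"),
      phase("test", "S1*", d$test, label = "test-S1s-postS1"),
      phase("train", "S1*", d$train2, stim_amp = stim_amp_train[length(stim_amp_train)]),
      phase("test", "S1", d$test, label = "test-S1-postS1s"),
      phase("test", "S1*", d$test, label = "test-S1s-postS1s"),
      phase("sleep", duration_s = d$sleep),
      phase("test", "S1", d$test, label = "test-S1-postsleep"),
      phase("test", "S1*", d$test, label = "test-S1s-postsleep")),
    "two-region" = list(
      phase("test", "S1", d$test, label = "test-S1-baseline"),
      phase("test", "S2", d$test, label = "test-S2-baseline"),
      phase("train", "S1", d$train1, stim_amp = stim_amp_train[1]),
      phase("test", "S1", d$test, label = "test-S1-postS1"),
      phase("train", "S2", d$train1, stim_amp = stim_amp_train[1]),
      phase("test", "S2", d$test, label = "test-S2-postS2"),
      phase("sleep", duration_s = d$sleep),
      phase("test", "S1", d$test, label = "test-S1-postsleep"),
      phase("test", "S2", d$test, label = "test-S2-postsleep")),
    "interleaved" = list(
      phase("test", "S1", d$test, label = "test-S1-baseline"),
      phase("interleaved-train", c("S1", "S1*"), d$train1 + d$train2, stim_amp = stim_amp_train[1]),
      phase("test", "S1", d$test, label = "test-S1-post"),
      phase("test", "S1*", d$test, label = "test-S1s-post")))
  experiment_config(layout = reduced_layout(),
                    projections = projections,
                    sequences = sequences,
                    phases = phases, seed = seed, ...)
}
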