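test_that("arousal states carry the neuromodulation constants", {
  aw <- arousal_state("awake")
  n3 <- arousal_state("N3")
  expect_equal(aw$gamma_gabaa_in, 0.22)
  expect_equal(n3$gamma_gabaa_in, 0.44)
  expect_equal(aw$ach_ampa_py, 0.133)
  expect_equal(n3$ach_ampa_py, 0.4332)
  # scaling ratios of the four synaptic constants: 2.0 everywhere except
  # the cortical AMPA gain, which more than triples
  expect_equal(n3$gamma_gabaa_in / aw$gamma_gabaa_in, 2.0)
  expect_equal(n3$gamma_gabaa_re / aw$gamma_gabaa_re, 2.0)
  expect_equal(n3$ach_ampa_tc / aw$ach_ampa_tc, 2.0)
  expect_equal(n3$ach_ampa_py / aw$ach_ampa_py, 3.258, tolerance = 1e-3)
  expect_error(arousal_state("rem"))
  expect_error(arousal_state("awake", nonsense = 1), "unknown")
  expect_length(state_scalars(aw), 9)
})

test_that("training schedules tile trials with the 10 ms / 5 ms pulse geometry", {
  sq <- reduced_sequences()$S1
  sch <- training_schedule(sq, t0 = 0, duration = 10e3)
  expect_equal(max(sch$trial), 10)
  one <- sch[sch$trial == 1, ]
  expect_equal(one$onset, (0:4) * 15)
  expect_equal(one$offset - one$onset, rep(10, 5))
  # stimulation spans 4*15 + 10 = 70 ms of each 1 s trial
  expect_equal(max(one$offset), 70)
  # reversed word: same timing, reversed letters
  rev_sch <- training_schedule(reverse_sequence(sq), 0, 10e3)
  expect_equal(rev_sch$letter[rev_sch$trial == 1], rev(one$letter))
  expect_error(training_schedule(sq, 0, 500), "one trial")
})

test_that("test schedules pulse only the first letter once per trial", {
  sq <- reduced_sequences()$S1
  sch <- test_schedule(sq, t0 = 0, duration = 7e3)
  expect_equal(nrow(sch), 7)
  expect_true(all(sch$letter == "A"))
  # first letter of the reversed word is the last letter of the original
  rs <- test_schedule(reverse_sequence(sq), 0, 3e3)
  expect_true(all(rs$letter == "E"))
})

test_that("probe schedules stimulate every group alone and interleaving alternates", {
  sq <- reduced_sequences()$S1
  pb <- probe_schedule(sq, t0 = 0, repeats = 2)
  expect_equal(nrow(pb), 10)
  expect_equal(pb$letter, rep(c("A", "B", "C", "D", "E"), 2))
  expect_true(all(diff(pb$onset) >= sq$period_ms))

  il <- interleaved_schedule(sq, reverse_sequence(sq), 0, 10e3)
  first_letters <- sapply(split(il, il$trial), function(d) d$letter[which.min(d$onset)])
  expect_equal(unname(first_letters[as.character(1:10)]),
               rep(c("A", "E"), 5))
  n_a <- sum(il$seq == "S1") / 5
  n_b <- sum(il$seq == "S1*") / 5
  expect_lte(abs(n_a - n_b), 1)
  expect_false(is.unsorted(il$onset))
  expect_true(all(il$offset[-nrow(il)] <= il$onset[-1] + 1e-9))
})

test_that("phase validation enforces the protocol rules", {
  expect_error(phase("sleep", seq = "S1"), "no stimulation")
  expect_error(phase("train"), "sequence label")
  expect_error(phase("interleaved-train", seq = "S1"), "two sequence")
  expect_equal(phase("train", "S1")$stdp, "training")
  expect_equal(phase("test", "S1")$stdp, "balanced")
  expect_equal(phase("sleep")$state, "N3")
  expect_equal(phase("test", "S1")$state, "awake")
})

test_that("experiments are bit-reproducible given the seed", {
  cfg <- preset_config("awake-spontaneous", seed = 21,
                       durations = list(test = 2), dt = 0.05,
                       warmup_s = 0.1)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(as.data.frame(r1$spikes[[1]]), as.data.frame(r2$spikes[[1]]))
  expect_identical(r1$snapshots[[2]]$w, r2$snapshots[[2]]$w)
  r3 <- run_experiment(preset_config("awake-spontaneous", seed = 22,
                                     durations = list(test = 2), dt = 0.05,
                                     warmup_s = 0.1))
  expect_false(identical(as.data.frame(r1$spikes[[1]]),
                         as.data.frame(r3$spikes[[1]])))
})

test_that("the interference protocol emits the canonical snapshot labels", {
  cfg <- preset_config("sequence-overlap", seed = 2, dt = 0.05,
                       durations = list(test = 1, train1 = 1, train2 = 1,
                                        sleep = 1), warmup_s = 0)
  res <- run_experiment(cfg)
  snaps <- names(res$snapshots)
  expect_equal(snaps[1], "baseline")
  expect_true(all(c("post-S1", "post-S1*", "post-sleep") %in% snaps))
  # training/sleep snapshots appear in protocol order
  core <- snaps[snaps %in% c("baseline", "post-S1", "post-S1*", "post-sleep")]
  expect_equal(core, c("baseline", "post-S1", "post-S1*", "post-sleep"))
  # sleep phases deliver no stimulus events
  expect_equal(nrow(res$schedules[["sleep"]]), 0)
  # zero-duration sleep reproduces the no-sleep ablation
  cfg0 <- preset_config("sequence-overlap", seed = 2, dt = 0.05,
                        durations = list(test = 1, train1 = 1, train2 = 1,
                                         sleep = 0), warmup_s = 0)
  res0 <- run_experiment(cfg0)
  expect_equal(nrow(res0$spikes[["sleep"]]), 0)
})

test_that("unknown presets and sequences are rejected with guidance", {
  expect_error(preset_config("fig999"), "available")
  expect_error(experiment_config(phases = list(phase("test", "nope"))),
               NA)  # config constructs; the error surfaces at run time
  cfg <- preset_config("awake-spontaneous", durations = list(test = 1))
  cfg$phases <- list(phase("test", "nope", 1))
  expect_error(run_experiment(cfg), "unknown sequence")
})
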