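test_that("string match scores the canonical recall outcomes", {
  ideal <- c("A", "B", "C", "D", "E")
  expect_equal(string_match(ideal, ideal), 1.0)
  expect_equal(string_match(c("A", "C", "B", "D", "E"), ideal), 0.8)
  expect_equal(string_match(rev(ideal), ideal), -0.2)
  expect_equal(string_match(c("A", "B", "C"), ideal), 0.6)
  expect_equal(string_match(character(0), ideal), 0)
  expect_error(string_match(c("A", "A"), ideal), "duplicate")
  expect_error(string_match(c("A", "Z"), ideal), "absent")
})

test_that("string match agrees with an independent literal implementation", {
  ideal <- c("A", "B", "C", "D", "E")
  set.seed(31)
  for (i in 1:120) {
    n <- sample(0:5, 1)
    s_test <- sample(ideal, n)
    expect_equal(string_match(s_test, ideal),
                 oracle_string_match(s_test, ideal))
  }
  # maximal iff the full ideal order is recalled
  for (i in 1:40) {
    s_test <- sample(ideal, sample(1:5, 1))
    sm <- string_match(s_test, ideal)
    expect_lte(sm, 1)
    if (sm == 1) expect_identical(s_test, ideal)
  }
})

test_that("recall order recovers planted group activations", {
  sq <- seq5_local()
  mk <- function(order_times) {
    tt <- c(); id <- c()
    for (k in seq_along(order_times)) {
      if (is.na(order_times[k])) next
      g <- sq$groups[[k]]
      tt <- c(tt, rep(order_times[k], 10) + seq(0, 4.5, by = 0.5))
      id <- c(id, g)
    }
    spike_record(tt, id)
  }
  rec <- mk(c(100, 120, 140, 160, 180))
  expect_equal(recall_order(rec, sq, 95), c("A", "B", "C", "D", "E"))
  # silent group D: order shortens
  rec2 <- mk(c(100, 120, 140, NA, 180))
  expect_equal(recall_order(rec2, sq, 95), c("A", "B", "C", "E"))
  # exact peak tie: deterministic break by group index
  rec3 <- mk(c(100, 100, NA, NA, NA))
  expect_equal(recall_order(rec3, sq, 95), c("A", "B"))
  # empty raster is a valid (empty) recall
  expect_length(recall_order(spike_record(numeric(0), integer(0)), sq, 0), 0)
})

test_that("performance is the percentage of trials at or above threshold", {
  expect_equal(performance(c(1, 1, 1)), 100)
  expect_equal(performance(c(0.2, 0.4, 0.6)), 0)
  expect_equal(performance(c(rep(0.9, 7), rep(0.5, 3))), 70)
  set.seed(5)
  sm <- runif(20)
  expect_equal(performance(sm), performance(sample(sm)))
  expect_gte(performance(sm), 0); expect_lte(performance(sm), 100)
  expect_error(performance(numeric(0)), "no trials")
})

test_that("Up-state detection recovers planted alternation and rejects tonic firing", {
  fx <- synth_up_down_raster(n_up = 5, up_ms = 200, down_ms = 500,
                             neurons = 1:50, seed = 2)
  ups <- detect_up_states(fx$record, neurons = 1:50)
  expect_equal(nrow(ups), 5)
  expect_lt(max(abs(ups$start - fx$intervals$start)), 15)
  expect_lt(max(abs(ups$end - fx$intervals$end)), 15)
  # continuous firing with no 300 ms silence contains no Up state
  set.seed(3)
  tonic <- spike_record(sort(runif(4000, 0, 20e3)),
                        sample.int(50, 4000, TRUE), t_start = 0, t_end = 20e3)
  expect_equal(nrow(detect_up_states(tonic)), 0)
  expect_equal(nrow(detect_up_states(spike_record(numeric(0), integer(0)))), 0)
})

test_that("Up-state detection matches the brute-force oracle on random rasters", {
  set.seed(17)
  for (i in 1:100) {
    rec <- random_raster(n_spikes = sample(10:150, 1), t_max = 8000)
    got <- detect_up_states(rec)
    want <- oracle_up_states(rec$time, t_start = 0, t_end = attr(rec, "t_end"))
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      # consecutive Up states are separated by at least a Down state
      if (nrow(got) > 1)
        expect_true(all(got$start[-1] - got$end[-nrow(got)] >= 300))
    }
  }
})

test_that("group activation instants follow the threshold-coincidence rule", {
  g <- 1:10
  rec <- spike_record(rep(100, 10), g)
  expect_equal(group_activation_times(rec, g), 100)
  rec4 <- spike_record(c(100, 101, 102, 103), 1:4)
  expect_length(group_activation_times(rec4, g, threshold = 5), 0)
  rec5 <- spike_record(c(100, 101, 102, 103, 104), 1:5)
  expect_equal(group_activation_times(rec5, g, threshold = 5), 102)
  # oracle equivalence on random rasters
  set.seed(23)
  for (i in 1:100) {
    n <- sample(10:80, 1)
    tt <- sort(runif(n, 0, 1000))
    id <- sample(g, n, TRUE)
    rec <- spike_record(tt, id)
    expect_equal(group_activation_times(rec, g, 15, 5),
                 oracle_activations(tt, id, 15, 5))
  }
})

test_that("full-sequence replay counting is ordered, disjoint and oracle-consistent", {
  sq <- seq5_local()
  acts <- list(A = 10, B = 20, C = 30, D = 40, E = 50)
  expect_equal(count_sequence_replays(acts, sq), 1L)
  expect_equal(count_sequence_replays(list(A = 10, B = 20, C = 30,
                                           E = 40, D = 50), sq), 0L)
  two_pass <- list(A = c(10, 110), B = c(20, 120), C = c(30, 130),
                   D = c(40, 140), E = c(50, 150))
  expect_equal(count_sequence_replays(two_pass, sq), 2L)
  set.seed(29)
  for (i in 1:100) {
    acts <- lapply(sq$letters, function(l) sort(runif(sample(0:6, 1), 0, 500)))
    names(acts) <- sq$letters
    sym_t <- unlist(acts)
    sym <- rep(names(acts), lengths(acts))[order(sym_t)]
    expect_equal(count_sequence_replays(acts, sq),
                 oracle_replay_count(sym, sq$letters))
  }
})

test_that("per-synapse replay scoring counts Up states with net positive kernel sums", {
  ups <- data.frame(start = c(0, 1000, 2000), end = c(400, 1400, 2400))
  syn <- data.frame(src = 1, dst = 2)
  # single causal pre->post pair: net positive in that Up state
  rec <- spike_record(c(100, 105), c(1, 2))
  tab <- synapse_replay_table(rec, ups[1, ], syn)
  expect_equal(tab$n_replayed, 1L)
  # symmetric quadruple cancels exactly under a balanced kernel
  rec2 <- spike_record(c(100, 105, 200, 205), c(2, 1, 1, 2))
  tab2 <- synapse_replay_table(rec2, ups[1, ], syn)
  expect_equal(tab2$n_replayed, 0L)
  # positive in 2 of 3 Up states: counted twice, below the 66% bar
  rec3 <- spike_record(c(100, 105, 1100, 1105, 2105, 2100),
                       c(1, 2, 1, 2, 1, 2))
  tab3 <- synapse_replay_table(rec3, ups, syn)
  expect_equal(tab3$n_replayed, 2L)
  expect_false(tab3$reliable)
  expect_equal(tab3$n_upstates, 3L)
  # mask lookups are validated
  m <- matrix(FALSE, 3, 3); m[1, 2] <- TRUE
  expect_error(synapse_replay_table(rec, ups[1, ],
                                    data.frame(src = 2, dst = 3), mask = m),
               "mask")
})

test_that("replay scoring net sums match a literal nearest-spike oracle", {
  set.seed(41)
  p <- stdp_params()
  for (i in 1:100) {
    pre <- sort(runif(sample(1:8, 1), 0, 300))
    post <- sort(runif(sample(1:8, 1), 0, 300))
    rec <- spike_record(c(pre, post), c(rep(1, length(pre)), rep(2, length(post))))
    ups <- data.frame(start = 0, end = 300)
    tab <- synapse_replay_table(rec, ups, data.frame(src = 1, dst = 2), p)
    expect_equal(tab$n_replayed == 1,
                 oracle_synapse_score(pre, post) > 0)
  }
})

test_that("flanking-group input totals match a brute-force double loop", {
  sq <- seq5_local()
  wm <- synth_weight_matrix(n = 50, radius = 12, prob = 0.5, seed = 8)
  got <- net_left_right_inputs(wm, sq)
  for (k in 2:4) {
    want <- oracle_left_right(wm$w, sq$groups, k)
    sub <- got[got$letter == sq$letters[k], ]
    expect_equal(sub$l, want$l)
    expect_equal(sub$r, want$r)
    expect_equal(sub$diff, want$l - want$r)
  }
  # uniform weights on full blocks: left equals right for interior groups
  m2 <- matrix(TRUE, 50, 50); diag(m2) <- FALSE
  wmu <- weight_matrix(m2, ifelse(m2, 0.05, 0), g_max = 0.15)
  d <- net_left_right_inputs(wmu, sq)
  expect_true(all(d$diff == 0))
  expect_true(all(d$l == 10 * 0.05))
})

test_that("weight directionality index maps the unit square as specified", {
  expect_equal(weight_directionality_index(0.5, 0.5), 0)
  expect_equal(weight_directionality_index(1, 0), 1)
  expect_equal(weight_directionality_index(0, 1), 1)
  expect_equal(weight_directionality_index(1, 0.5), 0.5 / sqrt(0.5))
  # symmetric under swapping the two sides
  set.seed(13)
  l <- runif(50); r <- runif(50)
  expect_equal(weight_directionality_index(l, r),
               weight_directionality_index(r, l))
  expect_true(all(weight_directionality_index(l, r) >= 0))
})

test_that("delay directionality is antisymmetric and bounded", {
  expect_equal(delay_directionality(10, 10), 0)
  expect_equal(delay_directionality(30, 10), -0.5)
  expect_equal(delay_directionality(30, 10, signed = FALSE), 0.5)
  expect_equal(delay_directionality(1e-9, 20), 1, tolerance = 1e-7)
  set.seed(19)
  a <- runif(30, 1, 50); b <- runif(30, 1, 50)
  expect_equal(delay_directionality(a, b), -delay_directionality(b, a))
  expect_true(all(abs(delay_directionality(a, b)) <= 1))
  expect_equal(delay_directionality(a, b, signed = FALSE),
               delay_directionality(b, a, signed = FALSE))
  expect_error(delay_directionality(0, 10), "positive")
})

test_that("response delays recover planted first-spike latencies", {
  sq <- seq5_local()
  sched <- probe_schedule(sq)
  set.seed(37)
  lat <- data.frame(neuron = 11:40,
                    dt_left = round(runif(30, 5, 60), 1),
                    dt_right = round(runif(30, 5, 60), 1))
  lat$dt_left[3] <- NA           # a non-responding neuron is flagged absent
  rec <- synth_latency_raster(sq, sched, lat)
  got <- response_delays(rec, sq, sched)
  expect_equal(got$dt_left, lat$dt_left)
  expect_equal(got$dt_right, lat$dt_right)
  # latency is the first spike only: add a later extra spike, nothing moves
  extra <- spike_record(c(rec$time, sched$onset[1] + 200), c(rec$neuron, 11))
  got2 <- response_delays(extra, sq, sched)
  expect_equal(got2$dt_left, lat$dt_left)
})

test_that("connection classification splits recurrent and unidirectional pairs", {
  m <- matrix(FALSE, 4, 4)
  m[1, 2] <- m[2, 1] <- TRUE     # reciprocal
  m[3, 4] <- m[4, 3] <- TRUE     # reciprocal
  m[1, 3] <- TRUE                # one-way
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.1; w[2, 1] <- 0.1           # both above threshold
  w[3, 4] <- 0.1; w[4, 3] <- 0.05          # one above
  w[1, 3] <- 0.1
  wm <- weight_matrix(m, w, g_max = 0.15)
  got <- classify_connections(wm, threshold = 0.065)
  expect_equal(got$n_recurrent, 1)
  expect_equal(got$n_unidirectional, 2)
  expect_equal(got$n_unidirectional_from_reciprocal, 1)
  # all weights below threshold
  wm0 <- weight_matrix(m, w * 0.1, g_max = 0.15)
  got0 <- classify_connections(wm0, threshold = 0.065)
  expect_equal(got0$n_recurrent + got0$n_unidirectional, 0)
  # pair conservation on a random matrix
  wmr <- synth_weight_matrix(n = 40, seed = 44)
  cl <- classify_connections(wmr, threshold = 0.065)
  expect_lte(cl$n_recurrent + cl$n_unidirectional_from_reciprocal,
             cl$n_reciprocal_pairs)
})

test_that("weight pair scatter enumerates reciprocal pairs canonically", {
  m <- matrix(FALSE, 3, 3)
  m[1, 2] <- m[2, 1] <- m[2, 3] <- m[3, 2] <- m[1, 3] <- m[3, 1] <- TRUE
  w <- matrix(0, 3, 3)
  w[1, 2] <- 0.01; w[2, 1] <- 0.02; w[2, 3] <- 0.03; w[3, 2] <- 0.04
  w[1, 3] <- 0.05; w[3, 1] <- 0.06
  wm <- weight_matrix(m, w, g_max = 0.15)
  sc <- weight_pair_scatter(wm)
  expect_equal(nrow(sc), 3)
  expect_true(all(sc$src < sc$dst))
  expect_equal(sc$w_forward[sc$src == 1 & sc$dst == 2], 0.01)
  expect_equal(sc$w_backward[sc$src == 1 & sc$dst == 2], 0.02)
  # symmetric matrix puts every point on the diagonal
  ws <- (w + t(w)) / 2 * (m * 1)
  wms <- weight_matrix(m, ws, g_max = 0.15)
  scs <- weight_pair_scatter(wms)
  expect_equal(scs$w_forward, scs$w_backward)
  # count equals the number of reciprocal pairs in the mask
  wmr <- synth_weight_matrix(n = 40, seed = 45)
  expect_equal(nrow(weight_pair_scatter(wmr)),
               sum(wmr$mask & t(wmr$mask) & upper.tri(wmr$mask)))
})

test_that("spike rasters round-trip through their text format", {
  rec <- random_raster(40)
  path <- withr::local_tempfile(fileext = ".tsv")
  save_spikes(rec, path)
  back <- load_spikes(path)
  expect_equal(back$time, rec$time, tolerance = 1e-12)
  expect_equal(back$neuron, rec$neuron)
  expect_equal(attr(back, "t_end"), attr(rec, "t_end"))
})
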