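# Synthetic spike rasters with planted structure: the analysis module's
# test bed, independent of the simulator.

#' Synthetic raster with planted Up/Down structure
#'
#' Alternates dense Poisson firing periods ("Up states") with silent
#' periods ("Down states") across a set of neurons.
#'
#' @param n_up number of planted Up states.
#' @param up_ms,down_ms Up- and Down-state durations (ms).
#' @param neurons neuron ids firing during Up states.
#' @param rate_hz per-neuron Poisson rate inside an Up state.
#' @param seed integer seed.
#' @param lead_ms silence before the first Up state.
#' @return list: `record` ([spike_record()]), `intervals` (data.frame
#'   of the planted `start`/`end` times).
#' @export
synth_up_down_raster <- function(n_up = 5, up_ms = 200, down_ms = 500,
                                 neurons = 1:50, rate_hz = 20,
                                 seed = 1, lead_ms = 500) {
  rng <- local_rng(seed)
  starts <- lead_ms + (seq_len(n_up) - 1) * (up_ms + down_ms)
  tt <- numeric(0); id <- integer(0)
  for (s in starts) {
    for (n in neurons) {
      k <- max(0, round(rng$rnorm(1, rate_hz * up_ms / 1000,
                                  sqrt(rate_hz * up_ms / 1000))))
      if (k > 0) {
        tt <- c(tt, s + sort(rng$runif(k, 0, up_ms)))
        id <- c(id, rep.int(n, k))
      }
    }
  }
  rec <- spike_record(tt, id, t_start = 0,
                      t_end = max(starts) + up_ms + down_ms,
                      phase = "synthetic-sleep")
  list(record = rec,
       intervals = data.frame(start = starts, end = starts + up_ms))
}

#' Synthetic raster with planted group activations
#'
#' Inside each planted Up state, activates the groups of `seq` in the
#' given letter orders: each activation makes every neuron of the group
#' fire once within a 2 ms jitter.  Background Up-state firing can be
#' added to exercise robustness.
#'
#' @param seq a [sequence_spec()].
#' @param orders list (one element per Up state) of character vectors —
#'   the letter orders to plant; letters may repeat for multiple
#'   passes.
#' @param up_gap_ms silence between Up states.
#' @param act_gap_ms time between successive planted activations.
#' @param seed integer seed.
#' @return list: `record`, `intervals`, `planted_replays` (integer
#'   vector of full ordered passes per Up state, computed by direct
#'   subsequence scan of the planted orders).
#' @export
synth_replay_raster <- function(seq, orders, up_gap_ms = 500,
                                act_gap_ms = 25, seed = 1) {
  rng <- local_rng(seed)
  tt <- numeric(0); id <- integer(0)
  t0 <- up_gap_ms
  intervals <- data.frame(start = numeric(0), end = numeric(0))
  for (ord in orders) {
    t <- t0
    for (letter in ord) {
      g <- seq$groups[[letter]]
      tt <- c(tt, t + rng$runif(length(g), 0, 2))
      id <- c(id, g)
      t <- t + act_gap_ms
    }
    intervals <- rbind(intervals,
                       data.frame(start = t0, end = t - act_gap_ms + 2))
    t0 <- t - act_gap_ms + 2 + up_gap_ms
  }
  planted <- vapply(orders, function(ord) {
    k <- 1L; cnt <- 0L
    for (s in ord) {
      if (s == seq$letters[k]) {
        k <- k + 1L
        if (k > length(seq$letters)) { cnt <- cnt + 1L; k <- 1L }
      }
    }
    cnt
  }, integer(1))
  list(record = spike_record(tt, id, t_start = 0, t_end = t0,
                             phase = "synthetic-replay"),
       intervals = intervals, planted_replays = planted)
}

#' Synthetic raster with planted response latencies
#'
#' For each probe stimulus of `sched`, neurons of the neighbouring
#' groups spike once at their planted latency.
#'
#' @param seq a [sequence_spec()].
#' @param sched a [probe_schedule()].
#' @param latencies data.frame with columns `neuron`, `dt_left`,
#'   `dt_right` (ms; `NA` = no response).
#' @return a [spike_record()].
#' @export
synth_latency_raster <- function(seq, sched, latencies) {
  G <- length(seq$groups)
  tt <- numeric(0); id <- integer(0)
  for (r in seq_len(nrow(sched))) {
    k <- sched$group_index[r]
    onset <- sched$onset[r]
    if (k + 1 <= G) {                      # stimulated group is left neighbour
      for (i in seq$groups[[k + 1]]) {
        lat <- latencies$dt_left[latencies$neuron == i]
        if (length(lat) && !is.na(lat)) { tt <- c(tt, onset + lat); id <- c(id, i) }
      }
    }
    if (k - 1 >= 1) {                      # stimulated group is right neighbour
      for (i in seq$groups[[k - 1]]) {
        lat <- latencies$dt_right[latencies$neuron == i]
        if (length(lat) && !is.na(lat)) { tt <- c(tt, onset + lat); id <- c(id, i) }
      }
    }
  }
  spike_record(tt, id, t_start = 0, phase = "synthetic-probe")
}

#' Random weight matrix on a radius-limited topographic graph
#'
#' @param n number of neurons.
#' @param radius connection radius.
#' @param prob connection probability.
#' @param mean,sd,g_max weight distribution (see [init_weights()]).
#' @param seed integer seed.
#' @return a `weight_matrix`.
#' @export
synth_weight_matrix <- function(n = 50, radius = 10, prob = 0.6,
                                mean = 0.075, sd = 0.0075, g_max = 0.15,
                                seed = 1) {
  layout <- population_layout(n_py = n, n_in = 2, n_tc = 2, n_re = 2)
  pr <- default_projections()
  pr <- pr[pr$name == "PY_PY_AMPA", , drop = FALSE]
  pr$radius <- radius; pr$prob <- prob
  conn <- build_connectivity(layout, pr, seed = seed)
  init_weights(pypy_mask(conn), mean = mean, sd = sd, g_max = g_max,
               seed = seed + 1)
}

#' Generate fixture files
#'
#' Writes a synthetic fixture of the requested kind to `dir` as plain
#' text (raster plus a YAML metadata sidecar describing the planted
#' structure), for testing the analysis operations independently of the
#' simulator.
#'
#' @param kind `"updown"`, `"replay"`, or `"latency"`.
#' @param seed integer seed.
#' @param dir output directory.
#' @return invisibly, the list of files written.
#' @export
make_fixtures <- function(kind = c("updown", "replay", "latency"),
                          seed = 1, dir = ".") {
  kind <- match.arg(kind)
  seq5 <- sequence_spec("S1", list(A = 1:10, B = 11:20, C = 21:30,
                                   D = 31:40, E = 41:50))
  raster_path <- file.path(dir, paste0("fixture-", kind, ".tsv"))
  meta_path <- file.path(dir, paste0("fixture-", kind, ".yaml"))
  if (kind == "updown") {
    fx <- synth_up_down_raster(seed = seed)
    save_spikes(fx$record, raster_path)
    yaml::write_yaml(list(kind = kind, seed = seed,
                          intervals = as.list(fx$intervals)), meta_path)
  } else if (kind == "replay") {
    orders <- list(c("A", "B", "C", "D", "E"),
                   c("A", "B", "C", "E", "D"),
                   rep(c("A", "B", "C", "D", "E"), 2))
    fx <- synth_replay_raster(seq5, orders, seed = seed)
    save_spikes(fx$record, raster_path)
    yaml::write_yaml(list(kind = kind, seed = seed,
                          planted_replays = fx$planted_replays,
                          intervals = as.list(fx$intervals)), meta_path)
  } else {
    sched <- probe_schedule(seq5)
    lat <- data.frame(neuron = 11:40,
                      dt_left = round(runif(30, 5, 60), 1),
                      dt_right = round(runif(30, 5, 60), 1))
    rec <- synth_latency_raster(seq5, sched, lat)
    save_spikes(rec, raster_path)
    yaml::write_yaml(list(kind = kind, seed = seed,
                          latencies = as.list(lat)), meta_path)
  }
  invisible(c(raster_path, meta_path))
}
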