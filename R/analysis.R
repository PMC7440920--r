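# Quantitative readouts: recall scoring, Up-state and replay detection,
# per-synapse replay reliability, synaptic-input asymmetry,
# directionality indices, connection-class statistics.

#' Spike record
#'
#' Time-sorted raster of (neuron id, spike time) events.
#'
#' @param time spike times (ms).
#' @param neuron global neuron ids (1-based).
#' @param layout optional [population_layout()] used to validate ids and
#'   tag populations.
#' @param phase phase label.
#' @param t_start,t_end recording bounds (ms); default 0 and the last
#'   spike time.
#' @return data.frame of class `spike_record` with columns `time`,
#'   `neuron` (and `pop` when a layout is given), sorted by time.
#' @export
spike_record <- function(time, neuron, layout = NULL, phase = "",
                         t_start = 0, t_end = NULL) {
  stopifnot(length(time) == length(neuron))
  o <- order(time)
  df <- data.frame(time = as.numeric(time)[o], neuron = as.integer(neuron)[o])
  if (!is.null(layout)) {
    if (nrow(df) && (min(df$neuron) < 1 || max(df$neuron) > layout$total))
      stop("neuron ids outside the population layout")
    df$pop <- if (nrow(df)) population_of(layout, df$neuron) else character(0)
  }
  if (is.null(t_end)) t_end <- if (nrow(df)) max(df$time) else t_start
  structure(df, phase = phase, layout = layout,
            t_start = t_start, t_end = t_end,
            class = c("spike_record", "data.frame"))
}

#' Write / read a spike raster as delimited text
#'
#' Three whitespace-delimited columns: time (ms), neuron id, population
#' tag (`NA` when unknown).
#' @param rec a [spike_record()].
#' @param path file path.
#' @export
save_spikes <- function(rec, path) {
  df <- as.data.frame(rec)
  if (!"pop" %in% names(df)) df$pop <- NA_character_
  hdr <- c(paste("# phase:", attr(rec, "phase")),
           paste("# t_start:", format(attr(rec, "t_start"), digits = 15)),
           paste("# t_end:", format(attr(rec, "t_end"), digits = 15)))
  writeLines(c(hdr, paste(format(df$time, digits = 15, trim = TRUE),
                          df$neuron, df$pop)), path)
  invisible(path)
}

#' @rdname save_spikes
#' @export
load_spikes <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  get_field <- function(key, default) {
    ln <- grep(paste0("^# ", key, ":"), lines[is_hdr], value = TRUE)
    if (!length(ln)) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  body <- lines[!is_hdr]
  if (!length(body))
    return(spike_record(numeric(0), integer(0),
                        phase = get_field("phase", ""),
                        t_start = as.numeric(get_field("t_start", 0))))
  parts <- strsplit(trimws(body), "\\s+")
  if (any(lengths(parts) < 2)) stop("parse error in raster file")
  spike_record(as.numeric(vapply(parts, `[[`, "", 1)),
               as.integer(vapply(parts, `[[`, "", 2)),
               phase = get_field("phase", ""),
               t_start = as.numeric(get_field("t_start", 0)),
               t_end = as.numeric(get_field("t_end", NA)))
}

# Gaussian smoothing kernel on a 1 ms grid; `window` is the full kernel
# width (ms), taken as +-2 standard deviations.
.gauss_kernel <- function(window = 50) {
  half <- window / 2
  sd <- window / 4
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sd^2))
  k / sum(k)
}

#' Detected letter order during a recall trial
#'
#' For each group of the sequence, the mean instantaneous firing rate of
#' the group's neurons inside the response window after the test
#' stimulus is smoothed with a 50 ms Gaussian kernel on a 1 ms grid; the
#' order of the smoothed-rate peak times over all groups with at least
#' one spike defines the detected letter order.  Peak ties are broken
#' toward the earlier time; equal peak times across groups are broken by
#' group index (ascending).
#'
#' @param spikes a [spike_record()] (PY ids must be PY-local, i.e.
#'   global ids for a layout whose PY population starts at 1).
#' @param seq a [sequence_spec()].
#' @param stim_time onset of the test stimulus (ms).
#' @param window response window length (ms).
#' @param kernel_window Gaussian kernel width (ms).
#' @return character vector of letters (possibly shorter than the
#'   sequence, empty for an empty raster).
#' @export
recall_order <- function(spikes, seq, stim_time, window = 350,
                         kernel_window = 50) {
  stopifnot(inherits(seq, "sequence_spec"))
  kern <- .gauss_kernel(kernel_window)
  grid <- seq(stim_time, stim_time + window)
  peaks <- rep(NA_real_, length(seq$groups))
  for (k in seq_along(seq$groups)) {
    ids <- seq$groups[[k]]
    tt <- spikes$time[spikes$neuron %in% ids &
                      spikes$time >= stim_time &
                      spikes$time <= stim_time + window]
    if (!length(tt)) next
    counts <- tabulate(findInterval(tt, grid), nbins = length(grid))
    sm <- stats::filter(counts, kern, sides = 2)
    sm[is.na(sm)] <- 0
    peaks[k] <- grid[which.max(sm)]
  }
  present <- which(!is.na(peaks))
  present <- present[order(peaks[present], present)]
  seq$letters[present]
}

#' String-match similarity between a recalled and an ideal letter order
#'
#' `SM = (2 N - sum_i |L_i - i|) / (2 |ideal|)` where `N = |S_test|`,
#' `S_sub` is the ideal sequence restricted to the letters present in
#' `S_test` (in ideal order) and `L_i` the 1-based position of
#' `S_sub[i]` in `S_test`.  Perfect recall scores 1; missing letters cap
#' the score below 1; inverted orders can score negative.
#'
#' @param s_test recalled letter order (character vector).
#' @param ideal ideal letter order (character vector, no duplicates).
#' @return similarity score in `(-Inf, 1]`.
#' @export
string_match <- function(s_test, ideal) {
  if (anyDuplicated(s_test)) stop("duplicate letters in the test sequence")
  if (anyDuplicated(ideal)) stop("duplicate letters in the ideal sequence")
  if (!all(s_test %in% ideal))
    stop("test sequence contains letters absent from the ideal sequence")
  n <- length(s_test)
  if (n == 0) return(0)
  s_sub <- ideal[ideal %in% s_test]
  L <- match(s_sub, s_test)
  (2 * n - sum(abs(L - seq_along(L)))) / (2 * length(ideal))
}

#' Score the recall trials of a test phase
#'
#' Applies [recall_order()] and [string_match()] to every test stimulus.
#'
#' @param spikes a [spike_record()].
#' @param seq a [sequence_spec()].
#' @param stim_times onsets of the test stimuli (ms), e.g. the `onset`
#'   column of a [test_schedule()].
#' @param Th success threshold on the string-match score.
#' @inheritParams recall_order
#' @return data.frame with one row per trial: `stim_time`, `order`
#'   (collapsed letter string), `sm`, `success`.
#' @export
recall_trials <- function(spikes, seq, stim_times, Th = 0.8,
                          window = 350, kernel_window = 50) {
  rows <- lapply(stim_times, function(t0) {
    ord <- recall_order(spikes, seq, t0, window, kernel_window)
    sm <- string_match(ord, seq$letters)
    data.frame(stim_time = t0, order = paste(ord, collapse = ""),
               sm = sm, success = sm >= Th)
  })
  do.call(rbind, rows)
}

#' Recall performance
#'
#' Percent of trials whose string-match score reaches the threshold.
#'
#' @param trials data.frame from [recall_trials()], or a numeric vector
#'   of string-match scores.
#' @param Th success threshold.
#' @return percent in \[0, 100\].
#' @export
performance <- function(trials, Th = 0.8) {
  sm <- if (is.data.frame(trials)) trials$sm else trials
  if (!length(sm)) stop("no trials to score")
  100 * mean(sm >= Th)
}

#' Detect Up states in a sleep raster
#'
#' Spikes of the given neurons are chained into candidate active
#' periods (consecutive spikes within `window` ms belong to the same
#' candidate); candidates separated by less than `min_down` ms are
#' merged; an interval qualifies as an Up state only when flanked on
#' both sides by at least `min_down` ms of silence (a Down state), the
#' recording bounds delimiting the outermost gaps.
#'
#' @param spikes a [spike_record()].
#' @param neurons neuron ids to pool (e.g. the trained region), or a
#'   list of group id vectors; defaults to all neurons present.
#' @param window chaining window (ms).
#' @param min_down minimum Down-state (silence) duration (ms).
#' @param t_start,t_end recording bounds; default from the record.
#' @return data.frame with columns `start`, `end` (ms), possibly empty.
#' @export
detect_up_states <- function(spikes, neurons = NULL, window = 15,
                             min_down = 300, t_start = NULL, t_end = NULL) {
  if (is.list(neurons)) neurons <- unlist(neurons)
  tt <- if (is.null(neurons)) spikes$time
        else spikes$time[spikes$neuron %in% neurons]
  tt <- sort(tt)
  if (is.null(t_start)) t_start <- attr(spikes, "t_start")
  if (is.null(t_start)) t_start <- 0
  if (is.null(t_end)) t_end <- attr(spikes, "t_end")
  if (is.null(t_end) || is.na(t_end)) t_end <- if (length(tt)) max(tt) else t_start
  empty <- data.frame(start = numeric(0), end = numeric(0))
  if (!length(tt)) return(empty)
  brk <- which(diff(tt) > window)
  start <- tt[c(1, brk + 1)]
  end <- tt[c(brk, length(tt))]
  # merge candidates whose separation is shorter than a Down state
  if (length(start) > 1) {
    keep_start <- c(TRUE, start[-1] - end[-length(end)] >= min_down)
    grp <- cumsum(keep_start)
    start <- tapply(start, grp, min)
    end <- tapply(end, grp, max)
  }
  ok <- (start - c(t_start, end[-length(end)])) >= min_down &
        (c(start[-1], t_end) - end) >= min_down
  data.frame(start = as.numeric(start[ok]), end = as.numeric(end[ok]),
             row.names = NULL)
}

#' Group activation instants
#'
#' A group is active when at least `threshold` distinct neurons of the
#' group spike within a `window` ms span; the activation instant is the
#' mean of the first `threshold` distinct-neuron spike times inside the
#' qualifying window.  After a detection the scan resumes past the end
#' of the window.
#'
#' @param spikes a [spike_record()].
#' @param group integer vector of neuron ids forming the group.
#' @param window coincidence window (ms).
#' @param threshold activation threshold (neurons); default half the
#'   group size.
#' @return numeric vector of activation times (ms), possibly empty.
#' @export
group_activation_times <- function(spikes, group, window = 15,
                                   threshold = max(1, floor(length(group) / 2))) {
  sel <- spikes$neuron %in% group
  tt <- spikes$time[sel]
  id <- spikes$neuron[sel]
  o <- order(tt)
  tt <- tt[o]; id <- id[o]
  out <- numeric(0)
  i <- 1L
  n <- length(tt)
  while (i <= n) {
    in_win <- which(tt >= tt[i] & tt <= tt[i] + window)
    first_per_neuron <- in_win[!duplicated(id[in_win])]
    if (length(first_per_neuron) >= threshold) {
      used <- sort(tt[first_per_neuron])[seq_len(threshold)]
      out <- c(out, mean(used))
      nxt <- which(tt > tt[i] + window)
      if (!length(nxt)) break
      i <- nxt[1]
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Count full-sequence replays
#'
#' Given activation instants per group, counts the disjoint occurrences
#' of the complete ordered chain of the sequence (all four transitions
#' of a 5-letter word observed in order); scanning is greedy in time, so
#' overlapping partial matches are not double-counted.
#'
#' @param activations named list mapping letters to activation-time
#'   vectors (e.g. within one Up state).
#' @param seq a [sequence_spec()].
#' @return integer replay count.
#' @export
count_sequence_replays <- function(activations, seq) {
  letters_all <- unlist(lapply(seq$letters, function(l) {
    tt <- activations[[l]]
    if (is.null(tt)) return(NULL)
    stats::setNames(tt, rep(l, length(tt)))
  }))
  if (is.null(letters_all) || !length(letters_all)) return(0L)
  sym <- names(letters_all)[order(letters_all)]
  want <- seq$letters
  k <- 1L; count <- 0L
  for (s in sym) {
    if (s == want[k]) {
      k <- k + 1L
      if (k > length(want)) { count <- count + 1L; k <- 1L }
    }
  }
  count
}

#' Replays per Up state
#'
#' Convenience wrapper: detects group activations inside each Up state
#' and counts full-sequence replays.
#'
#' @param spikes a [spike_record()].
#' @param seq a [sequence_spec()].
#' @param upstates data.frame from [detect_up_states()].
#' @inheritParams group_activation_times
#' @return integer vector, one count per Up state.
#' @export
replays_per_up_state <- function(spikes, seq, upstates, window = 15,
                                 threshold = NULL) {
  vapply(seq_len(nrow(upstates)), function(u) {
    sub <- spikes[spikes$time >= upstates$start[u] &
                  spikes$time <= upstates$end[u], , drop = FALSE]
    acts <- lapply(seq$groups, function(g) {
      th <- if (is.null(threshold)) max(1, floor(length(g) / 2)) else threshold
      group_activation_times(sub, g, window, th)
    })
    names(acts) <- seq$letters
    count_sequence_replays(acts, seq)
  }, integer(1))
}

# Signed delay from each pre spike to its nearest post spike (ties
# broken toward the causal, positive side).
.nearest_delays <- function(pre, post) {
  if (!length(pre) || !length(post)) return(numeric(0))
  vapply(pre, function(tp) {
    d <- post - tp
    d[which.min(abs(d) - 1e-12 * (d > 0))]
  }, numeric(1))
}

#' Per-synapse replay table
#'
#' For each directed synapse and each Up state, the delays between each
#' presynaptic spike and its nearest postsynaptic spike are passed
#' through an STDP-like exponential kernel and summed; a positive net
#' sum marks the synapse as preferentially replayed in that Up state.
#' The table accumulates the counts over all Up states and flags
#' synapses replayed reliably (in strictly more than `reliability` of
#' Up states; the default is the two-thirds bar quoted as 66\%).
#'
#' @param spikes a [spike_record()].
#' @param upstates data.frame from [detect_up_states()].
#' @param synapses data.frame with columns `src`, `dst` (neuron ids).
#' @param params an [stdp_params()] used as the scoring kernel.
#' @param reliability reliability fraction threshold.
#' @param mask optional logical adjacency matrix; synapses absent from
#'   it raise an error.
#' @param w_before,w_after optional weight matrices bracketing the
#'   sleep phase; adds a `dw` column (net weight change).
#' @return data.frame: `src`, `dst`, `n_replayed`, `n_upstates`,
#'   `reliable` (and `dw` when weights are given).
#' @export
synapse_replay_table <- function(spikes, upstates, synapses,
                                 params = stdp_params(),
                                 reliability = 2 / 3, mask = NULL,
                                 w_before = NULL, w_after = NULL) {
  stopifnot(all(c("src", "dst") %in% names(synapses)))
  if (!is.null(mask)) {
    off <- !mask[cbind(synapses$src, synapses$dst)]
    if (any(off))
      stop("synapse not in the anatomical mask: ",
           synapses$src[off][1], " -> ", synapses$dst[off][1])
  }
  n_up <- nrow(upstates)
  counts <- integer(nrow(synapses))
  spike_times <- split(spikes$time, spikes$neuron)
  for (u in seq_len(n_up)) {
    lo <- upstates$start[u]; hi <- upstates$end[u]
    for (s in seq_len(nrow(synapses))) {
      pre <- spike_times[[as.character(synapses$src[s])]]
      post <- spike_times[[as.character(synapses$dst[s])]]
      pre <- pre[pre >= lo & pre <= hi]
      post <- post[post >= lo & post <= hi]
      d <- .nearest_delays(pre, post)
      d <- d[d != 0]
      if (length(d) && sum(stdp_kernel(d, params)) > 0)
        counts[s] <- counts[s] + 1L
    }
  }
  out <- data.frame(src = synapses$src, dst = synapses$dst,
                    n_replayed = counts, n_upstates = n_up,
                    reliable = counts > reliability * n_up)
  if (!is.null(w_before) && !is.null(w_after))
    out$dw <- w_after[cbind(out$src, out$dst)] -
              w_before[cbind(out$src, out$dst)]
  out
}

#' Net synaptic input from the flanking groups
#'
#' For every neuron of the interior groups of a sequence, the total
#' incoming weight from the preceding group (`l`) and from the
#' following group (`r`), within-group edges excluded, and their
#' difference — the footprint of directional training on the weight
#' matrix.
#'
#' @param wm a `weight_matrix` (PY-local indexing).
#' @param seq a [sequence_spec()].
#' @return data.frame: `neuron`, `letter`, `l`, `r`, `diff`.
#' @export
net_left_right_inputs <- function(wm, seq) {
  stopifnot(inherits(wm, "weight_matrix"), inherits(seq, "sequence_spec"))
  G <- length(seq$groups)
  rows <- list()
  for (k in 2:(G - 1)) {
    prev <- seq$groups[[k - 1]]
    nxt <- seq$groups[[k + 1]]
    for (i in seq$groups[[k]]) {
      rows[[length(rows) + 1]] <- data.frame(
        neuron = i, letter = seq$letters[k],
        l = sum(wm$w[prev, i]), r = sum(wm$w[nxt, i]))
    }
  }
  out <- do.call(rbind, rows)
  out$diff <- out$l - out$r
  out
}

#' Weight directionality index
#'
#' Distance of the point `(l, r)` (normalised flanking-group inputs,
#' each in \[0, 1\]) from the centre of the unit square, scaled by
#' `sqrt(0.5)` so that purely one-sided input maps to 1 and balanced
#' input to 0.
#'
#' @param l,r normalised left/right input totals in \[0, 1\].
#' @return index values in \[0, 1\].
#' @export
weight_directionality_index <- function(l, r) {
  stopifnot(length(l) == length(r))
  sqrt((l - 0.5)^2 + (r - 0.5)^2) / sqrt(0.5)
}

#' Weight-based directionality of a trained region
#'
#' Computes [net_left_right_inputs()], normalises `l` and `r` by the
#' maximum single-side total observed in the region at this snapshot,
#' and summarises the per-neuron [weight_directionality_index()].
#'
#' @param wm a `weight_matrix`.
#' @param seq a [sequence_spec()].
#' @return list: `per_neuron` (data.frame with `index` column),
#'   `index` (mean), `var` (variance of the `l - r` differences).
#' @export
weight_directionality <- function(wm, seq) {
  d <- net_left_right_inputs(wm, seq)
  mx <- max(c(d$l, d$r), na.rm = TRUE)
  if (mx <= 0) mx <- 1
  d$l_norm <- d$l / mx
  d$r_norm <- d$r / mx
  d$index <- weight_directionality_index(d$l_norm, d$r_norm)
  list(per_neuron = d, index = mean(d$index), var = stats::var(d$diff))
}

#' Delay directionality index
#'
#' Signed: `(dt_S1* - dt_S1) / (dt_S1* + dt_S1)` in \[-1, 1\];
#' unsigned: its absolute value.  `dt_S1` is a neuron's first-spike
#' response delay after its left (S1-direction) neighbouring group is
#' stimulated, `dt_S1*` after the right group.
#'
#' @param dt_s1,dt_s1star response delays (ms), `> 0`.
#' @param signed logical.
#' @return index values.
#' @export
delay_directionality <- function(dt_s1, dt_s1star, signed = TRUE) {
  if (any(dt_s1 <= 0) || any(dt_s1star <= 0))
    stop("response delays must be positive")
  idx <- (dt_s1star - dt_s1) / (dt_s1star + dt_s1)
  if (signed) idx else abs(idx)
}

#' First-spike response delays after per-group probe stimulation
#'
#' For every neuron of the interior groups, the latency of its first
#' spike after the probe stimulation of its left and of its right
#' neighbouring group.
#'
#' @param spikes a [spike_record()] of the probe phase.
#' @param seq a [sequence_spec()].
#' @param sched the [probe_schedule()] that generated the phase.
#' @param max_latency latencies beyond this window are treated as
#'   absent (`NA`).
#' @return data.frame: `neuron`, `letter`, `dt_left`, `dt_right`
#'   (ms; `NA` when the neuron did not respond).
#' @export
response_delays <- function(spikes, seq, sched, max_latency = 350) {
  G <- length(seq$groups)
  first_latency <- function(ids, onset) {
    vapply(ids, function(i) {
      tt <- spikes$time[spikes$neuron == i & spikes$time > onset &
                        spikes$time <= onset + max_latency]
      if (length(tt)) min(tt) - onset else NA_real_
    }, numeric(1))
  }
  rows <- list()
  for (k in 2:(G - 1)) {
    ids <- seq$groups[[k]]
    on_left <- sched$onset[sched$group_index == k - 1]
    on_right <- sched$onset[sched$group_index == k + 1]
    dl <- rowMeans(do.call(cbind, lapply(on_left, function(o)
      first_latency(ids, o))), na.rm = TRUE)
    dr <- rowMeans(do.call(cbind, lapply(on_right, function(o)
      first_latency(ids, o))), na.rm = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      neuron = ids, letter = seq$letters[k],
      dt_left = dl, dt_right = dr)
  }
  out <- do.call(rbind, rows)
  out$dt_left[is.nan(out$dt_left)] <- NA
  out$dt_right[is.nan(out$dt_right)] <- NA
  rownames(out) <- NULL
  out
}

#' Classify connections as functionally recurrent or unidirectional
#'
#' After thresholding the weight matrix: an anatomically reciprocal
#' pair is functionally recurrent when both directions exceed the
#' threshold and unidirectional when exactly one does; anatomically
#' one-way edges above threshold are unidirectional.
#'
#' @param wm a `weight_matrix`.
#' @param threshold weight threshold (uS); the default is below the
#'   default initial mean weight.
#' @param neurons optional neuron-id subset restricting the analysis
#'   (e.g. a trained region).
#' @return list: `n_recurrent`, `n_unidirectional`, and the component
#'   counts `n_unidirectional_from_reciprocal`, `n_one_way_edges`.
#' @export
classify_connections <- function(wm, threshold = 0.065, neurons = NULL) {
  stopifnot(inherits(wm, "weight_matrix"))
  m <- wm$mask; w <- wm$w
  if (!is.null(neurons)) {
    keep <- matrix(FALSE, nrow(m), ncol(m))
    keep[neurons, neurons] <- TRUE
    m <- m & keep
  }
  rec_pair <- m & t(m)
  ut <- upper.tri(m)
  rp <- which(rec_pair & ut, arr.ind = TRUE)
  fwd_hi <- w[rp] > threshold
  bwd_hi <- w[rp[, c(2, 1), drop = FALSE]] > threshold
  n_rec <- sum(fwd_hi & bwd_hi)
  n_uni_rec <- sum(xor(fwd_hi, bwd_hi))
  one_way <- m & !t(m)
  n_one <- sum(w[one_way] > threshold)
  list(n_recurrent = n_rec,
       n_unidirectional = n_uni_rec + n_one,
       n_unidirectional_from_reciprocal = n_uni_rec,
       n_one_way_edges = n_one,
       n_reciprocal_pairs = nrow(rp))
}

#' Weight pairs of reciprocally connected neurons
#'
#' One point per anatomically reciprocal pair; the forward direction is
#' canonically the ascending-index (S1) direction.
#'
#' @param wm a `weight_matrix`.
#' @param neurons optional neuron-id subset.
#' @return data.frame: `src`, `dst` (`src < dst`), `w_forward`
#'   (`src -> dst`), `w_backward` (`dst -> src`).
#' @export
weight_pair_scatter <- function(wm, neurons = NULL) {
  stopifnot(inherits(wm, "weight_matrix"))
  m <- wm$mask
  if (!is.null(neurons)) {
    keep <- matrix(FALSE, nrow(m), ncol(m))
    keep[neurons, neurons] <- TRUE
    m <- m & keep
  }
  rp <- which(m & t(m) & upper.tri(m), arr.ind = TRUE)
  data.frame(src = rp[, 1], dst = rp[, 2],
             w_forward = wm$w[rp],
             w_backward = wm$w[rp[, c(2, 1), drop = FALSE]])
}
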