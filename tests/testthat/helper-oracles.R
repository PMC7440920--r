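# Independent brute-force reference implementations used as oracles.
# These are deliberately slow and literal: nested loops and exhaustive
# scans, sharing no code with the package internals they check.

# string match computed step by step from its definition
oracle_string_match <- function(s_test, ideal) {
  n <- length(s_test)
  if (n == 0) return(0)
  s_sub <- character(0)
  for (letter in ideal) if (letter %in% s_test) s_sub <- c(s_sub, letter)
  total <- 0
  for (i in seq_along(s_sub)) {
    L_i <- which(s_test == s_sub[i])
    total <- total + abs(L_i - i)
  }
  (2 * n - total) / (2 * length(ideal))
}

# Up states by exhaustive chain construction: grow a chain while the next
# spike is within `window`; then merge chains separated by < min_down and
# keep only intervals flanked by >= min_down of silence.
oracle_up_states <- function(times, window = 15, min_down = 300,
                             t_start = 0, t_end = max(c(times, t_start))) {
  times <- sort(times)
  if (!length(times)) return(data.frame(start = numeric(0), end = numeric(0)))
  chains <- list()
  cur <- c(times[1], times[1])
  for (t in times[-1]) {
    if (t - cur[2] <= window) cur[2] <- t
    else { chains[[length(chains) + 1]] <- cur; cur <- c(t, t) }
  }
  chains[[length(chains) + 1]] <- cur
  merged <- list(chains[[1]])
  for (ch in chains[-1]) {
    last <- merged[[length(merged)]]
    if (ch[1] - last[2] < min_down) merged[[length(merged)]] <- c(last[1], ch[2])
    else merged[[length(merged) + 1]] <- ch
  }
  keep <- list()
  for (i in seq_along(merged)) {
    lo <- if (i == 1) t_start else merged[[i - 1]][2]
    hi <- if (i == length(merged)) t_end else merged[[i + 1]][1]
    if (merged[[i]][1] - lo >= min_down && hi - merged[[i]][2] >= min_down)
      keep[[length(keep) + 1]] <- merged[[i]]
  }
  if (!length(keep)) return(data.frame(start = numeric(0), end = numeric(0)))
  data.frame(start = vapply(keep, `[`, 0, 1), end = vapply(keep, `[`, 0, 2))
}

# group activations by scanning every spike as a window anchor
oracle_activations <- function(times, ids, window = 15, threshold = 5) {
  o <- order(times); times <- times[o]; ids <- ids[o]
  out <- numeric(0)
  i <- 1
  while (i <= length(times)) {
    sel <- which(times >= times[i] & times <= times[i] + window)
    first <- sel[!duplicated(ids[sel])]
    if (length(first) >= threshold) {
      out <- c(out, mean(sort(times[first])[1:threshold]))
      nxt <- which(times > times[i] + window)
      if (!length(nxt)) break
      i <- nxt[1]
    } else i <- i + 1
  }
  out
}

# disjoint ordered occurrences of `want` in the time-ordered symbol list,
# earliest-completion greedy, written as an explicit repeated scan
oracle_replay_count <- function(symbols, want) {
  count <- 0
  pos <- 1
  repeat {
    k <- 1
    while (pos <= length(symbols) && k <= length(want)) {
      if (symbols[pos] == want[k]) k <- k + 1
      pos <- pos + 1
    }
    if (k > length(want)) count <- count + 1 else break
    if (pos > length(symbols)) break
  }
  count
}

# left/right group input totals by a double loop over all matrix entries
oracle_left_right <- function(W, groups, k) {
  prev <- groups[[k - 1]]; nxt <- groups[[k + 1]]
  out <- NULL
  for (i in groups[[k]]) {
    l <- 0; r <- 0
    for (s in seq_len(nrow(W))) {
      if (s %in% prev) l <- l + W[s, i]
      if (s %in% nxt) r <- r + W[s, i]
    }
    out <- rbind(out, data.frame(neuron = i, l = l, r = r))
  }
  out
}

# per-synapse net STDP-like score inside one window, literal
oracle_synapse_score <- function(pre, post, a = 0.002, tau = 20) {
  total <- 0
  for (tp in pre) {
    if (!length(post)) next
    d <- post - tp
    best <- d[order(abs(d), -sign(d))][1]
    if (best == 0) next
    total <- total + if (best > 0) a * exp(-best / tau) else -a * exp(best / tau)
  }
  total
}

# small random raster generator for property tests
random_raster <- function(n_spikes = 60, n_neurons = 20, t_max = 2000) {
  spike_record(runif(n_spikes, 0, t_max),
               sample.int(n_neurons, n_spikes, replace = TRUE),
               t_start = 0, t_end = t_max)
}

seq5_local <- function() {
  sequence_spec("S1", list(A = 1:10, B = 11:20, C = 21:30,
                           D = 31:40, E = 41:50))
}
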