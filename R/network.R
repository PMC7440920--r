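# Network construction: four-population thalamocortical graph with
# radius-limited topographic projections, the probabilistic plastic
# PY->PY AMPA layer, and weight-matrix snapshots.

#' Population layout
#'
#' Sizes and contiguous global index ranges of the four neuron
#' populations.  Global ids are 1-based and ordered PY, IN, TC, RE.
#'
#' @param n_py,n_in,n_tc,n_re population sizes (full scale:
#'   500/100/100/100).
#' @return an object of class `population_layout` with fields `n`
#'   (named counts) and `range` (named list of global-id ranges).
#' @export
population_layout <- function(n_py = 500, n_in = 100, n_tc = 100, n_re = 100) {
  n <- c(PY = n_py, IN = n_in, TC = n_tc, RE = n_re)
  if (any(n <= 0)) stop("population sizes must be positive")
  ends <- cumsum(n)
  starts <- c(1, ends[-4] + 1)
  range <- Map(function(s, e) s:e, starts, ends)
  names(range) <- names(n)
  structure(list(n = n, range = range, total = sum(n)),
            class = "population_layout")
}

#' Population of a global neuron id
#' @param layout a [population_layout()].
#' @param id global neuron id(s).
#' @return character vector of population names.
#' @export
population_of <- function(layout, id) {
  stopifnot(all(id >= 1), all(id <= layout$total))
  br <- c(0, cumsum(layout$n))
  names(layout$n)[findInterval(id, br, left.open = TRUE)]
}

#' Default projection table
#'
#' The thirteen projections of the thalamocortical circuit with their
#' receptors, connection radii (in target-population index units),
#' connection probabilities, and per-edge conductances.  Only the PY->PY
#' AMPA projection is probabilistic (p = 0.6) and plastic; all other
#' projections are deterministic within their radius.  `strength` is the
#' fixed per-edge maximal conductance (uS) of non-plastic projections
#' (plastic edges carry their own weights).
#'
#' @param radii optional named numeric vector overriding individual
#'   radii; names are `"<SRC>_<DST>_<RECEPTOR>"`, e.g. `"PY_PY_AMPA"`.
#' @param strengths optional named numeric vector overriding per-edge
#'   conductances, same naming scheme.
#' @param gains optional named numeric vector overriding the
#'   dimensionless per-projection gains that convert edge conductance
#'   (weight) into effective postsynaptic conductance; the cortical
#'   projections share a calibrated gain so that unitary PSPs lie in
#'   the physiological sub-millivolt-to-millivolt range.
#' @return data.frame with one row per projection.
#' @export
default_projections <- function(radii = NULL, strengths = NULL,
                                gains = NULL) {
  p <- data.frame(
    source   = c("TC", "RE", "RE", "RE", "PY", "PY", "PY", "PY", "IN",
                 "TC", "TC", "PY", "PY"),
    target   = c("RE", "TC", "TC", "RE", "PY", "PY", "IN", "IN", "PY",
                 "PY", "IN", "TC", "RE"),
    receptor = c("AMPA", "GABAA", "GABAB", "GABAA", "AMPA", "NMDA",
                 "AMPA", "NMDA", "GABAA", "AMPA", "AMPA", "AMPA", "AMPA"),
    radius   = c(8, 8, 8, 5, 20, 5, 1, 1, 5, 15, 3, 10, 8),
    prob     = c(1, 1, 1, 1, 0.6, 1, 1, 1, 1, 1, 1, 1, 1),
    strength = c(0.004, 0.01, 0.002, 0.01, NA, 0.015, 0.075, 0.01, 0.2,
                 0.007, 0.002, 0.002, 0.005),
    gain     = c(1, 1, 1, 1, 0.15, 0.15, 0.15, 0.15, 0.15,
                 1, 1, 1, 1),
    plastic  = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  p$name <- paste(p$source, p$target, p$receptor, sep = "_")
  if (!is.null(radii)) {
    bad <- setdiff(names(radii), p$name)
    if (length(bad)) stop("unknown projection name(s): ", paste(bad, collapse = ", "))
    p$radius[match(names(radii), p$name)] <- radii
  }
  if (!is.null(strengths)) {
    bad <- setdiff(names(strengths), p$name)
    if (length(bad)) stop("unknown projection name(s): ", paste(bad, collapse = ", "))
    p$strength[match(names(strengths), p$name)] <- strengths
  }
  if (!is.null(gains)) {
    bad <- setdiff(names(gains), p$name)
    if (length(bad)) stop("unknown projection name(s): ", paste(bad, collapse = ", "))
    p$gain[match(names(gains), p$name)] <- gains
  }
  p
}

# Topographic center of source neuron i (local, 1-based) in target index
# units.  Linear map that is exact for equal-size populations and
# symmetric under index reversal.
.target_center <- function(i, n_source, n_target) {
  (i - 0.5) * n_target / n_source + 0.5
}

#' Build anatomical connectivity
#'
#' Realises every projection of `projections` on `layout`: source neuron
#' `i` connects to target neuron `j` iff `|j - center(i)| <= radius` in
#' target index units (truncated at array edges, no wrap-around), the
#' Bernoulli(`prob`) draw succeeds, and `i != j` within a population.
#' Deterministic given `seed`.
#'
#' @param layout a [population_layout()].
#' @param projections projection table (see [default_projections()]).
#' @param seed integer seed for the probabilistic projections.
#' @return object of class `connectivity`: list with `layout`,
#'   `projections`, and `edges` — a named list of data.frames
#'   (`src`, `dst`, global ids) per projection.
#' @export
build_connectivity <- function(layout, projections = default_projections(),
                               seed = 1L) {
  stopifnot(inherits(layout, "population_layout"))
  for (k in seq_len(nrow(projections))) {
    nt <- layout$n[[projections$target[k]]]
    if (projections$radius[k] > nt)
      stop("radius of ", projections$name[k],
           " exceeds target population size (", nt, ")")
  }
  edges <- vector("list", nrow(projections))
  names(edges) <- projections$name
  rng <- local_rng(seed)
  for (k in seq_len(nrow(projections))) {
    src_pop <- projections$source[k]
    dst_pop <- projections$target[k]
    ns <- layout$n[[src_pop]]
    nt <- layout$n[[dst_pop]]
    r <- projections$radius[k]
    src_l <- integer(0); dst_l <- integer(0)
    for (i in seq_len(ns)) {
      c0 <- .target_center(i, ns, nt)
      js <- max(1, ceiling(c0 - r - 1e-9)):min(nt, floor(c0 + r + 1e-9))
      if (src_pop == dst_pop) js <- js[js != i]
      if (length(js)) {
        src_l <- c(src_l, rep.int(i, length(js)))
        dst_l <- c(dst_l, js)
      }
    }
    if (projections$prob[k] < 1) {
      keep <- rng$runif(length(src_l)) < projections$prob[k]
      src_l <- src_l[keep]; dst_l <- dst_l[keep]
    }
    edges[[k]] <- data.frame(
      src = layout$range[[src_pop]][1] - 1 + src_l,
      dst = layout$range[[dst_pop]][1] - 1 + dst_l)
  }
  structure(list(layout = layout, projections = projections, edges = edges,
                 seed = seed),
            class = "connectivity")
}

#' Anatomical mask of the plastic PY->PY AMPA projection
#'
#' @param conn a [build_connectivity()] result.
#' @return logical `n_PY x n_PY` matrix, `[i, j]` meaning an edge
#'   `i -> j` (PY-local indices).
#' @export
pypy_mask <- function(conn) {
  stopifnot(inherits(conn, "connectivity"))
  n <- conn$layout$n[["PY"]]
  e <- conn$edges[["PY_PY_AMPA"]]
  m <- matrix(FALSE, n, n)
  m[cbind(e$src, e$dst)] <- TRUE
  m
}

#' Initialise Gaussian-distributed plastic weights
#'
#' Draws one weight per masked edge from a normal distribution truncated
#' at 0 and `g_max` (rejection sampling).
#'
#' @param mask logical adjacency matrix (source x target).
#' @param mean,sd mean and standard deviation of the untruncated normal
#'   (uS).  Defaults: mean 0.075 uS, sd one tenth of the mean.
#' @param g_max weight upper bound (uS).
#' @param seed integer seed.
#' @param meta optional metadata list (phase label, time).
#' @return object of class `weight_matrix`: list with `mask`, `w`
#'   (numeric matrix, 0 off the mask), `g_max`, `meta`.
#' @export
init_weights <- function(mask, mean = 0.075, sd = 0.1 * mean,
                         g_max = 0.15, seed = 1L, meta = list()) {
  stopifnot(is.matrix(mask), is.logical(mask), sd >= 0)
  if (mean < 0 || mean > g_max)
    stop("initial mean must lie in [0, g_max]")
  rng <- local_rng(seed)
  ne <- sum(mask)
  w <- numeric(ne)
  todo <- seq_len(ne)
  while (length(todo)) {
    w[todo] <- rng$rnorm(length(todo), mean, sd)
    todo <- todo[w[todo] < 0 | w[todo] > g_max]
    if (sd == 0) break
  }
  W <- matrix(0, nrow(mask), ncol(mask))
  W[mask] <- w
  meta <- modifyList(list(phase = "baseline", time = 0, seed = seed), meta)
  structure(list(mask = mask, w = W, g_max = g_max, meta = meta),
            class = "weight_matrix")
}

#' Construct a weight-matrix snapshot
#'
#' @param mask logical adjacency matrix.
#' @param w numeric weight matrix (0 off the mask).
#' @param g_max weight upper bound (uS).
#' @param phase phase label of the snapshot.
#' @param time simulation time of the snapshot (ms).
#' @param seed seed of the run.
#' @return a `weight_matrix` object.
#' @export
weight_matrix <- function(mask, w, g_max = 0.15, phase = "snapshot",
                          time = 0, seed = NA_integer_) {
  stopifnot(is.matrix(mask), is.logical(mask),
            identical(dim(mask), dim(w)))
  if (any(w[!mask] != 0)) stop("weights present off the anatomical mask")
  if (any(w < 0) || any(w > g_max)) stop("weights outside [0, g_max]")
  structure(list(mask = mask, w = w, g_max = g_max,
                 meta = list(phase = phase, time = time, seed = seed)),
            class = "weight_matrix")
}

#' Save / load a weight-matrix snapshot as delimited text
#'
#' The file starts with `#`-prefixed metadata lines (phase, time, seed,
#' g_max, dimensions) followed by whitespace-delimited `src dst weight`
#' rows, one per anatomical edge.  `load_weights()` reconstructs the
#' mask from the edge list; if `mask` is supplied, the file's edge
#' support must match it exactly.
#'
#' @param wm a `weight_matrix`.
#' @param path file path.
#' @export
save_weights <- function(wm, path) {
  stopifnot(inherits(wm, "weight_matrix"))
  idx <- which(wm$mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  hdr <- c(paste("# phase:", wm$meta$phase),
           paste("# time:", format(wm$meta$time, digits = 15)),
           paste("# seed:", wm$meta$seed),
           paste("# g_max:", format(wm$g_max, digits = 17)),
           paste("# dim:", nrow(wm$mask), ncol(wm$mask)))
  rows <- paste(idx[, 1], idx[, 2],
                format(wm$w[idx], digits = 17, scientific = TRUE, trim = TRUE))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname save_weights
#' @param mask optional logical matrix the loaded support must equal.
#' @return `load_weights()`: a `weight_matrix`.
#' @export
load_weights <- function(path, mask = NULL) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("malformed weight file: missing header '", key, "'")
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  dm <- as.integer(strsplit(get_field("dim"), "\\s+")[[1]])
  body <- lines[!is_hdr]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(parts) != 3)
  if (length(bad))
    stop("parse error in weight file at line ", which(!is_hdr)[bad[1]])
  src <- as.integer(vapply(parts, `[[`, "", 1))
  dst <- as.integer(vapply(parts, `[[`, "", 2))
  w <- as.numeric(vapply(parts, `[[`, "", 3))
  if (anyNA(src) || anyNA(dst) || anyNA(w))
    stop("parse error in weight file: non-numeric entry")
  m <- matrix(FALSE, dm[1], dm[2])
  m[cbind(src, dst)] <- TRUE
  if (!is.null(mask) && !identical(which(mask), which(m)))
    stop("weight file support disagrees with the supplied anatomical mask")
  W <- matrix(0, dm[1], dm[2])
  W[cbind(src, dst)] <- w
  weight_matrix(m, W, g_max = as.numeric(get_field("g_max")),
                phase = get_field("phase"),
                time = as.numeric(get_field("time")),
                seed = suppressWarnings(as.integer(get_field("seed"))))
}

# Private RNG stream (xorshift-free: reuse R's RNG without touching the
# global seed state of the caller).
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  })
  with_state <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f(...)
  }
  list(runif = with_state(runif), rnorm = with_state(rnorm),
       rexp = with_state(rexp))
}
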