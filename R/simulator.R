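#' Initialize a frontier from a well-mixed inoculum
#'
#' Lays \code{n0} cells of width \code{a} around the initial ring and places a
#' domain wall at every boundary between unlike neighbours (angular positions
#' \code{k * 2*pi / n0}).  Labels are drawn iid with the inoculated
#' probabilities (\code{init_mode = "iid"}) or placed in exact rounded
#' proportions in uniformly random order (\code{"exact"}).  Uses the current
#' RNG state; seed beforehand for reproducibility.
#'
#' @param p a validated [sim_params()] object.
#' @return a [frontier_state()] at \code{L = 0}.  With a single strain (or a
#'   monoclonal draw) the state has zero walls.
#' @export
init_frontier <- function(p) {
  validate_params(p)
  n0 <- p$n0
  q <- p$q
  if (p$init_mode == "iid") {
    labels <- sample.int(q, n0, replace = TRUE, prob = p$init_fractions) - 1L
  } else {
    counts <- floor(n0 * p$init_fractions)
    short <- n0 - sum(counts)
    if (short > 0) {
      rem <- n0 * p$init_fractions - counts
      counts[order(rem, decreasing = TRUE)[seq_len(short)]] <-
        counts[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
    }
    labels <- sample(rep.int(0:(q - 1L), counts))
  }
  cell_labels_to_frontier(labels, p)
}

# build the wall representation from per-cell labels on the initial ring
cell_labels_to_frontier <- function(labels, p) {
  n0 <- length(labels)
  prev <- c(labels[n0], labels[-n0])
  at <- which(labels != prev)            # wall at the left edge of cell k
  geometry <- p$geometry
  if (length(at) == 0) {
    return(frontier_state(numeric(), integer(), p$q, R0 = p$R0,
                          geometry = geometry, mono = labels[1]))
  }
  frontier_state(phi = (at - 1) * 2 * pi / n0, labels = labels[at], q = p$q,
                 R0 = p$R0, geometry = geometry)
}

# shared call into the compiled engine; the engine's clock starts at zero and
# its starting radius is the state's *current* radius, so stepping a
# mid-trajectory state inflates correctly
engine_call <- function(st, p, snapshot_L, max_L, max_steps) {
  cpp_run_expansion(st$phi, st$labels, st$R,
                    radial = identical(st$geometry, "radial"),
                    a = p$a, d = p$d, bias = p$bias,
                    snapshot_L = snapshot_L, max_L = max_L,
                    max_steps = max_steps)
}

events_df <- function(ev) {
  d <- data.frame(L_at = ev$L_at,
                  kind = c("annihilation", "coalescence")[ev$kind],
                  left_in1 = ev$left_in1, right_in1 = ev$right_in1,
                  left_in2 = ev$left_in2, right_in2 = ev$right_in2,
                  left_out = ev$left_out, right_out = ev$right_out,
                  stringsAsFactors = FALSE)
  d
}

raw_to_state <- function(s, q, geometry, events, init_mono = NA_integer_,
                         R0 = s$R0) {
  mono <- NA_integer_
  if (s$n_walls == 0) {
    # surviving strain: outer flank of the last annihilation, or the initial
    # monoclonal strain if the run started with no walls
    mono <- if (length(events$L_at)) {
      k <- max(which(events$kind == 1L))
      events$left_in1[k]
    } else init_mono
  }
  frontier_state(s$phi, s$lab, q, R0 = R0, R = s$R, L = s$L, t = s$t,
                 geometry = geometry, mono = mono)
}

#' Advance a frontier by a single wall hop
#'
#' Performs one step of the random-walk update: a uniformly chosen wall of
#' type \eqn{ij} hops right with probability \eqn{(1 + r_{ij})/2} (else left)
#' by an angular distance \code{a / R}, reacting instantly with a neighbour it
#' reaches or crosses.  Time advances by \code{1/N} generations and the length
#' expanded by \code{d/N}, with \code{N} the wall count before the hop.
#'
#' @param st a [frontier_state()] with at least one wall.
#' @param p the [sim_params()] governing the run.
#' @return a list with elements \code{state} (the new frontier) and
#'   \code{event} (a one-row data frame describing the collision, or
#'   \code{NULL} if none occurred).
#' @export
step_frontier <- function(st, p) {
  if (length(st$phi) == 0) stop("cannot step a fixed frontier (0 walls)")
  res <- engine_call(st, p, snapshot_L = numeric(), max_L = Inf, max_steps = 1)
  new_st <- raw_to_state(res$final, st$q, st$geometry, res$events, R0 = st$R0)
  # carry forward elapsed time/length of the incoming state
  new_st$L <- st$L + (new_st$L)
  new_st$t <- st$t + (new_st$t)
  ev <- if (res$n_events > 0) events_df(res$events) else NULL
  if (!is.null(ev)) ev$L_at <- ev$L_at + st$L
  list(state = new_st, event = ev)
}

#' Run one range expansion to fixation or a target length
#'
#' Repeats the wall-hop update until no walls remain, until the length
#' expanded exceeds the last requested snapshot, or until \code{max_steps}
#' hops.  The frontier state is recorded at the first step where \code{L}
#' reaches each value in \code{p$snapshot_lengths}; if fixation occurs first,
#' the remaining snapshots repeat the fixed state.
#'
#' @param p a validated [sim_params()].
#' @param init optional initial [frontier_state()]; defaults to
#'   [init_frontier()] under \code{p}.
#' @param seed optional seed (defaults to \code{p$seed}; \code{NULL} leaves
#'   the RNG state untouched).
#' @return an object of class \code{"rw_trajectory"}: a list with
#'   \code{snapshots} (list of frontier states), \code{snapshot_at} (the
#'   requested lengths), \code{events} (chronological collision log),
#'   \code{final} state, and \code{params}.
#' @export
#' @examples
#' p <- sim_params(n0 = 60, q = 2, seed = 1, snapshot_lengths = c(5, 10))
#' tr <- run_expansion(p)
#' tr$final
run_expansion <- function(p, init = NULL, seed = p$seed) {
  validate_params(p)
  if (!is.null(seed)) set.seed(seed)
  st <- if (is.null(init)) init_frontier(p) else validate_frontier(init)
  snaps <- p$snapshot_lengths
  max_L <- if (length(snaps)) max(snaps) else Inf
  res <- engine_call(st, p, snapshot_L = snaps, max_L = max_L,
                     max_steps = p$max_steps)
  ev <- events_df(res$events)
  out <- list(
    snapshots = lapply(res$snapshots, raw_to_state, q = st$q,
                       geometry = st$geometry, events = res$events,
                       init_mono = st$mono),
    snapshot_at = snaps,
    events = ev,
    final = raw_to_state(res$final, st$q, st$geometry, res$events,
                         init_mono = st$mono),
    steps = res$steps,
    params = p
  )
  class(out) <- "rw_trajectory"
  out
}

#' @export
print.rw_trajectory <- function(x, ...) {
  na <- sum(x$events$kind == "annihilation")
  nc <- sum(x$events$kind == "coalescence")
  cat(sprintf(
    "Range-expansion trajectory: %d snapshots, %d annihilations, %d coalescences\n",
    length(x$snapshots), na, nc))
  cat(sprintf("  final: %d walls at L = %.4g (%.3g hops)\n",
              length(x$final$phi), x$final$L, x$steps))
  invisible(x)
}

#' Deterministic per-replicate seeds from a base seed
#'
#' The first \code{k} seeds are identical for any ensemble size, so
#' replicates are reproducible independently of how many are run.
#'
#' @param base_seed integer.
#' @param n_reps number of replicates.
#' @return integer vector of length \code{n_reps}.
#' @export
replicate_seeds <- function(base_seed, n_reps) {
  set.seed(base_seed)
  sample.int(.Machine$integer.max - 1L, n_reps)
}

#' Run an ensemble of independent range expansions
#'
#' Runs \code{n_reps} independent trajectories with per-replicate seeds
#' derived deterministically from \code{base_seed} (bit-for-bit reproducible,
#' order-independent) and, when snapshots were requested, aggregates them into
#' an [ensemble_summary()].
#'
#' @param p a validated [sim_params()].
#' @param n_reps number of replicates (>= 1).
#' @param base_seed integer base seed.
#' @param n_bins angular bins used when rasterizing snapshots for the
#'   ensemble observables.
#' @param init optional common initial state passed to every replicate
#'   (e.g. a single-sector state); default draws a fresh inoculum per
#'   replicate.
#' @param summarize compute the ensemble summary (set \code{FALSE} to return
#'   trajectories only).
#' @return list with \code{trajectories} and \code{summary} (an
#'   \code{"ensemble_summary"} or \code{NULL}).
#' @export
run_ensemble <- function(p, n_reps, base_seed, n_bins = 500, init = NULL,
                         summarize = TRUE) {
  stopifnot(n_reps >= 1)
  seeds <- replicate_seeds(base_seed, n_reps)
  trajectories <- lapply(seeds, function(s) run_expansion(p, init = init, seed = s))
  summ <- NULL
  if (summarize && length(p$snapshot_lengths)) {
    ff <- fraction_fields(trajectories, n_bins = n_bins)
    summ <- ensemble_summary(ff, lapply(trajectories, `[[`, "events"))
  }
  list(trajectories = trajectories, summary = summ)
}
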