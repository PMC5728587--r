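#' Simulation parameters for a domain-wall range-expansion run
#'
#' Bundles every microscopic input of the annihilating-coalescing random-walk
#' model: the initial number of cells at the frontier \code{n0}, the cell
#' width \code{a}, the length expanded per generation \code{d}, the number of
#' strains \code{q}, the inoculated fractions, the antisymmetric selection
#' bias matrix \code{bias} (entry \code{bias[i+1, j+1]} is the probability
#' bias \eqn{r_{ij}} with which a wall separating strain \eqn{i} on the left
#' from strain \eqn{j} on the right hops outward-right), the frontier
#' geometry, and the snapshot schedule.
#'
#' Strain labels are integers \code{0:(q-1)} throughout the package.  The
#' initial frontier is a ring of circumference \code{n0 * a}, so the initial
#' radius is \code{R0 = n0 * a / (2*pi)}; for \code{geometry = "linear"} the
#' radius (and hence the angular hop size) never inflates.
#'
#' @param n0 integer >= 2, initial number of cells at the frontier.
#' @param q integer >= 1, number of strains.
#' @param init_fractions numeric vector of length \code{q} summing to 1.
#' @param bias \code{q x q} antisymmetric matrix with entries in [-1, 1] and
#'   zero diagonal; defaults to all-neutral (zeros).
#' @param a cell width (length units).
#' @param d length expanded per generation; defaults to \code{a}.
#' @param geometry \code{"linear"} or \code{"radial"}.
#' @param seed optional RNG seed applied by [run_expansion()].
#' @param snapshot_lengths increasing numeric vector of expansion lengths
#'   \code{L} at which to record the frontier state.
#' @param init_mode \code{"iid"} draws each initial cell label independently
#'   with probabilities \code{init_fractions} (a well-mixed inoculum);
#'   \code{"exact"} places \code{round(n0 * f_i)} cells of each strain in
#'   uniformly random order.
#' @param max_steps safety cap on the number of wall hops.
#' @return a validated object of class \code{"sim_params"}.
#' @seealso [validate_params()], [run_expansion()]
#' @export
#' @examples
#' p <- sim_params(n0 = 100, q = 2, init_fractions = c(0.5, 0.5))
#' p$R0
sim_params <- function(n0, q, init_fractions = rep(1 / q, q), bias = NULL,
                       a = 1, d = a, geometry = c("linear", "radial"),
                       seed = NULL, snapshot_lengths = numeric(),
                       init_mode = c("iid", "exact"), max_steps = 1e12) {
  geometry <- match.arg(geometry)
  init_mode <- match.arg(init_mode)
  if (is.null(bias)) bias <- matrix(0, q, q)
  p <- structure(list(
    n0 = as.integer(n0), q = as.integer(q),
    init_fractions = as.numeric(init_fractions),
    bias = bias, a = a, d = d,
    R0 = n0 * a / (2 * pi),
    geometry = geometry, seed = seed,
    snapshot_lengths = as.numeric(snapshot_lengths),
    init_mode = init_mode, max_steps = max_steps
  ), class = "sim_params")
  validate_params(p)
}

#' Validate simulation parameters
#'
#' Checks every invariant of a [sim_params()] object and returns it unchanged
#' if all hold; otherwise stops with a message naming the first violation.
#'
#' @param p a \code{"sim_params"} object.
#' @return \code{p}, invisibly unchanged.
#' @export
validate_params <- function(p) {
  if (!inherits(p, "sim_params")) stop("not a sim_params object")
  if (is.na(p$n0) || p$n0 < 2) stop("n0 must be an integer >= 2")
  if (p$q < 1) stop("q must be >= 1")
  if (p$a <= 0 || p$d <= 0) stop("a and d must be positive")
  f <- p$init_fractions
  if (length(f) != p$q) stop("init_fractions must have length q")
  if (any(f < 0)) stop("init_fractions must be non-negative")
  if (abs(sum(f) - 1) > 1e-12) stop("fractions sum != 1")
  b <- p$bias
  if (!is.matrix(b) || any(dim(b) != p$q)) stop("bias must be a q x q matrix")
  if (any(abs(b) > 1)) stop("bias entries must lie in [-1, 1]")
  if (max(abs(b + t(b))) > 1e-12) stop("bias not antisymmetric")
  if (any(diag(b) != 0)) stop("bias diagonal must be zero")
  s <- p$snapshot_lengths
  if (length(s) && (any(s < 0) || is.unsorted(s, strictly = TRUE)))
    stop("snapshot_lengths must be strictly increasing and non-negative")
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "Domain-wall simulation parameters\n  q = %d strains, n0 = %d cells (R0 = %.4g), %s geometry\n",
    x$q, x$n0, x$R0, x$geometry))
  cat(sprintf("  a = %g, d = %g, init_mode = %s\n", x$a, x$d, x$init_mode))
  cat("  fractions:", paste(signif(x$init_fractions, 4), collapse = ", "), "\n")
  if (any(x$bias != 0)) cat("  selection biases present\n") else cat("  neutral\n")
  invisible(x)
}

#' Construct a frontier state
#'
#' A frontier state is the exact off-lattice representation of a colony edge:
#' a cyclically ordered set of domain walls at angular positions
#' \code{phi} in [0, 2*pi), where \code{labels[k]} is the strain occupying the
#' arc running counter-clockwise from wall \code{k} to wall \code{k + 1}
#' (wrapping).  The wall \code{k} therefore has type
#' \code{(labels[k-1] | labels[k])}.  A state with zero walls is a fixed
#' (monoclonal) frontier whose strain is \code{mono}.
#'
#' @param phi sorted numeric vector of wall angles in [0, 2*pi).
#' @param labels integer vector (0-based strain ids), same length as phi.
#' @param q number of strains the labels are drawn from.
#' @param R0 initial radius; \code{R} current radius; \code{L} length expanded
#'   (\code{R - R0} in radial geometry); \code{t} elapsed generations.
#' @param R,L,t see \code{R0}.
#' @param geometry \code{"linear"} or \code{"radial"}.
#' @param mono strain id of a wall-free frontier (ignored when walls exist).
#' @return object of class \code{"frontier_state"}.
#' @export
frontier_state <- function(phi, labels, q, R0, R = R0, L = 0, t = 0,
                           geometry = "linear", mono = NA_integer_) {
  st <- structure(list(
    phi = as.numeric(phi), labels = as.integer(labels), q = as.integer(q),
    R0 = R0, R = R, L = L, t = t, geometry = geometry,
    mono = as.integer(mono)
  ), class = "frontier_state")
  validate_frontier(st)
}

#' Validate a frontier state
#'
#' Checks that wall angles lie in [0, 2*pi) and are strictly increasing, that
#' adjacent arcs carry different strains (no null walls), and that arc widths
#' sum to 2*pi.
#'
#' @param st a \code{"frontier_state"}.
#' @return \code{st} unchanged.
#' @export
validate_frontier <- function(st) {
  n <- length(st$phi)
  if (length(st$labels) != n) stop("phi and labels must have equal length")
  if (n == 0) {
    if (is.na(st$mono)) stop("a wall-free state must name its strain (mono)")
    return(st)
  }
  if (n == 1) stop("a single wall cannot exist on a ring")
  if (any(st$phi < 0 | st$phi >= 2 * pi)) stop("phi must lie in [0, 2*pi)")
  if (is.unsorted(st$phi, strictly = TRUE)) stop("phi must be strictly increasing")
  if (any(st$labels < 0 | st$labels >= st$q)) stop("labels out of range")
  adj <- st$labels != c(st$labels[n], st$labels[-n])
  if (!all(adj)) stop("adjacent arcs must carry different strains")
  w <- arc_widths(st)
  if (abs(sum(w) - 2 * pi) > 1e-9) stop("arc widths must sum to 2*pi")
  st
}

#' Angular widths of the arcs of a frontier state
#'
#' @param st a \code{"frontier_state"}.
#' @return numeric vector; \code{arc_widths(st)[k]} is the width of the arc
#'   labelled \code{st$labels[k]}.  Sums to 2*pi.
#' @export
arc_widths <- function(st) {
  n <- length(st$phi)
  if (n == 0) return(2 * pi)
  d <- diff(c(st$phi, st$phi[1] + 2 * pi))
  d
}

#' @export
print.frontier_state <- function(x, ...) {
  n <- length(x$phi)
  cat(sprintf("Frontier state (%s): %d walls, q = %d\n", x$geometry, n, x$q))
  cat(sprintf("  R0 = %.4g, R = %.4g, L = %.4g, t = %.4g generations\n",
              x$R0, x$R, x$L, x$t))
  if (n == 0) cat(sprintf("  fixed: strain %d occupies the whole ring\n", x$mono))
  invisible(x)
}
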