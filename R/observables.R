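#' Exact angular occupancy profile of a frontier state
#'
#' Discretizes the exact wall representation onto \code{n_bins} uniform
#' angular bins.  Each bin's entry for strain \eqn{i} is the fraction of the
#' bin's angular measure occupied by that strain, computed from the arc
#' geometry (not by point sampling), so strain measure is conserved exactly.
#'
#' @param st a [frontier_state()].
#' @param n_bins number of angular bins (>= 1).
#' @return a \code{q x n_bins} matrix of local fractions; columns sum to 1.
#' @export
occupancy_profile <- function(st, n_bins) {
  stopifnot(n_bins >= 1)
  if (length(st$phi) == 0) {
    f <- matrix(0, st$q, n_bins)
    f[st$mono + 1L, ] <- 1
    return(f)
  }
  cpp_occupancy(st$phi, st$labels, st$q, as.integer(n_bins))
}

#' Build a local strain-fraction field from an ensemble of trajectories
#'
#' Rasterizes each requested snapshot of each trajectory with
#' [occupancy_profile()], producing the per-replicate local fraction field
#' \eqn{f_i(\phi_k, L_m)} on a uniform angular grid.
#'
#' @param trajectories list of \code{"rw_trajectory"} objects sharing the same
#'   snapshot schedule and strain count.
#' @param n_bins number of angular bins.
#' @return a [fraction_field()] object.
#' @export
fraction_fields <- function(trajectories, n_bins = 500) {
  stopifnot(length(trajectories) >= 1)
  t1 <- trajectories[[1]]
  q <- t1$final$q
  L_grid <- t1$snapshot_at
  n_L <- length(L_grid)
  if (n_L == 0) stop("trajectories carry no snapshots")
  n_rep <- length(trajectories)
  f <- array(NA_real_, dim = c(q, n_bins, n_L, n_rep))
  for (r in seq_len(n_rep)) {
    sn <- trajectories[[r]]$snapshots
    for (m in seq_len(n_L)) f[, , m, r] <- occupancy_profile(sn[[m]], n_bins)
  }
  fraction_field(f, L_grid)
}

#' Local strain-fraction field container
#'
#' Holds per-replicate local fractions \eqn{f_i(\phi_k, L_m)} on a uniform
#' angular grid, the form produced by rasterizing simulated frontiers or by an
#' imaging pipeline.  Normalization \eqn{\sum_i f_i = 1} is enforced at every
#' grid point.
#'
#' @param f numeric array with dimensions (strain, angular bin, length,
#'   replicate); a 3-d array is promoted to a single replicate.
#' @param L_grid lengths expanded corresponding to the third dimension.
#' @return object of class \code{"fraction_field"} with elements \code{f},
#'   \code{phi_grid} (bin centers), \code{L_grid}, \code{q}, \code{n_rep}.
#' @export
fraction_field <- function(f, L_grid) {
  if (length(dim(f)) == 3) dim(f) <- c(dim(f), 1)
  stopifnot(length(dim(f)) == 4, dim(f)[3] == length(L_grid))
  tot <- apply(f, c(2, 3, 4), sum)
  if (max(abs(tot - 1)) > 1e-9) stop("fractions must sum to 1 at every grid point")
  n_bins <- dim(f)[2]
  structure(list(
    f = f,
    phi_grid = (seq_len(n_bins) - 0.5) * 2 * pi / n_bins,
    L_grid = as.numeric(L_grid),
    q = dim(f)[1], n_rep = dim(f)[4]
  ), class = "fraction_field")
}

#' @export
print.fraction_field <- function(x, ...) {
  cat(sprintf(
    "Fraction field: %d strains x %d angular bins x %d lengths x %d replicates\n",
    x$q, length(x$phi_grid), length(x$L_grid), x$n_rep))
  invisible(x)
}

#' Ensemble-averaged strain fractions
#'
#' The average fraction of strain \eqn{i} at length \eqn{L} is the angular
#' mean of the local fraction, averaged over replicates; the standard error is
#' over replicates.  For a neutral expansion this stays at the inoculated
#' fractions; selection drives the fractions of less fit strains down.
#'
#' @param ff a [fraction_field()].
#' @return data frame with columns \code{L}, \code{strain} (0-based id),
#'   \code{F}, \code{se} (\code{NA} for a single replicate).
#' @export
average_fraction <- function(ff) {
  per_rep <- apply(ff$f, c(1, 3, 4), mean)     # strain x L x rep
  m <- apply(per_rep, c(1, 2), mean)
  s <- if (ff$n_rep > 1) apply(per_rep, c(1, 2), sd) / sqrt(ff$n_rep) else
    array(NA_real_, dim(m))
  data.frame(
    L = rep(ff$L_grid, each = ff$q),
    strain = rep(0:(ff$q - 1), length(ff$L_grid)),
    F = as.vector(m), se = as.vector(s)
  )
}

# circular cross-correlations of all strain pairs at one (L, replicate):
# corr[i,j,k] = mean_m f_i[m] * f_j[m + k]
circ_corr <- function(fmat) {
  n <- ncol(fmat)
  G <- stats::mvfft(t(fmat))                  # n x q
  q <- nrow(fmat)
  out <- array(0, c(q, q, n))
  for (i in seq_len(q)) for (j in seq_len(q)) {
    out[i, j, ] <- Re(stats::fft(Conj(G[, i]) * G[, j], inverse = TRUE)) / n^2
  }
  out
}

#' Two-point angular correlation functions
#'
#' Computes the symmetrized correlation
#' \eqn{F_{ij}(\phi, L) = \frac{1}{4\pi}\int d\phi'
#' \langle f_i(\phi') f_j(\phi' + \phi) + f_j(\phi') f_i(\phi' + \phi)\rangle}
#' as an exact circular convolution on the uniform angular grid, per
#' replicate, then averaged over replicates with standard errors.
#' \eqn{F_{ij}(\phi)} is the probability that two frontier points an angle
#' \eqn{\phi} apart carry strains \eqn{i} and \eqn{j}; it satisfies
#' \eqn{F_{ij} = F_{ji}}, \eqn{F_{ij}(\phi) = F_{ij}(-\phi)} and
#' \eqn{\sum_{ij} F_{ij} = 1}.
#'
#' @param ff a [fraction_field()] on a uniform angular grid.
#' @return object of class \code{"two_point"}: list with \code{phi_grid}
#'   (separations \code{k * 2*pi/n}), \code{L_grid}, \code{Fij} (array
#'   strain x strain x separation x L), \code{se}, and the per-replicate
#'   heterozygosity \code{H_rep} used by [heterozygosity()].
#' @export
two_point_correlation <- function(ff) {
  q <- ff$q; n <- length(ff$phi_grid)
  n_L <- length(ff$L_grid); n_rep <- ff$n_rep
  acc <- array(0, c(q, q, n, n_L))
  acc2 <- array(0, c(q, q, n, n_L))
  H_rep <- array(0, c(n, n_L, n_rep))
  for (r in seq_len(n_rep)) {
    for (m in seq_len(n_L)) {
      cc <- circ_corr(ff$f[, , m, r, drop = TRUE])
      if (q == 1) dim(cc) <- c(1, 1, n)
      sym <- (cc + aperm(cc, c(2, 1, 3))) / 2
      acc[, , , m] <- acc[, , , m] + sym
      acc2[, , , m] <- acc2[, , , m] + sym^2
      diag_sum <- apply(sym, 3, function(M) sum(diag(M)))
      H_rep[, m, r] <- 1 - diag_sum
    }
  }
  Fij <- acc / n_rep
  se <- if (n_rep > 1) sqrt(pmax(acc2 / n_rep - Fij^2, 0) / (n_rep - 1)) else
    array(NA_real_, dim(Fij))
  structure(list(phi_grid = (seq_len(n) - 1) * 2 * pi / n,
                 L_grid = ff$L_grid, Fij = Fij, se = se, H_rep = H_rep,
                 n_rep = n_rep),
            class = "two_point")
}

#' @export
print.two_point <- function(x, ...) {
  cat(sprintf(
    "Two-point correlation functions: %d strains, %d separations, %d lengths (%d replicates)\n",
    dim(x$Fij)[1], length(x$phi_grid), length(x$L_grid), x$n_rep))
  invisible(x)
}

#' Heterozygosity from two-point correlation functions
#'
#' \eqn{H(\phi, L) = \sum_{i \ne j} F_{ij}(\phi, L)} is the probability that
#' two frontier points separated by angle \eqn{\phi} carry different strains.
#' Computed per replicate (identically \eqn{1 - \sum_i F_{ii}}), with
#' standard errors over replicates.
#'
#' @param tp a \code{"two_point"} object from [two_point_correlation()].
#' @return list with \code{phi_grid}, \code{L_grid}, \code{H} (separation x L
#'   matrix), \code{se}.
#' @export
heterozygosity <- function(tp) {
  H <- apply(tp$H_rep, c(1, 2), mean)
  se <- if (tp$n_rep > 1) apply(tp$H_rep, c(1, 2), sd) / sqrt(tp$n_rep) else
    array(NA_real_, dim(H))
  list(phi_grid = tp$phi_grid, L_grid = tp$L_grid, H = H, se = se)
}

#' Annihilation asymmetry from collision logs
#'
#' Estimates \eqn{\Delta P}, the difference between the annihilation and
#' coalescence probabilities per domain-wall collision, as the least-squares
#' slope through the origin of the ensemble-averaged cumulative difference
#' \eqn{\langle A - C\rangle} against the ensemble-averaged cumulative
#' collision count \eqn{\langle A + C\rangle}, after discarding an initial
#' burn-in fraction of the collision record.  The standard error is a
#' between-replicate bootstrap.
#'
#' For compositions away from equal fractions the per-collision asymmetry is
#' not constant: it drifts as coarsening builds correlations between
#' neighbouring domains.  The closed-form neutral prediction for a given
#' inoculated composition refers to the uncorrelated (inoculated) domain
#' pattern, so its simulation estimate restricts the record to the earliest
#' collisions: \code{max_L} keeps only collisions within that length expanded
#' (one generation, \code{max_L = d}, is the natural window — the inoculated
#' pattern has barely evolved), while \code{max_collisions = 1} is the
#' parameter-free but higher-variance expectation over each replicate's first
#' collision.  For equal fractions the asymmetry is constant and the window
#' is immaterial.
#'
#' @param event_logs list of event data frames (one per replicate) as found
#'   in \code{trajectory$events}.
#' @param n_grid number of points of the length grid the cumulative counts
#'   are evaluated on.
#' @param burn_in fraction of the collision record discarded before the
#'   slope regression.
#' @param n_boot bootstrap resamples for the standard error (0 disables).
#' @param max_collisions optional per-replicate cap: only the first
#'   \code{max_collisions} collisions of each replicate enter the record.
#' @param max_L optional cap on the length expanded: only collisions with
#'   \code{L_at <= max_L} enter the record.
#' @return list with \code{delta_p}, \code{se}, \code{cum} (data frame of the
#'   averaged cumulative counts), \code{n_replicates}.  \code{delta_p} is
#'   \code{NA} when no collisions were recorded.
#' @export
annihilation_asymmetry <- function(event_logs, n_grid = 50, burn_in = 0.05,
                                   n_boot = 200, max_collisions = Inf,
                                   max_L = Inf) {
  if (is.data.frame(event_logs)) event_logs <- list(event_logs)
  if (is.finite(max_collisions)) {
    event_logs <- lapply(event_logs, function(e)
      e[seq_len(min(nrow(e), max_collisions)), , drop = FALSE])
  }
  if (is.finite(max_L)) {
    event_logs <- lapply(event_logs, function(e)
      e[e$L_at <= max_L, , drop = FALSE])
  }
  n_rep <- length(event_logs)
  all_L <- unlist(lapply(event_logs, function(e) e$L_at))
  if (length(all_L) == 0) {
    return(list(delta_p = NA_real_, se = NA_real_, cum = NULL,
                n_replicates = n_rep))
  }
  L_grid <- seq(0, max(all_L), length.out = n_grid + 1)[-1]
  cum_counts <- function(e) {
    la <- sort(e$L_at[e$kind == "annihilation"])
    lc <- sort(e$L_at[e$kind == "coalescence"])
    rbind(findInterval(L_grid, la), findInterval(L_grid, lc))
  }
  per_rep <- lapply(event_logs, cum_counts)   # each 2 x n_grid
  slope_of <- function(idx) {
    A <- Reduce(`+`, lapply(per_rep[idx], function(m) m[1, ])) / length(idx)
    C <- Reduce(`+`, lapply(per_rep[idx], function(m) m[2, ])) / length(idx)
    x <- A + C; y <- A - C
    keep <- x >= burn_in * max(x) & x > 0
    sum(x[keep] * y[keep]) / sum(x[keep]^2)
  }
  est <- slope_of(seq_len(n_rep))
  se <- NA_real_
  if (n_boot > 0 && n_rep > 1) {
    boots <- vapply(seq_len(n_boot), function(b)
      slope_of(sample.int(n_rep, n_rep, replace = TRUE)), numeric(1))
    se <- sd(boots)
  }
  A <- Reduce(`+`, lapply(per_rep, function(m) m[1, ])) / n_rep
  C <- Reduce(`+`, lapply(per_rep, function(m) m[2, ])) / n_rep
  list(delta_p = est, se = se,
       cum = data.frame(L = L_grid, cum_A = A, cum_C = C),
       n_replicates = n_rep)
}

#' Initial state holding a single sector of a focal strain
#'
#' Builds a frontier with exactly two walls: a sector of \code{focal} strain
#' of angular width \code{width0} starting at angle 0, in a background of
#' \code{background}.  Used for sector-growth measurements.
#'
#' @param p a [sim_params()] (supplies \code{R0}, geometry, \code{q}).
#' @param width0 initial angular width of the sector (radians).
#' @param focal,background 0-based strain ids.
#' @return a [frontier_state()].
#' @export
single_sector_state <- function(p, width0, focal = 1L, background = 0L) {
  stopifnot(width0 > 0, width0 < 2 * pi, focal != background)
  frontier_state(phi = c(0, width0), labels = c(focal, background),
                 q = p$q, R0 = p$R0, geometry = p$geometry)
}

#' Sector-width statistics over an ensemble of single-sector expansions
#'
#' For trajectories initialized by [single_sector_state()], records the
#' angular width of the focal sector at each snapshot and returns its mean
#' growth \eqn{\langle\phi - \phi_0\rangle} and variance versus radius.
#' Replicates whose sector is lost (or takes over the ring) are excluded from
#' that radius onward and counted.
#'
#' @param trajectories list of single-sector \code{"rw_trajectory"} objects.
#' @param focal 0-based id of the sector strain.
#' @param width0 initial angular width of the sector.
#' @return data frame with one row per snapshot: \code{L}, \code{R},
#'   \code{mean_dphi}, \code{se_mean}, \code{var_phi}, \code{se_var},
#'   \code{n_surviving}, \code{n_excluded}.
#' @export
sector_statistics <- function(trajectories, focal, width0) {
  t1 <- trajectories[[1]]
  if (length(t1$snapshots) == 0) stop("trajectories carry no snapshots")
  n_L <- length(t1$snapshots)
  widths <- vapply(trajectories, function(tr) {
    vapply(tr$snapshots, function(st) {
      if (length(st$phi) != 2) return(NA_real_)
      k <- which(st$labels == focal)
      if (length(k) != 1) return(NA_real_)
      w <- st$phi[k %% 2 + 1] - st$phi[k]
      if (w <= 0) w <- w + 2 * pi
      w
    }, numeric(1))
  }, numeric(n_L))
  widths <- matrix(widths, nrow = n_L)     # L x rep
  # once lost, excluded onward (snapshots after loss hold <2 walls anyway)
  out <- data.frame(
    L = vapply(t1$snapshots, `[[`, numeric(1), "L"),
    R = vapply(t1$snapshots, `[[`, numeric(1), "R"),
    mean_dphi = NA_real_, se_mean = NA_real_,
    var_phi = NA_real_, se_var = NA_real_,
    n_surviving = NA_integer_, n_excluded = NA_integer_
  )
  for (m in seq_len(n_L)) {
    w <- widths[m, ]
    ok <- !is.na(w)
    n <- sum(ok)
    out$n_surviving[m] <- n
    out$n_excluded[m] <- length(w) - n
    if (n >= 2) {
      out$mean_dphi[m] <- mean(w[ok]) - width0
      out$se_mean[m] <- sd(w[ok]) / sqrt(n)
      out$var_phi[m] <- var(w[ok])
      out$se_var[m] <- var(w[ok]) * sqrt(2 / (n - 1))
    }
  }
  out
}

#' Ensemble summary of simulated range expansions
#'
#' Aggregates a fraction-field ensemble and the matching collision logs into
#' the standard set of observables: average fractions, two-point correlation
#' functions, heterozygosity, cumulative collision counts and the annihilation
#' asymmetry.
#'
#' @param ff a [fraction_field()].
#' @param event_logs list of event data frames (optional).
#' @return object of class \code{"ensemble_summary"}.
#' @export
ensemble_summary <- function(ff, event_logs = NULL) {
  tp <- two_point_correlation(ff)
  het <- heterozygosity(tp)
  asym <- if (!is.null(event_logs)) annihilation_asymmetry(event_logs) else NULL
  structure(list(
    L_grid = ff$L_grid, phi_grid = ff$phi_grid,
    Fi = average_fraction(ff),
    Fij = tp, H = het, asymmetry = asym,
    n_replicates = ff$n_rep
  ), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Ensemble summary over %d replicates\n", x$n_replicates))
  cat(sprintf("  L grid: %s\n", paste(signif(x$L_grid, 4), collapse = ", ")))
  if (!is.null(x$asymmetry) && !is.na(x$asymmetry$delta_p))
    cat(sprintf("  annihilation asymmetry: %.3f (se %.3f)\n",
                x$asymmetry$delta_p, x$asymmetry$se))
  invisible(x)
}

#' Fold angular separations onto the principal range
#'
#' Maps separations on the full circle onto [0, pi], the physically distinct
#' range for a ring.
#'
#' @param phi numeric vector of angles.
#' @return folded angles.
#' @export
fold_angle <- function(phi) {
  phi <- phi %% (2 * pi)
  pmin(phi, 2 * pi - phi)
}
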