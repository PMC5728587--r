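#' Specification of a synthetic experiment-like dataset
#'
#' Describes a simulator-backed stand-in for the output of an imaging
#' pipeline: the generating truth (physical \eqn{D_w}, \eqn{R_0} and wall
#' velocities), the replicate count, the sampling grids, and an optional
#' domain-wall overlap blur emulating the image-analysis artifact in which
#' pixels spanned by two strains' masks are scored 1/2 each, so the observed
#' heterozygosity at zero separation fails to vanish.
#'
#' The physical parameters are mapped to microscopic simulation inputs by
#' fixing the simulated cell number \code{n0} (hence \code{a = 2*pi*R0/n0}),
#' choosing \code{d = a^2/(2*Dw)} so the wall diffusivity matches, and
#' setting the hop bias \code{r = vw * d / a}.
#'
#' @param Dw,R0 physical wall diffusion constant and initial radius (same
#'   length units).
#' @param vw \code{q x q} antisymmetric wall-velocity matrix (or \code{NULL}
#'   for neutral).
#' @param fractions inoculated fractions.
#' @param n_replicates ensemble size.
#' @param L_grid lengths expanded at which fields are recorded.
#' @param phi_bins angular bins of the rasterized fields.
#' @param overlap_blur angular half-width around each domain wall over which
#'   the two flanking strains are mixed 50/50 (radians; 0 disables).
#' @param n0 simulated cell number at the initial frontier.
#' @param seed base seed.
#' @return object of class \code{"fixture_spec"}.
#' @export
fixture_spec <- function(Dw, R0, vw = NULL, fractions, n_replicates,
                         L_grid, phi_bins = 360, overlap_blur = 0,
                         n0 = 500, seed = 1) {
  q <- length(fractions)
  if (is.null(vw)) vw <- matrix(0, q, q)
  stopifnot(Dw > 0, R0 > 0, overlap_blur >= 0,
            is.matrix(vw), all(dim(vw) == q))
  a <- 2 * pi * R0 / n0
  d <- a^2 / (2 * Dw)
  r <- vw * d / a
  if (max(abs(r)) > 1) stop("wall velocities too large for this n0/Dw; increase n0")
  structure(list(Dw = Dw, R0 = R0, vw = vw, fractions = fractions,
                 n_replicates = n_replicates, L_grid = as.numeric(L_grid),
                 phi_bins = phi_bins, overlap_blur = overlap_blur,
                 n0 = n0, a = a, d = d, bias = r, seed = seed),
            class = "fixture_spec")
}

# 50/50 mixing of the flanking strains within +/- blur of each wall
apply_overlap_blur <- function(f, st, blur, phi_grid) {
  if (blur <= 0 || length(st$phi) == 0) return(f)
  n <- length(phi_grid)
  for (k in seq_along(st$phi)) {
    left <- st$labels[if (k == 1) length(st$labels) else k - 1L] + 1L
    right <- st$labels[k] + 1L
    hit <- which(fold_angle(phi_grid - st$phi[k]) < blur)
    if (length(hit)) {
      f[, hit] <- 0
      f[left, hit] <- f[left, hit] + 0.5
      f[right, hit] <- f[right, hit] + 0.5
    }
  }
  f
}

#' Generate synthetic local-fraction fields with imaging-like blur
#'
#' Runs the simulator at the fixture's generating truth, rasterizes every
#' snapshot into exact angular occupancy profiles, optionally applies the
#' domain-wall overlap blur, and returns the ensemble together with the truth
#' record for closed-loop recovery tests.
#'
#' @param spec a [fixture_spec()].
#' @return list with \code{fields} (a [fraction_field()]), \code{events}
#'   (collision logs), and \code{truth} (the spec).
#' @export
make_fraction_fields <- function(spec) {
  p <- sim_params(n0 = spec$n0, q = length(spec$fractions),
                  init_fractions = spec$fractions, bias = spec$bias,
                  a = spec$a, d = spec$d, geometry = "radial",
                  snapshot_lengths = spec$L_grid)
  ens <- run_ensemble(p, spec$n_replicates, spec$seed,
                      n_bins = spec$phi_bins, summarize = FALSE)
  n_bins <- spec$phi_bins
  phi_grid <- (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  n_L <- length(spec$L_grid)
  f <- array(NA_real_, c(length(spec$fractions), n_bins, n_L,
                         spec$n_replicates))
  for (r in seq_along(ens$trajectories)) {
    for (m in seq_len(n_L)) {
      st <- ens$trajectories[[r]]$snapshots[[m]]
      fr <- occupancy_profile(st, n_bins)
      f[, , m, r] <- apply_overlap_blur(fr, st, spec$overlap_blur, phi_grid)
    }
  }
  list(fields = fraction_field(f, spec$L_grid),
       events = lapply(ens$trajectories, `[[`, "events"),
       truth = spec)
}

#' Generate synthetic single-sector angular-growth traces
#'
#' Simulates an ensemble of radial expansions each initialized with a single
#' sector of the focal (fitter) strain in a less fit background, records the
#' sector's angular width at the fixture's radii, and returns the mean-growth
#' trace versus \eqn{\ln(R/R_0)} together with the variance trace and the
#' generating truth.  Replicates that lose the sector are excluded from that
#' radius onward and counted.
#'
#' @param spec a [fixture_spec()] whose \code{vw} has a single focal pair:
#'   strain 1 sweeping through strain 0 (entry \code{vw[2, 1] >= 0}).
#' @param width0 initial angular width of the sector (radians).
#' @return list with \code{mean_trace} and \code{var_trace} (both
#'   [observed_curve()] with \code{x = log(R/R0)}), \code{stats} (the full
#'   [sector_statistics()] table) and \code{truth}.
#' @export
make_sector_traces <- function(spec, width0 = pi / 8) {
  q <- length(spec$fractions)
  stopifnot(q == 2)
  p <- sim_params(n0 = spec$n0, q = q, init_fractions = spec$fractions,
                  bias = spec$bias, a = spec$a, d = spec$d,
                  geometry = "radial", snapshot_lengths = spec$L_grid)
  init <- single_sector_state(p, width0, focal = 1L, background = 0L)
  ens <- run_ensemble(p, spec$n_replicates, spec$seed, init = init,
                      summarize = FALSE)
  st <- sector_statistics(ens$trajectories, focal = 1L, width0 = width0)
  x <- log(st$R / spec$R0)
  list(
    mean_trace = observed_curve(x, st$mean_dphi, st$se_mean),
    var_trace = observed_curve(x, st$var_phi, st$se_var),
    stats = st,
    truth = spec
  )
}
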