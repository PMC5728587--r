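#' Observed curve container
#'
#' A measured curve with pointwise standard errors, as produced by the
#' observables module or an external (e.g. imaging) pipeline: an abscissa
#' (angular separation, or log radius ratio for sector traces), values, and
#' standard errors.
#'
#' @param x abscissa values.
#' @param y observed values (same length).
#' @param se pointwise standard errors (> 0 wherever used in a fit), or
#'   \code{NULL}.
#' @param L length expanded the curve refers to, where applicable.
#' @return object of class \code{"observed_curve"}.
#' @export
observed_curve <- function(x, y, se = NULL, L = NULL) {
  stopifnot(length(x) == length(y))
  if (!is.null(se)) stopifnot(length(se) == length(y))
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 se = if (is.null(se)) NULL else as.numeric(se), L = L),
            class = "observed_curve")
}

fit_result <- function(estimate, ci_lo, ci_hi, objective = NA_real_,
                       grid = NULL, extra = list()) {
  structure(c(list(estimate = estimate, ci_lo = ci_lo, ci_hi = ci_hi,
                   objective = objective, grid = grid), extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit: estimate %.4g, 95%% CI [%.4g, %.4g]\n",
              x$estimate, x$ci_lo, x$ci_hi))
  invisible(x)
}

#' Fit the wall diffusion constant from heterozygosity curves
#'
#' For each observed heterozygosity curve \eqn{H(\phi)} at a known length
#' expanded, fits the neutral law [neutral_heterozygosity()] by (weighted)
#' nonlinear least squares with \eqn{D_w} the single free parameter, then
#' averages the per-length estimates; the confidence interval is the normal
#' interval from the standard error of that mean.
#'
#' @param curves a single [observed_curve()] or a list of them; each must
#'   carry its length expanded \code{L}.
#' @param R0 initial radius where domain walls form.
#' @param H0 heterozygosity at \code{L = 0}.
#' @param dw_interval search interval for \eqn{D_w}; default
#'   \code{c(1e-5, 10) * R0}.
#' @return a \code{"fit_result"}; \code{$per_L} holds the per-curve
#'   estimates.
#' @export
fit_dw_heterozygosity <- function(curves, R0, H0,
                                  dw_interval = c(1e-5, 10) * R0) {
  if (inherits(curves, "observed_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1)
  fit_one <- function(cv) {
    if (is.null(cv$L) || cv$L <= 0) stop("each curve needs its length expanded L > 0")
    if (diff(range(cv$y)) < 1e-10) stop("flat curve: Dw not identifiable")
    w <- if (!is.null(cv$se)) 1 / cv$se^2 else rep(1, length(cv$y))
    obj <- function(logdw) {
      Hhat <- neutral_heterozygosity(cv$x, cv$L, exp(logdw), R0, H0)
      sum(w * (cv$y - Hhat)^2)
    }
    op <- optimize(obj, log(dw_interval), tol = 1e-10)
    c(exp(op$minimum), op$objective)
  }
  per <- t(vapply(curves, fit_one, numeric(2)))
  est <- mean(per[, 1])
  n <- nrow(per)
  sem <- if (n > 1) sd(per[, 1]) / sqrt(n) else 0
  fit_result(est, est - 1.96 * sem, est + 1.96 * sem,
             objective = sum(per[, 2]),
             extra = list(per_L = data.frame(
               L = vapply(curves, function(cv) cv$L, numeric(1)),
               Dw = per[, 1], wsse = per[, 2])))
}

# cache key for universal curves
uc_key <- function(...) paste(vapply(list(...), function(v)
  paste(signif(as.numeric(v), 12), collapse = ","), character(1)), collapse = "|")

#' Simulated universal correlation curve at fixed kappa
#'
#' Runs an ensemble of radial pair-competition simulations at the requested
#' inflationary selection parameter \eqn{\kappa} (the particular simulated
#' \eqn{L_s} and \eqn{\phi_c} are irrelevant by the collapse of the dynamics)
#' and returns the cross-correlation \eqn{F_{01}} between the two strains on
#' the rescaled angular axis \eqn{\phi / \phi_c}, evaluated at the requested
#' rescaled length \eqn{L / L_s}.  Results are memoised in-package, keyed by
#' every argument, so repeated requests are served bit-identically.
#'
#' @param kappa inflationary selection parameter (>= 0; 0 is the neutral
#'   limit, for which \code{L_over_R0} must be given instead of
#'   \code{L_over_Ls}).
#' @param L_over_Ls rescaled length expanded of the curve.
#' @param fractions inoculated fractions, strain 0 (the fitter sweeper)
#'   first.
#' @param L_over_R0 rescaled length for the neutral case.
#' @param n_reps ensemble size.
#' @param n_bins angular bins of the rasterized field.
#' @param n0 initial cell number of the simulated frontier.
#' @param base_seed ensemble base seed.
#' @return object of class \code{"universal_curve"}: list with rescaled
#'   abscissa \code{x} (\eqn{\phi/\phi_c} folded onto the half circle),
#'   \code{y}, Monte-Carlo \code{se}, and the simulation metadata.
#' @export
universal_curve <- function(kappa, L_over_Ls = NULL, fractions = c(2/3, 1/3),
                            L_over_R0 = NULL, n_reps = 40, n_bins = 256,
                            n0 = 1000, base_seed = 1234) {
  stopifnot(kappa >= 0)
  key <- uc_key(kappa, if (kappa > 0) L_over_Ls else L_over_R0, fractions,
                n_reps, n_bins, n0, base_seed)
  if (!is.null(.rw_cache[[key]])) return(.rw_cache[[key]])
  a <- 1; d <- 1; Dw <- 0.5
  R0 <- n0 * a / (2 * pi)
  phic <- angular_correlation_length(Dw, R0)
  if (phic > pi) warning("phi_c approaches the system size; collapse unreliable")
  q <- length(fractions)
  bias <- matrix(0, q, q)
  if (kappa > 0) {
    stopifnot(!is.null(L_over_Ls))
    vw <- kappa * sqrt(Dw / R0)
    # strain 0 sweeps through every other strain with wall velocity vw
    bias[1, -1] <- vw
    bias[-1, 1] <- -vw
    L_sim <- L_over_Ls * Dw / vw^2
  } else {
    stopifnot(!is.null(L_over_R0))
    L_sim <- L_over_R0 * R0
  }
  p <- sim_params(n0 = n0, q = q, init_fractions = fractions, bias = bias,
                  a = a, d = d, geometry = "radial",
                  snapshot_lengths = L_sim)
  ens <- run_ensemble(p, n_reps, base_seed, n_bins = n_bins, summarize = FALSE)
  tp <- two_point_correlation(fraction_fields(ens$trajectories, n_bins))
  n <- n_bins
  half <- seq_len(n %/% 2 + 1)
  out <- structure(list(
    kappa = kappa, L_over_Ls = L_over_Ls, L_over_R0 = L_over_R0,
    x = tp$phi_grid[half] / phic,
    y = tp$Fij[1, 2, half, 1],
    se = tp$se[1, 2, half, 1],
    phic_sim = phic, n_reps = n_reps, fractions = fractions
  ), class = "universal_curve")
  .rw_cache[[key]] <- out
  out
}

#' Cache of universal correlation curves over a kappa grid
#'
#' Builds (and memoises) the simulated universal cross-correlation curve for
#' each \eqn{\kappa} in a grid, with the rescaled length of each curve tied
#' to the observation through \code{L_over_R0}
#' (\eqn{L/L_s = (L/R_0)\,\kappa^2}).
#'
#' @param kappa_grid strictly positive, sorted kappa values.
#' @param L_over_R0 observed length expanded divided by \code{R0}.
#' @param fractions inoculated fractions (sweeper first).
#' @param ... further arguments passed to [universal_curve()].
#' @return object of class \code{"uc_cache"}: list of curves plus the grid.
#' @export
universal_curve_cache <- function(kappa_grid, L_over_R0,
                                  fractions = c(2/3, 1/3), ...) {
  stopifnot(all(kappa_grid > 0), !is.unsorted(kappa_grid, strictly = TRUE))
  curves <- lapply(kappa_grid, function(k)
    universal_curve(k, L_over_Ls = L_over_R0 * k^2, fractions = fractions, ...))
  structure(list(kappa_grid = kappa_grid, L_over_R0 = L_over_R0,
                 curves = curves), class = "uc_cache")
}

# curve at kappa from a cache, linearly interpolated between neighbours
uc_lookup <- function(cache, kappa) {
  kg <- cache$kappa_grid
  j <- which(abs(kg - kappa) < 1e-9)
  if (length(j)) return(cache$curves[[j[1]]])
  if (kappa < kg[1] || kappa > kg[length(kg)])
    stop("kappa outside the cached grid")
  hi <- which(kg > kappa)[1]; lo <- hi - 1
  wl <- (kg[hi] - kappa) / (kg[hi] - kg[lo])
  clo <- cache$curves[[lo]]; chi <- cache$curves[[hi]]
  out <- clo
  out$kappa <- kappa
  out$y <- wl * clo$y + (1 - wl) * chi$y
  out$se <- sqrt((wl * clo$se)^2 + ((1 - wl) * chi$se)^2)
  out
}

#' Fit the selection length scale from an observed correlation function
#'
#' Implements the collapse-based inference: each candidate \eqn{L_s} fixes
#' \eqn{\kappa = \sqrt{R_0/L_s}} and the rescaled length \eqn{L/L_s}; the
#' simulated universal curve at that \eqn{\kappa} is compared with the
#' observed cross-correlation rescaled by \eqn{\phi_c = \sqrt{8 D_w/R_0}}
#' through the sum of squared displacements weighted by the inverse squared
#' standard errors.  Each candidate is assigned a probability proportional to
#' the inverse weighted sum of squares; the estimate is the minimizer and the
#' confidence bounds are the 2.5% and 97.5% quantiles of the normalized
#' distribution over the grid.
#'
#' @param observed an [observed_curve()]: cross-correlation \eqn{F_{ij}} vs
#'   angular separation (radians) at one length expanded \code{L}, with
#'   standard errors.
#' @param Dw wall diffusion constant.
#' @param R0 initial radius.
#' @param ls_grid candidate selection lengths; default 40 log-spaced values
#'   in \code{[R0/10, 100*R0]}.
#' @param fractions inoculated fractions (sweeper first).
#' @param cache optional [universal_curve_cache()] to interpolate in; built
#'   on the candidate kappas when absent.
#' @param ... further arguments passed to [universal_curve()].
#' @return a \code{"fit_result"} whose \code{$grid} holds \code{ls},
#'   \code{kappa}, \code{wsse} and normalized \code{prob}.
#' @export
fit_ls_correlation <- function(observed, Dw, R0, ls_grid = NULL,
                               fractions = c(2/3, 1/3), cache = NULL, ...) {
  stopifnot(inherits(observed, "observed_curve"), !is.null(observed$se),
            !is.null(observed$L), observed$L > 0)
  if (is.null(ls_grid))
    ls_grid <- exp(seq(log(R0 / 10), log(100 * R0), length.out = 40))
  ls_grid <- sort(ls_grid)
  phic_obs <- angular_correlation_length(Dw, R0)
  xs <- fold_angle(observed$x) / phic_obs
  use <- !is.null(observed$se) & observed$se > 0
  kappas <- sqrt(R0 / ls_grid)
  wsse <- vapply(seq_along(ls_grid), function(k) {
    kap <- kappas[k]
    uc <- if (is.null(cache))
      universal_curve(kap, L_over_Ls = observed$L / ls_grid[k],
                      fractions = fractions, ...)
    else uc_lookup(cache, kap)
    yhat <- approx(uc$x, uc$y, xout = xs, rule = 1)$y
    ok <- use & !is.na(yhat)
    sum(((observed$y[ok] - yhat[ok]) / observed$se[ok])^2)
  }, numeric(1))
  prob <- (1 / wsse) / sum(1 / wsse)
  if (length(ls_grid) > 1 && max(wsse) / min(wsse) < 1.05)
    warning("objective nearly flat over the grid; Ls poorly identified")
  cum <- cumsum(prob)
  ci_lo <- ls_grid[which(cum >= 0.025)[1]]
  ci_hi <- ls_grid[which(cum >= 0.975)[1]]
  best <- which.min(wsse)
  fit_result(ls_grid[best], ci_lo, ci_hi, objective = wsse[best],
             grid = data.frame(ls = ls_grid, kappa = kappas,
                               wsse = wsse, prob = prob))
}

#' Fit the wall velocity from sector angular-growth traces
#'
#' The mean angular width of a fitter sector grows as
#' \eqn{\langle\phi - \phi_0\rangle = 2 v_w \ln(R/R_0)}; \eqn{v_w} is half
#' the slope of a linear regression of the mean trace on
#' \eqn{\ln(R/R_0)}.
#'
#' @param traces an [observed_curve()] (or list of them, pooled) with
#'   \code{x = log(R/R0)} and \code{y} the mean angular width increase;
#'   optional \code{se} weights the regression by \code{1/se^2}.
#' @return a \code{"fit_result"} for \eqn{v_w} with the regression 95% CI.
#' @export
fit_vw_sectors <- function(traces) {
  if (inherits(traces, "observed_curve")) traces <- list(traces)
  if (length(traces) == 0) stop("no traces supplied")
  x <- unlist(lapply(traces, `[[`, "x"))
  y <- unlist(lapply(traces, `[[`, "y"))
  w <- unlist(lapply(traces, function(tr)
    if (is.null(tr$se)) rep(1, length(tr$x)) else 1 / tr$se^2))
  if (length(unique(x)) < 2) stop("need at least two distinct abscissa points")
  fit <- lm(y ~ x, weights = w)
  slope <- coef(fit)[["x"]]
  ci <- tryCatch(suppressWarnings(confint(fit, "x", level = 0.95)),
                 error = function(e) c(slope, slope))
  if (any(!is.finite(ci))) ci <- c(slope, slope)
  fit_result(slope / 2, min(ci) / 2, max(ci) / 2,
             objective = sum(w * fit$residuals^2),
             extra = list(model = fit))
}

#' Predict physical evolutionary dynamics from key parameters
#'
#' Runs the random-walk model at the dimensionless parameters
#' \eqn{\{\kappa_{ij}\}} implied by a set of physical key parameters
#' (\eqn{D_w}, \eqn{R_0} and the antisymmetric wall-velocity matrix), using
#' any convenient simulated \eqn{L_s} (the dynamics collapse), and maps the
#' resulting observables back to physical units: lengths through the ratio of
#' selection length scales and angles through the ratio of characteristic
#' angular correlation lengths.
#'
#' @param key list with \code{Dw}, \code{R0} and \code{vw} (a \code{q x q}
#'   antisymmetric matrix of dimensionless wall velocities,
#'   \code{vw[i+1, j+1]} positive when strain \code{i} sweeps through
#'   \code{j}).
#' @param fractions inoculated fractions (length q).
#' @param L_grid physical lengths expanded at which to report observables.
#' @param n_reps ensemble size.
#' @param n_bins angular bins.
#' @param n0 simulated initial cell number.
#' @param base_seed ensemble base seed.
#' @return an [ensemble_summary()] whose \code{L_grid} is the physical grid
#'   and whose \code{phi_grid} is in physical radians.
#' @export
predict_dynamics <- function(key, fractions, L_grid, n_reps = 100,
                             n_bins = 256, n0 = 1000, base_seed = 1) {
  vw <- key$vw
  q <- length(fractions)
  stopifnot(is.matrix(vw), all(dim(vw) == q))
  if (max(abs(vw + t(vw))) > 1e-12) stop("vw matrix must be antisymmetric")
  a <- 1; d <- 1; Dw_sim <- 0.5
  R0_sim <- n0 * a / (2 * pi)
  # vw_sim preserves every kappa_ij: kappa = |vw| sqrt(R0/Dw)
  scale_v <- sqrt(key$R0 / key$Dw) * sqrt(Dw_sim / R0_sim)
  vw_sim <- vw * scale_v
  if (max(abs(vw_sim)) > 1) stop("implied simulated bias exceeds 1; increase n0")
  if (max(abs(vw)) > 0) {
    ls_phys <- key$Dw / max(vw^2)
    ls_sim <- Dw_sim / max(vw_sim^2)
    L_sim <- L_grid * ls_sim / ls_phys
  } else {
    L_sim <- L_grid * R0_sim / key$R0      # neutral: lengths map through R0
  }
  p <- sim_params(n0 = n0, q = q, init_fractions = fractions, bias = vw_sim,
                  a = a, d = d, geometry = "radial", snapshot_lengths = L_sim)
  ens <- run_ensemble(p, n_reps, base_seed, n_bins = n_bins)
  summ <- ens$summary
  phi_ratio <- angular_correlation_length(key$Dw, key$R0) /
    angular_correlation_length(Dw_sim, R0_sim)
  summ$L_grid <- L_grid
  summ$phi_grid <- summ$phi_grid * phi_ratio
  summ$Fij$phi_grid <- summ$Fij$phi_grid * phi_ratio
  summ$Fij$L_grid <- L_grid
  summ$H$phi_grid <- summ$H$phi_grid * phi_ratio
  summ$H$L_grid <- L_grid
  summ$Fi$L <- rep(L_grid, each = q)
  summ
}
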