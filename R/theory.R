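#' Error function
#' @param x numeric.
#' @return erf(x).
#' @keywords internal
erf <- function(x) 2 * pnorm(sqrt(2) * x) - 1

#' Selection length scale
#'
#' The expansion length beyond which the deterministic displacement of a
#' sector boundary (rate \eqn{v_w} per length expanded) exceeds its diffusive
#' spread (diffusivity \eqn{D_w} per length expanded):
#' \eqn{L_s = D_w / v_w^2}.
#'
#' @param Dw wall diffusion constant per length expanded (length units).
#' @param vw dimensionless wall velocity (transverse displacement per length
#'   expanded).
#' @return \code{Ls} in the units of \code{Dw}; \code{Inf} in the neutral
#'   limit \code{vw = 0}.
#' @export
#' @examples
#' selection_length(0.1, 0.06)  # ~27.8 mm
selection_length <- function(Dw, vw) {
  stopifnot(Dw > 0, vw >= 0)
  if (any(vw == 0)) {
    out <- ifelse(vw == 0, Inf, Dw / vw^2)
    return(out)
  }
  Dw / vw^2
}

#' Wall velocity implied by a selection length scale
#'
#' Inverts \eqn{L_s = D_w / v_w^2} to \eqn{v_w = \sqrt{D_w / L_s}}.
#'
#' @param Dw wall diffusion constant (length units).
#' @param Ls selection length scale (same units).
#' @return dimensionless wall velocity.
#' @export
wall_velocity_from_ls <- function(Dw, Ls) {
  stopifnot(Dw > 0, Ls > 0)
  sqrt(Dw / Ls)
}

#' Inflationary selection parameter
#'
#' \eqn{\kappa = \sqrt{R_0 / L_s}} measures the strength of selection
#' relative to inflation and genetic drift on a radially inflating frontier:
#' for \eqn{\kappa \gg 1} inflation is negligible, for \eqn{\kappa \ll 1}
#' inflation and drift dominate selection out to very large lengths expanded.
#'
#' @param R0 initial radius where domain walls form.
#' @param Ls selection length scale (same units).
#' @return dimensionless kappa.
#' @export
#' @examples
#' kappa_param(3.5, 13)  # ~0.52
kappa_param <- function(R0, Ls) {
  stopifnot(R0 > 0, Ls > 0)
  sqrt(R0 / Ls)
}

#' Characteristic angular correlation length
#'
#' \eqn{\phi_c = \sqrt{8 D_w / R_0}}: the angular scale of neutral genetic
#' domains on an inflating frontier, arising from angular diffusion
#' \eqn{D_\phi = D_w / R^2} over the characteristic radius \eqn{R_0}.
#'
#' @param Dw wall diffusion constant (length units).
#' @param R0 initial radius (same units).
#' @return dimensionless angle (radians).
#' @export
#' @examples
#' angular_correlation_length(0.100, 3.50)  # ~0.48
angular_correlation_length <- function(Dw, R0) {
  stopifnot(Dw > 0, R0 > 0)
  sqrt(8 * Dw / R0)
}

#' Inflationary crossover length
#'
#' Solves the transcendental balance between deterministic sector growth and
#' diffusive growth on an inflating ring,
#' \deqn{\kappa \ln(1 + L_I/R_0) = \sqrt{1 - (1 + L_I/R_0)^{-1}},}
#' for the inflationary selection length \eqn{L_I}.  The solution
#' interpolates between \eqn{L_I/L_s \to 1} for \eqn{\kappa \gg 1} and
#' \eqn{L_I/L_s \approx \kappa^2 e^{1/\kappa}} for \eqn{\kappa \ll 1}.
#'
#' @param kappa dimensionless inflationary selection parameter (> 0); may be
#'   a vector.
#' @return data frame with columns \code{kappa}, \code{LI_over_R0},
#'   \code{LI_over_Ls}, \code{residual} (absolute residual of the
#'   transcendental equation at the returned root, < 1e-10).
#' @export
#' @examples
#' inflationary_crossover(100)$LI_over_Ls  # ~1
inflationary_crossover <- function(kappa) {
  stopifnot(all(kappa > 0))
  one <- function(k) {
    # g(x) = k*log1p(x) - sqrt(x/(1+x)); root x = L_I/R0 > 0
    g <- function(x) k * log1p(x) - sqrt(x / (1 + x))
    hi <- max(1e3, 10 * exp(min(1 / k, 700)))
    lo <- 1e-12
    # ensure a sign change (g < 0 just above 0, g > 0 at hi)
    while (g(lo) >= 0 && lo > 1e-300) lo <- lo / 100
    x <- uniroot(g, c(lo, hi), tol = .Machine$double.eps^0.75)$root
    # Newton polish for a residual below 1e-10
    for (it in 1:3) {
      fx <- g(x)
      # d/dx sqrt(x/(1+x)) = 1 / (2 sqrt(x/(1+x)) (1+x)^2)
      dfx <- k / (1 + x) - 0.5 / (sqrt(x / (1 + x)) * (1 + x)^2)
      x <- x - fx / dfx
      if (x <= 0) x <- abs(x) + 1e-12
    }
    c(x, abs(g(x)))
  }
  res <- t(vapply(kappa, one, numeric(2)))
  data.frame(kappa = kappa, LI_over_R0 = res[, 1],
             LI_over_Ls = res[, 1] * kappa^2, residual = res[, 2])
}

#' Annihilation asymmetry of q neutral strains at equal fractions
#'
#' \eqn{\Delta P = (3 - q)/(q - 1)}: with two strains every collision is an
#' annihilation (\eqn{\Delta P = 1}); with three, annihilations and
#' coalescences balance (\eqn{\Delta P = 0}); as \eqn{q \to \infty} only
#' coalescences occur (\eqn{\Delta P \to -1}).
#'
#' @param q number of strains (>= 2); may be fractional.
#' @return dimensionless asymmetry in (-1, 1].
#' @export
delta_p_equal_fractions <- function(q) {
  stopifnot(all(q >= 2))
  (3 - q) / (q - 1)
}

#' Effective fractional strain number from an annihilation asymmetry
#'
#' Inverts the equal-fraction relation to \eqn{q = (3 + \Delta P)/(1 + \Delta
#' P)}, giving the effective number of equally inoculated neutral strains
#' that would produce the observed asymmetry.
#'
#' @param delta_p asymmetry in (-1, 1].
#' @return effective q (real).
#' @export
#' @examples
#' fractional_q(0.51)  # ~2.32
fractional_q <- function(delta_p) {
  stopifnot(all(delta_p > -1), all(delta_p <= 1))
  (3 + delta_p) / (1 + delta_p)
}

#' Neutral heterozygosity on an inflating frontier
#'
#' The neutral voter-model prediction
#' \deqn{H(\phi, L) = H_0\, \mathrm{erf}\!\left(\sqrt{1 + R_0/L}\;
#' |\phi| / \phi_c\right)}
#' with \eqn{\phi_c = \sqrt{8 D_w / R_0}}.  The argument follows from the
#' pair-separation variance \eqn{4 D_w (1/R_0 - 1/R)} of two independently
#' diffusing walls on the inflating ring.
#'
#' @param phi angular separation(s), radians (folded internally onto
#'   [0, pi]).
#' @param L length(s) expanded, > 0.
#' @param Dw wall diffusion constant (length units).
#' @param R0 initial radius (same units).
#' @param H0 heterozygosity at \code{L = 0} (\eqn{1 - 1/q} for q strains at
#'   equal fractions).
#' @return H(phi, L), same shape as \code{phi}.
#' @export
neutral_heterozygosity <- function(phi, L, Dw, R0, H0) {
  stopifnot(all(L > 0), H0 >= 0, H0 <= 1)
  phic <- angular_correlation_length(Dw, R0)
  H0 * erf(sqrt(1 + R0 / L) * abs(fold_angle(phi)) / phic)
}

#' Neutral two-point correlation functions
#'
#' The neutral correlation matrix consistent with label exchangeability and
#' the heterozygosity law: with
#' \eqn{\xi = \sqrt{1 + R_0/L}\,|\phi|/\phi_c},
#' \eqn{F_{ij} = f_i f_j\,\mathrm{erf}(\xi)} for \eqn{i \ne j} and
#' \eqn{F_{ii} = f_i^2 + f_i (1 - f_i)(1 - \mathrm{erf}(\xi))}.  Rows
#' marginalize to the inoculated fractions and
#' \eqn{\sum_{i\ne j} F_{ij} = (1 - \sum_i f_i^2)\,\mathrm{erf}(\xi)}.
#'
#' @param phi angular separation(s), radians.
#' @param L length expanded (scalar, > 0).
#' @param Dw,R0 wall diffusion constant and initial radius.
#' @param f inoculated fractions (sums to 1).
#' @return array \code{q x q x length(phi)}.
#' @export
neutral_two_point <- function(phi, L, Dw, R0, f) {
  stopifnot(abs(sum(f) - 1) < 1e-9, L > 0)
  phic <- angular_correlation_length(Dw, R0)
  xi <- sqrt(1 + R0 / L) * abs(fold_angle(phi)) / phic
  e <- erf(xi)
  q <- length(f)
  out <- array(0, c(q, q, length(phi)))
  for (i in seq_len(q)) for (j in seq_len(q)) {
    out[i, j, ] <- if (i == j) f[i]^2 + f[i] * (1 - f[i]) * (1 - e)
                   else f[i] * f[j] * e
  }
  out
}

#' Mean angular width of a selected sector
#'
#' A sector of a fitter strain sweeping through a less fit one on an
#' inflating frontier grows on average as a logarithmic spiral:
#' \eqn{\langle\phi - \phi_0\rangle = 2 v_w \ln(R / R_0)}.
#'
#' @param vw dimensionless wall velocity of the sweeping pair.
#' @param R0 initial radius; \code{R} current radius (>= R0).
#' @param R current radius.
#' @return mean angular width increase (radians).
#' @export
sector_mean_width <- function(vw, R0, R) {
  stopifnot(all(R >= R0), R0 > 0)
  2 * vw * log(R / R0)
}

#' Variance of the angular width of a neutral-width sector
#'
#' \eqn{\mathrm{Var}(\phi) = 4 D_w (1/R_0 - 1/R)}: the two sector boundaries
#' diffuse independently with angular diffusivity \eqn{D_w / R^2}, so the
#' width variance saturates at \eqn{4 D_w / R_0} as \eqn{R \to \infty}.
#'
#' @param Dw wall diffusion constant (length units).
#' @param R0 initial radius; \code{R} current radius (>= R0).
#' @param R current radius.
#' @return variance of the angular width (radians^2).
#' @export
sector_variance <- function(Dw, R0, R) {
  stopifnot(all(R >= R0), R0 > 0, Dw >= 0)
  4 * Dw * (1 / R0 - 1 / R)
}

#' Microscopic-to-continuum parameter map
#'
#' Maps the simulation's microscopic inputs (cell width \code{a}, length
#' expanded per generation \code{d}, hop bias \code{r}) to the continuum
#' wall parameters: \eqn{D_w = a^2/(2d)} and \eqn{v_w = a r / d}.  With
#' \code{d = a} these reduce to \eqn{D_w = a/2} and \eqn{v_w = r}.
#'
#' @param a cell width (length units).
#' @param d length expanded per generation.
#' @param r hop bias (|r| <= 1); may be a matrix.
#' @return list with \code{Dw} and \code{vw}.
#' @export
microscopic_map <- function(a, d, r = 0) {
  stopifnot(a > 0, d > 0, all(abs(r) <= 1))
  list(Dw = a^2 / (2 * d), vw = a * r / d)
}

#' Relative fitness from expansion velocities
#'
#' \eqn{s = u_i / u_{ref} - 1}: the selective advantage of a strain with
#' radial expansion velocity \code{u_i} relative to a reference strain.
#'
#' @param u_i expansion velocity of the strain of interest.
#' @param u_ref expansion velocity of the reference strain (> 0).
#' @return dimensionless selective advantage.
#' @export
relative_fitness <- function(u_i, u_ref) {
  stopifnot(u_ref > 0)
  u_i / u_ref - 1
}
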