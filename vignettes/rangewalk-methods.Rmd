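---
title: "Domain-wall random walks for multi-strain range expansions: models and methods"
author: "rangewalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-wall random walks for multi-strain range expansions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangewalk)
```

## The model

When several non-motile microbial strains expand together across a hard
surface, growth is confined to a thin frontier and genetic drift there is
extreme: behind the advancing edge the population freezes into monoclonal
sectors separated by sharp genetic domain walls.  `rangewalk` models the
frontier as a one-dimensional ring of such walls performing annihilating and
coalescing random walks with deterministic selection biases — the
interface representation of a q-state voter model (zero-temperature Potts
dynamics) extended with selection and with the geometric inflation of a
radially growing colony.

The state is a cyclically ordered set of wall positions
$\phi_k \in [0, 2\pi)$ with a strain label on each arc.  One update step:

1. a wall is chosen uniformly at random; its type $ij$ is read off from the
   flanking strains ($i$ left, $j$ right);
2. it hops a distance $a$ (one cell width) to the right with probability
   $(1 + r_{ij})/2$, else left, i.e. by an angular step $\delta\phi = a/R$
   at the current radius $R$;
3. a hop that reaches or crosses the nearest neighbouring wall reacts
   instantly at the contact point: the two walls *annihilate* if the outer
   flanking strains match, otherwise they *coalesce* into the single wall
   separating the outer strains;
4. time advances by $\Delta t = 1/N$ generations ($N$ = wall count before
   the hop) and the length expanded by $\Delta L = d/N$, where $d$ is the
   length the colony expands per generation.

For radial geometry the radius tracks the expansion, $R = R_0 + L$ with
$R_0 = N_0 a / (2\pi)$ set by the initial number of frontier cells $N_0$;
for linear geometry $R \equiv R_0$ and the ring never inflates.  We keep
the radius equal to $R_0 + L$ rather than $R_0 + a t$ because the two
differ when $d \neq a$, and only the former preserves the identity
$L = R - R_0$ and the sector variance law below; with the default $d = a$
they coincide.

The microscopic inputs map onto two continuum parameters per wall type:

* diffusion per length expanded $D_w = a^2/(2d)$ (so $D_w = a/2$ at
  $d = a$), with $2 D_w = d\,\mathrm{Var}(x)/dL$;
* dimensionless wall velocity $v_w^{ij} = a\, r_{ij}/d$, the mean
  transverse displacement per length expanded.

`microscopic_map()` implements this map, and the test suite verifies both
relations directly on simulated wall ensembles.

### Collision handling and numerical tie-breaks

Reactions are instantaneous, so a hop is truncated at the first contact: a
wall can cross at most its nearest neighbour, and landing *exactly* on a
neighbour counts as a collision (the tie has measure zero but floating-point
arithmetic makes it reachable; breaking it toward reaction is the only
choice consistent with instantaneous reactions).  The collision test is
evaluated on the exact floating-point value that would be stored, never on
a separately rounded gap, so walls can never silently pass one another; a
post-wrap guard also catches the case where `-eps + 2*pi` rounds up to
`2*pi`.  After a coalescence the new wall inherits the collision point.
Cyclic order is maintained in a linked list, which is authoritative over
raw angle comparisons when positions wrap.

### Initial conditions

`init_frontier()` mimics a well-mixed inoculum: each of the $N_0$ founder
cells draws its strain independently from the inoculated fractions
(`init_mode = "iid"`, the default — it reproduces the stochastic scatter of
initial compositions seen in replicate experiments), or exact rounded
proportions are placed in random order (`init_mode = "exact"`).  Walls sit
at boundaries between unlike neighbours, so the expected initial wall count
is $N_0 (1 - \sum_i f_i^2)$.

## Key parameters

Three combinations of $(R_0, D_w, v_w^{ij})$ organise all of the dynamics
(`selection_length()`, `kappa_param()`, `angular_correlation_length()`,
`inflationary_crossover()`):

* $L_s^{ij} = D_w/(v_w^{ij})^2$ — the expansion length beyond which the
  deterministic displacement $2 v_w L$ of a sector outruns its diffusive
  spread $\sqrt{4 D_w L}$;
* $\kappa_{ij} = \sqrt{R_0/L_s^{ij}}$ — an inflationary selective
  advantage; for $\kappa \gg 1$ inflation is irrelevant, for
  $\kappa \ll 1$ inflation and drift dominate selection out to enormous
  lengths;
* $\phi_c = \sqrt{8 D_w / R_0}$ — the characteristic angular scale of
  neutral genetic domains on an inflating frontier.

The inflationary crossover length $L_I$ solves
$\kappa \ln(1 + L_I/R_0) = \sqrt{1 - (1 + L_I/R_0)^{-1}}$, found by
bracketed root finding with a Newton polish (residual $< 10^{-10}$ over
$\kappa \in [10^{-2}, 10^3]$; the bracket is widened to
$10\,e^{1/\kappa}$ to cover the small-$\kappa$ blow-up).  Its limits are
$L_I/L_s \to 1$ ($\kappa \gg 1$) and $L_I/L_s \to \kappa^2 e^{1/\kappa}$
($\kappa \ll 1$).

Rescaling $L$ by any $L_s^{ij}$ and $\phi$ by $\phi_c$ collapses the
average fractions, correlation functions and annihilation asymmetry onto
master curves indexed by $\{\kappa_{ij}\}$ alone; the fitting module is
built entirely on this collapse.

## Observables

`occupancy_profile()` rasterizes the exact wall representation onto a
uniform angular grid by arc–bin overlap (exact measure, not point
sampling).  From per-replicate fraction fields $f_i(\phi, L)$ the package
computes

* average fractions $F_i(L)$ (angular mean, then ensemble mean with
  standard errors over replicates);
* two-point correlations
  $F_{ij}(\phi, L) = \tfrac{1}{4\pi}\!\int d\phi'\,
  \langle f_i f_j' + f_j f_i'\rangle$ by exact circular convolution (FFT)
  on the grid — symmetric, mirror-symmetric and normalised to
  $\sum_{ij} F_{ij} = 1$ by construction;
* heterozygosity $H(\phi, L) = \sum_{i \neq j} F_{ij}$, computed per
  replicate so its standard errors are honest;
* the annihilation asymmetry $\Delta P$, the slope through the origin of
  the ensemble-averaged cumulative $\langle A - C\rangle$ against
  cumulative collisions $\langle A + C\rangle$, with a default burn-in of
  the first 5% of the record and a between-replicate bootstrap for its
  standard error;
* single-sector statistics: mean angular width growth
  $\langle\phi - \phi_0\rangle = 2 v_w \ln(R/R_0)$ (a logarithmic spiral)
  and width variance $4 D_w (1/R_0 - 1/R)$, with replicates that lose
  their sector excluded from that radius onward and counted.

The default angular grid (500 bins) mirrors a pixel-level image analysis;
doubling it changes no tested conclusion.

### The asymmetry of unequal inocula

For $q$ strains at equal fractions $\Delta P = (3-q)/(q-1)$ independent of
$L$ ($+1$ at $q=2$: only annihilations; $0$ at $q=3$; $\to -1$ as
$q \to \infty$).  For *unequal* fractions the per-collision asymmetry is
not constant: simulation shows it starts at the value set by the
uncorrelated inoculated pattern and drifts as coarsening builds
correlations between neighbouring domains (for fractions
$(0.1, 0.1, 0.8)$: $\approx 0.51$ for the earliest collisions, decaying
towards $\approx 0.43$ over a long record).  The closed-form prediction
for a given inoculated composition therefore refers to the inoculated
pattern, and its simulation estimate uses
`annihilation_asymmetry(..., max_L = d)` — the slope over the collisions of
the first generation of expansion, during which the inoculated pattern has
barely evolved (`max_collisions = 1`, the expectation over each replicate's
first collision, is the parameter-free but noisier alternative).
Inverting an observed asymmetry through $q = (3 + \Delta P)/(1 + \Delta P)$
gives the effective fractional strain number.

## Neutral theory and its range of validity

The neutral voter-model heterozygosity on an inflating ring is

$$H(\phi, L) = H_0\,\mathrm{erf}\!\left(\sqrt{1 + R_0/L}\,
\frac{|\phi|}{\phi_c}\right),$$

with $H_0 = 1 - 1/q$ for $q$ strains at equal fractions.  The argument is
fixed by the pair-separation variance $4 D_w (1/R_0 - 1/R)$ of two
independently diffusing walls, and the matching correlation matrix
(`neutral_two_point()`) follows from label exchangeability:
$F_{ij} = f_i f_j\,\mathrm{erf}(\xi)$ for $i \neq j$ and
$F_{ii} = f_i^2 + f_i(1 - f_i)(1 - \mathrm{erf}(\xi))$, which marginalises
to $\sum_j F_{ij} = f_i$.

Two caveats matter when comparing simulations (or data) to these formulas,
and both are visible in the test suite's probe choices:

* they are asymptotic in $L/R_0$: for $L \lesssim R_0$ the simulated $H$
  runs a few per cent above the law (early-coarsening transient), so
  quantitative 3-SE comparisons are made at $L/R_0 \ge 1.5$;
* on a finite ring the large-separation plateau sits slightly *above*
  $H_0$ (composition conservation anticorrelates antipodal points, a
  $\sim 1\%$ effect at $N_0 = 3000$), vanishing with system size.

Rasterized fields additionally inflate $H$ at separations of 1–3 bins
(bin-averaging), so tests compare beyond that scale.

## Fitting procedures

`fit_dw_heterozygosity()` fits $D_w$ — the single free parameter once
$R_0$ and $H_0$ are known — to each observed heterozygosity curve by
weighted nonlinear least squares and averages the per-length estimates;
the interval is the normal CI from the standard error of that mean.
Because the erf law is asymptotic, the recovered $D_w$ carries a small
($\sim 5\%$ at $L/R_0 \in [1.5, 4]$) downward transient bias relative to
the microscopic $a^2/(2d)$; the closed-loop test budgets 10% for it.  The
fit is robust to a fixture-generated overlap blur that keeps $H(0) > 0$,
emulating the image-analysis artifact in which pixels spanned by two
strains' masks are scored $1/2$ each.

`fit_vw_sectors()` reads $2 v_w$ off the slope of a linear regression of
the mean sector width against $\ln(R/R_0)$, weighting by inverse squared
standard errors.

`fit_ls_correlation()` implements the collapse-based inference of the
selection length: each candidate $L_s$ simultaneously sets
$\kappa = \sqrt{R_0/L_s}$ and the rescaled length $L/L_s$; a simulated
universal cross-correlation curve at that $\kappa$ (`universal_curve()`,
memoised; any convenient simulated $L_s$ and $\phi_c$ work because of the
collapse) is compared to the observed curve rescaled by $\phi_c$, through
the sum of squared displacements weighted by $1/\mathrm{SE}^2$.  Each
candidate receives a probability proportional to the inverse weighted sum
of squares; the estimate is the minimiser and the confidence bounds are the
2.5%/97.5% quantiles of that normalised distribution.  This inverse-WSS
uncertainty rule is deliberately non-standard (no $\chi^2$ likelihood is
substituted) because it defines the reported confidence semantics,
including the characteristic long upper tail in $L_s$.  The default
candidate grid is 40 log-spaced values in $[R_0/10, 100 R_0]$; the default
fitted component is the cross-correlation of the competing pair, which
separates fitness differences better than self-correlations.  A curve
cache over a $\kappa$ grid with linear interpolation between neighbours is
available (`universal_curve_cache()`) when many candidates share
simulations.

`predict_dynamics()` runs the model at the $\kappa_{ij}$ implied by fitted
physical parameters — using a convenient simulated system and the collapse
— and maps lengths back through the ratio of selection lengths and angles
through the ratio of $\phi_c$ values, so measured key parameters predict
average fractions, correlations and the asymmetry with no further fitting.

## The synthetic-data generator

`fixture_spec()` / `make_fraction_fields()` / `make_sector_traces()`
produce experiment-like datasets with known generating truth, so every
fitting operation is testable without any external data.  Physical
$(D_w, R_0, v_w)$ are mapped to microscopic inputs by fixing the simulated
cell number ($a = 2\pi R_0/N_0$, $d = a^2/(2 D_w)$, $r = v_w d/a$); with
the defaults ($N_0 = 500$, $D_w = 0.1$ mm, $R_0 = 3.5$ mm — the scale of
an *E. coli* colony on agar) the frontier resolves the experimental domain
structure at roughly the granularity the wall diffusivity itself implies.
The optional overlap blur assigns the two flanking strains 50/50 within a
half-width of each wall, the minimal emulation of the binary-mask overlap
rule; it reproduces the documented artifact that measured heterozygosity
fails to vanish at zero separation, fading as the frontier inflates.

What the generator does *not* emulate: pixel noise, illumination
inhomogeneity, stitching artifacts, super-diffusive wall wandering (walls
here are strictly diffusive), and chirality (a common transverse bias for
all walls, which cancels in sector widths).  Closed loops that pass on
these fixtures therefore validate the inference machinery and the model's
internal consistency, not the imaging pipeline.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use ensembles chosen to make
Monte-Carlo error comfortably smaller than the effects under test while
remaining quick on a single core: frontiers of $N_0 = 2000$–$3000$ cells
with 100–500 replicates for ensemble observables, $10^3$ replicates for
sector laws, and $N_0 = 10^5$ isolated wall pairs for the microscopic
diffusion check.  All ensembles derive per-replicate seeds deterministically
from a base seed (`replicate_seeds()`), so results are bit-for-bit
reproducible and independent of ensemble size: replicate $k$ is identical
whether 10 or 500 replicates are run.

## Known limitations

* The diffusive description is a deliberate simplification; experimentally
  reported super-diffusive wall motion is out of scope.
* The neutral closed forms are asymptotic (see above); the simulator, not
  the formulas, is the model.
* `fit_ls_correlation` inherits Monte-Carlo noise from its universal
  curves; with the default ensemble sizes that noise is far below
  experimental standard errors, but a pathologically precise observation
  would need a larger `n_reps`.
* Unequal-fraction asymmetry theory is provided only through simulation
  (the early-window estimator); no closed form is implemented.
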