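test_that("initial walls sit at boundaries between unlike neighbours", {
  p <- sim_params(n0 = 4, q = 2)
  st <- rangewalk:::cell_labels_to_frontier(c(0L, 1L, 0L, 1L), p)
  expect_equal(st$phi, c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(st$labels, c(0L, 1L, 0L, 1L))
  # single strain: no walls, strain recorded
  p1 <- sim_params(n0 = 10, q = 1)
  set.seed(1)
  st1 <- init_frontier(p1)
  expect_length(st1$phi, 0)
  expect_equal(st1$mono, 0L)
})

test_that("iid inoculation yields 1 - sum(f^2) walls per cell on average", {
  p <- sim_params(n0 = 1000, q = 3)
  counts <- vapply(1:100, function(s) {
    set.seed(s)
    length(init_frontier(p)$phi)
  }, numeric(1))
  # expectation 1000 * 2/3; SE of the mean ~ 1.5
  expect_lt(abs(mean(counts) - 1000 * 2 / 3), 5)
})

test_that("exact inoculation places rounded proportions", {
  p <- sim_params(n0 = 10, q = 3, init_fractions = c(0.5, 0.3, 0.2),
                  init_mode = "exact")
  set.seed(2)
  st <- init_frontier(p)
  w <- arc_widths(st)
  tot <- tapply(w, st$labels, sum) / (2 * pi)
  expect_equal(as.numeric(tot[order(names(tot))]), c(0.5, 0.3, 0.2))
})

test_that("a forced head-on hop annihilates when outer flanks match", {
  # walls (0|1) and (1|0): r = +1/-1 makes them approach deterministically
  p <- sim_params(n0 = 100, q = 2, bias = forced_bias(2, 0, 1))
  st <- frontier_state(c(1, 1.01), c(1L, 0L), q = 2, R0 = p$R0)
  set.seed(3)
  out <- step_frontier(st, p)
  expect_length(out$state$phi, 0)
  expect_equal(out$event$kind, "annihilation")
  expect_equal(out$state$mono, 0L)
  expect_error(step_frontier(out$state, p), "0 walls")
})

test_that("a forced collision of unlike flanks coalesces into one wall", {
  # walls (0|1) at 1 and (1|2) at 1.01 with strain 0 pushing right, 2 left
  b <- matrix(0, 3, 3)
  b[1, 2] <- 1; b[2, 1] <- -1   # wall (0|1) hops right
  b[2, 3] <- -1; b[3, 2] <- 1   # wall (1|2) hops left
  p <- sim_params(n0 = 100, q = 3, init_fractions = c(1, 1, 1) / 3, bias = b)
  st <- frontier_state(c(1, 1.01, 4), c(1L, 2L, 0L), q = 3, R0 = p$R0)
  set.seed(4)
  out <- step_frontier(st, p)
  repeat {
    if (!is.null(out$event)) break
    out <- step_frontier(out$state, p)
  }
  expect_equal(out$event$kind, "coalescence")
  expect_equal(out$event$left_out, 0L)
  expect_equal(out$event$right_out, 2L)
  expect_length(out$state$phi, 2)
})

test_that("neutral hops go right half the time and time advances by 1/N", {
  p <- sim_params(n0 = 10000, q = 2)
  st <- two_wall_state(phi = c(0.5, pi + 0.5), R0 = p$R0)
  set.seed(5)
  nright <- 0L
  n_steps <- 20000
  cur <- st
  for (k in seq_len(n_steps)) {
    out <- step_frontier(cur, p)
    moved <- which(out$state$phi != cur$phi)
    d <- out$state$phi[moved] - cur$phi[moved]
    if ((d %% (2 * pi)) < pi) nright <- nright + 1L
    cur <- out$state
  }
  expect_equal(cur$t, st$t + n_steps / 2)   # dt = 1/N with N = 2
  # binomial: 0.5 +/- 3 * sqrt(0.25/n)
  expect_lt(abs(nright / n_steps - 0.5), 3 * sqrt(0.25 / n_steps))
})

test_that("a two-strain run records only annihilations and the count identity", {
  p <- sim_params(n0 = 400, q = 2, geometry = "linear")
  tr <- run_expansion(p, seed = 11)
  expect_true(all(tr$events$kind == "annihilation"))
  set.seed(11)
  n0w <- length(init_frontier(p)$phi)
  na <- sum(tr$events$kind == "annihilation")
  nc <- sum(tr$events$kind == "coalescence")
  expect_equal(n0w - 2 * na - nc, length(tr$final$phi))
  expect_true(!is.unsorted(tr$events$L_at))
})

test_that("single-strain runs are inert", {
  p <- sim_params(n0 = 50, q = 1, snapshot_lengths = c(1, 2))
  tr <- run_expansion(p, seed = 1)
  expect_equal(nrow(tr$events), 0)
  expect_length(tr$snapshots[[1]]$phi, 0)
  expect_equal(tr$snapshots[[1]]$mono, tr$snapshots[[2]]$mono)
})

test_that("arc widths sum to 2*pi and labels stay distinct along a run", {
  for (geom in c("linear", "radial")) {
    p <- sim_params(n0 = 300, q = 3, geometry = geom,
                    snapshot_lengths = c(5, 20, 60))
    tr <- run_expansion(p, seed = 13)
    nw <- Inf
    for (st in c(tr$snapshots, list(tr$final))) {
      expect_lt(abs(sum(arc_widths(st)) - 2 * pi), 1e-9)
      n <- length(st$phi)
      if (n > 0) expect_false(any(st$labels == c(st$labels[n], st$labels[-n])))
      expect_lte(n, nw)
      nw <- n
    }
  }
})

test_that("radial runs inflate the radius with the length expanded", {
  p <- sim_params(n0 = 300, q = 2, geometry = "radial", snapshot_lengths = 40)
  tr <- run_expansion(p, seed = 17)
  st <- tr$snapshots[[1]]
  expect_equal(st$R, st$R0 + st$L)
  p2 <- sim_params(n0 = 300, q = 2, geometry = "linear", snapshot_lengths = 40)
  tr2 <- run_expansion(p2, seed = 17)
  expect_equal(tr2$snapshots[[1]]$R, tr2$snapshots[[1]]$R0)
})

test_that("ensembles are reproducible bit-for-bit and replicate-stable", {
  p <- sim_params(n0 = 200, q = 2, geometry = "radial", snapshot_lengths = 10)
  e1 <- run_ensemble(p, 5, 99, n_bins = 100)
  e2 <- run_ensemble(p, 5, 99, n_bins = 100)
  expect_identical(e1$summary$H, e2$summary$H)
  expect_identical(e1$trajectories[[3]]$events, e2$trajectories[[3]]$events)
  # first replicates agree independently of ensemble size
  e3 <- run_ensemble(p, 2, 99, summarize = FALSE)
  expect_identical(e3$trajectories[[1]]$final$phi, e1$trajectories[[1]]$final$phi)
  # single replicate reports no SEs
  e4 <- run_ensemble(p, 1, 99, n_bins = 100)
  expect_true(all(is.na(e4$summary$Fi$se)))
})

test_that("single-wall diffusion and drift match the microscopic map", {
  # Dw = a^2/(2d) with d != a; measured from sector-width variance growth
  a <- 1; d <- 2
  mm <- microscopic_map(a, d, r = 0.5)
  expect_equal(mm$Dw, 0.25)
  expect_equal(mm$vw, 0.25)
  p <- sim_params(n0 = 4000, q = 2, a = a, d = d, geometry = "linear",
                  snapshot_lengths = c(50, 100, 150, 200))
  init <- single_sector_state(p, width0 = pi)
  ens <- run_ensemble(p, 300, 31, init = init, summarize = FALSE)
  st <- sector_statistics(ens$trajectories, focal = 1L, width0 = pi)
  # width variance = 2 * (2 Dw L) / R0^2 in angular units on a linear ring
  slope <- coef(lm(st$var_phi ~ st$L))[[2]]
  expect_lt(abs(slope - 4 * mm$Dw / p$R0^2) / (4 * mm$Dw / p$R0^2), 0.15)
})
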