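# Integration, spike detection, burst statistics and regime classification.

test_that("a fast-subsystem equilibrium integrates to a constant trajectory", {
  p <- wb_params(I_app = 0.5, I_max = 1)
  eq <- find_equilibria(p, 10.6)
  node <- eq[eq$stability == "stable_node", ]
  y0 <- c(V = node$V, h = node$h, n = node$n)
  tr <- integrate_system(p, y0 = y0, t_end = 100, system = "fast",
                         K_fix = 10.6, thin = 100L)
  expect_lt(max(abs(tr$V - node$V)), 1e-8)
  expect_lt(max(abs(tr$h - node$h)), 1e-10)
})

test_that("integration rejects invalid settings", {
  p <- wb_params()
  expect_error(integrate_system(p, t_end = 10, dt = -1))
  expect_error(integrate_system(p, t_end = 10, transient = 20))
  expect_error(integrate_system(p, t_end = 10, system = "fast"), "K_fix")
  expect_error(integrate_system(p, y0 = c(1, 2), t_end = 10), "length")
})

test_that("fixed-step RK4 agrees with an independent integrator", {
  # deSolve's classical RK4 on the R-level right-hand side is the oracle
  skip_if_not_installed("deSolve")
  p <- wb_params(I_app = 0.5, I_max = 1)
  y0 <- initial_state(p)
  dt <- 0.02
  tr <- integrate_system(p, y0 = y0, t_end = 25, dt = dt, thin = 100L)
  rhs_desolve <- function(t, y, parms) list(unname(full_rhs(y, p)))
  ref <- deSolve::rk4(y0, seq(0, 25, dt), rhs_desolve, NULL)
  idx <- match(round(tr$t, 9), round(ref[, "time"], 9))
  expect_false(anyNA(idx))
  expect_lt(max(abs(tr$V - ref[idx, "V"])), 1e-8)
  expect_lt(max(abs(tr$K_out - ref[idx, "K_out"])), 1e-10)
})

test_that("integration error scales as dt^4 on a smooth segment", {
  # subthreshold relaxation (no spikes): errors vs a fine-dt reference
  p <- wb_params(I_app = 0.1, I_max = 1)
  y0 <- c(V = -75, h = h_inf(-75), n = n_inf(-75))
  end_V <- function(dt) {
    tr <- integrate_system(p, y0 = y0, t_end = 20, dt = dt, system = "fast",
                           K_fix = 4.8, thin = 1000000L)
    tr$V[nrow(tr)]
  }
  ref <- end_V(0.0005)
  e1 <- abs(end_V(0.08) - ref)
  e2 <- abs(end_V(0.04) - ref)
  expect_gt(e1 / e2, 8) # 4th order would give 16 (smaller dt hits roundoff)
})

test_that("spike detection finds interpolated crossings with refractoriness", {
  traj <- sawtooth_traj(k = 7)
  sp <- detect_spikes(traj, threshold = 0, refractory = 2)
  expect_identical(nrow(sp), 7L)
  # crossing time of the first ramp: V goes v_lo -> v_hi over period/2
  expect_equal(sp$time[1], 10 * 0.5 * (0 - (-60)) / (20 - (-60)),
               tolerance = 1e-6)
  # a refractory period longer than the sawtooth period merges spikes
  sp2 <- detect_spikes(traj, threshold = 0, refractory = 25)
  expect_lt(nrow(sp2), 7L)
  expect_true(all(diff(sp2$time) >= 25))
  # constant subthreshold trace: nothing
  expect_identical(nrow(detect_spikes(flat_traj(-70))), 0L)
})

test_that("burst summary recovers a synthetic burst structure exactly", {
  sp <- synthetic_burst_spikes(n_bursts = 6, k = 4, isi = 20, period = 500)
  tr <- envelope_traj(sp, t_end = 3000)
  s <- summarize_bursts(sp, tr)
  expect_identical(s$spikes_per_burst, 4L)
  expect_equal(s$interburst_period, 500, tolerance = 1e-10)
  expect_equal(s$intra_burst_isi_mean, 20, tolerance = 1e-10)
})

test_that("a perfectly regular train is unimodal, hence tonic", {
  times <- seq(0, 5000, by = 50)
  sp <- structure(tibble::tibble(time = times),
                  class = c("wb_spikes", class(tibble::tibble())),
                  threshold = 0, refractory = 2)
  tr <- envelope_traj(sp, 5000)
  tr$V[match(round(times), tr$t)] <- 10 # make the tail contain spikes
  s <- summarize_bursts(sp, tr)
  expect_identical(s$regime, "tonic")
  expect_false(s$period_doubled)
})

test_that("alternating interval sequences raise the period-doubled flag", {
  times <- cumsum(rep(c(30, 80), 12))
  sp <- structure(tibble::tibble(time = times),
                  class = c("wb_spikes", class(tibble::tibble())),
                  threshold = 0, refractory = 2)
  tr <- envelope_traj(sp, max(times))
  tr$V[match(round(times), tr$t)] <- 10
  s <- summarize_bursts(sp, tr)
  expect_true(s$period_doubled)
})

test_that("regime classification separates rest, block and undetermined", {
  expect_identical(classify_regime(flat_traj(-70)), "rest")
  expect_identical(classify_regime(flat_traj(-30)), "depolarization_block")
  expect_identical(classify_regime(flat_traj(-55)), "undetermined")
})

test_that("spike-count bisection recovers a known switch point", {
  # synthetic response: 12 "spikes" below the switch, 11 at or above
  switch_at <- 0.9731
  res <- locate_spike_count_transition(
    wb_params(), "I_max", c(0.9, 1.1), counts = c(11L, 12L), tol = 1e-6,
    count_fn = function(v) if (v < switch_at) 12L else 11L)
  expect_equal(res$value, switch_at, tolerance = 1e-4)
  expect_error(
    locate_spike_count_transition(
      wb_params(), "I_max", c(0.9, 1.1), counts = c(11L, 12L),
      count_fn = function(v) 11L),
    "same spike count")
  expect_error(
    locate_spike_count_transition(
      wb_params(), "I_max", c(0.9, 1.1), counts = c(11L, 12L),
      count_fn = function(v) if (v < 1) 4L else 20L),
    NA) # wide brackets straddling the divide are allowed
})

test_that("potassium rises spike-to-spike while bursting and falls between bursts", {
  sim <- burst_sim()
  expect_identical(sim$regime, "bursting")
  tr <- sim$trajectory
  sp <- sim$spikes$time
  isi <- diff(sp)
  gap_cut <- 200 # well above any intra-burst interval
  # K at each spike time
  K_sp <- approx(tr$t, tr$K_out, xout = sp)$y
  intra <- which(isi < gap_cut)
  expect_true(all(diff(K_sp)[intra] > 0))
  # across each inter-burst gap the concentration is pumped back down
  inter <- which(isi >= gap_cut)
  expect_true(all(diff(K_sp)[inter] < 0))
  # ISIs prolong within each complete burst (the first spiking segment is
  # the approach to the attractor and is excluded, as in the summaries)
  burst_id <- head(cumsum(c(1, as.integer(isi >= gap_cut))), length(isi))
  interior <- setdiff(unique(burst_id), range(burst_id))
  expect_gt(length(interior), 2)
  for (b in interior) {
    ii <- isi[burst_id == b & isi < gap_cut]
    expect_true(all(diff(ii) > 0))
  }
})

test_that("trajectories are bit-identical across repeated runs", {
  p <- wb_params(I_app = 0.5, I_max = 1)
  t1 <- integrate_system(p, t_end = 200, thin = 20L)
  t2 <- integrate_system(p, t_end = 200, thin = 20L)
  expect_identical(t1$V, t2$V)
  expect_identical(t1$K_out, t2$K_out)
})
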