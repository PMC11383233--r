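# Fast-subsystem bifurcation machinery: equilibria, continuation, limit
# cycles, branch terminations and the two organizing points.

test_that("the bistable strip holds exactly three equilibria of the right kinds", {
  p <- wb_params(I_app = 0.5, I_max = 1)
  eq <- find_equilibria(p, 10.6)
  expect_identical(nrow(eq), 3L)
  expect_identical(eq$stability, c("stable_node", "saddle", "unstable_focus"))
  expect_true(all(eq$residual < 1e-10))
  # below the fold only the focus remains; above it node and saddle exist
  eq_lo <- find_equilibria(p, 10.3)
  expect_identical(nrow(eq_lo), 1L)
  expect_identical(eq_lo$stability, "unstable_focus")
  eq_hi <- find_equilibria(p, 11.5)
  expect_true(all(c("stable_node", "saddle") %in% eq_hi$stability))
})

test_that("continuation finds the saddle-node where brute-force counting does", {
  p <- wb_params(I_app = 0.5, I_max = 1)
  eb <- memo("eq_branch_0.5", continue_equilibria(p, c(9, 16)))
  bif <- attr(eb, "bifurcations")
  sn <- bif[bif$type == "SN", ]
  expect_identical(nrow(sn), 1L)
  # brute-force oracle: bisection on the equilibrium count over a dense scan
  count2 <- function(K) nrow(find_equilibria(p, K, dV = 0.002,
                                             V_window = c(-90, -40))) >= 2
  lo <- 10; hi <- 11
  for (i in 1:20) {
    mid <- (lo + hi) / 2
    if (count2(mid)) hi <- mid else lo <- mid
  }
  expect_lt(abs(sn$K_out - (lo + hi) / 2), 1e-3)
  # fold has a near-zero real eigenvalue
  expect_lt(sn$diagnostic, 1e-6)
  # one Hopf on the upper branch inside the window
  expect_identical(sum(bif$type == "HOPF"), 1L)
  expect_gt(bif$K_out[bif$type == "HOPF"], sn$K_out)
})

test_that("shooting, simulation and spike detection agree on the cycle period", {
  p <- wb_params(I_app = 0.5, I_max = 1)
  lc <- find_limit_cycle(p, 10.0)
  expect_true(lc$found && lc$converged)
  expect_identical(lc$method, "shooting")
  # independent oracle: inter-spike interval of a plain long simulation
  tr <- integrate_system(p, y0 = c(V = -20, h = 0.5, n = 0.3), t_end = 3000,
                         system = "fast", K_fix = 10.0, thin = 2L,
                         transient = 2000)
  isi <- diff(detect_spikes(tr, threshold = -20)$time)
  expect_lt(abs(lc$tau - mean(isi)) / lc$tau, 1e-3)
  # autonomous-system property and stability
  expect_lt(abs(lc$trivial_multiplier - 1), 1e-4)
  expect_true(all(Mod(lc$multipliers) < 1))
  # cycle closure on the section
  expect_equal(unname(lc$y_section[["V"]]), -20)
})

test_that("the spiking branch at bursting parameters dies in a homoclinic", {
  br <- burst_branch()
  term <- attr(br, "termination")
  expect_identical(term$type, "HOM")
  # period divergence toward the homoclinic
  expect_gt(max(br$tau) / min(br$tau), 10)
  # the bistable window: SN below HOM
  expect_gt(term$K_end, term$K_sn)
  expect_lt(term$K_end - term$K_sn, 1)
  # V_min of the cycle approaches the saddle as the branch nears the HOM
  p <- wb_params(I_app = 0.5, I_max = 1)
  eq <- find_equilibria(p, max(br$K_out))
  saddle_V <- eq$V[eq$stability == "saddle"]
  expect_lt(abs(br$V_min[nrow(br)] - saddle_V), 2)
})

test_that("at high drive the branch ends in a fold of limit cycles instead", {
  p <- wb_params(I_app = 0.9, I_max = 1)
  br <- memo("lcb_0.9", continue_limit_cycles(p, c(3, 16), average = FALSE,
                                              min_step = 1e-4, step0 = 0.1))
  term <- attr(br, "termination")
  expect_identical(term$type, "FLC")
  # bounded period and a nontrivial multiplier pushing toward +1
  expect_lt(max(br$tau), 500)
  expect_gt(br$mult_max[nrow(br)], 0.5)
})

test_that("at low drive the cycle terminates on the saddle-node itself (SNIC)", {
  p <- wb_params(I_app = 0.25, I_max = 1)
  br <- memo("lcb_0.25", continue_limit_cycles(p, c(3, 16), average = FALSE,
                                               min_step = 1e-4, step0 = 0.1))
  term <- attr(br, "termination")
  expect_identical(term$type, "SNIC")
  expect_lt(abs(term$K_end - term$K_sn), 5e-3)
})

test_that("the SNL and HOM-inflection points bracket the canonical bursting drive", {
  p <- wb_params(I_max = 1)
  snl <- memo("snl_1", locate_snl(p, c(0.25, 0.55), tol = 0.1))
  expect_lt(snl$I_app, 0.5)
  expect_gt(snl$I_app, 0.25)
  infl <- memo("infl_1", locate_hom_inflection(p, c(0.5, 0.9), tol = 0.1))
  expect_gt(infl$I_app, 0.5)
  expect_lt(infl$I_app, 0.9)
  expect_gt(infl$I_app, snl$I_app)
})

test_that("two-parameter curves order SN below HOM inside the wedge", {
  p <- wb_params(I_max = 1)
  tp <- memo("tp_1",
             trace_two_parameter_curves(p, 0.5, K_window = c(8, 16)))
  for (ia in unique(tp$I_app)) {
    sn <- tp$K_out[tp$I_app == ia & tp$type == "SN"]
    hom <- tp$K_out[tp$I_app == ia & tp$type == "HOM"]
    expect_false(is.na(sn))
    expect_false(is.na(hom))
    expect_gt(hom, sn)
  }
})

test_that("the electroneutral fast subsystem is exactly pump-density invariant", {
  # I_P is absent from the voltage equation, so the entire fast subsystem -
  # hence every bifurcation curve - cannot depend on I_max
  st <- c(V = -50, h = 0.4, n = 0.2)
  for (K in c(5, 9, 13)) {
    p1 <- wb_params(I_app = 0.5, I_max = 0.5, electrogenic = FALSE)
    p2 <- wb_params(I_app = 0.5, I_max = 3, electrogenic = FALSE)
    expect_identical(fast_rhs(st, K, p1), fast_rhs(st, K, p2))
  }
  p1 <- wb_params(I_app = 0.5, I_max = 0.5, electrogenic = FALSE)
  p2 <- wb_params(I_app = 0.5, I_max = 3, electrogenic = FALSE)
  expect_equal(locate_fold_K(p1, c(3, 16)), locate_fold_K(p2, c(3, 16)),
               tolerance = 1e-9)
})

test_that("the electrogenic pump shears the saddle-node curve monotonically", {
  sn_at <- function(imax) locate_fold_K(wb_params(I_app = 0.5, I_max = imax),
                                        c(3, 18))
  sn <- vapply(c(0.5, 1, 2), sn_at, 0)
  expect_false(anyNA(sn))
  # stronger pump = more hyperpolarizing current at a given K, so the rest
  # state (and its fold) appears at lower potassium
  expect_true(all(diff(sn) < 0))
})
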