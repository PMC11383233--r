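# Model equations: gating kinetics, reversal potentials, pump sigmoid,
# currents and right-hand sides.

test_that("gating rates handle their removable singularities analytically", {
  r <- gating_rates(c(-34, -35, -44))
  # limits of x/(c(e^{x/10}-1)) as x -> 0 are 10/c
  expect_equal(r$alpha_n[1], 0.1, tolerance = 1e-10)
  expect_equal(r$alpha_m[2], 1.0, tolerance = 1e-10)
  expect_equal(r$beta_n[3], 0.125, tolerance = 1e-12)
  # continuity across the series branch
  eps <- 1e-8
  expect_equal(gating_rates(-34 + eps)$alpha_n, 0.1, tolerance = 1e-6)
  expect_equal(gating_rates(-34 - eps)$alpha_n, 0.1, tolerance = 1e-6)
  expect_error(gating_rates(NaN), "finite")
})

test_that("steady-state activation curves saturate and are monotone", {
  expect_equal(m_inf(200), 1, tolerance = 1e-6)
  expect_equal(m_inf(-200), 0, tolerance = 1e-6)
  # direct evaluation at the alpha_m singularity: 1 / (1 + 4 exp(-25/18))
  expect_equal(m_inf(-35), 1 / (1 + 4 * exp(-25 / 18)), tolerance = 1e-10)
  V <- seq(-90, 20, 0.5)
  expect_true(all(diff(m_inf(V)) > 0))
  expect_true(all(m_inf(V) >= 0 & m_inf(V) <= 1))
  expect_true(all(h_inf(V) >= 0 & h_inf(V) <= 1))
  expect_true(all(n_inf(V) >= 0 & n_inf(V) <= 1))
})

test_that("Nernst reversal potentials match direct evaluation", {
  p <- wb_params()
  expect_identical(reversal_EK(140, p), 0)
  expect_equal(reversal_EK(14, p), 26.71 * log(0.1), tolerance = 1e-12)
  expect_equal(reversal_EK(4.82, p), -89.98, tolerance = 1e-3)
  expect_identical(reversal_ENa(144, p), 0)
  expect_equal(reversal_ENa(18.4, p), 54.96, tolerance = 1e-2)
  expect_equal(reversal_ENa(144 / exp(1), p), 26.71, tolerance = 1e-10)
  K <- seq(1, 20, 0.5)
  expect_true(all(diff(reversal_EK(K, p)) > 0))
  expect_true(all(diff(reversal_ENa(K, p)) < 0))
  expect_error(reversal_EK(0, p), "positive")
  expect_error(reversal_ENa(-1, p), "positive")
})

test_that("pump current is a bounded, monotone sigmoid with midpoint K_half", {
  p <- wb_params(I_max = 1)
  expect_equal(pump_current(p$K_half, p), p$I_max / 2, tolerance = 1e-12)
  expect_equal(pump_current(1e4, p), p$I_max, tolerance = 1e-9)
  K <- seq(0.5, 40, 0.1)
  ip <- pump_current(K, p)
  expect_true(all(diff(ip) > 0))
  expect_true(all(ip > 0 & ip < p$I_max))
  # sodium-dependent variant multiplies a second sigmoid
  pn <- wb_params(I_max = 1, sodium_dynamic = TRUE)
  expect_equal(pump_current(pn$K_half, pn, Na_in = 18.4),
               0.5 / (1 + exp((25 - 18.4) / 3)), tolerance = 1e-12)
  expect_error(pump_current(5, pn), "Na_in")
})

test_that("ionic currents vanish with their driving forces and gates", {
  p <- wb_params()
  cur <- ionic_currents(c(V = p$E_L, h = 0, n = 0, K_out = 4.8), p)
  expect_identical(cur$I_L, 0)
  expect_identical(cur$I_Na, 0)
  expect_identical(cur$I_K, 0)
  cur2 <- ionic_currents(c(V = 10, h = 0, n = 0.3, K_out = 4.8), p)
  expect_identical(cur2$I_Na, 0)
  # spot value for the pump at classic resting potassium
  p1 <- wb_params(I_max = 1)
  expect_equal(ionic_currents(c(V = -65, h = 0.78, n = 0.09, K_out = 4.82),
                              p1)$I_P,
               1 / (1 + exp((p1$K_half - 4.82) / 1.1)), tolerance = 1e-12)
})

test_that("electrogenic and electroneutral voltage equations differ by I_P/C", {
  withr::with_seed(11, {
    for (i in 1:20) {
      st <- c(V = runif(1, -80, 20), h = runif(1), n = runif(1),
              K_out = runif(1, 3, 15))
      pe <- wb_params(I_app = runif(1, 0, 1.5), I_max = runif(1, 0.2, 3))
      pn <- pe
      pn$electrogenic <- FALSE
      de <- full_rhs(st, pe)
      dn <- full_rhs(st, pn)
      ip <- ionic_currents(st, pe)$I_P
      expect_lt(abs((dn[["V"]] - de[["V"]]) - ip / pe$C), 1e-12)
      # potassium balance is identical in the two variants
      expect_equal(de[["K_out"]], dn[["K_out"]], tolerance = 1e-15)
    }
  })
})

test_that("potassium mass balance carries the SI-derived conversion factor", {
  p <- wb_params()
  # from scratch: 1 uA/cm2 outward over A_cell gives A_cell*1e-6/F mol/s,
  # into the extracellular volume r_v*V_cell cm3 = r_v*V_cell*1e-3 L,
  # in mM (= 1e3 * mol/L), per ms (= 1e-3 s)
  flux_mol_per_s <- 1e-6 * p$A_cell / p$F
  mM_per_s <- flux_mol_per_s / (p$r_v * p$V_cell * 1e-3) * 1e3
  expect_equal(gamma_out(p), mM_per_s * 1e-3, tolerance = 1e-12)
  expect_equal(gamma_out(p), 4.1315e-4, tolerance = 1e-4)
  # dK/dt at I_K - 2 I_P = 1 equals gamma_out: build a state with I_K known
  st <- c(V = -30, h = 0.4, n = 0.5, K_out = 8)
  cur <- ionic_currents(st, p)
  d <- full_rhs(st, p)
  expect_equal(d[["K_out"]], (cur$I_K - 2 * cur$I_P) * gamma_out(p),
               tolerance = 1e-15)
})

test_that("a state balancing I_K against 2 I_P freezes the potassium", {
  p <- wb_params()
  st <- c(V = -40, h = 0.5, n = 0.4, K_out = 9)
  IK <- p$g_K * st[["n"]]^4 * (st[["V"]] - reversal_EK(9, p))
  # scale I_max so that I_P = I_K/2 exactly at this state
  p$I_max <- IK / 2 / (1 / (1 + exp((p$K_half - 9) / p$K_slope)))
  expect_equal(full_rhs(st, p)[["K_out"]], 0, tolerance = 1e-15)
})

test_that("steady-state gates zero their own dynamics", {
  p <- wb_params()
  V <- -52.3
  d <- fast_rhs(c(V = V, h = h_inf(V), n = n_inf(V)), K_out = 6, p)
  expect_equal(d[["h"]], 0, tolerance = 1e-15)
  expect_equal(d[["n"]], 0, tolerance = 1e-15)
})

test_that("R and compiled right-hand sides agree on random states", {
  withr::with_seed(7, {
    for (i in 1:15) {
      pe <- wb_params(I_app = runif(1, 0, 1.5), I_max = runif(1, 0.2, 3),
                      electrogenic = runif(1) > 0.3)
      st <- c(V = runif(1, -90, 30), h = runif(1), n = runif(1),
              K_out = runif(1, 2, 20))
      expect_equal(unname(full_rhs(st, pe)),
                   as.numeric(rhs_cpp(as.numeric(st), unclass(pe), 1L, NA)),
                   tolerance = 1e-12)
      expect_equal(unname(fast_rhs(st[1:3], st[["K_out"]], pe)),
                   as.numeric(rhs_cpp(as.numeric(st[1:3]), unclass(pe), 0L,
                                      st[["K_out"]])),
                   tolerance = 1e-12)
      pn <- pe
      pn$sodium_dynamic <- TRUE
      stn <- c(st, Na_in = runif(1, 5, 50))
      expect_equal(unname(full_rhs(stn, pn)),
                   as.numeric(rhs_cpp(as.numeric(stn), unclass(pn), 2L, NA)),
                   tolerance = 1e-12)
    }
  })
})

test_that("sodium-extended balance follows its continuity equation", {
  p <- wb_params(sodium_dynamic = TRUE)
  st <- c(V = -30, h = 0.4, n = 0.5, K_out = 8, Na_in = 18.4)
  cur <- ionic_currents(st, p)
  d <- full_rhs(st, p)
  expect_equal(d[["Na_in"]], (-cur$I_Na - 3 * cur$I_P) * gamma_in(p),
               tolerance = 1e-15)
  # E_Na is now the Nernst value, not the constant
  expect_equal(cur$I_Na,
               p$g_Na * 0.4 * m_inf(-30)^3 * (-30 - reversal_ENa(18.4, p)),
               tolerance = 1e-12)
})

test_that("gating variables stay inside [0,1] along trajectories", {
  p <- wb_params()
  withr::with_seed(3, {
    for (i in 1:5) {
      y0 <- c(V = runif(1, -80, 0), h = runif(1), n = runif(1),
              K_out = runif(1, 4, 12))
      tr <- integrate_system(p, y0 = y0, t_end = 500, thin = 5L)
      expect_true(all(tr$h >= 0 & tr$h <= 1))
      expect_true(all(tr$n >= 0 & tr$n <= 1))
      expect_true(all(tr$K_out > 0))
    }
  })
})

test_that("parameter validation reports violations and rejects unknowns", {
  expect_error(wb_params(g_Na = -1), "g_Na")
  expect_error(wb_params(frobnicate = 2), "unknown parameter")
  expect_error(wb_params(C = 0), "C must be")
  p <- wb_params()
  expect_s3_class(p, "wb_params")
  expect_identical(p$g_K, 9)     # conductance, mS/cm2
  expect_identical(p$gating_phi, 5)
  expect_identical(p$K_slope, 1.1)
})
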