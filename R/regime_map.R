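# Regime maps of the complete system over pump density (I_max) and applied
# current (I_app): one classified simulation per grid cell.

#' Scan the (I_max, I_app) plane and classify each cell
#'
#' Runs one deterministic, transient-discarded simulation of the complete
#' system per grid cell and classifies the regime (rest, tonic, bursting,
#' depolarization block). Cells are independent: results do not depend on
#' evaluation order.
#'
#' @param p Base [wb_params()] object (its `I_max`, `I_app` are overridden
#'   cell by cell).
#' @param I_max_values,I_app_values Grid values, uA/cm^2.
#' @param t_end,transient,dt Simulation settings per cell, ms.
#' @param y0 Optional shared initial state (default: low-potassium rest,
#'   [initial_state()]).
#' @return A `wb_regime_grid` tibble, one row per cell: `I_max`, `I_app`,
#'   `regime`, `spikes_per_burst`, `interburst_ms`, `isi_mean_ms`,
#'   `K_out_min`, `K_out_max`, `period_doubled`.
#' @export
scan_regimes <- function(p, I_max_values, I_app_values, t_end = 12000,
                         transient = 2000, dt = 0.005, y0 = NULL) {
  grid <- tidyr::expand_grid(I_max = I_max_values, I_app = I_app_values)
  rows <- purrr::pmap(grid, function(I_max, I_app) {
    pc <- p
    pc$I_max <- I_max
    pc$I_app <- I_app
    sim <- simulate_neuron(pc, y0 = y0, t_end = t_end, transient = transient,
                           dt = dt)
    s <- sim$summary
    tibble::tibble(
      I_max = I_max, I_app = I_app, regime = s$regime,
      spikes_per_burst = s$spikes_per_burst,
      interburst_ms = s$interburst_period, isi_mean_ms = s$intra_burst_isi_mean,
      K_out_min = s$K_out_min, K_out_max = s$K_out_max,
      period_doubled = s$period_doubled)
  })
  structure(dplyr::bind_rows(rows),
            class = c("wb_regime_grid", class(tibble::tibble())))
}

#' Potassium oscillation amplitude along an I_max sweep
#'
#' For each applied current, sweeps the pump density and records the minimal
#' and maximal \[K+\]_out over the post-transient oscillation, reproducing
#' the widening of the potassium range as the pump weakens and the burst
#' onset/offset along the sweep. Depolarization-block cells report the
#' settling potassium trend (the tail extrema) and are flagged.
#'
#' @inheritParams scan_regimes
#' @return A tibble: `I_app`, `I_max`, `regime`, `K_out_min`, `K_out_max`,
#'   `K_range`, `period_doubled`.
#' @export
amplitude_curves <- function(p, I_app_values, I_max_values, t_end = 12000,
                             transient = 2000, dt = 0.005) {
  g <- scan_regimes(p, I_max_values, I_app_values, t_end = t_end,
                    transient = transient, dt = dt)
  out <- dplyr::mutate(tibble::as_tibble(g),
                       K_range = .data$K_out_max - .data$K_out_min)
  out[, c("I_app", "I_max", "regime", "K_out_min", "K_out_max", "K_range",
          "period_doubled")]
}

#' Refine a regime boundary along one parameter by bisection
#'
#' Bisects between two parameter values with different classified regimes,
#' holding everything else fixed.
#'
#' @param p Base [wb_params()] object.
#' @param vary `"I_max"` or `"I_app"`.
#' @param bracket Length-2 bracket for the varied parameter.
#' @param tol Bracket width at which bisection stops.
#' @param ... Passed to [simulate_neuron()].
#' @return A list: `value` (midpoint), `regimes` (the two regimes found at
#'   the original bracket ends).
#' @export
refine_regime_boundary <- function(p, vary, bracket, tol = 1e-3, ...) {
  cls <- function(v) {
    pc <- p
    pc[[vary]] <- v
    simulate_neuron(pc, ...)$regime
  }
  lo <- bracket[1]; hi <- bracket[2]
  r_lo <- cls(lo); r_hi <- cls(hi)
  if (r_lo == r_hi) stop("same regime (", r_lo, ") at both bracket ends")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (cls(mid) == r_lo) lo <- mid else hi <- mid
  }
  list(value = (lo + hi) / 2, regimes = c(r_lo, r_hi))
}
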