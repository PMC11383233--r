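#' Integrate the fast subsystem or the complete system
#'
#' Fixed-step classical RK4 at time step `dt` (default 0.005 ms). The fast
#' subsystem (`system = "fast"`) holds extracellular potassium frozen at
#' `K_fix`; the complete system evolves it (and intracellular sodium when the
#' parameter set enables it). Only samples after `transient` and at stride
#' `thin` are retained, so long runs stay memory-light while the stepping is
#' always performed at full resolution.
#'
#' @param p A [wb_params()] object.
#' @param y0 Named initial state; defaults to [initial_state()] for the
#'   complete system. For `system = "fast"` it must contain `V`, `h`, `n`.
#' @param t_end Integration span, ms.
#' @param dt Time step, ms.
#' @param system `"full"` (default) or `"fast"`.
#' @param K_fix Frozen \[K+\]_out for the fast subsystem, mM.
#' @param thin Keep every `thin`-th sample (default such that the output
#'   resolution is 0.05 ms at the default `dt`).
#' @param transient Initial span to discard from the output, ms.
#' @return A `wb_trajectory` object: a tibble with columns `t` (ms), `V`
#'   (mV), `h`, `n` and (complete system) `K_out` (mM), plus `Na_in` (mM)
#'   when sodium is dynamic. Attributes carry the parameters and integrator
#'   metadata.
#' @examples
#' \donttest{
#' p <- wb_params(I_app = 0.5, I_max = 1)
#' tr <- integrate_system(p, t_end = 3000, transient = 0)
#' range(tr$K_out)
#' }
#' @export
integrate_system <- function(p, y0 = NULL, t_end = 12000, dt = 0.005,
                             system = c("full", "fast"), K_fix = NA_real_,
                             thin = 10L, transient = 0) {
  system <- match.arg(system)
  stopifnot(dt > 0, t_end > transient, transient >= 0)
  sys <- if (system == "fast") 0L else if (isTRUE(p$sodium_dynamic)) 2L else 1L
  if (sys == 0L && !is.finite(K_fix)) stop("K_fix required for the fast subsystem")
  if (is.null(y0)) {
    y0 <- initial_state(p)
    if (sys == 0L) y0 <- y0[c("V", "h", "n")]
  }
  dim_need <- c(3L, 4L, 5L)[sys + 1L]
  if (length(y0) != dim_need)
    stop("y0 has length ", length(y0), ", expected ", dim_need)
  res <- rk4_cpp(as.numeric(y0), t_end, dt, unclass(p), sys, K_fix,
                 as.integer(thin), transient)
  if (!res$completed)
    stop("non-finite state at t = ", res$t_last,
         " ms; last finite state retained in partial output")
  cols <- c("V", "h", "n", if (sys >= 1L) "K_out", if (sys == 2L) "Na_in")
  out <- tibble::as_tibble(as.data.frame(res$states))
  names(out) <- cols
  out <- dplyr::bind_cols(tibble::tibble(t = res$times), out)
  structure(out,
            class = c("wb_trajectory", class(out)),
            params = p,
            meta = list(method = "rk4", dt = dt, thin = thin,
                        transient = transient, system = system,
                        K_fix = K_fix, y_end = res$y_end))
}

#' Simulate the complete system and summarize its behaviour
#'
#' High-level driver: integrates the complete system from the default (or
#' given) initial condition, detects spikes, computes burst statistics and
#' classifies the dynamical regime. This is the entry point used for regime
#' maps and for reproducing the canonical bursting trace
#' (I_app = 0.5, I_max = 1).
#'
#' @inheritParams integrate_system
#' @param t_end Simulated span, ms (default 12 s).
#' @param transient Discarded initial span, ms (default 2 s).
#' @param threshold Spike threshold, mV (upward crossing).
#' @param refractory Minimal spike separation, ms.
#' @return A `wb_sim` object (list) with elements `trajectory`
#'   (`wb_trajectory` tibble), `spikes` ([detect_spikes()] result),
#'   `summary` ([summarize_bursts()] tibble) and `regime` (character).
#' @examples
#' \donttest{
#' sim <- simulate_neuron(wb_params(I_app = 0.5, I_max = 1))
#' sim$regime
#' sim$summary
#' }
#' @export
simulate_neuron <- function(p, y0 = NULL, t_end = 12000, transient = 2000,
                            dt = 0.005, thin = 10L,
                            threshold = 0, refractory = 2) {
  tr <- integrate_system(p, y0 = y0, t_end = t_end, dt = dt,
                         thin = thin, transient = transient)
  sp <- detect_spikes(tr, threshold = threshold, refractory = refractory)
  sm <- summarize_bursts(sp, tr)
  structure(list(trajectory = tr, spikes = sp, summary = sm,
                 regime = sm$regime[1], params = p),
            class = "wb_sim")
}

#' @export
print.wb_sim <- function(x, ...) {
  cat(sprintf("<wb_sim> I_app = %g, I_max = %g: regime = %s\n",
              x$params$I_app, x$params$I_max, x$regime))
  if (x$regime == "bursting")
    cat(sprintf("  %s spikes/burst, inter-burst period %.0f ms, K_out in [%.3f, %.3f] mM\n",
                paste(unique(x$summary$spikes_per_burst), collapse = "/"),
                x$summary$interburst_period, x$summary$K_out_min,
                x$summary$K_out_max))
  invisible(x)
}

#' @export
tidy.wb_sim <- function(x, ...) x$trajectory

#' @export
glance.wb_sim <- function(x, ...) x$summary
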