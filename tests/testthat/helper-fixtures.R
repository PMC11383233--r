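# Shared fixtures. Expensive objects (long simulations, branch
# continuations, hysteresis diagrams) are computed once per test run and
# memoised here, so several test files can interrogate the same canonical
# runs without re-simulating.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

p_burst <- function() wb_params(I_app = 0.5, I_max = 1)

# canonical bursting run: 12 s, 2 s transient (the standard classification
# protocol used throughout)
burst_sim <- function() memo("burst_sim", simulate_neuron(p_burst()))

anchor_sim <- function(I_max, I_app) {
  memo(sprintf("sim_%g_%g", I_max, I_app),
       simulate_neuron(wb_params(I_app = I_app, I_max = I_max)))
}

anchor_hysteresis <- function(I_max, I_app) {
  # all SN/HOM/Hopf/FLC structure of the anchor cases lies above 8 mM
  memo(sprintf("hys_%g_%g", I_max, I_app),
       assemble_hysteresis(wb_params(I_app = I_app, I_max = I_max),
                           K_window = c(8, 16)))
}

burst_branch <- function() {
  # spiking-branch continuation of the canonical case, from the cycle onset
  # at low potassium through the bistable strip, fine terminal steps
  memo("burst_branch",
       continue_limit_cycles(p_burst(), c(4, 16), average = FALSE))
}

# synthetic trajectory: piecewise-linear sawtooth crossing `threshold`
# `k` times, with a flat K_out column so burst summaries can run on it
sawtooth_traj <- function(k, period = 10, dt = 0.1, v_lo = -60, v_hi = 20) {
  t <- seq(0, k * period, by = dt)
  phase <- (t %% period) / period
  V <- ifelse(phase < 0.5, v_lo + (v_hi - v_lo) * 2 * phase,
              v_hi - (v_hi - v_lo) * 2 * (phase - 0.5))
  tibble::tibble(t = t, V = V, h = 0.5, n = 0.3, K_out = 5)
}

# synthetic trajectory that is flat at a voltage (rest / block fixtures)
flat_traj <- function(V, t_end = 6000, dt = 1) {
  t <- seq(0, t_end, by = dt)
  tibble::tibble(t = t, V = V, h = 0.5, n = 0.3, K_out = 5)
}

# synthetic spike train with known burst structure: `n_bursts` bursts of
# `k` spikes at intra-burst interval `isi`, cycle period `period`
synthetic_burst_spikes <- function(n_bursts = 5, k = 4, isi = 20,
                                   period = 500) {
  times <- unlist(lapply(seq_len(n_bursts) - 1, function(b)
    b * period + (seq_len(k) - 1) * isi))
  structure(tibble::tibble(time = times),
            class = c("wb_spikes", class(tibble::tibble())),
            threshold = 0, refractory = 2)
}

# trajectory envelope matching a synthetic spike train (flat, subthreshold;
# only t and K_out are consulted by the summary)
envelope_traj <- function(spikes, t_end) {
  t <- seq(0, t_end, by = 1)
  tibble::tibble(t = t, V = -60, h = 0.5, n = 0.3,
                 K_out = 5 + 0.1 * sin(2 * pi * t / t_end))
}
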