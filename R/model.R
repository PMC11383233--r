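#' Gating rate functions of the Wang-Buzsaki currents
#'
#' Opening/closing rates for sodium inactivation (h), potassium activation
#' (n) and the instantaneous sodium activation (m) at membrane potential `V`.
#' The removable singularities of `alpha_n` (V = -34 mV) and `alpha_m`
#' (V = -35 mV) are evaluated by their analytic limits through a series
#' branch for |V - V_sing| < 1e-6 mV. The temperature factor phi multiplying
#' dh/dt and dn/dt is applied at the right-hand-side level, not here.
#'
#' @param V Membrane potential, mV (vectorized).
#' @return A tibble with columns `V`, `alpha_h`, `beta_h`, `alpha_n`,
#'   `beta_n`, `alpha_m`, `beta_m` (all ms^-1).
#' @export
gating_rates <- function(V) {
  if (!all(is.finite(V))) stop("V must be finite")
  tibble::tibble(
    V = V,
    alpha_h = 0.07 * exp(-(V + 58) / 20),
    beta_h  = 1 / (exp(-(V + 28) / 10) + 1),
    alpha_n = rate_ratio(-34 - V, 100),
    beta_n  = 0.125 * exp(-(V + 44) / 80),
    alpha_m = rate_ratio(-35 - V, 10),
    beta_m  = 4 * exp(-(V + 60) / 18)
  )
}

# x / (c * (exp(x/10) - 1)) with the removable singularity at x = 0 replaced
# by its series (10/c)(1 - x/20 + O(x^2)) near 0.
rate_ratio <- function(x, c) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-7
  out[small] <- (10 / c) * (1 - x[small] / 20)
  out[!small] <- x[!small] / (c * (exp(x[!small] / 10) - 1))
  out
}

#' Steady-state gating curves
#'
#' `m_inf` is the instantaneous activation of the transient sodium current;
#' within this model m always sits on this curve, which reduces the fast
#' subsystem from four to three dimensions. `h_inf` and `n_inf` are the
#' voltage steady states of the two dynamic gates.
#'
#' @param V Membrane potential, mV (vectorized).
#' @return Dimensionless values in \[0, 1\].
#' @export
m_inf <- function(V) {
  r <- gating_rates(V)
  r$alpha_m / (r$alpha_m + r$beta_m)
}

#' @rdname m_inf
#' @export
h_inf <- function(V) {
  r <- gating_rates(V)
  r$alpha_h / (r$alpha_h + r$beta_h)
}

#' @rdname m_inf
#' @export
n_inf <- function(V) {
  r <- gating_rates(V)
  r$alpha_n / (r$alpha_n + r$beta_n)
}

#' Nernst reversal potentials
#'
#' `reversal_EK` gives the potassium reversal potential as a function of the
#' extracellular concentration (intracellular concentration fixed at
#' `K_in_ref`); `reversal_ENa` gives the sodium reversal potential as a
#' function of the intracellular concentration (extracellular fixed at
#' `Na_out_ref`), used by the dynamic-sodium variant.
#'
#' @param K_out Extracellular potassium, mM (> 0, vectorized).
#' @param Na_in Intracellular sodium, mM (> 0, vectorized).
#' @param p A [wb_params()] object.
#' @return Reversal potential, mV.
#' @export
reversal_EK <- function(K_out, p = wb_params()) {
  if (any(!is.finite(K_out) | K_out <= 0)) stop("K_out must be positive")
  p$nernst_prefactor * log(K_out / p$K_in_ref)
}

#' @rdname reversal_EK
#' @export
reversal_ENa <- function(Na_in, p = wb_params()) {
  if (any(!is.finite(Na_in) | Na_in <= 0)) stop("Na_in must be positive")
  p$nernst_prefactor * log(p$Na_out_ref / Na_in)
}

#' Na+/K+-ATPase pump current
#'
#' Sigmoidal pump activation: half-maximal at `K_half` mM extracellular
#' potassium with steepness `K_slope`; saturates at `I_max`. In the
#' dynamic-sodium variant a second sigmoid in intracellular sodium
#' multiplies the activation (half point `Na_half`, steepness `Na_slope`).
#'
#' @param K_out Extracellular potassium, mM (> 0, vectorized).
#' @param p A [wb_params()] object.
#' @param Na_in Intracellular sodium, mM; required when `p$sodium_dynamic`.
#' @return Pump current, uA/cm^2, in (0, I_max).
#' @export
pump_current <- function(K_out, p = wb_params(), Na_in = NULL) {
  if (any(!is.finite(K_out) | K_out <= 0)) stop("K_out must be positive")
  ip <- p$I_max / (1 + exp((p$K_half - K_out) / p$K_slope))
  if (isTRUE(p$sodium_dynamic)) {
    if (is.null(Na_in)) stop("Na_in required when sodium_dynamic = TRUE")
    ip <- ip / (1 + exp((p$Na_half - Na_in) / p$Na_slope))
  }
  ip
}

#' Membrane and pump currents at a state
#'
#' Evaluates the sodium, potassium, leak and pump currents at a full state.
#' E_Na is the fixed parameter unless the dynamic-sodium variant is active,
#' in which case it follows its Nernst equation.
#'
#' @param state Named numeric vector with `V`, `h`, `n`, `K_out` and, when
#'   `p$sodium_dynamic`, `Na_in`.
#' @param p A [wb_params()] object.
#' @return A tibble with one row: `I_Na`, `I_K`, `I_L`, `I_P` (uA/cm^2).
#' @export
ionic_currents <- function(state, p = wb_params()) {
  V <- state[["V"]]; h <- state[["h"]]; n <- state[["n"]]
  K_out <- state[["K_out"]]
  E_Na <- if (isTRUE(p$sodium_dynamic)) reversal_ENa(state[["Na_in"]], p) else p$E_Na
  Na_in <- if (isTRUE(p$sodium_dynamic)) state[["Na_in"]] else NULL
  tibble::tibble(
    I_Na = p$g_Na * h * m_inf(V)^3 * (V - E_Na),
    I_K  = p$g_K * n^4 * (V - reversal_EK(K_out, p)),
    I_L  = p$g_L * (V - p$E_L),
    I_P  = pump_current(K_out, p, Na_in)
  )
}

#' Right-hand sides of the fast subsystem and complete system
#'
#' `fast_rhs` treats extracellular potassium as a frozen parameter (the
#' slow-fast dissection view of the fast subsystem); `full_rhs` evolves it by
#' the potassium mass balance d\[K+\]_out/dt = (I_K - 2 I_P) * gamma_out and,
#' in the dynamic-sodium variant, d\[Na+\]_in/dt = (-I_Na - 3 I_P) * gamma_in.
#' The pump current enters dV/dt only when `p$electrogenic`.
#'
#' @param state For `fast_rhs` a named vector (V, h, n); for `full_rhs` a
#'   named vector (V, h, n, K_out\[, Na_in\]).
#' @param K_out Frozen extracellular potassium, mM (`fast_rhs` only).
#' @param p A [wb_params()] object.
#' @return Named numeric vector of time derivatives (mV/ms, 1/ms, mM/ms).
#' @export
fast_rhs <- function(state, K_out, p = wb_params()) {
  d <- full_rhs(c(state[c("V", "h", "n")], K_out = K_out,
                  if (isTRUE(p$sodium_dynamic)) c(Na_in = unname(state[["Na_in"]]))),
                p)
  d[c("V", "h", "n")]
}

#' @rdname fast_rhs
#' @export
full_rhs <- function(state, p = wb_params()) {
  V <- state[["V"]]; h <- state[["h"]]; n <- state[["n"]]
  cur <- ionic_currents(state, p)
  r <- gating_rates(V)
  I_mem <- p$I_app - cur$I_Na - cur$I_K - cur$I_L -
    if (isTRUE(p$electrogenic)) cur$I_P else 0
  d <- c(
    V = I_mem / p$C,
    h = p$gating_phi * (r$alpha_h * (1 - h) - r$beta_h * h),
    n = p$gating_phi * (r$alpha_n * (1 - n) - r$beta_n * n),
    K_out = (cur$I_K - 2 * cur$I_P) * gamma_out(p)
  )
  if (isTRUE(p$sodium_dynamic))
    d <- c(d, Na_in = (-cur$I_Na - 3 * cur$I_P) * gamma_in(p))
  d
}
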