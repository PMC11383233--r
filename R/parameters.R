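#' Model parameters for the pump-coupled Wang-Buzsaki neuron
#'
#' Builds the full parameter set of the model: Wang-Buzsaki spike-generating
#' conductances, the sigmoidal Na+/K+-ATPase pump, cell geometry governing the
#' extracellular potassium mass balance, and the variant switches. Defaults
#' are the published nominal values for a fast-spiking interneuron embedded in
#' a small extracellular space; `I_app` and `I_max` are the two knobs varied
#' across experiments and therefore default to the canonical bursting case.
#'
#' @param I_app Applied (stimulus) current, uA/cm^2.
#' @param I_max Maximal Na+/K+-ATPase pump current, uA/cm^2. Proportional to
#'   membrane pump density.
#' @param electrogenic If `TRUE` (default) the pump current enters the voltage
#'   equation (3 Na+ out / 2 K+ in carries net charge). `FALSE` gives the
#'   electroneutral control in which the pump moves K+ but carries no current.
#' @param sodium_dynamic If `TRUE`, intracellular sodium is a state variable:
#'   E_Na follows a Nernst equation and the pump gains a sodium-dependent
#'   activation factor.
#' @param ... Overrides for any other field, by name:
#'   `g_Na`, `g_K`, `g_L` (mS/cm^2), `E_Na`, `E_L` (mV), `C` (uF/cm^2),
#'   `K_half`, `K_slope`, `Na_half`, `Na_slope` (mM), `A_cell` (cm^2),
#'   `V_cell` (cm^3), `r_v` (extracellular/intracellular volume ratio),
#'   `F` (C/mol), `K_in_ref` (mM), `Na_out_ref` (mM),
#'   `nernst_prefactor` (mV), `gating_phi` (temperature factor on h, n
#'   kinetics).
#'
#' @return An object of class `wb_params`: a named list of all parameters.
#' @examples
#' p <- wb_params(I_app = 0.5, I_max = 1)
#' p$g_Na
#' @export
wb_params <- function(I_app = 0.5, I_max = 1, electrogenic = TRUE,
                      sodium_dynamic = FALSE, ...) {
  p <- list(
    g_Na = 35, g_K = 9, g_L = 0.1,
    E_Na = 55, E_L = -65, C = 1,
    I_app = I_app, I_max = I_max,
    K_half = 11, K_slope = 1.1,
    Na_half = 25, Na_slope = 3,
    A_cell = 3.142e-6, V_cell = 5.23e-10, r_v = 0.15,
    F = 9.694e4,
    K_in_ref = 140, Na_out_ref = 144,
    nernst_prefactor = 26.71,
    gating_phi = 5,
    electrogenic = electrogenic,
    sodium_dynamic = sodium_dynamic
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- modifyList(p, dots)
  num_fields <- setdiff(names(p), c("electrogenic", "sodium_dynamic"))
  p[num_fields] <- lapply(p[num_fields], function(v)
    if (is.integer(v)) as.numeric(v) else v)
  validate_wb_params(p)
  structure(p, class = "wb_params")
}

validate_wb_params <- function(p) {
  pos <- c("g_Na", "g_K", "g_L", "C", "I_max", "K_slope", "Na_slope",
           "A_cell", "V_cell", "r_v", "F", "K_in_ref", "Na_out_ref")
  problems <- character()
  for (f in pos)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      problems <- c(problems, paste0(f, " must be a single positive number"))
  num <- c("E_Na", "E_L", "I_app", "K_half", "Na_half", "nernst_prefactor",
           "gating_phi")
  for (f in num)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]))
      problems <- c(problems, paste0(f, " must be a single finite number"))
  for (f in c("electrogenic", "sodium_dynamic"))
    if (!is.logical(p[[f]]) || length(p[[f]]) != 1 || is.na(p[[f]]))
      problems <- c(problems, paste0(f, " must be TRUE or FALSE"))
  if (length(problems))
    stop("invalid parameters:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(p)
}

#' Conversion factor from membrane current density to d[K+]_out/dt
#'
#' `gamma_out` converts a net outward current density (uA/cm^2) into the rate
#' of change of the extracellular potassium concentration (mM/ms) through the
#' cell surface area, Faraday's constant and the extracellular volume
#' `r_v * V_cell`. `gamma_in` is the analogous factor for the intracellular
#' sodium balance (volume `V_cell`).
#'
#' @param p A [wb_params()] object.
#' @return A single number, mM/ms per uA/cm^2.
#' @export
gamma_out <- function(p) 1e-3 * p$A_cell / (p$r_v * p$F * p$V_cell)

#' @rdname gamma_out
#' @export
gamma_in <- function(p) 1e-3 * p$A_cell / (p$F * p$V_cell)

#' @export
print.wb_params <- function(x, ...) {
  cat("<wb_params> pump-coupled Wang-Buzsaki neuron\n")
  cat(sprintf("  I_app = %g, I_max = %g uA/cm^2; electrogenic = %s, dynamic Na = %s\n",
              x$I_app, x$I_max, x$electrogenic, x$sodium_dynamic))
  cat(sprintf("  g_Na/g_K/g_L = %g/%g/%g mS/cm^2, E_Na = %g, E_L = %g mV\n",
              x$g_Na, x$g_K, x$g_L, x$E_Na, x$E_L))
  cat(sprintf("  pump: K_half = %g mM (slope %g), Na_half = %g mM (slope %g)\n",
              x$K_half, x$K_slope, x$Na_half, x$Na_slope))
  invisible(x)
}

#' Parameter table
#'
#' All parameters of a `wb_params` object as a two-column tibble, convenient
#' for dumping a reproducible record of a run.
#'
#' @param p A [wb_params()] object.
#' @return A tibble with columns `parameter` and `value`.
#' @export
params_table <- function(p) {
  stopifnot(inherits(p, "wb_params"))
  tibble::tibble(
    parameter = names(p),
    value = vapply(p, function(v) as.character(v), character(1))
  )
}

#' Default initial state
#'
#' The default initial condition used throughout: V = -65 mV with gating
#' variables at their voltage steady state, [K+]_out = 4.8 mM (E_K close to
#' -90 mV, the classic resting value for this neuron class) and, when sodium
#' is dynamic, [Na+]_in = 18.4 mM (E_Na = 55 mV).
#'
#' @param p A [wb_params()] object.
#' @param V Initial membrane potential, mV.
#' @param K_out Initial extracellular potassium, mM.
#' @param Na_in Initial intracellular sodium, mM (used only when
#'   `p$sodium_dynamic`).
#' @return Named numeric vector (V, h, n, K_out[, Na_in]).
#' @export
initial_state <- function(p, V = -65, K_out = 4.8, Na_in = 18.4) {
  s <- c(V = V, h = h_inf(V), n = n_inf(V), K_out = K_out)
  if (isTRUE(p$sodium_dynamic)) s <- c(s, Na_in = Na_in)
  s
}
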