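# Two-parameter structure of the fast subsystem in the ([K+]_out, I_app)
# plane: the SN and HOM curves, and the two organizing points that bound the
# bursting region in applied current - the saddle-node loop (SNL), where the
# homoclinic merges with the saddle-node fold, and the homoclinic
# "inflection" (fold of the HOM curve), beyond which an upward potassium
# sweep meets a fold of limit cycles instead of a homoclinic.

# Termination of the spiking branch at one applied current; cheap settings
# for classification sweeps.
branch_termination <- function(p, I_app, K_window = c(3, 16),
                               min_step = 1e-4) {
  lcb <- continue_limit_cycles(p, K_window, I_app = I_app, average = FALSE,
                               min_step = min_step, step0 = 0.1,
                               tau_cut = 400, snic_tol = 0.05)
  attr(lcb, "termination")
}

#' Trace the SN and HOM curves in the (K_out, I_app) plane
#'
#' For each applied current on a grid, locates the saddle-node fold K by
#' equilibrium counting with fold polishing, and the homoclinic K from the
#' termination of the spiking-branch continuation. Grid points at which a
#' codimension-one point is absent (no fold in the window; branch ending in
#' a fold of limit cycles or at the window edge) are recorded as gaps
#' (`NA`).
#'
#' @param p A [wb_params()] object.
#' @param I_app_values Applied-current grid, uA/cm^2.
#' @param K_window \[K+\]_out window searched, mM.
#' @param min_step Continuation minimum step (see
#'   [continue_limit_cycles()]).
#' @return A `wb_two_param` tibble: `I_app`, `type` (SN or HOM), `K_out`
#'   (NA for a gap), `termination` (branch termination type at that
#'   I_app).
#' @export
trace_two_parameter_curves <- function(p, I_app_values, K_window = c(3, 16),
                                       min_step = 1e-4) {
  rows <- lapply(I_app_values, function(ia) {
    Ksn <- locate_fold_K(p, K_window, I_app = ia)
    term <- branch_termination(p, ia, K_window, min_step)
    Khom <- if (term$type %in% c("HOM", "SNIC")) term$K_end else NA_real_
    tibble::tibble(I_app = ia, type = c("SN", "HOM"),
                   K_out = c(Ksn, Khom), termination = term$type)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("wb_two_param", class(tibble::tibble())))
}

#' Locate the saddle-node-loop point
#'
#' Bisects in applied current on the classification of the spiking-branch
#' termination: below the SNL the cycle dies on the saddle-node itself
#' (SNIC; terminating saddle coincides with the fold), above it the
#' homoclinic separates from the fold and a bistable wedge opens.
#'
#' @param p A [wb_params()] object.
#' @param I_window Applied-current bracket, uA/cm^2. Must straddle the
#'   transition.
#' @param tol Bisection tolerance on I_app.
#' @param K_window,min_step Passed to the branch continuation.
#' @return A one-row tibble: `type = "SNL"`, `I_app`, `K_out` (fold K at
#'   the SNL), `diagnostic` (final HOM-SN separation just above).
#' @export
locate_snl <- function(p, I_window = c(0.1, 0.6), tol = 0.02,
                       K_window = c(3, 16), min_step = 1e-4) {
  is_snic <- function(ia) {
    term <- branch_termination(p, ia, K_window, min_step)
    if (!term$type %in% c("HOM", "SNIC"))
      stop("branch termination at I_app = ", ia, " is ", term$type,
           "; shrink the window")
    term$type == "SNIC"
  }
  lo <- I_window[1]; hi <- I_window[2]
  s_lo <- is_snic(lo); s_hi <- is_snic(hi)
  if (s_lo == s_hi)
    stop("no SNIC/HOM transition inside the I_app window")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is_snic(mid) == s_lo) lo <- mid else hi <- mid
  }
  ia <- (lo + hi) / 2
  tibble::tibble(type = "SNL", I_app = ia,
                 K_out = locate_fold_K(p, K_window, I_app = ia),
                 diagnostic = hi - lo)
}

#' Locate the fold of the homoclinic curve (HOM "inflection" point)
#'
#' Bisects in applied current on whether an upward potassium sweep of the
#' fast subsystem still meets a homoclinic (below the point) or instead
#' terminates in a fold of limit cycles (beyond it). This is the maximal
#' I_app reached by the HOM curve in the (K_out, I_app) plane, the upper
#' bound of the wedge in which bursting is possible.
#'
#' @inheritParams locate_snl
#' @return A one-row tibble: `type = "HOM_INFLECTION"`, `I_app`, `K_out`
#'   (homoclinic K just below the point), `diagnostic` (bracket width).
#' @export
locate_hom_inflection <- function(p, I_window = c(0.5, 0.9), tol = 0.02,
                                  K_window = c(3, 16), min_step = 1e-4) {
  last_hom <- NA_real_
  is_hom <- function(ia) {
    term <- branch_termination(p, ia, K_window, min_step)
    if (term$type %in% c("HOM", "SNIC")) {
      last_hom <<- term$K_end
      TRUE
    } else FALSE
  }
  lo <- I_window[1]; hi <- I_window[2]
  if (!is_hom(lo) || is_hom(hi))
    stop("I_app window must bracket the HOM-to-FLC transition")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is_hom(mid)) lo <- mid else hi <- mid
  }
  tibble::tibble(type = "HOM_INFLECTION", I_app = (lo + hi) / 2,
                 K_out = last_hom, diagnostic = hi - lo)
}
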