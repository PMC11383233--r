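# Limit cycles of the fast subsystem: single shooting on a Poincare section
# (upward crossing of V = section_V), Newton on (h, n, period), Floquet
# multipliers from a finite-difference monodromy matrix, with a long-time
# simulation fallback for the stable cycle.

# integrate the fast subsystem from y0 for tau ms, return end state
flow_fast <- function(y0, tau, K_out, p, dt = 0.005) {
  res <- rk4_cpp(as.numeric(y0), tau, dt, unclass(p), 0L, K_out, 10000000L, tau + 1)
  res$y_end
}

# crossing times of V = section upward, interpolated, plus interpolated h, n
section_crossings <- function(tr, section) {
  v <- tr$V
  up <- which(v[-length(v)] < section & v[-1] >= section)
  if (!length(up)) return(NULL)
  frac <- (section - v[up]) / (v[up + 1] - v[up])
  tibble::tibble(
    time = tr$t[up] + frac * (tr$t[up + 1] - tr$t[up]),
    h = tr$h[up] + frac * (tr$h[up + 1] - tr$h[up]),
    n = tr$n[up] + frac * (tr$n[up + 1] - tr$n[up])
  )
}

# simulation-based cycle estimate: settle onto the attractor, measure the
# period from section crossings
cycle_from_simulation <- function(p, K_out, I_app, section = -20,
                                  t_settle = 1200, t_measure = 2500,
                                  y0 = NULL, dt = 0.005) {
  p$I_app <- I_app
  if (is.null(y0)) y0 <- c(V = -20, h = h_inf(-60), n = n_inf(-60))
  tr <- integrate_system(p, y0 = y0, t_end = t_settle + t_measure, dt = dt,
                         system = "fast", K_fix = K_out, thin = 2L,
                         transient = t_settle)
  cr <- section_crossings(tr, section)
  if (is.null(cr) || nrow(cr) < 3) return(NULL)
  per <- diff(cr$time)
  k <- min(length(per), 5)
  list(tau = mean(tail(per, k)), h = tail(cr$h, 1), n = tail(cr$n, 1),
       y_end = unlist(tr[nrow(tr), c("V", "h", "n")]))
}

# First return to the section V = section (upward) from a state on the
# section: integrates up to t_max, brackets the crossing on the coarse grid,
# then refines it by micro-stepping from the bracketing sample. Returns the
# return time and the interpolated (h, n) at the crossing.
first_return <- function(y0, K_out, p, section, t_max, dt = 0.005) {
  res <- rk4_cpp(as.numeric(y0), t_max, dt, unclass(p), 0L, K_out, 1L, 0)
  V <- res$states[, 1]
  i <- which(V[-length(V)] < section & V[-1] >= section)
  if (!length(i)) return(NULL)
  i <- i[1]
  t0 <- res$times[i]
  y <- res$states[i, ]
  # refine within [t_i, t_i + dt] with fine steps
  dtf <- dt / 50
  fine <- rk4_cpp(y, dt + dtf, dtf, unclass(p), 0L, K_out, 1L, 0)
  Vf <- fine$states[, 1]
  j <- which(Vf[-length(Vf)] < section & Vf[-1] >= section)
  if (!length(j)) return(NULL)
  j <- j[1]
  frac <- (section - Vf[j]) / (Vf[j + 1] - Vf[j])
  list(tau = t0 + fine$times[j] + frac * dtf,
       h = fine$states[j, 2] + frac * (fine$states[j + 1, 2] - fine$states[j, 2]),
       n = fine$states[j, 3] + frac * (fine$states[j + 1, 3] - fine$states[j, 3]))
}

#' Limit cycle of the fast subsystem
#'
#' Finds a periodic orbit of the fast subsystem at frozen \[K+\]_out by
#' shooting on the Poincare return map: states are anchored on the section
#' (upward crossing of `section` mV) and Newton iterates on (h, n) until the
#' first-return map fixes them; the period is the return time. Floquet
#' multipliers are the eigenvalues of the monodromy matrix obtained by
#' integrating the variational system over one period; one multiplier of an
#' autonomous-system cycle is always 1 and is reported separately as
#' `trivial_multiplier`. If shooting fails and the cycle is
#' stable, a long-time simulation estimate is returned
#' (`method = "simulation"`).
#'
#' @param p A [wb_params()] object.
#' @param K_out Frozen extracellular potassium, mM.
#' @param I_app Applied current; defaults to `p$I_app`.
#' @param guess Optional warm start: list with `h`, `n`, `tau`.
#' @param section Poincare section voltage, mV.
#' @param dt Integration step, ms.
#' @param shoot_tol Newton tolerance on the weighted return residual.
#' @param keep_cycle If `TRUE` (default), one period sampled at `dt` is
#'   attached (used by the slow averaging).
#' @return A `wb_limit_cycle` list: `found`, `K_out`, `I_app`, `tau` (ms),
#'   `y_section`, `V_max`, `V_min`, `multipliers` (nontrivial),
#'   `trivial_multiplier`, `method`, `cycle` (tibble), `converged`.
#' @export
find_limit_cycle <- function(p, K_out, I_app = p$I_app, guess = NULL,
                             section = -20, dt = 0.005, shoot_tol = 1e-8,
                             keep_cycle = TRUE, max_newton = 20,
                             fallback_sim = TRUE) {
  p$I_app <- I_app
  not_found <- structure(list(found = FALSE, K_out = K_out, I_app = I_app),
                         class = "wb_limit_cycle")
  if (is.null(guess)) {
    est <- cycle_from_simulation(p, K_out, I_app, section, dt = dt)
    if (is.null(est)) return(not_found)
    guess <- est
  }
  x <- c(guess$h, guess$n)
  tau_est <- guess$tau
  ret <- function(x) {
    first_return(c(section, x[1], x[2]), K_out, p, section,
                 t_max = 3 * tau_est + 20, dt = dt)
  }
  resid <- function(x) {
    fr <- ret(x)
    if (is.null(fr)) return(NULL)
    tau_est <<- fr$tau
    c(fr$h - x[1], fr$n - x[2])
  }
  converged <- FALSE
  r <- resid(x)
  if (!is.null(r)) for (it in seq_len(max_newton)) {
    if (max(abs(r)) < shoot_tol) { converged <- TRUE; break }
    # Picard step first: the stable cycle's return map is contracting, so
    # x + r is an excellent update and needs no finite differences - which
    # matters close to a homoclinic, where FD perturbations can knock the
    # orbit off the branch entirely
    xp <- x + r
    if (all(xp > 0) && all(xp < 1)) {
      rp <- resid(xp)
      if (!is.null(rp) && max(abs(rp)) < 0.5 * max(abs(r))) {
        x <- xp; r <- rp
        next
      }
    }
    J <- matrix(0, 2, 2)
    eps <- c(1e-6, 1e-6)
    bad <- FALSE
    for (j in 1:2) {
      xp <- x; xp[j] <- xp[j] + eps[j]
      rp <- resid(xp)
      if (is.null(rp)) { bad <- TRUE; break }
      J[, j] <- (rp - r) / eps[j]
    }
    if (bad) break
    stp <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(stp)) break
    lam <- 1
    ok_step <- FALSE
    for (tries in 1:6) {
      xn <- x + lam * stp
      if (all(xn > 0) && all(xn < 1)) {
        rn <- resid(xn)
        if (!is.null(rn) && (max(abs(rn)) < max(abs(r)) || tries == 6)) {
          x <- xn; r <- rn; ok_step <- TRUE; break
        }
      }
      lam <- lam / 2
    }
    if (!ok_step) break
  }
  method <- "shooting"
  if (!converged) {
    if (!fallback_sim) return(not_found)
    est <- cycle_from_simulation(p, K_out, I_app, section, dt = dt)
    if (is.null(est)) return(not_found)
    x <- c(est$h, est$n)
    tau_est <- est$tau
    method <- "simulation"
  }
  y0 <- c(V = section, h = x[1], n = x[2])
  fr <- ret(x)
  if (is.null(fr)) return(not_found)
  tau <- fr$tau
  # monodromy from the variational (tangent) system over one period
  M <- rk4_variational_cpp(as.numeric(y0), tau, dt, unclass(p),
                           K_fix = K_out)$monodromy
  mult <- eigen(M, only.values = TRUE)$values
  triv <- which.min(abs(mult - 1))
  # sample one period; stride chosen to keep a few thousand samples even for
  # near-homoclinic periods
  thin_c <- max(1L, as.integer(floor(tau / dt / 4000)))
  trc <- integrate_system(p, y0 = y0, t_end = tau, dt = dt, system = "fast",
                          K_fix = K_out, thin = thin_c, transient = 0)
  V_max <- max(trc$V); V_min <- min(trc$V)
  cyc <- if (keep_cycle) trc else NULL
  structure(list(found = TRUE, K_out = K_out, I_app = I_app, tau = tau,
                 y_section = y0, V_max = V_max, V_min = V_min,
                 multipliers = mult[-triv], trivial_multiplier = mult[triv],
                 method = method, cycle = cyc, converged = converged),
            class = "wb_limit_cycle")
}

#' @export
print.wb_limit_cycle <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("<wb_limit_cycle> none found at K_out = %g, I_app = %g\n",
                x$K_out, x$I_app))
  } else {
    cat(sprintf("<wb_limit_cycle> K_out = %g, I_app = %g: period %.3f ms (%s)\n",
                x$K_out, x$I_app, x$tau, x$method))
    cat(sprintf("  V in [%.1f, %.1f] mV; nontrivial |multipliers| %s\n",
                x$V_min, x$V_max,
                paste(signif(Mod(x$multipliers), 3), collapse = ", ")))
  }
  invisible(x)
}

# Fit tau ~ a - b*log(K_hom - K) over the terminal points of a branch and
# return the extrapolated K_hom (homoclinic period divergence law).
fit_hom_K <- function(K, tau, n_fit = 8) {
  k <- length(K)
  use <- max(1, k - n_fit + 1):k
  K <- K[use]; tau <- tau[use]
  if (length(K) < 4) return(max(K) + 1e-6)
  obj <- function(Kh) {
    x <- log(Kh - K)
    f <- lm(tau ~ x)
    sum(f$residuals^2)
  }
  upper <- max(K) + max(1e-3, 2 * (max(K) - min(K)))
  opt <- optimize(obj, c(max(K) + 1e-9, upper), tol = 1e-12)
  opt$minimum
}

#' Continue the stable limit cycle of the fast subsystem in \[K+\]_out
#'
#' Continues the spiking limit cycle upward in extracellular potassium with
#' warm-started shooting and adaptive steps. The branch terminates either in
#' a homoclinic bifurcation (HOM) - detected by period divergence, with the
#' homoclinic K estimated from the logarithmic scaling law
#' tau = a - b log(K_hom - K) - or in a fold of limit cycles (FLC) -
#' detected when the cycle disappears at bounded period, the nontrivial
#' Floquet multiplier approaching +1. A HOM whose saddle coincides with the
#' saddle-node fold (within `snic_tol` in K) is classified SNIC.
#'
#' @param p A [wb_params()] object.
#' @param K_range K window to traverse (continuation runs upward), mM.
#' @param I_app Applied current; defaults to `p$I_app`.
#' @param step0 Initial K step, mM.
#' @param tau_cut Period (ms) above which the branch is declared numerically
#'   homoclinic.
#' @param snic_tol Margin (mM) for the SNIC test: the termination is a SNIC
#'   when the saddle-node fold lies at or above the last continued K minus
#'   this margin (at a SNIC the cycle dies on the fold itself; at a
#'   separate HOM the fold sits strictly inside the traversed window).
#' @param average Also compute the cycle-averaged d\[K+\]_out/dt of the
#'   reduced slow subsystem at every point (used by
#'   [assemble_hysteresis()]).
#' @param min_step Smallest K step before the branch is declared terminated,
#'   mM. Coarser values stop the near-homoclinic creep earlier, which is
#'   enough when only the termination type is needed.
#' @param max_evals Budget of shooting attempts before the continuation
#'   gives up and reports where it stopped.
#' @param dt Integration step, ms.
#' @return A `wb_lc_branch` tibble: `K_out`, `tau`, `V_max`, `V_min`,
#'   `mult_max` (largest nontrivial |multiplier|), `dKdt_avg` (when
#'   `average`), `method`; attributes `termination` (list: `type` in
#'   HOM/SNIC/FLC/window_end, `K_end`, `K_sn`, diagnostics) and `I_app`.
#' @export
continue_limit_cycles <- function(p, K_range, I_app = p$I_app, step0 = 0.05,
                                  tau_cut = 1000, snic_tol = 5e-3,
                                  average = TRUE, dt = 0.005,
                                  max_evals = 800, min_step = 1e-7) {
  p$I_app <- I_app
  # the cycle may only exist above some onset K (sheared SNIC at low K):
  # walk up from the window start until a cycle is found
  lc <- list(found = FALSE)
  for (K_start in seq(K_range[1], K_range[2], by = 0.5)) {
    lc <- find_limit_cycle(p, K_start, keep_cycle = average, dt = dt)
    if (lc$found) break
  }
  if (!lc$found)
    return(structure(tibble::tibble(), termination = list(type = "no_cycle"),
                     class = c("wb_lc_branch", "tbl_df", "tbl", "data.frame")))
  rows <- list()
  add_row <- function(lc) {
    dkdt <- if (average) averaged_kout_derivative(p, lc$K_out, cycle = lc) else NA_real_
    rows[[length(rows) + 1]] <<- tibble::tibble(
      K_out = lc$K_out, tau = lc$tau, V_max = lc$V_max, V_min = lc$V_min,
      mult_max = max(Mod(lc$multipliers)), dKdt_avg = dkdt,
      trivial_multiplier = Re(lc$trivial_multiplier), method = lc$method)
  }
  add_row(lc)
  K <- lc$K_out
  h <- step0
  guess <- list(h = lc$y_section[["h"]], n = lc$y_section[["n"]], tau = lc$tau)
  termination <- list(type = "window_end")
  evals <- 0
  while (evals < max_evals) {
    if (lc$tau > tau_cut) {
      termination <- list(type = "HOM")
      break
    }
    # contract steps as the period climbs toward the homoclinic
    if (lc$tau > 150 && length(rows) > 4) {
      Kh_est <- fit_hom_K(vapply(rows, `[[`, 0, "K_out"),
                          vapply(rows, `[[`, 0, "tau"))
      h <- min(h, max(min_step, 0.3 * (Kh_est - K)))
    }
    if (K + h > K_range[2]) {
      if (K >= K_range[2] - 1e-9) break
      h <- K_range[2] - K
    }
    evals <- evals + 1
    lcn <- find_limit_cycle(p, K + h, guess = guess, keep_cycle = average,
                            dt = dt, max_newton = 12, fallback_sim = FALSE)
    ok <- lcn$found && lcn$converged &&
      abs(lcn$tau - lc$tau) < max(0.75 * lc$tau, 30)
    if (!ok) {
      h <- h / 2
      if (h >= min_step) next
      # Step underflow: the branch has terminated just above K. Classify by
      # where the flow goes once the cycle is gone: a homoclinic hands the
      # state to the low-voltage rest node, a fold of limit cycles to the
      # depolarized upstate. (The period cannot be followed to arbitrarily
      # large values in double precision when the divergence constant is
      # small, so the settling target is the robust discriminator.) The
      # probe distance escalates until the cycle is really gone: step
      # underflow can occur slightly before the actual end of the branch.
      y_probe <- as.numeric(lc$y_section)
      termination <- list(type = "undetermined_end")
      for (dK_probe in c(10 * min_step, 1e-3, 5e-3, 0.02, 0.1)) {
        trp <- integrate_system(p, y0 = y_probe, t_end = 4000, dt = dt,
                                system = "fast", K_fix = K + dK_probe,
                                thin = 20L, transient = 0)
        v_tail <- tail(trp$V, 100)
        if (max(v_tail) - min(v_tail) >= 1) next # still spiking: go further
        termination <- list(
          type = if (mean(v_tail) > -45) "FLC" else "HOM")
        break
      }
      break
    }
    K <- K + h
    lc <- lcn
    add_row(lc)
    guess <- list(h = lc$y_section[["h"]], n = lc$y_section[["n"]], tau = lc$tau)
    h <- min(step0, h * 1.3)
  }
  br <- dplyr::bind_rows(rows)
  # terminal K estimate and SNIC refinement
  if (termination$type == "HOM") {
    termination$K_end <- if (nrow(br) >= 4) fit_hom_K(br$K_out, br$tau) else
      max(br$K_out)
    termination$tau_end <- max(br$tau)
    K_sn <- locate_fold_K(p, c(max(K_range[1], termination$K_end - 2),
                               termination$K_end + 2))
    termination$K_sn <- K_sn
    # SNIC: the cycle dies on the saddle-node itself, so the fold sits at
    # (or numerically above) the end of the cycle branch. At a genuine HOM
    # the fold lies strictly below the branch end, inside the bistable
    # window the branch traverses.
    if (is.finite(K_sn) && K_sn >= max(br$K_out) - snic_tol)
      termination$type <- "SNIC"
  } else if (termination$type == "FLC") {
    termination$K_end <- max(br$K_out) + h
    termination$mult_max_end <- br$mult_max[nrow(br)]
  } else {
    termination$K_end <- max(br$K_out)
  }
  structure(br, class = c("wb_lc_branch", class(tibble::tibble())),
            termination = termination, I_app = I_app)
}
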