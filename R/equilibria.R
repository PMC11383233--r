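# Equilibria of the 3-D fast subsystem (V, h, n) at frozen [K+]_out.
#
# At an equilibrium the gates sit on their steady-state curves, so the root
# problem reduces to a scalar current-balance equation in V; roots found on a
# fine grid are then polished by Newton on the full 3-D right-hand side.

# Scalar current balance F(V; K_out) with gates at steady state.
current_balance <- function(V, K_out, p) {
  ip <- if (isTRUE(p$electrogenic)) pump_current(K_out, p) else 0
  p$I_app - p$g_Na * h_inf(V) * m_inf(V)^3 * (V - p$E_Na) -
    p$g_K * n_inf(V)^4 * (V - reversal_EK(K_out, p)) -
    p$g_L * (V - p$E_L) - ip
}

# Numerical Jacobian of the fast right-hand side at a point, central
# differences with per-component steps.
fast_jacobian <- function(state, K_out, p, eps = c(1e-4, 1e-7, 1e-7)) {
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    up <- state; dn <- state
    up[j] <- up[j] + eps[j]; dn[j] <- dn[j] - eps[j]
    J[, j] <- (fast_rhs(up, K_out, p) - fast_rhs(dn, K_out, p)) / (2 * eps[j])
  }
  dimnames(J) <- list(c("V", "h", "n"), c("V", "h", "n"))
  J
}

classify_stability <- function(ev, tol = 1e-9) {
  re <- Re(ev)
  if (all(re < tol)) {
    if (any(abs(Im(ev)) > 1e-9)) "stable_focus" else "stable_node"
  } else if (all(abs(Im(ev[re > tol])) < 1e-9)) {
    "saddle"
  } else "unstable_focus"
}

# 3-D Newton polish of an equilibrium from a scalar-root seed.
polish_equilibrium <- function(V0, K_out, p, tol = 1e-12, max_iter = 30) {
  y <- c(V = V0, h = h_inf(V0), n = n_inf(V0))
  for (i in seq_len(max_iter)) {
    r <- fast_rhs(y, K_out, p)
    if (max(abs(r)) < tol) break
    J <- fast_jacobian(y, K_out, p)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    y <- y + step
  }
  y
}

#' Equilibria of the fast subsystem
#'
#' Finds all equilibria of the fast subsystem (V, h, n) at a frozen
#' extracellular potassium concentration. At an equilibrium the gates are on
#' their steady-state curves, so candidate roots of the scalar current
#' balance are located on a fine voltage grid (sign changes, resolved by
#' `uniroot`), polished by 3-D Newton, deduplicated, and classified by the
#' eigenvalues of the Jacobian.
#'
#' @param p A [wb_params()] object.
#' @param K_out Frozen extracellular potassium, mM.
#' @param I_app Applied current; defaults to `p$I_app`.
#' @param V_window Voltage window searched, mV.
#' @param dV Scan resolution, mV. Close saddle-node pairs are resolved down
#'   to roughly `dV` separation.
#' @return A `wb_equilibria` tibble: `K_out`, `I_app`, `V`, `h`, `n`,
#'   `stability`, `eig` (list of complex eigenvalue triples), `residual`
#'   (max |rhs|).
#' @export
find_equilibria <- function(p, K_out, I_app = p$I_app,
                            V_window = c(-90, 20), dV = 0.005) {
  p$I_app <- I_app
  Vg <- seq(V_window[1], V_window[2], by = dV)
  f <- current_balance(Vg, K_out, p)
  idx <- which(diff(sign(f)) != 0)
  roots <- vapply(idx, function(j)
    uniroot(current_balance, c(Vg[j], Vg[j + 1]), K_out = K_out, p = p,
            tol = 1e-13)$root, 0)
  if (length(roots) == 0)
    return(structure(tibble::tibble(K_out = numeric(), I_app = numeric(),
                                    V = numeric(), h = numeric(),
                                    n = numeric(), stability = character(),
                                    eig = list(), residual = numeric()),
                     class = c("wb_equilibria", class(tibble::tibble()))))
  pts <- lapply(roots, polish_equilibrium, K_out = K_out, p = p)
  # dedupe after polishing
  Vs <- vapply(pts, `[[`, 0, "V")
  keep <- !duplicated(round(Vs, 6))
  pts <- pts[keep]
  rows <- lapply(pts, function(y) {
    ev <- eigen(fast_jacobian(y, K_out, p), only.values = TRUE)$values
    tibble::tibble(K_out = K_out, I_app = p$I_app,
                   V = y[["V"]], h = y[["h"]], n = y[["n"]],
                   stability = classify_stability(ev), eig = list(ev),
                   residual = max(abs(fast_rhs(y, K_out, p))))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$V)
  structure(out, class = c("wb_equilibria", class(tibble::tibble())))
}

# Solve the scalar balance for K at fixed V near a seed (local branch
# parameterization by V, valid through folds in K).
solve_K_at_V <- function(V, K_seed, p, tol = 1e-12) {
  g <- function(K) current_balance(V, K, p)
  K <- K_seed
  for (i in 1:50) {
    gv <- g(K)
    dg <- (g(K + 1e-7) - g(K - 1e-7)) / 2e-7
    if (abs(dg) < 1e-14) return(NA_real_)
    Knew <- K - gv / dg
    if (Knew <= 0) Knew <- K / 2
    if (abs(Knew - K) < tol) return(Knew)
    K <- Knew
  }
  NA_real_
}

#' Continue equilibrium branches of the fast subsystem in \[K+\]_out
#'
#' Pseudo-arclength continuation of the scalar current-balance curve in the
#' (V, K_out) plane at fixed applied current. Saddle-node (fold) points are
#' detected by sign changes of the K-component of the curve tangent and
#' refined by extremizing K along the V-parameterized branch; Hopf points by
#' real-part sign changes of the complex eigenvalue pair of the 3-D
#' Jacobian, refined by bisection in V. Distinct curves (the node-saddle
#' fold curve and the upper focus branch) are continued from every
#' equilibrium found at the ends of the window and deduplicated.
#'
#' @param p A [wb_params()] object.
#' @param K_range Length-2 window of extracellular potassium, mM.
#' @param I_app Applied current; defaults to `p$I_app`.
#' @param step Initial arclength step (weighted units; V is weighted by 0.1
#'   relative to K).
#' @param max_points Per-curve cap on continuation points.
#' @return A `wb_eq_branch` tibble: `curve`, `K_out`, `V`, `h`, `n`,
#'   `stability`, `re_max` (largest real part), with attribute
#'   `bifurcations`: tibble (`type` in SN/HOPF, `K_out`, `V`, `I_app`,
#'   `diagnostic`).
#' @export
continue_equilibria <- function(p, K_range, I_app = p$I_app, step = 0.04,
                                max_points = 4000) {
  p$I_app <- I_app
  wV <- 0.1 # weight of V relative to K in arclength
  Fu <- function(u) current_balance(u[1], u[2], p)
  grad <- function(u) {
    c(dV = (Fu(u + c(1e-6, 0)) - Fu(u - c(1e-6, 0))) / 2e-6,
      dK = (Fu(u + c(0, 1e-7)) - Fu(u - c(0, 1e-7))) / 2e-7)
  }
  tangent <- function(u) {
    g <- grad(u) # gradient in weighted coords is (F_V / wV, F_K)
    t <- c(-g[2], g[1] / wV)
    t / sqrt(sum(t^2))
  }
  run_curve <- function(u0, dir) {
    tg <- tangent(u0) * dir
    pts <- matrix(NA_real_, max_points, 2)
    pts[1, ] <- u0
    h <- step
    u <- u0
    np <- 1
    while (np < max_points) {
      pred <- u + h * tg * c(1 / wV, 1)
      # corrector: F = 0 and weighted tangent condition
      un <- pred
      ok <- FALSE
      for (it in 1:25) {
        r1 <- Fu(un)
        r2 <- sum(tg * ((un - u) * c(wV, 1))) - h
        if (abs(r1) < 1e-11 && abs(r2) < 1e-11) { ok <- TRUE; break }
        g <- grad(un)
        J <- rbind(g, tg * c(wV, 1))
        st <- tryCatch(solve(J, -c(r1, r2)), error = function(e) NULL)
        if (is.null(st)) break
        un <- un + st
      }
      if (!ok || !is.finite(un[2]) || un[2] <= 0) {
        h <- h / 2
        if (h < 1e-7) break
        next
      }
      tg_new <- tangent(un)
      if (sum(tg_new * tg) < 0) tg_new <- -tg_new
      tg <- tg_new
      u <- un
      np <- np + 1
      pts[np, ] <- u
      h <- min(step, h * 1.5)
      if (u[2] < K_range[1] - 1e-9 || u[2] > K_range[2] + 1e-9) break
      if (u[1] < -100 || u[1] > 40) break
    }
    pts[seq_len(np), , drop = FALSE]
  }

  seeds <- dplyr::bind_rows(
    find_equilibria(p, K_range[2]),
    find_equilibria(p, K_range[1])
  )
  curves <- list()
  for (i in seq_len(nrow(seeds))) {
    u0 <- c(seeds$V[i], seeds$K_out[i])
    # skip seeds already covered by an existing curve
    covered <- any(vapply(curves, function(cv) {
      d <- sqrt(((cv[, 1] - u0[1]) * wV)^2 + (cv[, 2] - u0[2])^2)
      min(d) < 5 * step
    }, TRUE))
    if (covered) next
    dir0 <- if (abs(seeds$K_out[i] - K_range[2]) < abs(seeds$K_out[i] - K_range[1]))
      -sign(tangent(u0)[2] + 1e-15) else sign(tangent(u0)[2] + 1e-15)
    if (dir0 == 0) dir0 <- 1
    curves[[length(curves) + 1]] <- run_curve(u0, dir0)
  }

  rows <- list(); bifs <- list()
  for (ci in seq_along(curves)) {
    cv <- curves[[ci]]
    eqs <- lapply(seq_len(nrow(cv)), function(r) {
      y <- polish_equilibrium(cv[r, 1], cv[r, 2], p)
      ev <- eigen(fast_jacobian(y, cv[r, 2], p), only.values = TRUE)$values
      tibble::tibble(curve = ci, K_out = cv[r, 2], V = y[["V"]],
                     h = y[["h"]], n = y[["n"]],
                     stability = classify_stability(ev),
                     re_max = max(Re(ev)), eig = list(ev))
    })
    br <- dplyr::bind_rows(eqs)
    rows[[ci]] <- br
    # fold (SN): extremum of K along the curve
    dK <- diff(br$K_out)
    folds <- which(dK[-1] * dK[-length(dK)] < 0) + 1
    for (fi in folds) {
      mx <- br$K_out[fi] > br$K_out[fi - 1] # K increasing into the fold
      opt <- optimize(function(V) {
        K <- solve_K_at_V(V, br$K_out[fi], p)
        if (is.na(K)) (if (mx) -Inf else Inf) else K
      }, interval = sort(br$V[c(fi - 1, fi + 1)]), maximum = mx, tol = 1e-10)
      Vsn <- if (mx) opt$maximum else opt$minimum
      Ksn <- solve_K_at_V(Vsn, br$K_out[fi], p)
      ysn <- polish_equilibrium(Vsn, Ksn, p)
      ev <- eigen(fast_jacobian(ysn, Ksn, p), only.values = TRUE)$values
      bifs[[length(bifs) + 1]] <- tibble::tibble(
        type = "SN", K_out = Ksn, V = ysn[["V"]], I_app = p$I_app,
        diagnostic = min(abs(Re(ev))))
    }
    # Hopf: sign change of the real part of the complex pair
    cplx_re <- vapply(br$eig, function(ev) {
      im <- abs(Im(ev)) > 1e-9
      if (any(im)) max(Re(ev[im])) else NA_real_
    }, 0)
    for (r in seq_len(nrow(br) - 1)) {
      a <- cplx_re[r]; b <- cplx_re[r + 1]
      if (is.na(a) || is.na(b) || a * b >= 0) next
      g <- function(V) {
        K <- solve_K_at_V(V, br$K_out[r], p)
        y <- polish_equilibrium(V, K, p)
        ev <- eigen(fast_jacobian(y, K, p), only.values = TRUE)$values
        im <- abs(Im(ev)) > 1e-9
        if (!any(im)) return(NA_real_)
        max(Re(ev[im]))
      }
      Vh <- tryCatch(uniroot(g, sort(c(br$V[r], br$V[r + 1])), tol = 1e-10)$root,
                     error = function(e) NA_real_)
      if (is.na(Vh)) next
      Kh <- solve_K_at_V(Vh, br$K_out[r], p)
      bifs[[length(bifs) + 1]] <- tibble::tibble(
        type = "HOPF", K_out = Kh, V = Vh, I_app = p$I_app,
        diagnostic = abs(g(Vh)))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$eig <- NULL
  bif_tbl <- if (length(bifs)) dplyr::distinct(
    dplyr::bind_rows(bifs), round2 = round(.data$K_out, 6),
    round3 = round(.data$V, 4), .keep_all = TRUE)[, 1:5] else
      tibble::tibble(type = character(), K_out = numeric(), V = numeric(),
                     I_app = numeric(), diagnostic = numeric())
  structure(out, class = c("wb_eq_branch", class(tibble::tibble())),
            bifurcations = bif_tbl, I_app = p$I_app)
}

#' Saddle-node location of the fast subsystem by fold solving
#'
#' Direct locator for the saddle-node bifurcation in \[K+\]_out at fixed
#' applied current: brackets the change in equilibrium count on a coarse K
#' grid, then extremizes K along the V-parameterized branch to the fold.
#'
#' @inheritParams continue_equilibria
#' @param K_window Search window, mM.
#' @return The fold `K_out` (mM), or `NA` if no fold is present in the
#'   window.
#' @export
locate_fold_K <- function(p, K_window = c(3, 20), I_app = p$I_app) {
  p$I_app <- I_app
  counts <- function(K) nrow(find_equilibria(p, K, dV = 0.01,
                                             V_window = c(-90, -20)))
  Kg <- seq(K_window[1], K_window[2], length.out = 35)
  nc <- vapply(Kg, counts, 0)
  j <- which(diff(nc >= 2) != 0)
  if (!length(j)) return(NA_real_)
  lo <- Kg[j[1]]; hi <- Kg[j[1] + 1]
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if ((counts(mid) >= 2) == (nc[j[1] + 1] >= 2)) hi <- mid else lo <- mid
    if (hi - lo < 1e-4) break
  }
  # polish: extremize K over V along the branch through the fold
  eq <- find_equilibria(p, if (nc[j[1] + 1] >= 2) hi else lo, dV = 0.002,
                        V_window = c(-90, -20))
  eq <- eq[eq$stability %in% c("stable_node", "saddle"), ]
  if (nrow(eq) < 2) return((lo + hi) / 2)
  Kref <- eq$K_out[1]
  opt <- optimize(function(V) {
    K <- solve_K_at_V(V, Kref, p)
    if (is.na(K)) Inf else K
  }, interval = range(eq$V), tol = 1e-11)
  opt$objective
}
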