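#' Detect spikes in a voltage trajectory
#'
#' A spike is an upward crossing of `threshold` by the membrane potential,
#' with crossing times linearly interpolated between samples and successive
#' spikes separated by at least `refractory`.
#'
#' @param traj A `wb_trajectory` (or any data frame with columns `t`, `V`).
#' @param threshold Spike threshold, mV. Spikes of this neuron model
#'   overshoot 0 mV robustly, so 0 mV is the default.
#' @param refractory Minimal separation between detected spikes, ms.
#' @return A `wb_spikes` object: tibble with column `time` (ms); attributes
#'   `threshold` and `refractory`. Zero rows when nothing crosses.
#' @export
detect_spikes <- function(traj, threshold = 0, refractory = 2) {
  stopifnot(all(c("t", "V") %in% names(traj)))
  v <- traj$V; tt <- traj$t
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  if (length(up)) {
    frac <- (threshold - v[up]) / (v[up + 1] - v[up])
    times <- tt[up] + frac * (tt[up + 1] - tt[up])
    keep <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= refractory) {
        keep[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[keep]
  } else times <- numeric()
  structure(tibble::tibble(time = times),
            class = c("wb_spikes", class(tibble::tibble())),
            threshold = threshold, refractory = refractory)
}

# Two-class split of the inter-spike intervals at the largest gap in log-ISI.
# Bimodal (bursting-like) when the ISIs just across the gap differ by more
# than `ratio_min` and both classes have at least two members.
split_isi <- function(isi, ratio_min = 3) {
  s <- sort(isi)
  n <- length(s)
  if (n < 4) return(list(bimodal = FALSE, cut = Inf))
  gaps <- diff(log(s))
  i <- which.max(gaps)
  ratio <- s[i + 1] / s[i]
  bimodal <- ratio > ratio_min && i >= 2 && (n - i) >= 2
  list(bimodal = bimodal, cut = sqrt(s[i] * s[i + 1]), ratio = ratio)
}

# ABAB alternation of a sequence: lag-2 subsequences each nearly constant
# while the two interleaved levels differ clearly.
is_period_doubled <- function(x, rel_within = 0.05, rel_between = 0.05) {
  if (length(x) < 6) return(FALSE)
  odd <- x[seq(1, length(x), by = 2)]
  even <- x[seq(2, length(x), by = 2)]
  spread <- function(v) (max(v) - min(v)) / median(v)
  spread(odd) < rel_within && spread(even) < rel_within &&
    abs(median(odd) - median(even)) / median(x) > rel_between
}

#' Burst statistics of a spike train
#'
#' Splits the inter-spike intervals (ISIs) into intra-burst and inter-burst
#' classes at the largest gap of the log-ISI distribution (bimodality
#' criterion), counts spikes per burst between inter-burst gaps, measures
#' the burst-cycle period as the interval between first spikes of successive
#' bursts, and records the extracellular potassium extrema over complete
#' cycles. A period-doubled flag is set when the cycle (or ISI) sequence
#' alternates between two values.
#'
#' @param spikes A [detect_spikes()] result.
#' @param traj The trajectory the spikes came from.
#' @param isi_ratio_min Minimal ISI ratio across the log-gap for bimodality.
#' @param tail_window Terminal window (ms) over which potassium extrema are
#'   reported for settled, non-bursting regimes.
#' @return A one-row tibble: `regime`, `n_spikes`, `spikes_per_burst`
#'   (modal count over complete bursts), `spikes_per_burst_all` (list
#'   column), `interburst_period` (ms), `intra_burst_isi_mean` (ms),
#'   `K_out_min`, `K_out_max` (mM), `period_doubled`.
#' @export
summarize_bursts <- function(spikes, traj, isi_ratio_min = 3,
                             tail_window = 2000) {
  K <- if ("K_out" %in% names(traj)) traj$K_out else rep(NA_real_, nrow(traj))
  n_sp <- nrow(spikes)
  # settled (non-bursting) regimes report potassium extrema over the tail
  # window only, so the initial approach to the attractor does not inflate
  # the oscillation range
  tail_idx <- traj$t >= max(traj$t) - tail_window
  base <- tibble::tibble(
    regime = classify_regime(traj, spikes),
    n_spikes = n_sp, spikes_per_burst = NA_integer_,
    spikes_per_burst_all = list(integer()),
    interburst_period = NA_real_, intra_burst_isi_mean = NA_real_,
    K_out_min = suppressWarnings(min(K[tail_idx])),
    K_out_max = suppressWarnings(max(K[tail_idx])),
    period_doubled = FALSE
  )
  if (n_sp < 2) return(base)
  isi <- diff(spikes$time)
  sp <- split_isi(isi, ratio_min = isi_ratio_min)
  if (!sp$bimodal) {
    base$intra_burst_isi_mean <- mean(isi)
    base$period_doubled <- is_period_doubled(isi)
    return(base)
  }
  inter <- which(isi > sp$cut)
  # bursts delimited by inter-burst gaps; first and last may be truncated by
  # the analysis window, so counts come from interior bursts only
  starts <- c(1, inter + 1)
  ends <- c(inter, n_sp)
  counts <- ends - starts + 1
  complete <- if (length(starts) > 2) counts[-c(1, length(counts))] else counts
  first_spikes <- spikes$time[starts[-1]]
  cyc <- diff(first_spikes)
  intra <- isi[isi <= sp$cut]
  base$spikes_per_burst <- as.integer(stat_mode(complete))
  base$spikes_per_burst_all <- list(as.integer(complete))
  base$interburst_period <- if (length(cyc)) mean(cyc) else NA_real_
  base$intra_burst_isi_mean <- mean(intra)
  if (length(first_spikes) >= 2 && all(is.finite(K))) {
    win <- traj$t >= first_spikes[1] & traj$t <= first_spikes[length(first_spikes)]
    base$K_out_min <- min(K[win]); base$K_out_max <- max(K[win])
  }
  base$period_doubled <- if (length(cyc) >= 6) is_period_doubled(cyc) else FALSE
  base
}

stat_mode <- function(x) {
  ux <- unique(x)
  ux[which.max(tabulate(match(x, ux)))]
}

#' Classify the dynamical regime of a simulated trajectory
#'
#' Four regimes: `rest` (no spikes, V settled below `rest_ceiling`),
#' `depolarization_block` (no spikes over the tail window while V stays
#' above `block_floor`), `tonic` (spiking with unimodal ISI distribution)
#' and `bursting` (spiking with bimodal ISI distribution). Trajectories that
#' fit none of these (still transient) are labelled `undetermined` rather
#' than silently guessed.
#'
#' @param traj A post-transient `wb_trajectory`.
#' @param spikes Optional [detect_spikes()] result (recomputed if missing).
#' @param rest_ceiling Voltage ceiling for rest, mV.
#' @param block_floor Voltage floor for depolarization block, mV.
#' @param tail_window Length of the terminal window inspected for silence,
#'   ms.
#' @param isi_ratio_min Bimodality threshold passed to the ISI split.
#' @return One of `"rest"`, `"tonic"`, `"bursting"`,
#'   `"depolarization_block"`, `"undetermined"`.
#' @export
classify_regime <- function(traj, spikes = NULL, rest_ceiling = -60,
                            block_floor = -50, tail_window = 2000,
                            isi_ratio_min = 3) {
  if (is.null(spikes)) spikes <- detect_spikes(traj)
  t_hi <- max(traj$t)
  tail_idx <- traj$t >= t_hi - tail_window
  v_tail <- traj$V[tail_idx]
  tail_spikes <- spikes$time[spikes$time >= t_hi - tail_window]
  if (length(tail_spikes) == 0) {
    if (max(v_tail) < rest_ceiling) return("rest")
    if (min(v_tail) > block_floor) return("depolarization_block")
    return("undetermined")
  }
  if (nrow(spikes) < 4) return("undetermined")
  sp <- split_isi(diff(spikes$time), ratio_min = isi_ratio_min)
  if (sp$bimodal) "bursting" else "tonic"
}

#' Locate a spike-adding transition by bisection
#'
#' Finds the parameter value at which the number of spikes per burst switches
#' between `counts[1]` and `counts[2]` (e.g. the 11-to-12 spike-adding
#' transition as the pump density I_max varies). Each evaluation runs a fresh
#' transient-discarded simulation of the complete system.
#'
#' @param p Base [wb_params()] object.
#' @param vary Name of the parameter to bisect on (e.g. `"I_max"`).
#' @param bracket Length-2 numeric bracket for the parameter.
#' @param counts The two adjacent spike counts expected at the bracket ends.
#' @param tol Bracket width at which bisection stops.
#' @param t_end,transient,dt Simulation settings per evaluation.
#' @param count_fn Evaluation function mapping a parameter value to a spike
#'   count. The default runs a fresh transient-discarded simulation; a
#'   custom function allows bisection on any integer-valued response.
#' @return A list: `value` (bracket midpoint at convergence), `bracket`,
#'   `evaluations` (tibble of parameter values and spike counts).
#' @export
locate_spike_count_transition <- function(p, vary = "I_max",
                                          bracket, counts = c(11L, 12L),
                                          tol = 1e-4, t_end = 12000,
                                          transient = 2000, dt = 0.005,
                                          count_fn = NULL) {
  count_at <- if (!is.null(count_fn)) count_fn else function(val) {
    pv <- p; pv[[vary]] <- val
    sim <- simulate_neuron(pv, t_end = t_end, transient = transient, dt = dt)
    if (sim$regime != "bursting")
      stop("regime at ", vary, " = ", val, " is ", sim$regime,
           ", not bursting")
    sim$summary$spikes_per_burst
  }
  k <- min(counts)
  lo <- bracket[1]; hi <- bracket[2]
  c_lo <- count_at(lo); c_hi <- count_at(hi)
  if (c_lo == c_hi)
    stop("same spike count (", c_lo, ") at both bracket ends")
  # side of the (k, k+1) divide; brackets wider than the two adjacent
  # counts are allowed, the bisection then homes in on the k/k+1 switch
  side <- function(cnt) cnt >= k + 1
  if (side(c_lo) == side(c_hi))
    stop("bracket counts (", c_lo, ", ", c_hi, ") do not straddle the ",
         k, "/", k + 1, " transition")
  evals <- tibble::tibble(value = c(lo, hi), count = c(c_lo, c_hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    c_mid <- count_at(mid)
    evals <- dplyr::bind_rows(evals, tibble::tibble(value = mid, count = c_mid))
    if (side(c_mid) == side(c_lo)) lo <- mid else hi <- mid
  }
  list(value = (lo + hi) / 2, bracket = c(lo, hi),
       evaluations = dplyr::arrange(evals, .data$value))
}
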