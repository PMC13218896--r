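#' Agency input schedule
#'
#' A piecewise-constant schedule mapping simulation time to the scalar
#' agency level \eqn{A \in [0, 1]} that scales the ventral-subiculum drive.
#'
#' @param levels Agency level(s). A single value gives a constant schedule.
#' @param times Onset times (ms) for each level; must start at 0 and be
#'   strictly increasing. Each level holds from its onset to the next.
#' @return An `agency_input` object.
#' @examples
#' agency_input(0.35)                       # constant control level
#' agency_input(c(0.35, 0.85), c(0, 5000))  # step up at 5 s
#' @export
agency_input <- function(levels, times = 0) {
  stopifnot(length(levels) == length(times), times[1] == 0)
  if (any(levels < 0 | levels > 1)) stop("agency levels must lie in [0, 1]")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(levels = as.numeric(levels), times = as.numeric(times)),
            class = "agency_input")
}

# evaluate an agency schedule on a per-step grid (step midpoints)
agency_at <- function(agency, t_ms) {
  idx <- findInterval(t_ms, agency$times)
  agency$levels[pmax(idx, 1L)]
}

#' Reward-prediction-error event
#'
#' A transient RPE of magnitude `delta` (obtained minus expected reward,
#' scaled to \eqn{[-1, 1]}). Positive RPEs drive the excitatory PPTN input
#' to the VTA; negative RPEs drive the inhibitory RMTN input.
#'
#' @param onset Event onset, ms.
#' @param delta RPE in \eqn{[-1, 1]}.
#' @param duration Event duration, ms (default 200).
#' @return An `rpe_event` object.
#' @export
rpe_event <- function(onset, delta, duration = 200) {
  stopifnot(onset >= 0, duration > 0)
  if (abs(delta) > 1) stop("delta must lie in [-1, 1]")
  structure(list(onset = onset, delta = delta, duration = duration),
            class = "rpe_event")
}

#' Network configuration
#'
#' Fully determines a circuit simulation: population sizes and neuron
#' models, projection weights, drive encodings, integration settings, and
#' the wiring seed. The defaults are calibrated so that at the control
#' agency level (`A_control = 0.35`) about half of the VTA DA neurons are
#' spontaneously active, with the ventral pallidum near its 7 Hz tonic
#' rate and the accumbens MSNs nearly silent.
#'
#' @param n_nacc,n_vp,n_da Population sizes.
#' @param msn,vp,da Neuron parameter sets for the three populations.
#' @param connection_probability Bernoulli wiring probability for the
#'   NAcc->VP and VP->VTA projections.
#' @param vsub_afferents Number of vSub afferents converging on each MSN.
#' @param vsub_rate_max Firing rate of one vSub afferent at A = 1, Hz.
#' @param w_vsub vSub synaptic weight, pA per afferent spike.
#' @param w_nacc_vp NAcc->VP inhibitory weight (pA-equivalents per spike).
#' @param vp_inh_max Saturation ceiling on the total NAcc->VP inhibitory
#'   current per VP neuron (receptor saturation); keeps disinhibition
#'   graded at high agency instead of silencing the pallidum outright.
#' @param w_vp_da Median VP->VTA inhibitory weight for the sparsely
#'   innervated DA group.
#' @param vp_da_sdlog Log-normal spread (sdlog) of per-neuron VP->VTA
#'   weights within each innervation group.
#' @param da_deep_fraction Fraction of DA neurons receiving dense VP
#'   innervation; these are the neurons held silent by pallidal tone and
#'   recruitable by disinhibition but not by moderate excitatory drive.
#' @param da_deep_ratio Weight ratio of the densely innervated group to
#'   the sparse group.
#' @param tau_exc,tau_inh Excitatory / inhibitory synaptic decay, ms.
#' @param pptn_rate_max PPTN drive rate per DA neuron at |RPE| = 1, Hz.
#' @param rmtn_rate_max RMTN drive rate per DA neuron at |RPE| = 1, Hz.
#' @param w_pptn,w_rmtn Drive event weights for transient RPE events
#'   (pA-equivalents): few large kicks that burst active pacemakers but
#'   cannot bridge the hyperpolarization of silenced neurons.
#' @param w_pptn_tonic,w_rmtn_tonic Drive weights for sustained
#'   (activation-protocol) PPTN/RMTN input: smaller kicks mimicking a
#'   steady depolarizing drive.
#' @param aversive_fraction Fraction of DA neurons that respond to the
#'   aversive (RMTN) channel with excitation; the paper-cited range is
#'   3--14 percent.
#' @param aversive_gain Gain on the RMTN drive for the aversive subset.
#' @param vsub_ou_tau,vsub_ou_sd Time constant (ms) and stationary SD of
#'   the slow Ornstein-Uhlenbeck modulation of each MSN's vSub drive rate
#'   (correlated afferent fluctuations). This produces the up-/down-state
#'   dynamics of accumbens MSNs and a graded agency -> NAcc rate mapping.
#' @param msn_noise Fast background current-noise intensity on the MSNs.
#' @param vp_noise,da_noise Membrane current-noise intensities.
#' @param A_control,A_high Default control / high agency levels.
#' @param dt Integration step, ms.
#' @param duration Simulated time, ms.
#' @param seed Wiring seed.
#' @return A `network_config` object.
#' @export
network_config <- function(n_nacc = 100, n_vp = 100, n_da = 100,
                           msn = izhikevich_params(),
                           vp = qif_preset("vp"), da = qif_preset("da"),
                           connection_probability = 0.25,
                           vsub_afferents = 50, vsub_rate_max = 40,
                           w_vsub = 40, w_nacc_vp = 0.22, vp_inh_max = 0.47,
                           w_vp_da = 0.12, vp_da_sdlog = 0.45,
                           da_deep_fraction = 0.5, da_deep_ratio = 12,
                           tau_exc = 6, tau_inh = 12,
                           pptn_rate_max = 30, rmtn_rate_max = 30,
                           w_pptn = 12, w_rmtn = 12,
                           w_pptn_tonic = 5, w_rmtn_tonic = 5,
                           aversive_fraction = 0.08, aversive_gain = 0.3,
                           vsub_ou_tau = 200, vsub_ou_sd = 0.8,
                           msn_noise = 0, vp_noise = 0.3, da_noise = 0.3,
                           A_control = 0.35, A_high = 0.85,
                           dt = 0.5, duration = 12000, seed = 1L) {
  stopifnot(n_nacc >= 1, n_vp >= 1, n_da >= 1,
            connection_probability >= 0, connection_probability <= 1,
            aversive_fraction >= 0, aversive_fraction <= 1,
            dt > 0, duration > 0)
  structure(list(n_nacc = n_nacc, n_vp = n_vp, n_da = n_da, msn = msn,
                 vp = vp, da = da,
                 connection_probability = connection_probability,
                 vsub_afferents = vsub_afferents,
                 vsub_rate_max = vsub_rate_max, w_vsub = w_vsub,
                 w_nacc_vp = w_nacc_vp, vp_inh_max = vp_inh_max,
                 w_vp_da = w_vp_da,
                 vp_da_sdlog = vp_da_sdlog,
                 da_deep_fraction = da_deep_fraction,
                 da_deep_ratio = da_deep_ratio, tau_exc = tau_exc,
                 tau_inh = tau_inh, pptn_rate_max = pptn_rate_max,
                 rmtn_rate_max = rmtn_rate_max, w_pptn = w_pptn,
                 w_rmtn = w_rmtn, w_pptn_tonic = w_pptn_tonic,
                 w_rmtn_tonic = w_rmtn_tonic,
                 aversive_fraction = aversive_fraction,
                 aversive_gain = aversive_gain,
                 vsub_ou_tau = vsub_ou_tau, vsub_ou_sd = vsub_ou_sd,
                 msn_noise = msn_noise,
                 vp_noise = vp_noise,
                 da_noise = da_noise, A_control = A_control,
                 A_high = A_high, dt = dt, duration = duration,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Build the disinhibition circuit
#'
#' Draws the Bernoulli wiring of the NAcc->VP and VP->VTA projections
#' (log-normal VP->VTA weights), assigns the aversive-responding DA
#' subset, and returns a network object ready for [run_simulation()].
#' Wiring is deterministic given the seed.
#'
#' @param config A [network_config()].
#' @param seed Wiring seed; defaults to `config$seed`.
#' @return An `adds_network` object.
#' @export
build_network <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "network_config"))
  set.seed(seed)
  p <- config$connection_probability
  W_vp_nacc <- matrix(rbinom(config$n_vp * config$n_nacc, 1, p) *
                        config$w_nacc_vp,
                      config$n_vp, config$n_nacc)
  conn <- matrix(rbinom(config$n_da * config$n_vp, 1, p),
                 config$n_da, config$n_vp)
  deep <- rbinom(config$n_da, 1, config$da_deep_fraction)
  per_neuron <- config$w_vp_da * config$da_deep_ratio^deep *
    exp(rnorm(config$n_da, 0, config$vp_da_sdlog))
  W_da_vp <- conn * matrix(per_neuron, config$n_da, config$n_vp)
  n_av <- round(config$aversive_fraction * config$n_da)
  aversive <- integer(config$n_da)
  if (n_av > 0) aversive[sample.int(config$n_da, n_av)] <- 1L
  structure(list(config = config, seed = as.integer(seed),
                 W_vp_nacc = W_vp_nacc, W_da_vp = W_da_vp,
                 deep = deep, aversive = aversive),
            class = "adds_network")
}

#' @export
print.adds_network <- function(x, ...) {
  cfg <- x$config
  cat("ADDS disinhibition circuit\n")
  cat(sprintf("  populations: NAcc %d MSN, VP %d QIF, VTA_DA %d QIF (%d aversive-responding)\n",
              cfg$n_nacc, cfg$n_vp, cfg$n_da, sum(x$aversive)))
  cat(sprintf("  wiring: Bernoulli p=%.2f, seed %d\n",
              cfg$connection_probability, x$seed))
  cat(sprintf("  drives: vSub %d afferents x %g Hz x A; PPTN/RMTN up to %g/%g Hz\n",
              cfg$vsub_afferents, cfg$vsub_rate_max, cfg$pptn_rate_max,
              cfg$rmtn_rate_max))
  invisible(x)
}

#' Run a circuit simulation
#'
#' Integrates the full network: the agency schedule sets the vSub Poisson
#' drive rate (`vsub_afferents * vsub_rate_max * A` per MSN), NAcc MSNs
#' inhibit the VP, the VP inhibits the VTA DA pacemakers, and each RPE
#' event adds a PPTN (positive RPE) or RMTN (negative RPE) Poisson drive
#' of rate `rate_max * |delta|` per DA neuron for the event duration.
#'
#' @param network An [build_network()] result.
#' @param agency An [agency_input()]; defaults to the control level.
#' @param rpe_events List of [rpe_event()]s; must be non-overlapping and
#'   fall inside the simulation.
#' @param seed Run seed governing drive realizations, noise, and initial
#'   membrane phases. Identical seed and network give an identical
#'   recording.
#' @param duration Override of `config$duration`, ms.
#' @param pptn_tonic,rmtn_tonic Sustained drive rates (Hz per DA neuron)
#'   applied for the whole run, used by activation protocols.
#' @return An `adds_recording`: per-population lists of spike-time vectors
#'   (ms), plus the drive rate traces and run metadata.
#' @export
run_simulation <- function(network, agency = NULL, rpe_events = list(),
                           seed = 1L, duration = NULL, pptn_tonic = 0,
                           rmtn_tonic = 0) {
  stopifnot(inherits(network, "adds_network"))
  cfg <- network$config
  if (is.null(agency)) agency <- agency_input(cfg$A_control)
  if (inherits(rpe_events, "rpe_event")) rpe_events <- list(rpe_events)
  if (is.null(duration)) duration <- cfg$duration
  dt <- cfg$dt
  n_steps <- as.integer(round(duration / dt))
  tmid <- (seq_len(n_steps) - 0.5) * dt

  vsub_rate <- cfg$vsub_afferents * cfg$vsub_rate_max * agency_at(agency, tmid)
  pptn_rate <- numeric(n_steps)
  rmtn_rate <- numeric(n_steps)
  pptn_tonic_rate <- rep(pptn_tonic, n_steps)
  rmtn_tonic_rate <- rep(rmtn_tonic, n_steps)
  if (length(rpe_events)) {
    on <- vapply(rpe_events, `[[`, 0, "onset")
    dur <- vapply(rpe_events, `[[`, 0, "duration")
    if (any(on + dur > duration)) stop("RPE event outside simulation duration")
    o <- order(on)
    if (length(on) > 1 && any(on[o][-1] < (on + dur)[o][-length(on)]))
      stop("RPE events must be non-overlapping")
    for (ev in rpe_events) {
      idx <- tmid >= ev$onset & tmid < ev$onset + ev$duration
      if (ev$delta > 0)
        pptn_rate[idx] <- pptn_rate[idx] + cfg$pptn_rate_max * ev$delta
      else if (ev$delta < 0)
        rmtn_rate[idx] <- rmtn_rate[idx] - cfg$rmtn_rate_max * ev$delta
    }
  }

  set.seed(seed)
  v0_nacc <- rep(cfg$msn$v_rest, cfg$n_nacc)
  u0_nacc <- rep(0, cfg$n_nacc)
  v0_vp <- runif(cfg$n_vp, cfg$vp$reset, cfg$vp$v_critical)
  v0_da <- runif(cfg$n_da, cfg$da$reset, cfg$da$v_critical)

  msn_par <- unlist(cfg$msn[c("capacitance", "gain_k", "v_rest",
                              "v_threshold", "recovery_rate_a",
                              "recovery_coupling_b", "reset_c",
                              "adaptation_increment_d", "v_peak")])
  vp_par <- unlist(cfg$vp[c("membrane_time_constant", "v_rest", "v_critical",
                            "reset", "v_peak")])
  da_par <- unlist(cfg$da[c("membrane_time_constant", "v_rest", "v_critical",
                            "reset", "v_peak")])

  res <- sim_circuit_cpp(msn_par, vp_par, da_par,
                         rep(cfg$vp$bias_current, cfg$n_vp),
                         rep(cfg$da$bias_current, cfg$n_da),
                         cfg$msn_noise, cfg$vp_noise, cfg$da_noise,
                         network$W_vp_nacc, network$W_da_vp,
                         network$aversive, cfg$aversive_gain,
                         cfg$vp_inh_max, cfg$vsub_ou_tau, cfg$vsub_ou_sd,
                         vsub_rate, pptn_rate, rmtn_rate,
                         pptn_tonic_rate, rmtn_tonic_rate,
                         cfg$w_vsub, cfg$w_pptn, cfg$w_rmtn,
                         cfg$w_pptn_tonic, cfg$w_rmtn_tonic,
                         cfg$tau_exc, cfg$tau_inh, dt, n_steps,
                         v0_nacc, u0_nacc, v0_vp, v0_da)

  to_trains <- function(id, step, n) {
    t_ms <- step * dt
    tr <- split(t_ms, factor(id, levels = seq_len(n)))
    lapply(tr, as.numeric)
  }
  structure(list(
    nacc = to_trains(res$nacc_id, res$nacc_step, cfg$n_nacc),
    vp = to_trains(res$vp_id, res$vp_step, cfg$n_vp),
    da = to_trains(res$da_id, res$da_step, cfg$n_da),
    aversive = network$aversive,
    duration = duration, dt = dt, seed = as.integer(seed),
    agency = agency, rpe_events = rpe_events,
    drives = list(pptn_tonic = pptn_tonic, rmtn_tonic = rmtn_tonic),
    config = cfg), class = "adds_recording")
}

#' @export
print.adds_recording <- function(x, ...) {
  rate <- function(tr) mean(lengths(tr)) / x$duration * 1000
  cat(sprintf("ADDS recording: %.1f s, seed %d\n", x$duration / 1000, x$seed))
  cat(sprintf("  mean rates (Hz): NAcc %.2f, VP %.2f, VTA DA %.2f\n",
              rate(x$nacc), rate(x$vp), rate(x$da)))
  cat(sprintf("  %d RPE event(s)\n", length(x$rpe_events)))
  invisible(x)
}

#' Population mean firing rate of a recording
#'
#' @param recording An `adds_recording`.
#' @param population One of `"nacc"`, `"vp"`, `"da"`.
#' @param window Analysis interval `c(start, end)` in ms; default the full
#'   recording.
#' @return Mean rate in Hz across neurons.
#' @export
population_rate <- function(recording, population = c("nacc", "vp", "da"),
                            window = NULL) {
  population <- match.arg(population)
  if (is.null(window)) window <- c(0, recording$duration)
  tr <- recording[[population]]
  n_sp <- vapply(tr, function(s) sum(s >= window[1] & s < window[2]), 0)
  mean(n_sp) / diff(window) * 1000
}

#' Classify DA neurons as silent, tonic, or phasic
#'
#' A neuron is *silent* if its firing rate in the window is below
#' `tonic_threshold` (a rate exactly at threshold counts as tonic);
#' *phasic* if it emits at least one burst, where a burst starts with an
#' inter-spike interval below `burst_isi_on` and ends with one above
#' `burst_isi_off` (the standard DA burst convention); otherwise *tonic*.
#'
#' @param recording An `adds_recording`, or a list of spike-time vectors.
#' @param window Analysis interval `c(start, end)` in ms, at least 1000 ms
#'   long. Defaults to the recording after a 2 s burn-in.
#' @param tonic_threshold Hz.
#' @param burst_isi_on,burst_isi_off Burst entry / exit ISI criteria, ms.
#' @return A factor of labels (`silent`, `tonic`, `phasic`) with
#'   attributes `rate` (per-neuron Hz) and `n_bursts`.
#' @export
classify_da_states <- function(recording, window = NULL,
                               tonic_threshold = 0.5, burst_isi_on = 80,
                               burst_isi_off = 160) {
  if (inherits(recording, "adds_recording")) {
    trains <- recording$da
    if (is.null(window)) window <- c(min(2000, recording$duration / 6),
                                     recording$duration)
  } else {
    trains <- recording
    if (is.null(window)) stop("window is required for raw spike trains")
  }
  if (length(trains) == 0) stop("empty recording")
  if (diff(window) < 1000) stop("analysis window must be at least 1000 ms")
  dur_s <- diff(window) / 1000
  lab <- character(length(trains))
  rate <- numeric(length(trains))
  n_bursts <- integer(length(trains))
  for (i in seq_along(trains)) {
    s <- trains[[i]]
    s <- s[s >= window[1] & s < window[2]]
    rate[i] <- length(s) / dur_s
    nb <- 0L
    if (length(s) >= 2) {
      isi <- diff(s)
      in_burst <- FALSE
      for (x in isi) {
        if (!in_burst && x < burst_isi_on) {
          in_burst <- TRUE
          nb <- nb + 1L
        } else if (in_burst && x > burst_isi_off) in_burst <- FALSE
      }
    }
    n_bursts[i] <- nb
    lab[i] <- if (rate[i] < tonic_threshold) "silent"
              else if (nb > 0) "phasic" else "tonic"
  }
  out <- factor(lab, levels = c("silent", "tonic", "phasic"))
  attr(out, "rate") <- rate
  attr(out, "n_bursts") <- n_bursts
  out
}
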