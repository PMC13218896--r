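#' Izhikevich neuron parameters
#'
#' Parameter set for the two-variable Izhikevich model
#' \deqn{C\,\dot v = k (v - v_r)(v - v_t) - u + I, \qquad
#'       \dot u = a\,[\,b (v - v_r) - u\,],}
#' with a spike recorded when \eqn{v \ge v_{peak}}, after which \eqn{v
#' \leftarrow c} and \eqn{u \leftarrow u + d}. The defaults are the
#' published striatal medium-spiny-neuron (MSN) parameterization of this
#' model family: an MSN is silent without input (tonic rate 0 Hz) and shows
#' the up-/down-state behaviour characteristic of accumbens projection
#' neurons under fluctuating synaptic drive.
#'
#' @param capacitance Membrane capacitance, pF.
#' @param v_rest Resting potential \eqn{v_r}, mV.
#' @param v_threshold Instantaneous threshold \eqn{v_t}, mV.
#' @param gain_k Quadratic gain \eqn{k} (dimensionless).
#' @param recovery_rate_a Recovery time scale \eqn{a}, 1/ms.
#' @param recovery_coupling_b Recovery coupling \eqn{b}, nS.
#' @param reset_c Post-spike reset potential, mV.
#' @param adaptation_increment_d Post-spike recovery increment, pA.
#' @param v_peak Spike cutoff, mV.
#' @return An object of class `izhikevich_params`.
#' @examples
#' p <- izhikevich_params()          # striatal MSN defaults
#' simulate_neuron(p, input = 0, duration = 1000)$rate   # 0 Hz
#' @export
izhikevich_params <- function(capacitance = 50, v_rest = -80,
                              v_threshold = -25, gain_k = 1,
                              recovery_rate_a = 0.01,
                              recovery_coupling_b = -20, reset_c = -55,
                              adaptation_increment_d = 150, v_peak = 40) {
  stopifnot(capacitance > 0, recovery_rate_a > 0)
  if (!(v_rest < v_threshold && v_threshold < v_peak))
    stop("require v_rest < v_threshold < v_peak")
  structure(list(capacitance = capacitance, v_rest = v_rest,
                 v_threshold = v_threshold, gain_k = gain_k,
                 recovery_rate_a = recovery_rate_a,
                 recovery_coupling_b = recovery_coupling_b,
                 reset_c = reset_c,
                 adaptation_increment_d = adaptation_increment_d,
                 v_peak = v_peak),
            class = "izhikevich_params")
}

#' Quadratic integrate-and-fire (QIF) neuron parameters
#'
#' Parameter set for the QIF model
#' \deqn{\tau\,\dot v = \frac{(v - v_r)(v - v_c)}{v_c - v_r} + I,}
#' with reset to `reset` when \eqn{v \ge v_{peak}}. Input currents are in
#' pA-equivalents (unit input resistance), so the rheobase is
#' \eqn{(v_c - v_r)/4}. Two presets are used throughout the circuit:
#' ventral pallidum (VP) projection neurons, bias-calibrated to a 7 Hz
#' tonic rate, and VTA dopamine neurons, slow pacemakers calibrated to
#' about 4.5 Hz when uninhibited.
#'
#' @param membrane_time_constant \eqn{\tau}, ms.
#' @param v_rest Resting potential, mV (stable fixed point without drive).
#' @param v_critical Unstable threshold potential, mV.
#' @param reset Post-spike reset potential, mV.
#' @param v_peak Spike cutoff, mV.
#' @param bias_current Intrinsic drive, pA-equivalents; see
#'   [calibrate_bias_current()].
#' @param noise_sd Membrane current-noise intensity (pA sqrt(ms)); 0 for
#'   the deterministic pallidal default.
#' @return An object of class `qif_params`.
#' @seealso [qif_preset()] for the VP and DA presets.
#' @export
qif_params <- function(membrane_time_constant = 10, v_rest = -65,
                       v_critical = -50, reset = -65, v_peak = 30,
                       bias_current = 0, noise_sd = 0) {
  stopifnot(membrane_time_constant > 0, noise_sd >= 0)
  if (!(v_rest < v_critical && v_critical < v_peak))
    stop("require v_rest < v_critical < v_peak")
  structure(list(membrane_time_constant = membrane_time_constant,
                 v_rest = v_rest, v_critical = v_critical, reset = reset,
                 v_peak = v_peak, bias_current = bias_current,
                 noise_sd = noise_sd),
            class = "qif_params")
}

#' QIF presets for the circuit populations
#'
#' `"vp"` returns the ventral pallidum parameter set (fast, tonically
#' active; bias calibrated so an isolated neuron fires 7 Hz). `"da"`
#' returns the VTA dopamine pacemaker (slower membrane, bias calibrated to
#' 4.5 Hz when uninhibited). Calibrated bias values are computed once via
#' [calibrate_bias_current()] and stored as defaults.
#'
#' @param which `"vp"` or `"da"`.
#' @return A `qif_params` object.
#' @export
qif_preset <- function(which = c("vp", "da")) {
  which <- match.arg(which)
  if (which == "vp") {
    p <- qif_params(membrane_time_constant = 10, v_rest = -65,
                    v_critical = -50, reset = -65, v_peak = 30,
                    bias_current = 0, noise_sd = 0)
    p$bias_current <- .cal_bias("vp", p, 7)
  } else {
    p <- qif_params(membrane_time_constant = 20, v_rest = -60,
                    v_critical = -45, reset = -60, v_peak = 30,
                    bias_current = 0, noise_sd = 0)
    p$bias_current <- .cal_bias("da", p, 4.5)
  }
  p
}

# memoised bias calibration for the presets (deterministic)
.addsim_cal <- new.env(parent = emptyenv())
.cal_bias <- function(key, params, target) {
  if (is.null(.addsim_cal[[key]]))
    .addsim_cal[[key]] <- calibrate_bias_current(params, target,
                                                 tolerance = 0.05)
  .addsim_cal[[key]]
}

#' @export
print.izhikevich_params <- function(x, ...) {
  cat("Izhikevich neuron parameters\n")
  cat(sprintf("  C=%g pF, k=%g, vr=%g mV, vt=%g mV, a=%g, b=%g, c=%g, d=%g, vpeak=%g\n",
              x$capacitance, x$gain_k, x$v_rest, x$v_threshold,
              x$recovery_rate_a, x$recovery_coupling_b, x$reset_c,
              x$adaptation_increment_d, x$v_peak))
  invisible(x)
}

#' @export
print.qif_params <- function(x, ...) {
  cat("QIF neuron parameters\n")
  cat(sprintf("  tau=%g ms, vr=%g mV, vc=%g mV, reset=%g mV, vpeak=%g mV, bias=%g, noise_sd=%g\n",
              x$membrane_time_constant, x$v_rest, x$v_critical, x$reset,
              x$v_peak, x$bias_current, x$noise_sd))
  invisible(x)
}

#' Initial state of a single neuron
#'
#' @param v Membrane potential, mV.
#' @param recovery_u Recovery variable, pA (Izhikevich model only).
#' @param time_since_last_spike ms; `Inf` if the neuron has not spiked.
#' @return A `neuron_state` list.
#' @export
neuron_state <- function(v, recovery_u = 0, time_since_last_spike = Inf) {
  structure(list(v = v, recovery_u = recovery_u,
                 time_since_last_spike = time_since_last_spike),
            class = "neuron_state")
}

#' Advance an Izhikevich neuron by one Euler step
#'
#' @param state A [neuron_state()].
#' @param params An [izhikevich_params()] object.
#' @param input_current Synaptic input, pA.
#' @param dt Step, ms (> 0).
#' @return The updated state, with attribute `spike` (logical).
#' @export
step_izhikevich <- function(state, params, input_current, dt) {
  stopifnot(dt > 0)
  if (!all(is.finite(c(state$v, state$recovery_u, input_current))))
    stop("non-finite state or input: integration diverged (dt too large?)")
  v <- state$v; u <- state$recovery_u
  spike <- FALSE
  rem <- dt
  # adaptive substepping: limit each Euler substep to a 2 mV change so the
  # fast quadratic upswing does not advance the spike time at coarse dt
  while (rem > 0) {
    dv <- (params$gain_k * (v - params$v_rest) * (v - params$v_threshold) -
             u + input_current) / params$capacitance
    h <- min(rem, if (abs(dv) > 0) 2 / abs(dv) else rem)
    un <- u + h * params$recovery_rate_a *
      (params$recovery_coupling_b * (v - params$v_rest) - u)
    v <- v + h * dv
    u <- un
    rem <- rem - h
    if (v >= params$v_peak) {
      v <- params$reset_c
      u <- u + params$adaptation_increment_d
      spike <- TRUE
      break  # step ends at the spike; v left at reset
    }
  }
  out <- neuron_state(v, u, if (spike) 0 else state$time_since_last_spike + dt)
  attr(out, "spike") <- spike
  out
}

#' Advance a QIF neuron by one Euler step
#'
#' The intrinsic `bias_current` of `params` is added to `input_current`.
#'
#' @inheritParams step_izhikevich
#' @param params A [qif_params()] object.
#' @return The updated state, with attribute `spike` (logical).
#' @export
step_qif <- function(state, params, input_current, dt) {
  stopifnot(dt > 0)
  if (!all(is.finite(c(state$v, input_current))))
    stop("non-finite state or input: integration diverged (dt too large?)")
  v <- state$v
  spike <- FALSE
  rem <- dt
  while (rem > 0) {
    dv <- ((v - params$v_rest) * (v - params$v_critical) /
             (params$v_critical - params$v_rest) +
             params$bias_current + input_current) /
      params$membrane_time_constant
    h <- min(rem, if (abs(dv) > 0) 2 / abs(dv) else rem)
    v <- v + h * dv
    rem <- rem - h
    if (v >= params$v_peak) {
      v <- params$reset
      spike <- TRUE
      break  # step ends at the spike; v left at reset
    }
  }
  out <- neuron_state(v, 0, if (spike) 0 else state$time_since_last_spike + dt)
  attr(out, "spike") <- spike
  out
}

#' Simulate one isolated neuron
#'
#' Runs the compiled Euler loop for a single Izhikevich or QIF neuron under
#' constant (or per-step) input current and returns its spike train.
#'
#' @param params An [izhikevich_params()] or [qif_params()] object.
#' @param input Constant input current (pA), or a vector with one value per
#'   step.
#' @param duration Simulated time, ms.
#' @param dt Integration step, ms.
#' @param v0,u0 Initial state; defaults to rest.
#' @param seed Optional seed (only relevant when `noise_sd > 0`).
#' @return A list: `spike_times` (ms), `rate` (Hz), `n_spikes`, and the
#'   final membrane state.
#' @examples
#' simulate_neuron(qif_preset("vp"), input = 0, duration = 10000)$rate
#' @export
simulate_neuron <- function(params, input = 0, duration = 10000, dt = 0.5,
                            v0 = NULL, u0 = 0, seed = NULL) {
  stopifnot(dt > 0, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- as.integer(round(duration / dt))
  if (inherits(params, "izhikevich_params")) {
    if (is.null(v0)) v0 <- params$v_rest
    res <- sim_izh_cpp(unlist(params[c("capacitance", "gain_k", "v_rest",
                                       "v_threshold", "recovery_rate_a",
                                       "recovery_coupling_b", "reset_c",
                                       "adaptation_increment_d", "v_peak")]),
                       as.numeric(input), dt, n_steps, v0, u0, 0)
  } else if (inherits(params, "qif_params")) {
    if (is.null(v0)) v0 <- params$v_rest
    res <- sim_qif_cpp(unlist(params[c("membrane_time_constant", "v_rest",
                                       "v_critical", "reset", "v_peak")]),
                       params$bias_current, as.numeric(input), dt, n_steps,
                       v0, params$noise_sd)
  } else stop("params must be izhikevich_params or qif_params")
  st <- res$spike_steps * dt
  list(spike_times = st, n_spikes = length(st),
       rate = length(st) / duration * 1000, v = res$v,
       u = if (!is.null(res$u)) res$u else 0)
}

#' Calibrate the intrinsic bias current of a QIF neuron
#'
#' Bisection on the simulated firing rate of an isolated, noiseless neuron:
#' returns the bias current for which a 10 s simulation fires within
#' `tolerance` of `target_rate`. Deterministic given `params`. Used to pin
#' the ventral pallidum preset at 7 Hz and the dopamine pacemaker at
#' 4.5 Hz.
#'
#' @param params A [qif_params()] object (its `bias_current` is ignored).
#' @param target_rate Target tonic rate, Hz (>= 0).
#' @param tolerance Acceptable rate error, Hz.
#' @param duration Simulation horizon used to measure the rate, ms.
#' @param dt Integration step, ms.
#' @param bias_range Search interval for the bias, pA-equivalents.
#' @return The calibrated bias current (pA-equivalents).
#' @export
calibrate_bias_current <- function(params, target_rate, tolerance = 0.1,
                                   duration = 10000, dt = 0.5,
                                   bias_range = c(0, 100)) {
  stopifnot(target_rate >= 0, tolerance > 0)
  rate_at <- function(b) {
    p <- params
    p$bias_current <- b
    p$noise_sd <- 0
    simulate_neuron(p, input = 0, duration = duration, dt = dt)$rate
  }
  if (target_rate == 0) return(0)
  lo <- bias_range[1]; hi <- bias_range[2]
  if (rate_at(hi) < target_rate - tolerance)
    stop("calibration failure: target rate unreachable within bias_range")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (abs(r - target_rate) <= tolerance / 2) return(mid)
    if (r < target_rate) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  if (abs(rate_at(mid) - target_rate) > tolerance)
    stop("calibration failure: bisection did not converge to tolerance")
  mid
}
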