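#' Dopamine release/clearance kernel
#'
#' Converts spike trains to extracellular DA concentration: each spike adds
#' `release_increment` (arbitrary concentration units) which decays with
#' `clearance_tau`. Two presets capture regional kinetics: the accumbens
#' (`"nacc"`), with fast transporter-dominated clearance, and frontal
#' cortex (`"cortex"`), where clearance is slow and release is strongly
#' facilitated during burst firing, so a single phasic burst keeps the
#' cortical trace above baseline for tens of minutes.
#'
#' @param region `"nacc"` or `"cortex"` (chooses defaults), or `"custom"`.
#' @param release_increment Concentration added per tonic spike, a.u.
#' @param clearance_tau Clearance time constant, s.
#' @param baseline Baseline concentration offset, a.u.
#' @param phasic_gain Release facilitation factor for spikes fired within a
#'   burst (preceding inter-spike interval below `burst_isi` ms). 1 in the
#'   accumbens preset (no facilitation), large in cortex.
#' @param burst_isi ISI threshold (ms) below which a spike counts as
#'   intra-burst for release facilitation.
#' @param mode `"exponential"` first-order clearance (default) or
#'   `"michaelis_menten"` saturable reuptake.
#' @param vmax,km Michaelis-Menten parameters (a.u./s and a.u.), used only
#'   in `"michaelis_menten"` mode.
#' @return A `da_kernel` object.
#' @export
da_kernel <- function(region = c("nacc", "cortex", "custom"),
                      release_increment = 1,
                      clearance_tau = switch(region[1], nacc = 0.2,
                                             cortex = 600, 1),
                      baseline = 50,
                      phasic_gain = switch(region[1], nacc = 1,
                                           cortex = 30, 1),
                      burst_isi = 100, mode = c("exponential",
                                                "michaelis_menten"),
                      vmax = NULL, km = NULL) {
  region <- match.arg(region)
  mode <- match.arg(mode)
  stopifnot(release_increment > 0, clearance_tau > 0, baseline >= 0,
            phasic_gain >= 1)
  if (mode == "michaelis_menten" && (is.null(vmax) || is.null(km)))
    stop("michaelis_menten mode requires vmax and km")
  structure(list(region = region, release_increment = release_increment,
                 clearance_tau = clearance_tau, baseline = baseline,
                 phasic_gain = phasic_gain, burst_isi = burst_isi,
                 mode = mode, vmax = vmax, km = km),
            class = "da_kernel")
}

#' Convert DA spike trains to a concentration trace
#'
#' Superposes the release kernel over all spikes of all supplied trains:
#' \deqn{c(t) = \mathrm{baseline} + \sum_s w_s\, e^{-(t - t_s)/\tau}, \quad t \ge t_s,}
#' where \eqn{w_s} is `release_increment`, multiplied by `phasic_gain` for
#' intra-burst spikes. Evaluated on a regular grid by exact recursive
#' exponential filtering (spikes snapped to the following grid point).
#'
#' @param spike_trains A list of spike-time vectors (ms), a single numeric
#'   vector, or an `adds_recording` (its DA population is used).
#' @param kernel A [da_kernel()].
#' @param resolution Grid step, s.
#' @param duration Trace duration, s; defaults to covering the last spike.
#' @return A `da_trace`: list with `times` (s), `concentration` (a.u.),
#'   `region`.
#' @examples
#' k <- da_kernel("nacc")
#' tr <- spikes_to_concentration(c(100, 400), k, resolution = 0.01,
#'                               duration = 2)
#' max(tr$concentration)  # baseline + release_increment
#' @export
spikes_to_concentration <- function(spike_trains, kernel, resolution = 0.01,
                                    duration = NULL) {
  stopifnot(inherits(kernel, "da_kernel"), resolution > 0)
  if (inherits(spike_trains, "adds_recording")) {
    if (is.null(duration)) duration <- spike_trains$duration / 1000
    spike_trains <- spike_trains$da
  }
  if (is.numeric(spike_trains)) spike_trains <- list(spike_trains)
  for (s in spike_trains)
    if (is.unsorted(s, strictly = TRUE) && length(s) > 1)
      stop("spike times must be strictly increasing within each train")
  if (is.null(duration)) {
    last <- suppressWarnings(max(unlist(spike_trains), -Inf))
    duration <- if (is.finite(last)) last / 1000 + 5 * kernel$clearance_tau
                else 1
  }
  n <- as.integer(ceiling(duration / resolution))
  impulse <- numeric(n)
  for (s in spike_trains) {
    if (!length(s)) next
    w <- rep(kernel$release_increment, length(s))
    if (kernel$phasic_gain > 1 && length(s) > 1) {
      burst <- c(FALSE, diff(s) < kernel$burst_isi)
      w[burst] <- w[burst] * kernel$phasic_gain
    }
    idx <- pmin(pmax(ceiling(s / 1000 / resolution), 1L), n)
    for (j in seq_along(idx)) impulse[idx[j]] <- impulse[idx[j]] + w[j]
  }
  conc <- numeric(n)
  if (kernel$mode == "exponential") {
    decay <- exp(-resolution / kernel$clearance_tau)
    acc <- 0
    for (i in seq_len(n)) {
      acc <- acc * decay + impulse[i]
      conc[i] <- acc
    }
  } else {
    acc <- 0
    for (i in seq_len(n)) {
      acc <- max(acc - resolution * kernel$vmax * acc / (kernel$km + acc), 0)
      acc <- acc + impulse[i]
      conc[i] <- acc
    }
  }
  structure(list(times = (seq_len(n) - 0.5) * resolution,
                 concentration = conc + kernel$baseline,
                 region = kernel$region, kernel = kernel),
            class = "da_trace")
}

#' @export
print.da_trace <- function(x, ...) {
  cat(sprintf("DA concentration trace (%s): %d samples over %.1f s, mean %.2f a.u.\n",
              x$region, length(x$times), max(x$times) + x$times[1],
              mean(x$concentration)))
  invisible(x)
}

#' @export
plot.da_trace <- function(x, ...) {
  graphics::plot(x$times, x$concentration, type = "l",
                 xlab = "time (s)", ylab = "DA concentration (a.u.)",
                 main = sprintf("Extracellular DA (%s)", x$region), ...)
  graphics::abline(h = x$kernel$baseline, lty = 2, col = "grey50")
  invisible(x)
}

#' DA concentration change around an RPE event
#'
#' Mean concentration in the response window (starting at event onset)
#' minus the mean in the baseline window (ending at event onset), from the
#' pooled DA-population trace of a recording.
#'
#' @param recording An `adds_recording` (or a `da_trace`).
#' @param event The [rpe_event()] around which to measure.
#' @param kernel A [da_kernel()]; ignored when a trace is supplied.
#' @param baseline_window Length of the pre-onset baseline window, s.
#' @param response_window Length of the post-onset response window, s.
#' @param resolution Trace resolution, s.
#' @return The concentration change, a.u.
#' @export
delta_da <- function(recording, event, kernel = da_kernel("nacc"),
                     baseline_window = 1, response_window = 0.5,
                     resolution = 0.01) {
  stopifnot(inherits(event, "rpe_event"), baseline_window > 0,
            response_window > 0)
  onset_s <- event$onset / 1000
  if (onset_s - baseline_window < 0)
    stop("baseline window extends before the recording start")
  trace <- if (inherits(recording, "da_trace")) recording
           else spikes_to_concentration(recording, kernel,
                                        resolution = resolution)
  if (onset_s + response_window > max(trace$times) + resolution / 2)
    stop("response window extends past the recording end")
  base <- trace$times >= onset_s - baseline_window & trace$times < onset_s
  resp <- trace$times >= onset_s & trace$times < onset_s + response_window
  mean(trace$concentration[resp]) - mean(trace$concentration[base])
}

#' DA response curve over a grid of reward-prediction errors
#'
#' Runs one full circuit simulation per (RPE, seed), measures the
#' accumbens DA change with [delta_da()], and summarizes per RPE value.
#' An increase in agency recruits more tonically active DA neurons and
#' therefore steepens this curve.
#'
#' @param agency_level Scalar agency level for all runs.
#' @param delta_grid RPE values in \eqn{[-1, 1]}.
#' @param n_seeds Simulations per grid point (>= 2).
#' @param config A [network_config()].
#' @param kernel Accumbens [da_kernel()].
#' @param event_onset RPE event onset, ms.
#' @param duration Simulation length, ms.
#' @param baseline_window,response_window Measurement windows, s.
#' @param seeds Optional explicit seed vector (length `n_seeds`).
#' @return A data.frame with columns `delta`, `mean_dda`, `se`, `n_seeds`,
#'   plus attribute `per_seed` (matrix of per-seed measurements).
#' @export
rpe_response_curve <- function(agency_level, delta_grid = seq(-1, 1, 0.25),
                               n_seeds = 10, config = network_config(),
                               kernel = da_kernel("nacc"),
                               event_onset = 3000, duration = 4000,
                               baseline_window = 1, response_window = 0.5,
                               seeds = NULL) {
  stopifnot(n_seeds >= 2)
  if (is.null(seeds)) seeds <- seq_len(n_seeds)
  per_seed <- matrix(NA_real_, length(delta_grid), length(seeds))
  for (j in seq_along(seeds)) {
    net <- build_network(config, seed = seeds[j])
    for (i in seq_along(delta_grid)) {
      d <- delta_grid[i]
      ev <- if (d != 0) list(rpe_event(event_onset, d)) else list()
      rec <- run_simulation(net, agency_input(agency_level), ev,
                            seed = seeds[j] + 1000L * i,
                            duration = duration)
      per_seed[i, j] <- delta_da(rec, rpe_event(event_onset, d), kernel,
                                 baseline_window, response_window)
    }
  }
  out <- data.frame(delta = delta_grid,
                    mean_dda = rowMeans(per_seed),
                    se = apply(per_seed, 1, sd) / sqrt(length(seeds)),
                    n_seeds = length(seeds))
  attr(out, "per_seed") <- per_seed
  out
}
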