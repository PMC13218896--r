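# Independent oracles used by the tests; deliberately closed-form or
# brute-force, never calling the code paths they check.

# Analytic period of a QIF neuron under constant suprathreshold drive:
# integrate dv / ((v-vr)(v-vc)/(vc-vr) + I) from reset to v_peak.
qif_period_analytic <- function(params, I) {
  D <- params$v_critical - params$v_rest
  stopifnot(I > D / 4)  # suprathreshold
  q <- sqrt(4 * I * D - D^2)
  arg <- function(v) (2 * v - params$v_rest - params$v_critical) / q
  2 * params$membrane_time_constant * D / q *
    (atan(arg(params$v_peak)) - atan(arg(params$reset)))
}

# Shot-noise stationary mean of an exponentially filtered Poisson process:
# n trains at `rate` Hz, increment `inc`, clearance tau (s), plus baseline.
shot_noise_mean <- function(rate, inc, tau, n, baseline) {
  baseline + n * rate * inc * tau
}

# Exact two-sided permutation p-value by full enumeration of group
# assignments (small n only).
exact_perm_pvalue <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  idx <- utils::combn(length(pool), nx)
  d <- apply(idx, 2, function(i) abs(mean(pool[i]) - mean(pool[-i])))
  mean(d >= obs - 1e-12)
}

# Indifference discounting rate for a sooner/later pair: the alpha at
# which u_s D(t_s) = u_l D(t_l) under hyperbolic discounting.
indifference_alpha <- function(u_s, u_l, t_s, t_l) {
  (u_l - u_s) / (u_s * t_l - u_l * t_s)
}

# Small network configuration for fast structural tests (not the study
# conditions; those use the defaults).
small_config <- function(...) {
  network_config(n_nacc = 30, n_vp = 30, n_da = 30, duration = 4000, ...)
}
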