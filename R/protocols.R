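#' In-silico activation protocol (ventral subiculum / PPTN)
#'
#' Reproduces the classic activation experiment: under control conditions,
#' after ventral subiculum activation (high agency drive), after sustained
#' pedunculopontine (PPTN) activation, or both. For each seed, a fresh
#' network is wired and simulated, DA neurons are classified with
#' [classify_da_states()], and two measures are taken: the percentage of
#' tonically active (non-silent) DA neurons, and the mean firing rate of
#' the currently active neurons. The expected double dissociation: vSub
#' activation raises the percentage active without changing the rate of
#' active neurons; PPTN activation raises the rate without changing the
#' percentage active.
#'
#' @param condition `"control"`, `"vsub"`, `"pptn"`, or `"both"`.
#' @param n_seeds Number of replicate simulations (>= 10 recommended for
#'   significance testing).
#' @param config A [network_config()].
#' @param pptn_drive Sustained PPTN drive rate (Hz per DA neuron) in the
#'   PPTN conditions.
#' @param burn_in Discarded transient, ms.
#' @param window_length Analysis window length after burn-in, ms.
#' @param seeds Optional explicit seed vector.
#' @return An `adds_protocol_result`: per-seed measures, summary
#'   statistics, and metadata.
#' @export
run_lodge_grace <- function(condition = c("control", "vsub", "pptn", "both"),
                            n_seeds = 20, config = network_config(),
                            pptn_drive = 5, burn_in = 2000,
                            window_length = 10000, seeds = NULL) {
  condition <- match.arg(condition)
  if (is.null(seeds)) seeds <- seq_len(n_seeds)
  if (length(seeds) < 2) stop("need at least 2 seeds")
  A <- if (condition %in% c("vsub", "both")) config$A_high else config$A_control
  pt <- if (condition %in% c("pptn", "both")) pptn_drive else 0
  duration <- burn_in + window_length
  win <- c(burn_in, duration)
  pct <- rate <- numeric(length(seeds))
  for (j in seq_along(seeds)) {
    net <- build_network(config, seed = seeds[j])
    rec <- run_simulation(net, agency_input(A), seed = seeds[j],
                          duration = duration, pptn_tonic = pt)
    st <- classify_da_states(rec, win)
    r <- attr(st, "rate")
    act <- st != "silent"
    pct[j] <- mean(act) * 100
    rate[j] <- if (any(act)) mean(r[act]) else NA_real_
  }
  structure(list(condition = condition,
                 per_seed = data.frame(seed = seeds,
                                       percent_tonically_active = pct,
                                       mean_rate_active = rate),
                 percent_tonically_active = c(mean = mean(pct),
                                              se = sd(pct) / sqrt(length(seeds))),
                 mean_rate_active = c(mean = mean(rate, na.rm = TRUE),
                                      se = sd(rate, na.rm = TRUE) /
                                        sqrt(sum(!is.na(rate)))),
                 n_seeds = length(seeds), seeds = seeds,
                 agency = A, pptn_drive = pt,
                 config_hash = config_hash(config)),
            class = "adds_protocol_result")
}

#' @export
print.adds_protocol_result <- function(x, ...) {
  cat(sprintf("Protocol result [%s], %d seeds\n", x$condition, x$n_seeds))
  cat(sprintf("  %% tonically active: %.1f (SE %.2f)\n",
              x$percent_tonically_active["mean"],
              x$percent_tonically_active["se"]))
  cat(sprintf("  mean rate of active neurons: %.2f Hz (SE %.3f)\n",
              x$mean_rate_active["mean"], x$mean_rate_active["se"]))
  if (!is.null(x$p_vs_control)) {
    cat(sprintf("  vs control: p(%%active) = %.4g, p(rate) = %.4g\n",
                x$p_vs_control["percent_tonically_active"],
                x$p_vs_control["mean_rate_active"]))
  }
  invisible(x)
}

#' Sweep the agency level
#'
#' Runs the control protocol at each agency level and returns one
#' [run_lodge_grace()]-style result per level. The fraction of tonically
#' active DA neurons increases with agency; the firing rate of the active
#' neurons does not.
#'
#' @param levels Agency levels in \eqn{[0, 1]} (at least 2).
#' @param n_seeds Replicates per level.
#' @param config A [network_config()].
#' @param ... Passed to [run_lodge_grace()].
#' @return A list of `adds_protocol_result`, names `A=<level>`.
#' @export
agency_sweep <- function(levels, n_seeds = 20, config = network_config(),
                         ...) {
  stopifnot(length(levels) >= 2)
  out <- lapply(levels, function(A) {
    cfg <- config
    cfg$A_control <- A
    run_lodge_grace("control", n_seeds = n_seeds, config = cfg, ...)
  })
  names(out) <- sprintf("A=%g", levels)
  out
}

#' Compare two protocol results
#'
#' Two-sided p-values, per measure, for the difference in means between a
#' condition and its control, via a seeded Monte-Carlo permutation test
#' (default) or Welch's t-test.
#'
#' @param result,control_result `adds_protocol_result` objects.
#' @param method `"permutation"` or `"welch"`.
#' @param n_perm Number of label shuffles for the permutation test.
#' @param seed Seed for the shuffles.
#' @return Named numeric vector of p-values (`percent_tonically_active`,
#'   `mean_rate_active`). Also attached to `result` when assigned.
#' @export
compare_to_control <- function(result, control_result,
                               method = c("permutation", "welch"),
                               n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(result, "adds_protocol_result"),
            inherits(control_result, "adds_protocol_result"))
  if (result$n_seeds < 2 || control_result$n_seeds < 2)
    stop("need at least 2 seeds per group")
  p <- vapply(c("percent_tonically_active", "mean_rate_active"),
              function(m) {
                x <- result$per_seed[[m]]
                y <- control_result$per_seed[[m]]
                x <- x[!is.na(x)]; y <- y[!is.na(y)]
                if (method == "welch") t.test(x, y)$p.value
                else permutation_pvalue(x, y, n_perm = n_perm, seed = seed)
              }, 0)
  p
}

#' Two-sided permutation p-value for a difference in means
#'
#' Monte-Carlo permutation test: shuffles group labels `n_perm` times and
#' counts shuffles whose absolute mean difference is at least the observed
#' one (add-one correction).
#'
#' @param x,y Numeric samples.
#' @param n_perm Number of shuffles.
#' @param seed Seed.
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(x, y, n_perm = 10000, seed = 1) {
  set.seed(seed)
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  nx <- length(x)
  n <- length(pool)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, nx)
    d <- abs(mean(pool[idx]) - mean(pool[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}
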