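#' Deterministic fixture spike trains
#'
#' Generates synthetic spike trains for testing the concentration readout
#' and the state classifier: homogeneous Poisson trains, perfectly regular
#' trains, or a regular train with one injected high-frequency burst.
#'
#' @param kind `"poisson"`, `"regular"`, or `"burst_injected"`.
#' @param rate Firing rate, Hz (>= 0).
#' @param duration Train duration, ms.
#' @param seed Seed (Poisson only).
#' @param n_trains Number of trains.
#' @param burst_time Burst onset, ms (`burst_injected`).
#' @param burst_k Number of spikes in the burst.
#' @param burst_isi Burst inter-spike interval, ms.
#' @return A list of `n_trains` numeric vectors of spike times (ms),
#'   strictly increasing within each train.
#' @examples
#' length(generate_fixture_spiketrains("regular", 7, 10000)[[1]])  # 70
#' @export
generate_fixture_spiketrains <- function(kind = c("poisson", "regular",
                                                  "burst_injected"),
                                         rate, duration, seed = 1,
                                         n_trains = 1, burst_time = NULL,
                                         burst_k = 10, burst_isi = 60) {
  kind <- match.arg(kind)
  if (rate < 0) stop("rate must be non-negative")
  stopifnot(duration > 0, n_trains >= 1)
  if (is.null(burst_time)) burst_time <- duration / 2
  set.seed(seed)
  one <- function() {
    if (kind == "poisson") {
      n <- rpois(1, rate * duration / 1000)
      return(sort(runif(n, 0, duration)))
    }
    per <- 1000 / rate
    reg <- if (rate > 0) seq(per / 2, duration, by = per) else numeric()
    if (kind == "regular") return(reg)
    burst <- burst_time + (seq_len(burst_k) - 1) * burst_isi
    keep <- reg < burst_time - burst_isi | reg > max(burst) + burst_isi
    sort(c(reg[keep], burst))
  }
  lapply(seq_len(n_trains), function(i) one())
}
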