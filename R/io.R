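#' Export recording spike trains as CSV
#'
#' Long format, one row per spike: `population`, `neuron_id`, `time_ms`.
#'
#' @param recording An `adds_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(recording, path) {
  rows <- do.call(rbind, lapply(c("nacc", "vp", "da"), function(pop) {
    tr <- recording[[pop]]
    n <- lengths(tr)
    data.frame(population = rep(pop, sum(n)),
               neuron_id = rep(seq_along(tr), n),
               time_ms = unlist(tr, use.names = FALSE))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read spike trains from CSV
#'
#' @param path CSV written by [write_spikes_csv()].
#' @return A named list of populations, each a list of spike-time vectors.
#' @export
read_spikes_csv <- function(path) {
  d <- read.csv(path)
  lapply(split(d, d$population), function(dd) {
    n <- max(dd$neuron_id)
    split(dd$time_ms, factor(dd$neuron_id, levels = seq_len(n)))
  })
}

#' Export a DA trace as CSV
#'
#' Two columns: `time_s`, `concentration`.
#'
#' @param trace A `da_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(data.frame(time_s = trace$times,
                       concentration = trace$concentration),
            path, row.names = FALSE)
  invisible(path)
}

#' Export a full recording to a directory
#'
#' Writes the spike CSV plus a JSON summary embedding the seed, the config
#' hash, population rates and DA state counts, so any published artifact
#' can be regenerated from its metadata.
#'
#' @param recording An `adds_recording`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
export_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spikes_csv(recording, file.path(dir, "spikes.csv"))
  st <- classify_da_states(recording)
  summary <- list(
    duration_ms = recording$duration, dt_ms = recording$dt,
    seed = recording$seed,
    config_hash = config_hash(recording$config),
    agency_levels = recording$agency$levels,
    n_rpe_events = length(recording$rpe_events),
    rates_hz = list(nacc = population_rate(recording, "nacc"),
                    vp = population_rate(recording, "vp"),
                    da = population_rate(recording, "da")),
    da_states = as.list(table(st)))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Export a protocol result as JSON
#'
#' @param result An `adds_protocol_result` (or list of them).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_protocol_json <- function(result, path) {
  strip <- function(x) {
    list(condition = x$condition, n_seeds = x$n_seeds, seeds = x$seeds,
         agency = x$agency, pptn_drive = x$pptn_drive,
         config_hash = x$config_hash,
         percent_tonically_active = as.list(x$percent_tonically_active),
         mean_rate_active = as.list(x$mean_rate_active),
         p_vs_control = if (!is.null(x$p_vs_control))
           as.list(x$p_vs_control),
         per_seed = x$per_seed)
  }
  out <- if (inherits(result, "adds_protocol_result")) strip(result)
         else lapply(result, strip)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
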