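#' Default run configuration
#'
#' The schema for YAML/JSON run configuration files: a nested list with
#' sections `network` (circuit parameters, including the `msn`, `vp` and
#' `da` neuron parameter blocks), `kernels` (accumbens and cortical DA
#' kernels), `protocol` (seeds, drives, windows), `decision`
#' (utility, weighting, discounting, agency coupling), and top-level
#' `seed` and `output_dir`. [load_config()] fills any omitted keys from
#' these defaults and rejects unknown keys.
#'
#' @return A nested list (class `run_config`).
#' @export
default_run_config <- function() {
  net <- network_config()
  simple <- function(x, drop) x[setdiff(names(x), drop)]
  structure(list(
    schema_version = 1L,
    seed = 1L,
    output_dir = ".",
    network = c(simple(unclass(net), c("msn", "vp", "da")),
                list(msn = unclass(net$msn), vp = unclass(net$vp),
                     da = unclass(net$da))),
    kernels = list(
      nacc = unclass(da_kernel("nacc"))[c("region", "release_increment",
                                          "clearance_tau", "baseline",
                                          "phasic_gain", "burst_isi")],
      cortex = unclass(da_kernel("cortex"))[c("region", "release_increment",
                                              "clearance_tau", "baseline",
                                              "phasic_gain", "burst_isi")]),
    protocol = list(n_seeds = 20L, pptn_drive = 5, burn_in = 2000,
                    window_length = 10000),
    decision = list(
      gain_exponent = 0.88, loss_exponent = 0.88,
      gain_anchor = c(79, 50), loss_anchor = c(-48, -50),
      gain_multiplier_high = 1.38, loss_multiplier_high = 1.06,
      distortion_gamma = 0.61, da_modulation = 0,
      weighting_mode = "identity",
      alpha = 0.01, alpha_min = 0.005, da_optimum = 1.5, curvature = 2)),
    class = "run_config")
}

# recursive merge of user values into defaults; errors on unknown keys
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults) || !is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^/", "", paste0(path, "/", unknown)), collapse = ", "))
  for (k in names(user))
    defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                  paste0(path, "/", k))
  defaults
}

#' Load a run configuration from YAML or JSON
#'
#' Reads the file (format chosen by extension, `.json` vs `.yaml`/`.yml`),
#' validates it against the [default_run_config()] schema (unknown keys
#' are an error, naming the offending keys), and fills omitted keys with
#' defaults. An empty file yields the full default configuration.
#'
#' @param path Config file path.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(unclass(default_run_config()), user)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration
#'
#' @param config A `run_config` list.
#' @param path Output path (`.json` or `.yaml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  else yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build circuit and decision objects from a run configuration
#'
#' @param config A `run_config` list.
#' @return A list with `network_config`, `kernels`, `uparams`, `wparams`,
#'   `dparams`, and helper `context(A)`.
#' @export
config_objects <- function(config) {
  nc <- config$network
  msn <- do.call(izhikevich_params, nc$msn)
  vp <- do.call(qif_params, nc$vp)
  da <- do.call(qif_params, nc$da)
  net_args <- nc[setdiff(names(nc), c("msn", "vp", "da"))]
  net <- do.call(network_config, c(net_args, list(msn = msn, vp = vp,
                                                  da = da)))
  kern <- lapply(config$kernels, function(k) do.call(da_kernel, k))
  dec <- config$decision
  cal <- calibrate_utility(dec$gain_anchor, dec$loss_anchor,
                           dec$gain_exponent, dec$loss_exponent)
  uparams <- utility_params(dec$gain_exponent, dec$loss_exponent,
                            cal$gain_scale, cal$loss_aversion_lambda)
  wparams <- prob_weight_params(dec$distortion_gamma, dec$da_modulation,
                                dec$weighting_mode)
  dparams <- discount_params(dec$alpha, dec$alpha_min, dec$da_optimum,
                             dec$curvature)
  ctx_fun <- function(A) agency_context(
    A, A_control = net$A_control, A_high = net$A_high,
    gain_multiplier_high = dec$gain_multiplier_high,
    loss_multiplier_high = dec$loss_multiplier_high)
  list(network_config = net, kernels = kern, uparams = uparams,
       wparams = wparams, dparams = dparams, context = ctx_fun)
}

#' Hash of a configuration (for provenance)
#'
#' @param config Any R object.
#' @return Character md5 hash of the serialized object.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}
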