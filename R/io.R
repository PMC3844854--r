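## Text-based input/output: spike-train files, voltage traces, YAML configs.

#' Write and read multi-unit spike-train files
#'
#' Delimited text with a commented header (number of units, duration,
#' protocol label, seed) followed by `unit time` rows (time in ms).
#'
#' @param trains list of [spike_train()]s.
#' @param path file path.
#' @param protocol_label,seed optional metadata stored in the header.
#' @return `write_spike_trains` returns `path` invisibly;
#'   `read_spike_trains` returns a list of [spike_train()]s with the header
#'   metadata attached as attributes.
#' @export
write_spike_trains <- function(trains, path, protocol_label = NA, seed = NA) {
  iv <- trains[[1]]$interval
  hdr <- c(sprintf("# n_units: %d", length(trains)),
           sprintf("# t0: %g", iv[1]),
           sprintf("# t1: %g", iv[2]),
           sprintf("# protocol: %s", protocol_label),
           sprintf("# seed: %s", seed),
           "unit\ttime")
  rows <- unlist(lapply(trains, function(s)
    if (length(s$times)) sprintf("%s\t%.6f", as.character(s$id), s$times)))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# *", "", h)
    key <- sub(":.*", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*: *", "", kv))
  }
  body <- utils::read.delim(text = lines[!grepl("^#", lines)],
                            stringsAsFactors = FALSE)
  iv <- c(as.numeric(meta$t0), as.numeric(meta$t1))
  n <- as.integer(meta$n_units)
  ids <- unique(body$unit)
  trains <- lapply(seq_len(n), function(u) {
    id <- if (u <= length(ids)) ids[u] else u
    spike_train(sort(body$time[body$unit == id]), iv, id = id)
  })
  attr(trains, "meta") <- meta
  trains
}

#' Export a voltage trace as delimited text
#'
#' @param trace data.frame with columns `t` (ms) and `v` (mV).
#' @param path file path.
#' @export
write_voltage_trace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# fields a config YAML may set
.config_keys <- c("n_gp", "n_stn", "gp_fanout", "stn_fanout", "condition",
                  "duration", "analysis_window_start", "seed",
                  "g_gg", "g_sg", "protocol", "downregulation")
.protocol_keys <- c("label", "period", "active_duration",
                    "inactive_duration", "active_rate", "inactive_rate")
.downreg_keys <- c("T_HCN", "k_HCN", "theta", "sigma", "update_interval",
                   "enabled")

#' Load and validate a configuration file
#'
#' YAML file with top-level simulation fields and optional `protocol:` and
#' `downregulation:` blocks.  Unknown keys are rejected; missing fields take
#' the package defaults; all type invariants are checked by the underlying
#' constructors.  An empty file yields the full default (healthy, 100 GP)
#' configuration.
#'
#' @param path path to the YAML config.
#' @return A [network_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' @rdname load_config
#' @param raw a named list of configuration values (as parsed from YAML).
#' @export
validate_config <- function(raw) {
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  args <- raw[setdiff(names(raw), c("protocol", "downregulation"))]
  if (!is.null(raw$protocol)) {
    unknown <- setdiff(names(raw$protocol), .protocol_keys)
    if (length(unknown))
      stop("unknown protocol keys: ", paste(unknown, collapse = ", "))
    args$protocol <- do.call(swa_protocol, c(
      list(label = if (is.null(raw$protocol$label)) "custom"
           else raw$protocol$label),
      raw$protocol[setdiff(names(raw$protocol), "label")]))
  }
  if (!is.null(raw$downregulation)) {
    unknown <- setdiff(names(raw$downregulation), .downreg_keys)
    if (length(unknown))
      stop("unknown downregulation keys: ", paste(unknown, collapse = ", "))
    args$downregulation <- do.call(downregulation_params, raw$downregulation)
  }
  do.call(network_config, args)
}

#' Write a configuration back to YAML
#'
#' The dump is itself a valid config file: loading it reproduces the same
#' resolved configuration (idempotent round trip).
#'
#' @param cfg a [network_config()].
#' @param path file path.
#' @export
dump_config <- function(cfg, path) {
  x <- list(
    n_gp = cfg$n_gp, n_stn = cfg$n_stn, gp_fanout = cfg$gp_fanout,
    stn_fanout = cfg$stn_fanout, condition = cfg$condition,
    duration = cfg$duration,
    analysis_window_start = cfg$analysis_window_start,
    seed = cfg$seed,
    g_gg = cfg$synapses$gp_gp$g_mean,
    g_sg = cfg$synapses$stn_gp$g_mean,
    protocol = cfg$protocol[.protocol_keys],
    downregulation = cfg$downregulation[.downreg_keys])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Write per-neuron category tables
#'
#' @param reports list of `category_report`s.
#' @param path file path (tab-delimited text).
#' @return The table invisibly.
#' @export
write_category_table <- function(reports, path = NULL) {
  tb <- do.call(rbind, lapply(reports, function(r)
    data.frame(id = r$id, label = r$label, rate = r$rate, cv = r$cv,
               confidence = r$phase$confidence,
               mean_phase = r$phase$mean_phase,
               n_spikes = r$phase$n_spikes)))
  if (!is.null(path))
    utils::write.table(tb, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(tb)
}

#' Export a correlogram as delimited text
#'
#' @param cg a `correlogram`.
#' @param path file path.
#' @export
write_correlogram <- function(cg, path) {
  df <- cg$bins
  df$ci_lower <- cg$ci_lower
  df$ci_upper <- cg$ci_upper
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
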