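## Named experiments: end-to-end protocols mapping to the study's
## characterizations (isolated-neuron surface, healthy/Parkinsonian network
## batteries, downregulation ablation, scaling, beta-band variant).

.experiment_names <- c("characterization", "healthy_battery",
                       "parkinsonian_battery", "downregulation_ablation",
                       "scaling_200", "scaling_300", "beta_band",
                       "hcn_blockade", "post_downregulation_pacemaking")

#' Run a named experiment
#'
#' Executes one of the package's standard experiments end to end
#' (simulation, analysis, summary tables) and optionally writes its outputs
#' (spike trains, category tables, run manifest) to a directory.
#'
#' Experiments:
#' \describe{
#'   \item{characterization}{isolated heterogeneous population (default 500
#'     neurons), no input: pacemaking fraction and rate distribution.}
#'   \item{hcn_blockade}{same with both HCN conductances zeroed.}
#'   \item{healthy_battery / parkinsonian_battery}{network trial batteries
#'     under the named condition.}
#'   \item{downregulation_ablation}{Parkinsonian battery with the HCN
#'     downregulation mechanism disabled.}
#'   \item{scaling_200 / scaling_300}{Parkinsonian batteries with 200/100
#'     and 300/150 GP/STN neurons (constant fan-outs).}
#'   \item{beta_band}{Parkinsonian battery driven at a 70 ms (beta) cycle;
#'     reports STN-GP cross-correlograms rather than phase categories.}
#'   \item{post_downregulation_pacemaking}{Parkinsonian runs (6.5 s) whose
#'     neurons are then isolated to measure intrinsic rates after
#'     downregulation.}
#' }
#'
#' @param name experiment name (see above).
#' @param seed master seed.
#' @param n_trials number of network trials (where applicable).
#' @param n_neurons population size for isolated-neuron experiments.
#' @param out_dir optional output directory; created if missing.
#' @param overrides named list of [network_config()] field overrides.
#' @return A list with experiment-specific results and, when `out_dir` is
#'   given, a `manifest` describing the outputs.
#' @export
run_experiment <- function(name, seed = 1, n_trials = 4, n_neurons = 500,
                           out_dir = NULL, overrides = list()) {
  name <- match.arg(name, .experiment_names)
  res <- switch(name,
    characterization = {
      pop <- sample_population(n_neurons, seed = seed)
      rr <- isolated_rates(pop)
      list(population = pop, rates = rr,
           summary = c(pacemaking_pct = 100 * mean(rr$pacemaking),
                       mean_rate = mean(rr$rate[rr$pacemaking]),
                       sd_rate = stats::sd(rr$rate[rr$pacemaking])))
    },
    hcn_blockade = {
      pop <- sample_population(n_neurons, seed = seed)
      pop$hcnf <- 0
      pop$hcns <- 0
      rr <- isolated_rates(pop)
      list(population = pop, rates = rr,
           summary = c(silent_pct = 100 * mean(!rr$pacemaking),
                       mean_rate = mean(rr$rate[rr$pacemaking]),
                       sd_rate = stats::sd(rr$rate[rr$pacemaking])))
    },
    healthy_battery = .battery_experiment("healthy", seed, n_trials,
                                          overrides),
    parkinsonian_battery = .battery_experiment("parkinsonian", seed,
                                               n_trials, overrides),
    downregulation_ablation = .battery_experiment(
      "parkinsonian", seed, n_trials,
      utils::modifyList(list(downregulation =
                               downregulation_params(enabled = FALSE)),
                        overrides)),
    scaling_200 = .battery_experiment(
      "parkinsonian", seed, min(n_trials, 3),
      utils::modifyList(list(n_gp = 200, n_stn = 100), overrides)),
    scaling_300 = .battery_experiment(
      "parkinsonian", seed, min(n_trials, 3),
      utils::modifyList(list(n_gp = 300, n_stn = 150), overrides)),
    beta_band = {
      cfg <- do.call(network_config, utils::modifyList(
        list(condition = "parkinsonian", protocol = swa_protocol("beta"),
             seed = seed), overrides))
      sim <- simulate_network(cfg)
      w <- c(cfg$analysis_window_start, cfg$duration)
      stn_all <- spike_train(
        unique(sort(unlist(lapply(sim$stn_trains, function(s) s$times)))),
        c(0, cfg$duration), id = "stn_pooled")
      active <- Filter(function(s) sum(s$times >= w[1] & s$times < w[2]) > 0,
                       sim$spikes)
      cgs <- lapply(active[seq_len(min(20, length(active)))], function(s)
        correlogram(.window_train(stn_all, w), .window_train(s, w),
                    bin_width = 5, n_bins = 30))
      list(result = sim, stn_gp_correlograms = cgs)
    },
    post_downregulation_pacemaking = {
      set.seed(seed)
      trial_seeds <- sample.int(.Machine$integer.max - 1, n_trials)
      runs <- lapply(trial_seeds, function(s) {
        cfg <- do.call(network_config, utils::modifyList(
          list(condition = "parkinsonian", duration = 6500, seed = s),
          overrides))
        sim <- simulate_network(cfg)
        measure_post_downregulation_pacemaking(sim)
      })
      rates <- unlist(lapply(runs, `[[`, "rates"))
      list(runs = runs,
           summary = c(mean_rate = mean(rates), sd_rate = stats::sd(rates),
                       quiet_pct = 100 * mean(vapply(
                         runs, `[[`, numeric(1), "quiet_fraction"))))
    })
  if (!is.null(out_dir)) res$manifest <- .write_experiment(name, seed, res,
                                                           out_dir)
  invisible(res)
}

.window_train <- function(train, w) {
  spike_train(train$times[train$times >= w[1] & train$times < w[2]], w,
              id = train$id)
}

.battery_experiment <- function(condition, seed, n_trials, overrides) {
  cfg <- do.call(network_config, utils::modifyList(
    list(condition = condition, seed = seed), overrides))
  battery <- run_trial_battery(cfg, n_trials = n_trials)
  list(battery = battery, summary = group_summary(battery), config = cfg)
}

.write_experiment <- function(name, seed, res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (!is.null(res$battery)) {
    for (i in seq_along(res$battery)) {
      sim <- res$battery[[i]]
      f1 <- file.path(out_dir, sprintf("trial%02d_gp_spikes.tsv", i))
      write_spike_trains(sim$spikes, f1,
                         protocol_label = sim$config$protocol$label,
                         seed = sim$config$seed)
      f2 <- file.path(out_dir, sprintf("trial%02d_categories.tsv", i))
      write_category_table(categorize_result(sim), f2)
      files <- c(files, f1, f2)
    }
    f <- file.path(out_dir, "group_summary.tsv")
    utils::write.table(res$summary$per_label, f, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  if (!is.null(res$rates)) {
    f <- file.path(out_dir, "isolated_rates.tsv")
    utils::write.table(res$rates, f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    experiment = name, seed = seed,
    package_version = as.character(utils::packageVersion("pallidalnet")),
    timestamp = format(Sys.time(), tz = "UTC"),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
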