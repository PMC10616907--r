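#' Resolved configuration for a full pipeline run
#'
#' Bundles every stage parameter with its default: 30 ms TE window, 4 ms
#' sharpness extension, 1 ms bins, +/- 10 ms jitter window, 100
#' surrogates, 20 x 20 detection grid with excess ratio 2, 0.1 Hz
#' activity threshold, and 10000 permutations for group tests. The
#' resolved configuration is written verbatim next to every output for
#' provenance.
#'
#' @param simulation a [simulation_config()] describing the recording to
#'   simulate (or `NULL` when `raster`/`neuron_table` inputs are given to
#'   [run_pipeline()] directly).
#' @param d_max,tau TE window parameters.
#' @param shuffle_window jitter window in bins.
#' @param n_surrogates surrogate ensemble size.
#' @param detection a [detection_config()].
#' @param rate_threshold_hz active-neuron threshold.
#' @param n_perm permutation count for group statistics.
#' @param seed master seed for every stochastic stage.
#' @param stages character vector of stages to run, in dependency order.
#' @return a `run_config` list.
#' @export
run_config <- function(simulation = simulation_config(),
                       d_max = 30, tau = 4, shuffle_window = 10,
                       n_surrogates = 100,
                       detection = detection_config(),
                       rate_threshold_hz = 0.1, n_perm = 10000,
                       seed = 1L,
                       stages = c("simulate", "profile", "shuffle",
                                  "classify", "detect", "metrics", "layers")) {
  structure(list(simulation = simulation, d_max = d_max, tau = tau,
                 shuffle_window = shuffle_window,
                 n_surrogates = n_surrogates, detection = detection,
                 rate_threshold_hz = rate_threshold_hz, n_perm = n_perm,
                 seed = as.integer(seed), stages = stages),
            class = "run_config")
}

.stage_fail <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
       call. = FALSE)
}

#' Run the full spike-raster-to-network pipeline
#'
#' Executes, in dependency order: simulate (or ingest), pairwise TE
#' profiles, surrogate ensemble, E/I classification, connection
#' detection, network metrics, and layer metrics. Every output is a
#' plain-text TSV (plus a JSON sidecar with the resolved configuration),
#' and a run with the same configuration and seed is byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param raster optional pre-existing [spike_raster()] (skips the
#'   simulate stage); requires `neuron_table`.
#' @param neuron_table metadata for `raster` neurons.
#' @return invisibly, a list with the intermediate objects (`raster`,
#'   `truth`, `profiles`, `ensemble`, `labels`, `network`, `metrics`,
#'   `layer_metrics`) and the output paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         raster = NULL, neuron_table = NULL) {
  stopifnot(inherits(config, "run_config"))
  res <- list(config = config)
  want <- function(s) s %in% config$stages

  if (want("simulate") && is.null(raster)) {
    tryCatch({
      sim <- config$simulation
      sim$seed <- config$seed
      truth <- simulate_network(sim)
      raster <- simulate_spikes(truth, sim)
      neuron_table <- truth$neuron_table
      res$truth <- truth
    }, error = function(e) .stage_fail("simulate", e))
  }
  if (is.null(raster)) stop("no raster: provide one or enable the simulate stage")
  if (is.null(neuron_table))
    neuron_table <- data.frame(neuron_id = raster$neuron_ids,
                               stringsAsFactors = FALSE)
  neuron_table$firing_rate_hz <- firing_rates(raster)[neuron_table$neuron_id]
  res$raster <- raster

  if (want("profile")) tryCatch({
    res$profiles <- all_pairs_profiles(raster, d_max = config$d_max,
                                       tau = config$tau)
  }, error = function(e) .stage_fail("profile", e))

  if (want("shuffle")) tryCatch({
    res$ensemble <- surrogate_ensemble(raster, res$profiles,
                                       n_surrogates = config$n_surrogates,
                                       window = config$shuffle_window,
                                       seed = config$seed + 1L)
  }, error = function(e) .stage_fail("shuffle", e))

  if (want("classify")) tryCatch({
    feats <- suppressWarnings(
      ei_features(res$profiles, firing_rates(raster, per = "bin")))
    res$labels <- suppressWarnings(classify_ei(feats))
    res$features <- feats
    neuron_table$ei_label_inferred <-
      unname(res$labels[neuron_table$neuron_id])
  }, error = function(e) .stage_fail("classify", e))

  if (want("detect")) tryCatch({
    nt <- neuron_table
    res$network <- detect_connections(res$profiles, res$ensemble,
                                      res$labels, config$detection,
                                      neuron_table = nt)
  }, error = function(e) .stage_fail("detect", e))

  if (want("metrics")) tryCatch({
    net <- res$network
    deg <- degrees(net)
    core <- kcore(net)
    metr <- data.frame(node = deg$node, in_degree = deg$in_degree,
                       out_degree = deg$out_degree,
                       core = core[deg$node], stringsAsFactors = FALSE)
    fv <- tryCatch(wmfvs(net), error = function(e) character())
    metr$in_wmfvs <- metr$node %in% fv
    res$metrics <- metr
    res$interlayer <- if ("layer" %in% names(net$nodes))
      interlayer_weights(net) else NULL
  }, error = function(e) .stage_fail("metrics", e))

  if (want("layers")) tryCatch({
    nt <- neuron_table
    if (!"ei_label" %in% names(nt) && "ei_label_inferred" %in% names(nt))
      nt$ei_label <- nt$ei_label_inferred
    area <- 4.0 * 2.0  # mm^2 of the array sheet
    res$layer_metrics <- if (all(c("ei_label", "layer") %in% names(nt)))
      active_density(nt, area, config$rate_threshold_hz) else NULL
    res$ei_balance <- if ("ei_label" %in% names(nt))
      ei_balance(nt, config$rate_threshold_hz) else NULL
  }, error = function(e) .stage_fail("layers", e))

  res$neuron_table <- neuron_table

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    cfg <- config
    cfg$simulation <- unclass(cfg$simulation)
    cfg$detection <- unclass(cfg$detection)
    jsonlite::write_json(unclass(cfg), p("config.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    write_raster(raster, p("raster.tsv"))
    write_neuron_table(neuron_table, p("neuron_table.tsv"))
    if (!is.null(res$network))
      write_edge_list(res$network$edges, p("edges.tsv"))
    if (!is.null(res$profiles)) {
      write_matrix_tsv(res$profiles$strength, p("strength.tsv"))
      write_matrix_tsv(res$profiles$sharpness, p("sharpness.tsv"))
      write_matrix_tsv(res$profiles$ei_bias, p("ei_bias.tsv"))
      jsonlite::write_json(list(d_max = config$d_max, tau = config$tau,
                                bin_ms = 1, log_base = "natural"),
                           p("te_params.json"), auto_unbox = TRUE)
    }
    if (!is.null(res$metrics))
      write.table(res$metrics, p("node_metrics.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(res$layer_metrics))
      write.table(res$layer_metrics, p("layer_metrics.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    res$paths <- list.files(out_dir, full.names = TRUE)
  }
  invisible(res)
}
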