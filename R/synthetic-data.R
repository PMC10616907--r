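#' The 16 cortical region-group labels
#'
#' Eight circumferential categories per hemisphere: occipital dorsal (OD),
#' dorsal (D), frontal dorsal (FD), frontal (F), frontal ventral (FV),
#' ventral (V), occipital ventral (OV) and occipital (O), prefixed by
#' hemisphere (L/R).
#'
#' @return character vector of 16 labels.
#' @export
region_groups <- function() {
  as.vector(outer(c("L", "R"),
                  c("OD", "D", "FD", "F", "FV", "V", "OV", "O"),
                  paste0))
}

#' Simulation configuration for synthetic spiking networks
#'
#' Parameters emulate acute-slice recordings on a 2.0 x 4.0 mm
#' multielectrode array: sparse directed synaptic connectivity near 3%
#' density, Dale-conforming excitatory/inhibitory senders, integer synaptic
#' delays of a few milliseconds, and baseline rates in the 0.1-10 Hz range.
#' Coupling gains are on the logit scale of the Bernoulli-GLM dynamics
#' used by [simulate_spikes()]; inhibitory gain defaults higher than
#' excitatory because suppressing an already-rare event leaves a much
#' fainter information trace than eliciting one.
#'
#' @param n_neurons number of neurons.
#' @param frac_inhibitory fraction of inhibitory senders in `[0, 1]`.
#' @param connection_density edge probability for each ordered pair.
#' @param weight_scale_exc,weight_scale_inh positive coupling gains
#'   (logit units); per-edge weights are the gain times a log-normal
#'   multiplier, mirroring the roughly logarithmic weight distributions of
#'   real effective networks.
#' @param delay_range_ms integer delay interval, within `[1, 10]` ms so
#'   every causal lag sits inside the 30 ms TE window.
#' @param baseline_rate_hz length-2 range for excitatory neurons;
#'   per-neuron baselines are drawn log-uniformly between the bounds.
#' @param baseline_rate_hz_inh length-2 range for inhibitory neurons;
#'   defaults higher than the excitatory range, emulating the elevated
#'   firing of fast-spiking interneurons relative to pyramidal cells.
#' @param duration_ms recording length (>= 1000 except for the degenerate
#'   zero-duration raster).
#' @param seed RNG seed.
#' @param region_group one of [region_groups()].
#' @param layer_profile list with `peaks_um`, `widths_um`, `amplitudes`
#'   (three each, for the layer 3/4/6 density peaks) and `thickness_um`.
#' @return a validated `simulation_config`.
#' @export
simulation_config <- function(n_neurons = 100, frac_inhibitory = 0.2,
                              connection_density = 0.03,
                              weight_scale_exc = 2, weight_scale_inh = 6,
                              delay_range_ms = c(1, 10),
                              baseline_rate_hz = c(0.5, 4),
                              baseline_rate_hz_inh = c(4, 10),
                              duration_ms = 9000000, seed = 1L,
                              region_group = "LF",
                              layer_profile = list(
                                peaks_um = c(300, 550, 900),
                                widths_um = c(80, 70, 120),
                                amplitudes = c(1, 0.8, 0.9),
                                thickness_um = 1100)) {
  stopifnot(n_neurons >= 1, frac_inhibitory >= 0, frac_inhibitory <= 1,
            connection_density >= 0, connection_density <= 1,
            weight_scale_exc > 0, weight_scale_inh > 0)
  delay_range_ms <- as.integer(delay_range_ms)
  if (length(delay_range_ms) != 2 || delay_range_ms[1] < 1 ||
      delay_range_ms[2] > 10 || delay_range_ms[1] > delay_range_ms[2])
    stop("delay_range_ms must be an integer interval within [1, 10]")
  if (length(baseline_rate_hz) == 1)
    baseline_rate_hz <- rep(baseline_rate_hz, 2)
  if (length(baseline_rate_hz_inh) == 1)
    baseline_rate_hz_inh <- rep(baseline_rate_hz_inh, 2)
  if (any(c(baseline_rate_hz, baseline_rate_hz_inh) <= 0))
    stop("baseline rates must be positive")
  if (duration_ms != 0 && duration_ms < 1000)
    stop("duration_ms must be at least 1000 (or 0 for an empty raster)")
  if (!region_group %in% region_groups()) stop("unknown region group")
  structure(list(n_neurons = as.integer(n_neurons),
                 frac_inhibitory = frac_inhibitory,
                 connection_density = connection_density,
                 weight_scale_exc = weight_scale_exc,
                 weight_scale_inh = weight_scale_inh,
                 delay_range_ms = delay_range_ms,
                 baseline_rate_hz = baseline_rate_hz,
                 baseline_rate_hz_inh = baseline_rate_hz_inh,
                 duration_ms = as.integer(duration_ms), bin_ms = 1,
                 seed = as.integer(seed), region_group = region_group,
                 layer_profile = layer_profile),
            class = "simulation_config")
}

#' Depth-density profile of the simulated cortical sheet
#'
#' A three-Gaussian mixture over cortical depth with density peaks at the
#' centers of layers 3, 4 and 6 -- the landmark structure the
#' layer-boundary rules expect. Depth is binned at 10 um.
#'
#' @param config a [simulation_config()] (only `layer_profile` is used).
#' @return a `layer_profile` list with `depth_um` (bin centers), `density`
#'   (nonnegative), and the generating parameters.
#' @export
make_layer_profile <- function(config) {
  lp <- config$layer_profile
  if (any(lp$amplitudes <= 0)) stop("profile amplitudes must be positive")
  if (is.unsorted(lp$peaks_um, strictly = TRUE))
    stop("peak depths must be three distinct increasing values")
  if (length(lp$peaks_um) != 3) stop("exactly three peaks required")
  depth <- seq(5, lp$thickness_um - 5, by = 10)
  dens <- rowSums(vapply(1:3, function(k) {
    lp$amplitudes[k] * exp(-0.5 * ((depth - lp$peaks_um[k]) / lp$widths_um[k])^2)
  }, numeric(length(depth))))
  prof <- structure(list(depth_um = depth, density = dens,
                         thickness_um = lp$thickness_um, params = lp),
                    class = "layer_profile")
  lm <- tryCatch(find_landmarks(prof, smooth = 1), error = function(e) e)
  if (inherits(lm, "error"))
    stop("profile parameters do not produce three separated peaks: ",
         conditionMessage(lm))
  prof
}

#' Simulate ground-truth network structure
#'
#' Draws a directed Erdos-Renyi-style adjacency at the configured density
#' (no self-edges), assigns exactly `round(n * frac_inhibitory)` neurons as
#' inhibitory senders so every out-edge of a neuron shares its sign
#' (Dale's principle), and equips each edge with an integer delay and a
#' positive weight. Neuron positions are placed on the 2.0 x 4.0 mm array
#' sheet with depths sampled from the layer profile and layer labels
#' derived from its boundary rules.
#'
#' @param config a [simulation_config()].
#' @return a `ground_truth` list: `adjacency` (logical n x n, sender in
#'   rows), `signs` (per-neuron "excitatory"/"inhibitory"), `delays_ms`
#'   and `weights` (matrices, nonzero on edges), `neuron_table`, and the
#'   `layer_profile` used.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_neurons
  set.seed(config$seed)
  ids <- sprintf("n%03d", seq_len(n))
  n_inh <- round(n * config$frac_inhibitory)
  signs <- rep("excitatory", n)
  if (n_inh > 0) signs[sample.int(n, n_inh)] <- "inhibitory"

  adj <- matrix(runif(n * n) < config$connection_density, n, n,
                dimnames = list(ids, ids))
  diag(adj) <- FALSE
  m <- sum(adj)
  delays <- matrix(0L, n, n, dimnames = list(ids, ids))
  weights <- matrix(0, n, n, dimnames = list(ids, ids))
  if (m > 0) {
    dvals <- seq(config$delay_range_ms[1], config$delay_range_ms[2])
    delays[adj] <- if (length(dvals) == 1) rep(dvals, m) else
      sample(dvals, m, replace = TRUE)
    scale <- ifelse(signs[row(adj)[adj]] == "excitatory",
                    config$weight_scale_exc, config$weight_scale_inh)
    weights[adj] <- scale * exp(rnorm(m, 0, 0.3))
  }

  prof <- make_layer_profile(config)
  lb <- layer_boundaries(find_landmarks(prof, smooth = 1),
                         bottom = prof$thickness_um)
  # depth sampled from the mixture, truncated to the cortex
  depth <- numeric(n)
  for (k in seq_len(n)) {
    repeat {
      comp <- sample.int(3, 1, prob = config$layer_profile$amplitudes *
                           config$layer_profile$widths_um)
      d <- rnorm(1, config$layer_profile$peaks_um[comp],
                 config$layer_profile$widths_um[comp])
      if (d >= 0 && d <= prof$thickness_um) { depth[k] <- d; break }
    }
  }
  rr_e <- config$baseline_rate_hz
  rr_i <- config$baseline_rate_hz_inh
  lograte <- ifelse(signs == "excitatory",
                    runif(n, log(rr_e[1]), log(rr_e[2])),
                    runif(n, log(rr_i[1]), log(rr_i[2])))
  tab <- data.frame(neuron_id = ids,
                    x_um = runif(n, 0, 4000),
                    y_um = depth,
                    depth_um = depth,
                    region_group = config$region_group,
                    hemisphere = substr(config$region_group, 1, 1),
                    baseline_hz = exp(lograte),
                    firing_rate_hz = NA_real_,
                    ei_label = signs,
                    stringsAsFactors = FALSE)
  tab <- assign_layers(tab, lb)
  structure(list(adjacency = adj, signs = setNames(signs, ids),
                 delays_ms = delays, weights = weights,
                 neuron_table = tab, layer_profile = prof,
                 boundaries = lb, config = config),
            class = "ground_truth")
}

#' Simulate a spike raster from ground-truth structure
#'
#' Discrete-time Bernoulli-GLM dynamics at 1 ms resolution: neuron i
#' spikes at bin t with probability
#' `logistic(b_i + sum_j s_j w_ji x_j(t - d_ji))`, where `b_i` is the
#' logit of the baseline rate per bin, `s_j` is +1 for excitatory and -1
#' for inhibitory senders, and a 2 ms absolute refractory period prevents
#' degenerate bursting. This yields millisecond-lagged causal structure
#' that delay-resolved TE can detect, at a small computational cost.
#'
#' @param truth a `ground_truth` from [simulate_network()].
#' @param config the matching [simulation_config()].
#' @return a [spike_raster()]; the truth's `neuron_table$firing_rate_hz`
#'   is not modified (use [firing_rates()]). Warns about runaway
#'   excitation if any neuron exceeds 0.5 spikes per bin.
#' @export
simulate_spikes <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- config$n_neurons
  T_bins <- config$duration_ms
  if (T_bins == 0)
    return(spike_raster(rep(list(integer()), n), 0,
                        neuron_ids = truth$neuron_table$neuron_id))
  if (max(truth$delays_ms) >= T_bins) stop("delays must be shorter than duration")
  adj <- truth$adjacency
  e_src <- row(adj)[adj] - 1L
  e_tgt <- col(adj)[adj] - 1L
  e_delay <- truth$delays_ms[adj]
  sgn <- ifelse(truth$signs == "excitatory", 1, -1)
  e_w <- sgn[e_src + 1L] * truth$weights[adj]
  b <- qlogis(truth$neuron_table$baseline_hz / 1000)
  set.seed(config$seed + 1L)
  sp <- simulate_spikes_cpp(n, T_bins, b, as.integer(e_src),
                            as.integer(e_tgt), as.integer(e_delay),
                            as.numeric(e_w), refractory = 2L)
  raster <- spike_raster(lapply(sp, function(s) s + 1L), T_bins,
                         neuron_ids = truth$neuron_table$neuron_id)
  per_bin <- lengths(raster$spikes) / T_bins
  if (any(per_bin > 0.5))
    warning(sprintf("runaway excitation: %d neuron(s) above 0.5 spikes/bin",
                    sum(per_bin > 0.5)))
  raster
}
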