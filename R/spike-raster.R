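#' Binned binary spike raster
#'
#' A sparse container for a neurons-by-time binary spike matrix at fixed
#' 1 ms resolution. Spikes are stored as per-neuron vectors of 1-based bin
#' indices, which keeps multi-hour recordings of hundreds of neurons cheap
#' to hold in memory.
#'
#' @param spikes list of integer vectors, one per neuron, each holding the
#'   1-based bin indices at which that neuron spiked.
#' @param n_bins total number of time bins in the recording.
#' @param neuron_ids optional character ids; defaults to `n1..nN`.
#' @param bin_ms bin width in milliseconds; fixed at 1 for this analysis.
#' @return an object of class `spike_raster`.
#' @export
spike_raster <- function(spikes, n_bins, neuron_ids = NULL, bin_ms = 1) {
  stopifnot(is.list(spikes), n_bins >= 0)
  if (bin_ms != 1) stop("bin_ms is fixed at 1 ms")
  spikes <- unname(lapply(spikes, function(s) {
    s <- sort(unique(as.integer(s)))
    if (length(s) && (s[1] < 1L || s[length(s)] > n_bins))
      stop("spike bin outside [1, n_bins]")
    s
  }))
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_along(spikes))
  if (length(neuron_ids) != length(spikes)) stop("neuron_ids length mismatch")
  structure(list(spikes = spikes, n_bins = as.integer(n_bins),
                 neuron_ids = as.character(neuron_ids), bin_ms = 1),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d neurons x %d bins (%.1f s), %d spikes\n",
              length(x$spikes), x$n_bins, x$n_bins / 1000,
              sum(lengths(x$spikes))))
  invisible(x)
}

#' Number of neurons in a raster
#' @param raster a `spike_raster`.
#' @return integer count.
#' @export
n_neurons <- function(raster) length(raster$spikes)

#' Dense binary matrix view of a raster
#'
#' Intended for small rasters (tests, examples); a 2.5 h recording should
#' stay in sparse form.
#'
#' @param x a `spike_raster`.
#' @param ... unused.
#' @return integer matrix `[n_neurons x n_bins]` with entries in \{0, 1\}.
#' @export
as.matrix.spike_raster <- function(x, ...) {
  m <- matrix(0L, length(x$spikes), x$n_bins,
              dimnames = list(x$neuron_ids, NULL))
  for (i in seq_along(x$spikes)) m[i, x$spikes[[i]]] <- 1L
  m
}

#' Build a raster from a dense binary matrix
#' @param m binary matrix, neurons in rows.
#' @param neuron_ids optional ids (defaults to rownames).
#' @return a `spike_raster`.
#' @export
raster_from_matrix <- function(m, neuron_ids = rownames(m)) {
  if (!all(m %in% c(0, 1))) stop("raster entries must be 0/1")
  spike_raster(apply(m, 1, function(r) which(r == 1), simplify = FALSE),
               ncol(m), neuron_ids = neuron_ids)
}

#' Per-neuron firing rates
#'
#' @param raster a `spike_raster`.
#' @param per either "s" for Hz (spikes per second) or "bin" for spikes per
#'   1 ms bin (the probability scale used by the TE normalization).
#' @return named numeric vector.
#' @export
firing_rates <- function(raster, per = c("s", "bin")) {
  per <- match.arg(per)
  if (raster$n_bins == 0) stop("raster has zero duration")
  r <- lengths(raster$spikes) / raster$n_bins
  r <- if (per == "s") r * 1000 else r
  setNames(r, raster$neuron_ids)
}
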