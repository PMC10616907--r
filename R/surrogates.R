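#' Jitter-shuffled surrogate raster
#'
#' Builds a null raster by relocating every spike of every neuron uniformly
#' among bins within +/- `window` ms that were spike-free in the *original*
#' series. Per-neuron spike counts are preserved exactly; millisecond-scale
#' timing relationships between neurons are destroyed while firing rates
#' and slow rate fluctuations survive. Spikes are relocated one at a time
#' in temporal order; destination collisions are resolved by resampling
#' among the remaining free bins, and a spike with no admissible
#' destination stays put (counted in the `fallback` attribute).
#'
#' Uses the current R RNG state; call `set.seed()` for reproducibility.
#'
#' @param raster a [spike_raster()].
#' @param window maximum displacement in bins (default 10, i.e. +/- 10 ms).
#' @return a `spike_raster` with attribute `fallback` (per-neuron counts of
#'   spikes that could not move).
#' @export
shuffle_raster <- function(raster, window = 10) {
  stopifnot(inherits(raster, "spike_raster"))
  out <- vector("list", n_neurons(raster))
  fb <- integer(n_neurons(raster))
  for (k in seq_along(out)) {
    r <- shuffle_times_cpp(raster$spikes[[k]] - 1L, raster$n_bins,
                           as.integer(window))
    out[[k]] <- r$times + 1L
    fb[k] <- r$fallback
  }
  res <- spike_raster(out, raster$n_bins, neuron_ids = raster$neuron_ids)
  attr(res, "fallback") <- setNames(fb, raster$neuron_ids)
  res
}

#' Surrogate ensemble of pairwise TE profiles
#'
#' Generates `n_surrogates` jitter-shuffled rasters and, for each, computes
#' pairwise TE profiles with the *shuffled* series as senders and the
#' *original* series as receivers (only presynaptic spikes are jittered in
#' the null). For every ordered pair the ensemble records the surrogate
#' Strength, Sharpness, and the surrogate TE evaluated at the real pair's
#' peak delay, which is what the connection-weight definition needs.
#'
#' @param raster a [spike_raster()].
#' @param real a `pairwise_profiles` object from [all_pairs_profiles()] on
#'   the same raster (supplies the real peak delays).
#' @param n_surrogates ensemble size (default 100; 10 is adequate for
#'   quick runs).
#' @param window jitter window in bins (default 10).
#' @param seed integer seed; one sub-seed per surrogate is drawn from it
#'   and kept in the returned seed ledger.
#' @return a `surrogate_ensemble` list with arrays `strength`, `sharpness`,
#'   `te_at_real_peak` of dim `c(n, n, n_surrogates)`, the seed ledger, and
#'   per-surrogate fallback counts.
#' @export
surrogate_ensemble <- function(raster, real, n_surrogates = 100, window = 10,
                               seed = 1L) {
  stopifnot(inherits(raster, "spike_raster"),
            inherits(real, "pairwise_profiles"), n_surrogates >= 1)
  n <- n_neurons(raster)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_surrogates)
  strength <- array(NA_real_, c(n, n, n_surrogates))
  sharp <- array(NA_real_, c(n, n, n_surrogates))
  te_at <- array(NA_real_, c(n, n, n_surrogates))
  fallback <- integer(n_surrogates)
  idx <- cbind(rep(seq_len(n), n), rep(seq_len(n), each = n))
  dp <- real$d_peak
  ok <- !is.na(dp)
  for (s in seq_len(n_surrogates)) {
    set.seed(sub_seeds[s])
    shuf <- shuffle_raster(raster, window = window)
    fallback[s] <- sum(attr(shuf, "fallback"))
    prof <- all_pairs_profiles(raster, d_max = real$d_max, tau = real$tau,
                               source_raster = shuf)
    strength[, , s] <- prof$strength
    sharp[, , s] <- prof$sharpness
    m <- matrix(NA_real_, n, n)
    sel <- cbind(idx[ok, , drop = FALSE], dp[ok] + 1L)
    m[ok] <- prof$te[sel]
    te_at[, , s] <- m
  }
  structure(list(strength = strength, sharpness = sharp,
                 te_at_real_peak = te_at, n_surrogates = n_surrogates,
                 window = window, seeds = sub_seeds, fallback = fallback,
                 neuron_ids = raster$neuron_ids),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble> %d surrogates, %d neurons, window +/-%d bins\n",
              x$n_surrogates, length(x$neuron_ids), x$window))
  invisible(x)
}

#' Connection weight against the surrogate null
#'
#' The information-theoretic connection weight of an ordered pair is the
#' real peak TE minus the surrogate expectation at the same delay:
#' \deqn{IT_{j\to i} = TE^{real}_{j\to i} - \overline{TE^{shuffle}_{j\to i}}}
#' The surrogate summary is the ensemble mean by default (median
#' available). Negative values can occur for non-connections and are
#' discarded when edges are formed.
#'
#' @param te_real_peak real TE at the peak delay (scalar or matrix).
#' @param te_shuffle_peaks numeric vector of surrogate TE values at the
#'   real peak delay (or an array whose last dimension indexes surrogates
#'   when `te_real_peak` is a matrix).
#' @param summary "mean" (default) or "median".
#' @return weight(s) on the same shape as `te_real_peak`.
#' @export
connection_weight <- function(te_real_peak, te_shuffle_peaks,
                              summary = c("mean", "median")) {
  summary <- match.arg(summary)
  if (is.array(te_shuffle_peaks) && length(dim(te_shuffle_peaks)) == 3) {
    f <- if (summary == "mean") mean else median
    null <- apply(te_shuffle_peaks, c(1, 2), f)
  } else {
    if (length(te_shuffle_peaks) < 1 || anyNA(te_shuffle_peaks))
      stop("surrogate values missing")
    null <- if (summary == "mean") mean(te_shuffle_peaks) else
      median(te_shuffle_peaks)
  }
  te_real_peak - null
}
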