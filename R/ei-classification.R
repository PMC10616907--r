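#' Per-neuron E/I classification features
#'
#' For each *sending* neuron, ranks its outgoing E-I bias values (SLTE at
#' the TE-peak delay) by absolute value, drops the bottom 10% (floor of
#' 0.1 x count, per sender) as a signal-to-noise filter, and sums the rest
#' into an `ei_score`. Ties in |E-I bias| are broken by the firing-rate
#' normalized peak TE of the pair, so that among equally biased pairs the
#' least informative is discarded first. The score is paired with the log
#' firing rate (per bin), giving the two-dimensional feature space used
#' for clustering.
#'
#' @param pairwise a `pairwise_profiles` object.
#' @param rates per-neuron firing rate per bin, in (0, 1), named or in
#'   raster order (see [firing_rates()] with `per = "bin"`).
#' @return data frame with columns `neuron_id`, `ei_score`, `log_fr`,
#'   `retained_count`. Senders without any usable outgoing pair (all
#'   no-signal) are dropped with a warning, as are silent neurons.
#' @export
ei_features <- function(pairwise, rates) {
  stopifnot(inherits(pairwise, "pairwise_profiles"))
  ids <- pairwise$neuron_ids
  n <- length(ids)
  if (length(rates) != n) stop("one rate per neuron required")
  te_nor <- pairwise$strength /
    abs(rep(rates, each = n) * log(rep(rates, each = n)) +
        (1 - rep(rates, each = n)) * log1p(-rep(rates, each = n)))
  rows <- lapply(seq_len(n), function(jj) {
    bias <- pairwise$ei_bias[jj, ]
    tn <- te_nor[jj, ]
    keep <- !is.na(bias)
    bias <- bias[keep]; tn <- tn[keep]
    if (length(bias) == 0 || rates[jj] <= 0 || rates[jj] >= 1) return(NULL)
    drop_n <- floor(0.1 * length(bias))
    ord <- order(abs(bias), tn)   # weakest |bias| first, low TE_nor first on ties
    kept <- ord[seq_along(ord) > drop_n]
    data.frame(neuron_id = ids[jj], ei_score = sum(bias[kept]),
               log_fr = log(rates[jj]), retained_count = length(kept))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(sprintf("%d neuron(s) excluded from E/I features (silent or no usable outgoing pair)",
                    dropped))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no neuron has usable E/I features")
  rownames(out) <- NULL
  out
}

#' Cluster neurons into excitatory and inhibitory classes
#'
#' Standardizes the (`ei_score`, `log_fr`) feature plane and applies
#' Ward-linkage hierarchical clustering. The tree is cut at `k` clusters
#' (default 4) rather than 2 so that the heavy upper tail of excitatory
#' scores -- senders with many or strong outgoing synapses -- separates
#' into its own cluster instead of hijacking the main split. Each cluster
#' is then labeled by the side of zero its mean raw `ei_score` falls on,
#' the sign structure Dale's principle predicts for SLTE sums:
#' positive-mean clusters are excitatory, negative-mean inhibitory.
#'
#' When every cluster mean falls on the same side of zero, the extreme
#' cluster nearest zero is still assigned the opposite class if its mean
#' is well separated from the rest (below `margin` times the median of
#' the other cluster means) -- this absorbs the small positive shift that
#' network-wide common drive adds to every score. Otherwise all neurons
#' receive the common side's label with a warning. A further warning is
#' raised when the excitatory side is not also the more common one.
#'
#' @param features data frame from [ei_features()].
#' @param k number of Ward clusters to cut (>= 2).
#' @param margin relative separation required to split off an
#'   opposite-class cluster when all means share a sign (default 0.25).
#' @return named character vector of labels ("excitatory"/"inhibitory"),
#'   one per feature row, with a `report` attribute (cluster sizes, means,
#'   warnings raised).
#' @export
classify_ei <- function(features, k = 4, margin = 0.25) {
  stopifnot(all(c("neuron_id", "ei_score", "log_fr") %in% names(features)))
  if (nrow(features) < 4) stop("need at least 4 neurons with features")
  k <- min(k, nrow(features) - 1)
  x <- cbind(features$ei_score, features$log_fr)
  if (all(apply(x, 2, sd) == 0)) stop("all features identical; clustering impossible")
  z <- apply(x, 2, function(col) {
    s <- sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  cl <- cutree(hclust(dist(z), method = "ward.D2"), k = k)
  means <- tapply(features$ei_score, cl, mean)
  sizes <- table(cl)
  warns <- character()
  cl_side <- ifelse(means > 0, "excitatory", "inhibitory")
  if (all(means > 0)) {
    low <- which.min(means)
    if (means[low] < margin * median(means[-low])) {
      cl_side[low] <- "inhibitory"
    } else {
      warns <- c(warns, "all cluster means on the positive side; every neuron labeled excitatory")
    }
  } else if (all(means <= 0)) {
    high <- which.max(means)
    if (abs(means[high]) < margin * abs(median(means[-high]))) {
      cl_side[high] <- "excitatory"
    } else {
      cl_side[] <- "inhibitory"
      warns <- c(warns, "all cluster means on the negative side; every neuron labeled inhibitory")
    }
  }
  labels <- as.character(cl_side[as.character(cl)])
  n_exc <- sum(labels == "excitatory")
  if (n_exc > 0 && n_exc < length(labels) / 2)
    warns <- c(warns, "excitatory side is not the more common one; sign rule applied over commonality")
  for (w in warns) warning(w)
  structure(setNames(labels, features$neuron_id),
            report = list(k = k, cluster_sizes = as.integer(sizes),
                          cluster_mean_ei_score = as.numeric(means),
                          warnings = warns))
}
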