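#' Configuration for surrogate-based connection detection
#'
#' Connections are accepted where real pairs outnumber surrogate
#' expectation on a grid over the (log10 Strength) x Sharpness plane,
#' separately within each of the four E/I connection categories. The grid
#' and excess-ratio defaults were calibrated so that the default simulated
#' recording yields network densities in the low-percent range.
#'
#' @param grid_bins bins per axis (default 20).
#' @param excess_ratio how many times the surrogate expectation the real
#'   cell count must reach for acceptance (default 3, must exceed 1).
#' @param min_count minimum real pairs in an accepted cell (default 1).
#' @return a `detection_config` list.
#' @export
detection_config <- function(grid_bins = 20, excess_ratio = 3, min_count = 1) {
  if (grid_bins < 4) stop("grid_bins must be at least 4 per axis")
  if (excess_ratio <= 1) stop("excess_ratio must exceed 1")
  structure(list(grid_bins = as.integer(grid_bins),
                 excess_ratio = excess_ratio,
                 min_count = as.integer(min_count)),
            class = "detection_config")
}

.cell_index <- function(x, breaks) {
  i <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  i
}

#' Detect connections and build the effective network
#'
#' Implements the final estimation step: ordered pairs are split into the
#' four sender-class x receiver-class categories (EE, EI, IE, II), and
#' within each category the 2D histogram of real pairs on the
#' log10(Strength) x Sharpness plane is compared cell-by-cell with the
#' surrogate histogram scaled by 1/n_surrogates. Cells where the real
#' count reaches `excess_ratio` times the surrogate expectation are
#' accepted; pairs in accepted cells become directed edges weighted by
#' `IT = TE_real(d_peak) - mean TE_shuffle(d_peak)`, and edges with
#' nonpositive weight are dropped. Pairs with no TE signal are never
#' edges.
#'
#' @param real `pairwise_profiles` of the recording.
#' @param ensemble `surrogate_ensemble` for the same recording.
#' @param labels named character vector of "excitatory"/"inhibitory"
#'   neuron labels (neurons missing a label are excluded from edges).
#' @param config a [detection_config()].
#' @param neuron_table optional per-neuron metadata data frame (must carry
#'   a `neuron_id` column); stored as the node table.
#' @return an `effective_network` with `nodes` (data frame) and `edges`
#'   (data frame: src, dst, weight, strength, sharpness, d_peak,
#'   category), plus the per-category acceptance maps for audit.
#' @export
detect_connections <- function(real, ensemble, labels,
                               config = detection_config(),
                               neuron_table = NULL) {
  stopifnot(inherits(real, "pairwise_profiles"),
            inherits(ensemble, "surrogate_ensemble"))
  ids <- real$neuron_ids
  n <- length(ids)
  S <- ensemble$n_surrogates
  lab <- labels[ids]
  cls <- ifelse(is.na(lab), NA,
                ifelse(lab == "excitatory", "E", "I"))
  src_i <- rep(seq_len(n), n)          # column-major pair layout
  dst_i <- rep(seq_len(n), each = n)
  off <- src_i != dst_i
  cat_of <- function(s, d) paste0(cls[s], cls[d])

  real_x <- log10(real$strength)
  real_y <- real$sharpness
  surr_x <- log10(ensemble$strength)
  surr_y <- ensemble$sharpness
  usable <- off & !is.na(real_x) & is.finite(real_x) & !is.na(real_y) &
    !is.na(cls[src_i]) & !is.na(cls[dst_i])

  # common grid over the pooled finite range so real and surrogate
  # histograms are comparable
  fin <- c(real_x[usable], surr_x[is.finite(surr_x)])
  if (length(fin) == 0) {
    edges <- data.frame(src = character(), dst = character(),
                        weight = numeric(), strength = numeric(),
                        sharpness = numeric(), d_peak = integer(),
                        category = character())
    return(.effective_network(ids, lab, edges, neuron_table, list()))
  }
  xb <- seq(min(fin), max(fin), length.out = config$grid_bins + 1)
  yb <- seq(0, 1, length.out = config$grid_bins + 1)

  null_mean <- apply(ensemble$te_at_real_peak, c(1, 2), mean)
  it <- real$strength - null_mean

  maps <- list()
  keep <- logical(n * n)
  for (cat in c("EE", "EI", "IE", "II")) {
    in_cat <- usable & cat_of(src_i, dst_i) == cat
    in_cat[is.na(in_cat)] <- FALSE
    if (!any(in_cat)) { maps[[cat]] <- NULL; next }
    gb <- config$grid_bins
    rx <- .cell_index(real_x[in_cat], xb)
    ry <- .cell_index(real_y[in_cat], yb)
    real_h <- matrix(tabulate(rx + (ry - 1L) * gb, gb * gb), gb, gb)
    surr_h <- matrix(0, gb, gb)
    surr_max <- matrix(0, gb, gb)
    cat_mask <- matrix(in_cat, n, n)
    for (s in seq_len(S)) {
      sx <- surr_x[, , s][cat_mask]
      sy <- surr_y[, , s][cat_mask]
      ok <- is.finite(sx) & !is.na(sy)
      if (!any(ok)) next
      cx <- .cell_index(sx[ok], xb)
      cy <- .cell_index(sy[ok], yb)
      h <- matrix(tabulate(cx + (cy - 1L) * gb, gb * gb), gb, gb)
      surr_h <- surr_h + h
      surr_max <- pmax(surr_max, h)
    }
    expected <- surr_h / S
    # the strict max guard makes sparse cells honest: one real pair in a
    # cell the surrogates also reach occasionally must beat every single
    # surrogate, not just their diluted mean
    accepted <- real_h >= config$excess_ratio * expected &
      real_h > surr_max &
      real_h >= config$min_count
    maps[[cat]] <- list(real = real_h, expected = expected,
                        accepted = accepted)
    pair_ids <- which(in_cat)
    acc_pair <- accepted[cbind(rx, ry)]
    keep[pair_ids[acc_pair]] <- TRUE
  }
  keep <- keep & it > 0 & !is.na(it)
  ke <- which(keep)
  edges <- data.frame(src = ids[src_i[ke]], dst = ids[dst_i[ke]],
                      weight = it[ke], strength = real$strength[ke],
                      sharpness = real$sharpness[ke],
                      d_peak = real$d_peak[ke],
                      category = cat_of(src_i[ke], dst_i[ke]),
                      stringsAsFactors = FALSE)
  .effective_network(ids, lab, edges, neuron_table, maps)
}

.effective_network <- function(ids, labels, edges, neuron_table, maps) {
  nodes <- data.frame(neuron_id = ids,
                      ei_label = ifelse(is.na(labels), "unknown",
                                        as.character(labels)),
                      stringsAsFactors = FALSE)
  if (!is.null(neuron_table)) {
    extra <- neuron_table[match(ids, neuron_table$neuron_id),
                          setdiff(names(neuron_table), c("neuron_id", "ei_label")),
                          drop = FALSE]
    nodes <- cbind(nodes, extra)
    rownames(nodes) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, acceptance_maps = maps),
            class = "effective_network")
}

#' @export
print.effective_network <- function(x, ...) {
  n <- nrow(x$nodes)
  cat(sprintf("<effective_network> %d nodes, %d edges (density %.3f%%)\n",
              n, nrow(x$edges),
              if (n > 1) 100 * nrow(x$edges) / (n * (n - 1)) else NA))
  invisible(x)
}

#' Network density summarized across recordings
#'
#' Per-recording connection probability is the number of accepted edges
#' over the number of ordered pairs, n(n-1); across recordings it is
#' summarized as a median and standard deviation, the form in which slice
#' connection probabilities are conventionally reported.
#'
#' @param networks a single `effective_network` or a list of them.
#' @return list with `densities`, `median`, and `sd`.
#' @export
connection_probability <- function(networks) {
  if (inherits(networks, "effective_network")) networks <- list(networks)
  dens <- vapply(networks, function(net) {
    n <- nrow(net$nodes)
    if (n < 2) stop("network with fewer than 2 nodes")
    nrow(net$edges) / (n * (n - 1))
  }, numeric(1))
  list(densities = dens, median = median(dens),
       sd = if (length(dens) > 1) sd(dens) else 0)
}

#' Convert an effective network to an igraph graph
#' @param network an `effective_network`.
#' @return a directed, weighted `igraph` graph with `ei_label` vertex
#'   attribute.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "effective_network"))
  g <- igraph::graph_from_data_frame(network$edges[, c("src", "dst")],
                                     directed = TRUE,
                                     vertices = network$nodes)
  if (nrow(network$edges) > 0)
    igraph::E(g)$weight <- network$edges$weight
  g
}
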