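#' Interlayer mean connection-weight matrix
#'
#' Averages edge weights by (sender layer, receiver layer) over layers
#' 2-6, the per-recording matrix underlying interlayer group comparisons.
#'
#' @param network an `effective_network` whose node table carries `layer`.
#' @return 5 x 5 matrix (rows = sender layer 2-6, cols = receiver layer),
#'   `NA` where a layer pair has no edges.
#' @export
interlayer_weights <- function(network) {
  stopifnot(inherits(network, "effective_network"),
            "layer" %in% names(network$nodes))
  lay <- setNames(network$nodes$layer, network$nodes$neuron_id)
  e <- network$edges
  out <- matrix(NA_real_, 5, 5, dimnames = list(paste0("L", 2:6), paste0("L", 2:6)))
  if (nrow(e) == 0) return(out)
  sl <- lay[e$src]; rl <- lay[e$dst]
  ok <- !is.na(sl) & !is.na(rl) & sl >= 2 & rl >= 2
  if (!any(ok)) return(out)
  agg <- tapply(e$weight[ok], list(factor(sl[ok], 2:6), factor(rl[ok], 2:6)),
                mean)
  out[] <- agg
  out
}

#' Aggregate a metric over the 16 region groups
#'
#' Group means with the raw per-recording values retained, the form used
#' for radar-chart style summaries across the circumferential region
#' categories.
#'
#' @param table data frame with at least `region_group`, `metric`, `value`.
#' @param metric metric name to aggregate.
#' @return list with `means` (data frame region_group/mean/n, all 16
#'   groups, `NA` where empty) and `raw` (the selected rows).
#' @export
radar_aggregate <- function(table, metric) {
  stopifnot(all(c("region_group", "metric", "value") %in% names(table)))
  raw <- table[table$metric == metric, ]
  groups <- region_groups()
  means <- data.frame(region_group = groups,
                      mean = vapply(groups, function(g) {
                        v <- raw$value[raw$region_group == g]
                        if (length(v)) mean(v) else NA_real_
                      }, numeric(1)),
                      n = vapply(groups, function(g)
                        sum(raw$region_group == g), numeric(1)),
                      stringsAsFactors = FALSE)
  rownames(means) <- NULL
  list(means = means, raw = raw)
}

#' Mann-Whitney group comparison with Bonferroni correction
#'
#' Two-sided Mann-Whitney U test of the target sample against the
#' reference sample, with the p-value multiplied by `n_comparisons` and
#' capped at 1. The exact null distribution is used when both samples are
#' small (min n <= 8) and tie-free; otherwise the normal approximation
#' with tie correction. The effect size is the common-language effect size
#' (probability of superiority) `U / (n1 n2)`, counting ties as 1/2:
#' swapping the sample roles maps it to its complement.
#'
#' @param target,reference numeric samples.
#' @param n_comparisons Bonferroni multiplier (default 1).
#' @return list with `p_raw`, `p_corrected`, `effect_size`, `n` (c(n1, n2)).
#' @export
group_test <- function(target, reference, n_comparisons = 1) {
  target <- target[!is.na(target)]; reference <- reference[!is.na(reference)]
  if (length(target) == 0 || length(reference) == 0)
    stop("both samples must be nonempty")
  n1 <- length(target); n2 <- length(reference)
  gt <- sum(outer(target, reference, ">"))
  ties <- sum(outer(target, reference, "=="))
  if (ties == n1 * n2) {
    return(list(p_raw = 1, p_corrected = 1, effect_size = 0.5, n = c(n1, n2)))
  }
  exact <- min(n1, n2) <= 8 && ties == 0
  wt <- suppressWarnings(wilcox.test(target, reference, exact = exact,
                                     correct = !exact))
  p <- wt$p.value
  list(p_raw = p, p_corrected = min(1, p * n_comparisons),
       effect_size = (gt + 0.5 * ties) / (n1 * n2), n = c(n1, n2))
}

#' Per-cell permutation test on interlayer weight matrices
#'
#' Network-based-statistic style group comparison: for every layer x layer
#' cell, the observed two-sample t statistic between the recordings of
#' group A and group B is compared with its permutation null obtained by
#' shuffling group labels; `p = (1 + #{|t_perm| >= |t_obs|}) / (1 +
#' n_perm)` (add-one estimator, so p is never exactly zero). The effect
#' size is the difference in cell means, mean(A) - mean(B). Cells missing
#' in more than half of the recordings of either group are marked
#' untestable.
#'
#' @param group_a,group_b lists of 5 x 5 matrices from
#'   [interlayer_weights()] (>= 2 recordings each).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list of 5 x 5 matrices: `p`, `effect_size`, `t_obs`, and
#'   logical `testable`.
#' @export
nbs_interlayer <- function(group_a, group_b, n_perm = 10000, seed = 1L) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  a <- simplify2array(group_a)  # 5 x 5 x nA
  b <- simplify2array(group_b)
  nA <- dim(a)[3]; nB <- dim(b)[3]
  all_m <- array(c(a, b), c(5, 5, nA + nB))
  is_a <- c(rep(TRUE, nA), rep(FALSE, nB))
  testable <- apply(!is.na(a), c(1, 2), sum) >= nA / 2 &
    apply(!is.na(b), c(1, 2), sum) >= nB / 2
  flat <- matrix(all_m, 25, nA + nB)   # cells x recordings
  flat2 <- flat^2
  miss <- is.na(flat)
  tstat <- function(lab) {
    ka <- rowSums(!miss[, lab, drop = FALSE])
    kb <- rowSums(!miss[, !lab, drop = FALSE])
    sa <- rowSums(flat[, lab, drop = FALSE], na.rm = TRUE)
    sb <- rowSums(flat[, !lab, drop = FALSE], na.rm = TRUE)
    qa <- rowSums(flat2[, lab, drop = FALSE], na.rm = TRUE)
    qb <- rowSums(flat2[, !lab, drop = FALSE], na.rm = TRUE)
    ma <- sa / ka; mb <- sb / kb
    va <- (qa - ka * ma^2) / (ka - 1)
    vb <- (qb - kb * mb^2) / (kb - 1)
    (ma - mb) / sqrt(va / ka + vb / kb)
  }
  t_obs <- tstat(is_a)
  set.seed(seed)
  exceed <- rep(0, 25)
  for (pth in seq_len(n_perm)) {
    lab <- sample(is_a)
    tp <- tstat(lab)
    exceed <- exceed + as.numeric(!is.na(tp) & !is.na(t_obs) &
                                    abs(tp) >= abs(t_obs))
  }
  p <- (1 + exceed) / (1 + n_perm)
  p[is.na(t_obs)] <- NA_real_
  eff <- rowMeans(flat[, is_a, drop = FALSE], na.rm = TRUE) -
    rowMeans(flat[, !is_a, drop = FALSE], na.rm = TRUE)
  shape <- function(v) {
    m <- matrix(v, 5, 5, dimnames = list(paste0("L", 2:6), paste0("L", 2:6)))
    m[!testable] <- NA
    m
  }
  list(p = shape(p), effect_size = shape(eff), t_obs = shape(t_obs),
       testable = testable)
}

#' Frontal-versus-rest convenience contrast
#'
#' Runs [group_test()] with the frontal and frontal-ventral groups (LF,
#' LFV, RF, RFV) as the target and all other region groups as the
#' reference, for a metric in a long table. The layer-6 input/output
#' weight contrasts reported for effective networks are this test applied
#' to edge weights of edges leaving (or entering) layer 6.
#'
#' @param table long data frame with `region_group`, `metric`, `value`.
#' @param metric metric to test.
#' @param target_groups frontal side labels (default LF, LFV, RF, RFV).
#' @param n_comparisons Bonferroni multiplier.
#' @return [group_test()] result plus the group definitions.
#' @export
frontal_contrast <- function(table, metric,
                             target_groups = c("LF", "LFV", "RF", "RFV"),
                             n_comparisons = 1) {
  raw <- table[table$metric == metric, ]
  tgt <- raw$value[raw$region_group %in% target_groups]
  ref <- raw$value[!raw$region_group %in% target_groups]
  res <- group_test(tgt, ref, n_comparisons = n_comparisons)
  c(res, list(target_groups = target_groups,
              reference_groups = setdiff(region_groups(), target_groups)))
}
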