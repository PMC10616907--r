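#' Landmarks of a cortical depth-density profile
#'
#' After moving-average smoothing, locates the interior local maxima
#' ("convex points", expected at the centers of layers 3, 4 and 6) and the
#' local minima ("concave points") between consecutive maxima. Exactly
#' three maxima are required; a profile that smooths to any other count is
#' rejected with a structured error naming the count found.
#'
#' @param profile a `layer_profile` (list with `depth_um`, `density`) or a
#'   plain numeric density vector (depths default to the bin index).
#' @param smooth moving-average window in depth bins (default 5; 1
#'   disables smoothing).
#' @return list with `convex_um` (3 depths), `concave_um` (>= 2 depths),
#'   and `surface_um = 0`.
#' @export
find_landmarks <- function(profile, smooth = 5) {
  if (inherits(profile, "layer_profile")) {
    depth <- profile$depth_um; dens <- profile$density
  } else {
    dens <- as.numeric(profile); depth <- seq_along(dens)
  }
  if (length(dens) < 20) stop("profile must have at least 20 depth bins")
  if (any(dens < 0)) stop("profile density must be nonnegative")
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    sm <- as.numeric(stats::filter(dens, k, sides = 2))
    keep <- !is.na(sm)
    dens <- sm[keep]; depth <- depth[keep]
  }
  d1 <- diff(dens)
  s <- sign(d1)
  s[s == 0] <- 1   # plateaus break toward the earlier extremum
  turn <- diff(s)
  max_i <- which(turn < 0) + 1L
  min_i <- which(turn > 0) + 1L
  if (length(max_i) != 3)
    stop(sprintf("expected 3 density maxima, found %d", length(max_i)))
  concave <- vapply(1:2, function(k) {
    span <- seq(max_i[k], max_i[k + 1])
    depth[span[which.min(dens[span])]]
  }, numeric(1))
  list(convex_um = depth[max_i], concave_um = concave, surface_um = 0)
}

#' Layer boundaries from profile landmarks
#'
#' Applies the landmark rules to derive the five layer boundaries: L1/2 at
#' one third of the way from the surface to the first convex point; L2/3
#' at two thirds of the way to the first convex point; L3/4 at the concave
#' point between the first and second convex points; L4/5 at the midpoint
#' of the second convex and second concave points; and L5/6 at the
#' midpoint of the second concave and third convex points. Two documented
#' alternatives reproduce the literal variants of the L2/3 and L5/6 rules
#' (see `rule_l23`, `rule_l56`).
#'
#' @param landmarks output of [find_landmarks()].
#' @param surface cortical surface depth (default 0).
#' @param bottom cortical bottom depth (> last boundary).
#' @param rule_l23 "first_convex" (default) or "second_convex" for the 2/3
#'   rule's reference point.
#' @param rule_l56 "concave_convex" (default: midpoint of second concave
#'   and third convex points) or "concave_concave" (midpoint of second and
#'   third concave points; requires a third concave point).
#' @return a `layer_boundaries` list with `boundaries_um` (named L1/2 ..
#'   L5/6), `surface_um`, `bottom_um`, and `thickness_um` per layer 1-6.
#' @export
layer_boundaries <- function(landmarks, surface = 0, bottom,
                             rule_l23 = c("first_convex", "second_convex"),
                             rule_l56 = c("concave_convex", "concave_concave")) {
  rule_l23 <- match.arg(rule_l23)
  rule_l56 <- match.arg(rule_l56)
  cx <- landmarks$convex_um
  cc <- landmarks$concave_um
  if (length(cx) != 3 || length(cc) < 2) stop("invalid landmark set")
  l12 <- surface + (cx[1] - surface) / 3
  l23 <- surface + 2 * (switch(rule_l23, first_convex = cx[1],
                               second_convex = cx[2]) - surface) / 3
  l34 <- cc[1]
  l45 <- (cx[2] + cc[2]) / 2
  l56 <- switch(rule_l56,
                concave_convex = (cc[2] + cx[3]) / 2,
                concave_concave = {
                  if (length(cc) < 3) stop("third concave point required for the literal L5/6 rule")
                  (cc[2] + cc[3]) / 2
                })
  b <- c("L1/2" = l12, "L2/3" = l23, "L3/4" = l34, "L4/5" = l45, "L5/6" = l56)
  if (is.unsorted(b, strictly = TRUE) || b[1] <= surface || b[5] >= bottom)
    stop("boundary sequence is not strictly increasing within the cortex")
  thick <- diff(c(surface, b, bottom))
  names(thick) <- paste0("L", 1:6)
  structure(list(boundaries_um = b, surface_um = surface, bottom_um = bottom,
                 thickness_um = thick),
            class = "layer_boundaries")
}

#' Assign cortical layers to neurons by depth
#'
#' Layers occupy half-open depth intervals `[lower, upper)`, so a neuron
#' sitting exactly on a boundary goes to the deeper layer (the bottom of
#' layer 6 is closed). Neurons above the L1/2 boundary are flagged layer 1
#' and excluded from per-layer metrics; depths outside `[0, bottom]` are
#' flagged non-cortical (`NA` layer).
#'
#' @param neurons data frame with a `depth_um` column.
#' @param boundaries a [layer_boundaries()] object.
#' @return `neurons` with columns `layer` (integer 1-6 or `NA`) and
#'   `in_analysis` (TRUE for layers 2-6).
#' @export
assign_layers <- function(neurons, boundaries) {
  stopifnot(inherits(boundaries, "layer_boundaries"), "depth_um" %in% names(neurons))
  cuts <- c(boundaries$surface_um, boundaries$boundaries_um, boundaries$bottom_um)
  d <- neurons$depth_um
  layer <- findInterval(d, cuts, rightmost.closed = TRUE)
  layer[d < boundaries$surface_um | d > boundaries$bottom_um] <- NA_integer_
  neurons$layer <- as.integer(layer)
  neurons$in_analysis <- !is.na(layer) & layer >= 2
  neurons
}

#' Density of active neurons per class and layer
#'
#' Counts neurons firing strictly above `rate_threshold` (0.1 Hz), split
#' by E/I class and cortical layer, divided by the recording area in mm^2
#' (not volume-normalized; slices share a fixed 300 um thickness).
#'
#' @param neurons data frame with `firing_rate_hz`, `ei_label`, `layer`.
#' @param area_mm2 recording area (> 0).
#' @param rate_threshold activity threshold in Hz (strict inequality).
#' @return data frame with `layer` ("all" plus each layer 2-6 present),
#'   `ei_label`, `n_active`, `density_per_mm2`.
#' @export
active_density <- function(neurons, area_mm2, rate_threshold = 0.1) {
  if (area_mm2 <= 0) stop("area must be positive")
  act <- neurons[!is.na(neurons$firing_rate_hz) &
                   neurons$firing_rate_hz > rate_threshold, ]
  classes <- c("excitatory", "inhibitory")
  layers <- c("all", sort(unique(act$layer[act$in_analysis])))
  grid <- expand.grid(layer = layers, ei_label = classes,
                      stringsAsFactors = FALSE)
  grid$n_active <- mapply(function(ly, cl) {
    sub <- act[act$ei_label == cl, ]
    if (ly != "all") sub <- sub[!is.na(sub$layer) & sub$layer == as.integer(ly), ]
    else sub <- sub[sub$in_analysis, ]
    nrow(sub)
  }, grid$layer, grid$ei_label)
  grid$density_per_mm2 <- grid$n_active / area_mm2
  grid
}

#' Excitatory/inhibitory balance among active neurons
#'
#' @param neurons data frame with `firing_rate_hz` and `ei_label`.
#' @param rate_threshold activity threshold in Hz (strict).
#' @return named numeric: fractions of active labeled neurons that are
#'   excitatory and inhibitory (sums to 1); both `NA` with a warning when
#'   no neuron is active.
#' @export
ei_balance <- function(neurons, rate_threshold = 0.1) {
  act <- neurons[!is.na(neurons$firing_rate_hz) &
                   neurons$firing_rate_hz > rate_threshold &
                   neurons$ei_label %in% c("excitatory", "inhibitory"), ]
  if (nrow(act) == 0) {
    warning("no active labeled neurons")
    return(c(excitatory = NA_real_, inhibitory = NA_real_))
  }
  c(excitatory = mean(act$ei_label == "excitatory"),
    inhibitory = mean(act$ei_label == "inhibitory"))
}

#' Firing-rate stationarity across record halves
#'
#' Spearman correlation of per-neuron rates between the second and fourth
#' quarters of the recording -- a check that slow drift is not masquerading
#' as structure.
#'
#' @param raster a [spike_raster()].
#' @return Spearman correlation coefficient.
#' @export
rate_stationarity <- function(raster) {
  q <- floor(raster$n_bins / 4)
  if (q < 1) stop("recording too short")
  r1 <- vapply(raster$spikes, function(s) sum(s > q & s <= 2 * q), numeric(1))
  r2 <- vapply(raster$spikes, function(s) sum(s > 3 * q & s <= 4 * q), numeric(1))
  stats::cor(r1, r2, method = "spearman")
}
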