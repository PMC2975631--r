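#' Brain extraction by seeded per-slice region growing
#'
#' Emulates semi-automatic skull stripping: starting from a user-placed seed
#' in the bright subarachnoid CSF on one axial T2-weighted slice, the
#' 4-connected component of voxels whose T2 intensity lies in `[low, high]`
#' is grown, the threshold setting is propagated slice-to-slice (the next
#' slice is seeded by the overlap with the previous slice's region), and each
#' slice is finalized by hole-filling so the mask keeps all intrameningeal
#' tissue while excluding skull, muscle and other extrameningeal voxels.
#'
#' @param volume A [neo_volume()]; growing operates on the T2 channel.
#' @param seed_voxel Integer voxel index `c(x, y, z)` (1-based) inside the
#'   T2-bright CSF.
#' @param low,high Threshold band on T2 intensity, `low < high`.
#' @return A logical 3-D array (brain mask) with attribute `spacing`.
#' @export
extract_brain_mask <- function(volume, seed_voxel, low, high) {
  stopifnot(inherits(volume, "neo_volume"))
  if (low >= high) neo_stop("low must be < high", "neoseg_value_error")
  t2 <- volume$t2
  d <- dim(t2)
  seed_voxel <- as.integer(seed_voxel)
  if (length(seed_voxel) != 3L || any(seed_voxel < 1L) || any(seed_voxel > d)) {
    neo_stop("seed voxel outside the volume", "neoseg_value_error")
  }
  if (t2[seed_voxel[1L], seed_voxel[2L], seed_voxel[3L]] < low ||
      t2[seed_voxel[1L], seed_voxel[2L], seed_voxel[3L]] > high) {
    neo_stop("seed intensity outside the threshold band: nothing to grow",
             "neoseg_empty_growth_error")
  }
  grown <- array(FALSE, d)

  grow_slice <- function(z, seeds) {
    band <- t2[, , z] >= low & t2[, , z] <= high
    seeds <- seeds & band
    if (!any(seeds)) return(matrix(FALSE, d[1L], d[2L]))
    comp <- label_components_slice(band)
    ids <- setdiff(unique(comp[seeds]), 0)
    matrix(comp %in% ids, d[1L], d[2L])
  }

  # slices are seeded by overlap with the previous slice's *filled* region:
  # the rim can shift inward by more than its own width near the poles
  mask <- array(FALSE, d)
  z0 <- seed_voxel[3L]
  seeds0 <- matrix(FALSE, d[1L], d[2L])
  seeds0[seed_voxel[1L], seed_voxel[2L]] <- TRUE
  grown[, , z0] <- grow_slice(z0, seeds0)
  mask[, , z0] <- fill_holes_slice(grown[, , z0])
  step <- function(z, z_prev) {
    grown[, , z] <<- grow_slice(z, mask[, , z_prev])
    if (any(grown[, , z])) mask[, , z] <<- fill_holes_slice(grown[, , z])
  }
  if (z0 < d[3L]) for (z in (z0 + 1L):d[3L]) step(z, z - 1L)
  if (z0 > 1L) for (z in (z0 - 1L):1L) step(z, z + 1L)
  attr(mask, "spacing") <- volume$spacing
  mask
}

#' Perona-Malik anisotropic diffusion
#'
#' Edge-preserving denoising applied independently to each axial slice, with
#' exponential conductance `g(d) = exp(-(d/kappa)^2)` and a conservative
#' (flux-form) update so the global mean intensity is preserved. `n_iter = 0`
#' is the identity.
#'
#' @param channel 3-D numeric array (one intensity channel).
#' @param n_iter Number of diffusion iterations (default 10).
#' @param kappa Conductance scale; default is twice the robust noise estimate
#'   (median absolute neighbour difference over the volume).
#' @param lambda Integration step, `0 < lambda <= 0.25` for 2-D stability.
#' @return The diffused channel, same dimensions.
#' @export
anisotropic_diffusion <- function(channel, n_iter = 10L, kappa = NULL,
                                  lambda = 0.25) {
  channel <- as_array3d(channel, "channel")
  if (any(!is.finite(channel))) {
    neo_stop("channel contains non-finite values", "neoseg_value_error")
  }
  if (n_iter < 0L) neo_stop("n_iter must be >= 0", "neoseg_value_error")
  if (lambda <= 0 || lambda > 0.25) {
    neo_stop("lambda must be in (0, 0.25]", "neoseg_value_error")
  }
  if (n_iter == 0L) return(channel)
  if (is.null(kappa)) {
    g <- abs(diff(channel))  # x-differences, cheap robust gradient proxy
    g <- g[g > 0]
    kappa <- if (length(g)) 2 * stats::median(g) else 1
  }
  if (kappa <= 0) neo_stop("kappa must be > 0", "neoseg_value_error")
  out <- channel
  for (z in seq_len(dim(channel)[3L])) {
    m <- out[, , z]
    for (it in seq_len(n_iter)) {
      dd <- slice_diffs(m)
      m <- m + lambda * (exp(-(dd$n / kappa)^2) * dd$n +
                         exp(-(dd$s / kappa)^2) * dd$s +
                         exp(-(dd$w / kappa)^2) * dd$w +
                         exp(-(dd$e / kappa)^2) * dd$e)
    }
    out[, , z] <- m
  }
  out
}

norm_probs <- function() c(0.01, seq(0.1, 0.9, by = 0.1), 0.99)

#' Landmark-based histogram normalization
#'
#' Standardizes the intensity distribution of an input scan to that of the
#' training set, per channel, using the two-extreme-plus-decile landmark
#' method: within-mask percentiles at 1%, 10%, ..., 90%, 99% are mapped
#' piecewise-linearly onto a standard scale learned from the training
#' volumes. The transform is monotone non-decreasing.
#'
#' @param training_volumes List of [neo_volume()] training scans.
#' @param masks List of logical brain masks, one per training volume.
#' @param standard_range Intensity range of the standard scale
#'   (default `c(0, 100)`).
#' @return An object of class `neo_norm_model`: per-channel standard-scale
#'   landmarks and the percentile probabilities.
#' @export
fit_normalization <- function(training_volumes, masks,
                              standard_range = c(0, 100)) {
  if (inherits(training_volumes, "neo_volume")) training_volumes <- list(training_volumes)
  if (is.logical(masks) || is.array(masks)) masks <- list(masks)
  if (!length(training_volumes)) neo_stop("need >= 1 training volume", "neoseg_value_error")
  if (length(masks) != length(training_volumes)) {
    neo_stop("one mask per training volume required", "neoseg_value_error")
  }
  probs <- norm_probs()
  landmarks <- lapply(c("pd", "t2"), function(ch) {
    mapped <- sapply(seq_along(training_volumes), function(i) {
      v <- training_volumes[[i]][[ch]][masks[[i]]]
      if (!length(v)) neo_stop("empty training mask", "neoseg_value_error")
      q <- stats::quantile(v, probs, names = FALSE, type = 7)
      if (q[length(q)] <= q[1L]) {
        neo_stop("degenerate (constant) training intensities",
                 "neoseg_normalization_error")
      }
      # map this volume's [p1, p99] linearly onto the standard range
      standard_range[1L] + (q - q[1L]) / (q[length(q)] - q[1L]) *
        diff(standard_range)
    })
    lm <- rowMeans(as.matrix(mapped))
    if (any(diff(lm) <= 0)) {
      neo_stop("standard-scale landmarks are not strictly increasing",
               "neoseg_normalization_error")
    }
    lm
  })
  structure(list(landmarks = stats::setNames(landmarks, c("pd", "t2")),
                 probs = probs, standard_range = standard_range),
            class = "neo_norm_model")
}

#' @rdname fit_normalization
#' @param volume A [neo_volume()] to standardize.
#' @param mask Logical brain mask used to compute the input's landmarks.
#' @param model A fitted `neo_norm_model`.
#' @return `apply_normalization` returns a [neo_volume()] on the standard
#'   intensity scale.
#' @export
apply_normalization <- function(volume, mask, model) {
  stopifnot(inherits(volume, "neo_volume"), inherits(model, "neo_norm_model"))
  out <- volume
  for (ch in c("pd", "t2")) {
    v <- volume[[ch]]
    q <- stats::quantile(v[mask], model$probs, names = FALSE, type = 7)
    if (q[length(q)] <= q[1L]) {
      neo_stop("degenerate (constant) input intensities",
               "neoseg_normalization_error")
    }
    keep <- c(TRUE, diff(q) > 0)  # collapse tied interior landmarks
    out[[ch]] <- array(stats::approx(q[keep], model$landmarks[[ch]][keep],
                                     xout = as.vector(v), rule = 2)$y,
                       dim(v))
    # linear extension beyond the extreme landmarks keeps the map monotone
    lo <- v < q[1L]; hi <- v > q[length(q)]
    slope <- diff(model$landmarks[[ch]][c(1L, length(q))]) / (q[length(q)] - q[1L])
    if (any(lo)) out[[ch]][lo] <- model$landmarks[[ch]][1L] + (v[lo] - q[1L]) * slope
    if (any(hi)) out[[ch]][hi] <- model$landmarks[[ch]][length(q)] + (v[hi] - q[length(q)]) * slope
  }
  out
}
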