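#' Kernel bandwidth for the Parzen-window feature map
#'
#' Per-class bandwidth `h_n = pooled SD x n^(-1/6)`, where the pooled SD is
#' the root mean of the per-axis (PD, T2) sample variances — a Silverman-type
#' rate for a two-dimensional Gaussian kernel. The rule is a documented
#' package choice and can be overridden by passing explicit bandwidths to
#' [build_feature_map()].
#'
#' @param samples Data frame of training samples with columns `pd`, `t2`,
#'   `label` (tissue codes).
#' @return Named numeric vector of bandwidths, one per class code.
#' @export
estimate_bandwidth <- function(samples) {
  samples <- validate_samples(samples)
  classes <- sort(unique(samples$label))
  h <- vapply(classes, function(k) {
    s <- samples[samples$label == k, ]
    n <- nrow(s)
    if (n < 2L) {
      neo_stop(sprintf("class %d has fewer than 2 samples", k),
               "neoseg_bandwidth_error")
    }
    pooled <- sqrt((stats::var(s$pd) + stats::var(s$t2)) / 2)
    if (!is.finite(pooled) || pooled <= 0) {
      neo_stop(sprintf("class %d has zero intensity variance", k),
               "neoseg_bandwidth_error")
    }
    pooled * n^(-1 / 6)
  }, numeric(1))
  stats::setNames(h, classes)
}

validate_samples <- function(samples) {
  samples <- as.data.frame(samples)
  need <- c("pd", "t2", "label")
  if (!all(need %in% names(samples))) {
    neo_stop("samples need columns pd, t2, label", "neoseg_value_error")
  }
  if (any(!is.finite(samples$pd)) || any(!is.finite(samples$t2))) {
    neo_stop("sample intensities must be finite", "neoseg_value_error")
  }
  samples$label <- as.integer(samples$label)
  samples
}

#' Parzen-window density feature map in the PD-T2 plane
#'
#' For each tissue class the kernel density
#' `p(x) = (1/n) sum_i (2 pi h^2)^(-1) exp(-||x - xi_i||^2 / (2 h^2))`
#' over the class's training samples `xi_i` is evaluated on a regular grid
#' spanning the standardized intensity range. Each class density must carry
#' at least 99% of its mass inside the grid.
#'
#' @param samples Training samples (`pd`, `t2`, `label`).
#' @param grid_range Intensity range covered per axis, `c(min, max)`, or a
#'   list with elements `pd` and `t2`; default spans the samples with a
#'   4-bandwidth margin.
#' @param bins Grid resolution per axis (default 256).
#' @param bandwidths Named per-class bandwidths; default
#'   [estimate_bandwidth()].
#' @return An object of class `neo_featuremap`: per-class density matrices,
#'   bin centers, bandwidths, sample counts, and the training samples (kept
#'   for off-support nearest-neighbour fallback).
#' @export
build_feature_map <- function(samples, grid_range = NULL, bins = 256L,
                              bandwidths = NULL) {
  samples <- validate_samples(samples)
  classes <- sort(unique(samples$label))
  if (is.null(bandwidths)) bandwidths <- estimate_bandwidth(samples)
  bandwidths <- bandwidths[as.character(classes)]
  if (is.null(grid_range)) {
    pad <- 4 * max(bandwidths)
    grid_range <- list(pd = range(samples$pd) + c(-pad, pad),
                       t2 = range(samples$t2) + c(-pad, pad))
  }
  if (!is.list(grid_range)) grid_range <- list(pd = grid_range, t2 = grid_range)
  if (any(samples$pd < grid_range$pd[1L]) || any(samples$pd > grid_range$pd[2L]) ||
      any(samples$t2 < grid_range$t2[1L]) || any(samples$t2 > grid_range$t2[2L])) {
    warning("training samples fall outside the feature-map grid")
  }
  wx <- diff(grid_range$pd) / bins
  wy <- diff(grid_range$t2) / bins
  xc <- grid_range$pd[1L] + (seq_len(bins) - 0.5) * wx
  yc <- grid_range$t2[1L] + (seq_len(bins) - 0.5) * wy
  density <- lapply(classes, function(k) {
    s <- samples[samples$label == k, ]
    h <- bandwidths[[as.character(k)]]
    # separable evaluation: kernel sum = A %*% t(B) summed over samples
    A <- exp(-outer(xc, s$pd, "-")^2 / (2 * h^2))
    B <- exp(-outer(yc, s$t2, "-")^2 / (2 * h^2))
    dens <- (A %*% t(B)) / (nrow(s) * 2 * pi * h^2)
    mass <- sum(dens) * wx * wy
    if (mass < 0.99) {
      neo_stop(sprintf("class %d density mass on grid is %.3f < 0.99: grid does not cover the samples",
                       k, mass), "neoseg_normalization_error")
    }
    dens
  })
  structure(list(density = stats::setNames(density, classes),
                 classes = classes,
                 xcenters = xc, ycenters = yc,
                 range = grid_range, bins = as.integer(bins),
                 h = bandwidths,
                 n = stats::setNames(as.integer(table(samples$label)[as.character(classes)]), classes),
                 samples = samples),
            class = "neo_featuremap")
}

#' @export
print.neo_featuremap <- function(x, ...) {
  cat(sprintf("<neo_featuremap> %d x %d bins, classes %s, h = %s\n",
              x$bins, x$bins, paste(x$classes, collapse = " "),
              paste(signif(x$h, 4), collapse = " ")))
  invisible(x)
}

# Exact per-class kernel-density argmax at arbitrary (pd, t2) points,
# evaluated in chunks to bound memory.
parzen_exact_classify <- function(pd, t2, feature_map) {
  out <- integer(length(pd))
  s <- feature_map$samples
  for (start in seq(1L, length(pd), by = 8192L)) {
    idx <- start:min(start + 8191L, length(pd))
    dens <- vapply(feature_map$classes, function(k) {
      sk <- s[s$label == k, ]
      h <- feature_map$h[[as.character(k)]]
      colSums(exp(-(outer(sk$pd, pd[idx], "-")^2 +
                      outer(sk$t2, t2[idx], "-")^2) / (2 * h^2))) /
        (nrow(sk) * 2 * pi * h^2)
    }, numeric(length(idx)))
    dens <- matrix(dens, ncol = length(feature_map$classes))
    out[idx] <- feature_map$classes[max.col(dens, ties.method = "first")]
  }
  out
}

fm_bin_index <- function(v, centers) {
  w <- centers[2L] - centers[1L]
  pmin(pmax(as.integer(floor((v - (centers[1L] - w / 2)) / w)) + 1L, 1L),
       length(centers))
}

#' Initial tissue classification from the feature map
#'
#' Each in-mask voxel is assigned the class whose Parzen density is largest
#' at the voxel's (PD, T2) position (nearest feature-map bin). Ties break by
#' fixed priority CSF > GM > WM. Voxels where all class densities vanish
#' (off the training support) are assigned the class of the nearest training
#' sample in PD-T2 Euclidean distance. Out-of-mask voxels get background.
#'
#' @param volume A [neo_volume()] on the feature map's intensity scale.
#' @param mask Logical brain mask.
#' @param feature_map A [build_feature_map()] result.
#' @param max_off_grid Maximum tolerated fraction of in-mask voxels falling
#'   outside the grid range before an intensity-scale error is raised
#'   (default 0.05).
#' @return A [neo_labelmap()] of initial tissue labels.
#' @export
classify_initial <- function(volume, mask, feature_map, max_off_grid = 0.05) {
  stopifnot(inherits(volume, "neo_volume"), inherits(feature_map, "neo_featuremap"))
  mask <- as_array3d(mask, "mask") > 0
  pd <- volume$pd[mask]; t2 <- volume$t2[mask]
  off <- pd < feature_map$range$pd[1L] | pd > feature_map$range$pd[2L] |
         t2 < feature_map$range$t2[1L] | t2 > feature_map$range$t2[2L]
  if (mean(off) > max_off_grid) {
    neo_stop(sprintf("%.1f%% of in-mask voxels fall off the feature-map grid: input not on the map's intensity scale",
                     100 * mean(off)), "neoseg_scale_error")
  }
  ix <- fm_bin_index(pd, feature_map$xcenters)
  iy <- fm_bin_index(t2, feature_map$ycenters)
  dens <- vapply(feature_map$classes, function(k) {
    feature_map$density[[as.character(k)]][cbind(ix, iy)]
  }, numeric(length(ix)))
  dens <- matrix(dens, ncol = length(feature_map$classes))
  # columns are in ascending code order (CSF, GM, WM); ties.method = "first"
  # realizes the CSF > GM > WM priority
  lab <- feature_map$classes[max.col(dens, ties.method = "first")]
  # near-tie voxels (where half-bin quantization could flip the argmax) are
  # re-evaluated with the exact kernel sums instead of the gridded lookup
  m1 <- rep(-Inf, nrow(dens)); m2 <- m1
  for (j in seq_len(ncol(dens))) {
    v <- dens[, j]
    gt <- v > m1
    m2[gt] <- m1[gt]; m1[gt] <- v[gt]
    mid <- !gt & v > m2
    m2[mid] <- v[mid]
  }
  close <- m1 > 0 & (m1 - m2) < 0.5 * m1
  if (any(close)) {
    lab[close] <- parzen_exact_classify(pd[close], t2[close], feature_map)
  }
  zero <- rowSums(dens) == 0
  if (any(zero)) {
    s <- feature_map$samples
    lab[zero] <- vapply(which(zero), function(i) {
      s$label[which.min((s$pd - pd[i])^2 + (s$t2 - t2[i])^2)]
    }, integer(1))
  }
  labels <- array(0L, dim(volume$pd))
  labels[mask] <- lab
  neo_labelmap(labels, spacing = volume$spacing)
}

#' Serialize and restore a feature map
#'
#' The density grids are written as a `bins x bins x K` NIfTI volume (one
#' frame per class) and the metadata (bin ranges, bandwidths, sample counts,
#' training samples) as `<path>.json`.
#'
#' @param feature_map A `neo_featuremap`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_feature_map <- function(feature_map, path) {
  stopifnot(inherits(feature_map, "neo_featuremap"))
  arr <- array(0, c(feature_map$bins, feature_map$bins, length(feature_map$classes)))
  for (i in seq_along(feature_map$classes)) {
    arr[, , i] <- feature_map$density[[i]]
  }
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "double")
  meta <- list(classes = feature_map$classes, range = feature_map$range,
               bins = feature_map$bins, h = as.list(feature_map$h),
               n = as.list(feature_map$n),
               samples = feature_map$samples)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_map
#' @export
read_feature_map <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  classes <- as.integer(meta$classes)
  bins <- as.integer(meta$bins)
  rng <- list(pd = as.numeric(meta$range$pd), t2 = as.numeric(meta$range$t2))
  wx <- diff(rng$pd) / bins; wy <- diff(rng$t2) / bins
  structure(list(
    density = stats::setNames(lapply(seq_along(classes), function(i) arr[, , i]), classes),
    classes = classes,
    xcenters = rng$pd[1L] + (seq_len(bins) - 0.5) * wx,
    ycenters = rng$t2[1L] + (seq_len(bins) - 0.5) * wy,
    range = rng, bins = bins,
    h = stats::setNames(as.numeric(unlist(meta$h)), names(meta$h)),
    n = stats::setNames(as.integer(unlist(meta$n)), names(meta$n)),
    samples = as.data.frame(meta$samples)),
    class = "neo_featuremap")
}
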