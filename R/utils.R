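# Internal helpers shared across modules. All image operations act on plain
# 3-D arrays in column-major (x, y, z) order; per-slice operations work on the
# axial (x, y) plane.

neo_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "neoseg_error", "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_array3d <- function(x, what = "array") {
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) {
    neo_stop(sprintf("%s must be a 2-D or 3-D array", what), "neoseg_value_error")
  }
  x
}

same_geometry <- function(dim_a, dim_b, spacing_a = NULL, spacing_b = NULL,
                          tol = 1e-4) {
  if (!identical(as.integer(dim_a), as.integer(dim_b))) return(FALSE)
  if (!is.null(spacing_a) && !is.null(spacing_b) &&
      any(abs(spacing_a - spacing_b) > tol)) return(FALSE)
  TRUE
}

# Replicate-boundary neighbour differences for one axial slice.
slice_diffs <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  list(
    n = m[c(1L, seq_len(nr - 1L)), , drop = FALSE] - m,
    s = m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE] - m,
    w = m[, c(1L, seq_len(nc - 1L)), drop = FALSE] - m,
    e = m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE] - m
  )
}

# Zero-padded in-plane shift of a 3-D array (same shift applied to every slice).
shift_inplane <- function(a, dx, dy) {
  d <- dim(a)
  out <- array(0, d)
  xs <- seq_len(d[1L]) - dx
  ys <- seq_len(d[2L]) - dy
  okx <- xs >= 1L & xs <= d[1L]
  oky <- ys >= 1L & ys <= d[2L]
  out[okx, oky, ] <- a[xs[okx], ys[oky], , drop = FALSE]
  out
}

# Zero-padded shift along z.
shift_axial <- function(a, dz) {
  d <- dim(a)
  out <- array(0, d)
  zs <- seq_len(d[3L]) - dz
  okz <- zs >= 1L & zs <= d[3L]
  out[, , okz] <- a[, , zs[okz], drop = FALSE]
  out
}

inplane_offsets_8 <- function() {
  cbind(dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
        dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L))
}

# Count, for every voxel and class, the neighbours carrying that class.
# Background (0) neighbours are never counted. Returns an nvox x K matrix.
neighbor_class_counts <- function(labels, K, neighborhood = "8-2d") {
  d <- dim(labels)
  nvox <- prod(d)
  counts <- matrix(0, nvox, K)
  add_shift <- function(sh) {
    for (k in seq_len(K)) counts[, k] <<- counts[, k] + as.numeric(sh == k)
  }
  if (neighborhood == "8-2d") {
    off <- inplane_offsets_8()
    for (i in seq_len(nrow(off))) add_shift(shift_inplane(labels, off[i, 1L], off[i, 2L]))
  } else if (neighborhood == "6-3d") {
    for (s in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      add_shift(shift_inplane(labels, s[1L], s[2L]))
    }
    add_shift(shift_axial(labels, -1L))
    add_shift(shift_axial(labels, 1L))
  } else {
    neo_stop("unknown neighborhood", "neoseg_value_error")
  }
  counts
}

# 4-connected component labelling of a logical slice.
label_components_slice <- function(mask) {
  EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
}

# Fill interior holes of a logical slice: background components not touching
# the slice border are holes.
fill_holes_slice <- function(mask) {
  comp <- label_components_slice(!mask)
  nr <- nrow(mask); nc <- ncol(mask)
  border <- unique(c(comp[1L, ], comp[nr, ], comp[, 1L], comp[, nc]))
  border <- setdiff(border, 0)
  mask | !(matrix(comp %in% c(0, border), nr, nc))
}

# Binary erosion of a logical slice with a 3x3 box, `depth` times. Voxels
# outside the image count as background, so the image border erodes too.
erode_slice <- function(mask, depth = 1L) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- mask
  for (i in seq_len(depth)) {
    out <- m
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0L && dy == 0L) next
      sh <- matrix(FALSE, nr, nc)
      xs <- seq_len(nr) - dx; ys <- seq_len(nc) - dy
      okx <- xs >= 1L & xs <= nr; oky <- ys >= 1L & ys <= nc
      sh[okx, oky] <- m[xs[okx], ys[oky]]
      out <- out & sh
    }
    m <- out
  }
  m
}

# Binary dilation of a logical slice with a disc of radius `radius_px`.
dilate_slice <- function(mask, radius_px) {
  size <- 2L * as.integer(ceiling(radius_px)) + 1L
  if (size < 3L) return(mask)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  brush <- EBImage::makeBrush(size, shape = "disc")
  EBImage::dilate(m, brush) > 0.5
}

# Masked Gaussian smoothing of one slice. Large kernels are evaluated on a
# downsampled copy (the result is band-limited anyway) and resized back.
smooth_slice_masked <- function(x, mask, sigma_px) {
  nr <- nrow(x); nc <- ncol(x)
  w <- matrix(as.numeric(mask), nr, nc)
  xw <- x * w
  f <- max(1L, as.integer(floor(sigma_px / 12)))
  if (f > 1L) {
    nr2 <- max(8L, ceiling(nr / f)); nc2 <- max(8L, ceiling(nc / f))
    xw <- EBImage::resize(xw, w = nr2, h = nc2)
    w2 <- EBImage::resize(w, w = nr2, h = nc2)
    sig <- sigma_px * nr2 / nr
  } else {
    w2 <- w
    sig <- sigma_px
  }
  size <- 2L * as.integer(ceiling(3 * sig)) + 1L
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sig)
  # zero-pad so the kernel always fits (sigma may rival the slice extent)
  pr <- max(0L, size - nrow(xw)); pc <- max(0L, size - ncol(xw))
  if (pr > 0L || pc > 0L) {
    pad <- function(m) {
      out <- matrix(0, nrow(m) + 2L * pr, ncol(m) + 2L * pc)
      out[pr + seq_len(nrow(m)), pc + seq_len(ncol(m))] <- m
      out
    }
    xw <- pad(xw); w2 <- pad(w2)
  }
  num <- EBImage::filter2(xw, brush, boundary = 0)
  den <- EBImage::filter2(w2, brush, boundary = 0)
  out <- num / pmax(den, 1e-10)
  if (pr > 0L || pc > 0L) {
    out <- out[pr + seq_len(nrow(out) - 2L * pr), pc + seq_len(ncol(out) - 2L * pc)]
  }
  if (f > 1L) out <- EBImage::resize(out, w = nr, h = nc)
  matrix(out, nr, nc)
}
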