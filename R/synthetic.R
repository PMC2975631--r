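#' Specification of a dual-echo neonatal head phantom
#'
#' Defines the geometry and signal model of a synthetic two-channel (PD, T2)
#' scan with full ground truth, at the acquisition geometry of axial
#' dual-echo neonatal volumetry (0.36 x 0.36 x 1.98 mm voxels, reduced
#' in-plane matrix). The head is a set of nested ellipsoidal shells — skull,
#' subarachnoid CSF, cortical gray-matter ribbon, white-matter core — plus
#' lateral-ventricle CSF, nine subcortical structural blobs and
#' periventricular WMSA lesions adjacent to the ventricles. Intensities are
#' per-class Gaussian in the joint (PD, T2) plane; partial volume is
#' emulated by an in-plane Gaussian point-spread blur of the ideal
#' class-mean image, on top of which smooth multiplicative bias and additive
#' noise act.
#'
#' The defaults put the smallest class-mean separation (GM vs WM, 50
#' intensity units) at about 6.4 total per-voxel SDs, the intensity ordering
#' being CSF bright on both channels, WM dark, GM intermediate; WMSA means
#' sit between WM and CSF, close to CSF.
#'
#' @param dim Grid dimensions (default `c(128, 128, 24)`).
#' @param spacing Voxel size in mm (default `c(0.36, 0.36, 1.98)`).
#' @param brain_axes Brain ellipsoid semi-axes in mm.
#' @param csf_frac,gm_frac Relative (fractional-radius) boundaries of the
#'   subarachnoid CSF rim and the GM ribbon: CSF occupies
#'   `(csf_frac, 1]`, GM `(gm_frac, csf_frac]`, WM `<= gm_frac`.
#' @param skull_frac Outer fractional radius of the skull shell
#'   (`(1.02, skull_frac]`).
#' @param ventricle_centers,ventricle_axes Lateral ventricle ellipsoids (mm).
#' @param structure_radius_mm Radius of the nine structural blobs.
#' @param wmsa_n,wmsa_radius_mm Number and radius of periventricular WMSA
#'   lesions (placed against the ventricle borders).
#' @param means Named list of class mean vectors `c(pd, t2)` for `csf`,
#'   `gm`, `wm`, `wmsa`, `skull`, `background`.
#' @param class_sd Within-class intensity SD per axis (isotropic).
#' @param noise_sd Additive scanner-noise SD per channel.
#' @param bias_amplitude Peak relative deviation of the multiplicative bias
#'   ramp (0 disables bias).
#' @param pv_sigma_mm In-plane PSF sigma emulating partial volume (0
#'   disables).
#' @param seed Random seed; mandatory for any stochastic output.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(128L, 128L, 24L),
                         spacing = c(0.36, 0.36, 1.98),
                         brain_axes = c(19, 17, 20),
                         csf_frac = 0.90, gm_frac = 0.78,
                         skull_frac = 1.12,
                         ventricle_centers = list(c(-2.8, 0, 0), c(2.8, 0, 0)),
                         ventricle_axes = c(2, 4.5, 4.5),
                         structure_radius_mm = 2.2,
                         wmsa_n = 2L, wmsa_radius_mm = 1.6,
                         means = list(csf = c(210, 220), gm = c(150, 130),
                                      wm = c(120, 90), wmsa = c(178, 174),
                                      skull = c(90, 60), background = c(25, 18)),
                         class_sd = 6, noise_sd = 5,
                         bias_amplitude = 0.10, pv_sigma_mm = 0.4,
                         seed = 1L) {
  if (any(skull_frac * brain_axes[1:2] > dim[1:2] * spacing[1:2] / 2)) {
    neo_stop("head ellipsoid does not fit the grid in-plane", "neoseg_spec_error")
  }
  if (class_sd < 0 || noise_sd < 0 || bias_amplitude < 0 || pv_sigma_mm < 0) {
    neo_stop("noise, bias and PV parameters must be >= 0", "neoseg_spec_error")
  }
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 brain_axes = brain_axes, csf_frac = csf_frac,
                 gm_frac = gm_frac, skull_frac = skull_frac,
                 ventricle_centers = ventricle_centers,
                 ventricle_axes = ventricle_axes,
                 structure_radius_mm = structure_radius_mm,
                 wmsa_n = as.integer(wmsa_n), wmsa_radius_mm = wmsa_radius_mm,
                 means = means, class_sd = class_sd, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude, pv_sigma_mm = pv_sigma_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# mm coordinates of every voxel center relative to the grid center
phantom_coords <- function(spec) {
  d <- spec$dim; sp <- spec$spacing
  ax <- (seq_len(d[1L]) - (d[1L] + 1) / 2) * sp[1L]
  ay <- (seq_len(d[2L]) - (d[2L] + 1) / 2) * sp[2L]
  az <- (seq_len(d[3L]) - (d[3L] + 1) / 2) * sp[3L]
  list(x = ax, y = ay, z = az)
}

ellipsoid_r2 <- function(co, center, axes) {
  d <- c(length(co$x), length(co$y), length(co$z))
  xs <- ((co$x - center[1L]) / axes[1L])^2
  ys <- ((co$y - center[2L]) / axes[2L])^2
  zs <- ((co$z - center[3L]) / axes[3L])^2
  array(rep(xs, times = d[2L] * d[3L]), d) +
    array(rep(rep(ys, each = d[1L]), times = d[3L]), d) +
    array(rep(zs, each = d[1L] * d[2L]), d)
}

# Fixed layout of the nine structural blobs: a ring deep in the WM core.
structure_centers <- function() {
  codes <- structural_codes()
  theta <- 2 * pi * (seq_along(codes) - 1) / length(codes)
  data.frame(code = as.integer(codes), name = names(codes),
             x = 8 * cos(theta), y = 8 * sin(theta),
             z = rep(c(-2, 0, 2), length.out = length(codes)))
}

#' Generate a seeded dual-echo phantom with ground truth
#'
#' Builds the nested geometry of [phantom_spec()], draws per-voxel
#' intensities from the class Gaussians (with the partial-volume PSF applied
#' to the ideal class-mean image), applies the multiplicative bias ramp and
#' additive noise. Fully reproducible given the spec's seed; the generator is
#' the package's only stochastic component.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `neo_phantom`: `volume` (a [neo_volume()]) and
#'   `truth` — a list with `tissue` and `structural` [neo_labelmap()]s,
#'   logical `wmsa` and `brain_mask` arrays, and the per-channel `bias`
#'   fields.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$dim
  co <- phantom_coords(spec)
  r2 <- ellipsoid_r2(co, c(0, 0, 0), spec$brain_axes)
  r <- sqrt(r2)
  s <- neoseg_scheme()

  brain <- r <= 1
  skull <- r > 1.02 & r <= spec$skull_frac
  tissue <- array(0L, d)
  tissue[brain & r > spec$csf_frac] <- s[["csf"]]
  tissue[r <= spec$csf_frac & r > spec$gm_frac] <- s[["gm"]]
  tissue[r <= spec$gm_frac] <- s[["wm"]]
  for (vc in spec$ventricle_centers) {
    vent <- ellipsoid_r2(co, vc, spec$ventricle_axes) <= 1
    tissue[vent & brain] <- s[["csf"]]
  }

  structural <- array(0L, d)
  sc <- structure_centers()
  for (i in seq_len(nrow(sc))) {
    blob <- ellipsoid_r2(co, c(sc$x[i], sc$y[i], sc$z[i]),
                         rep(spec$structure_radius_mm, 3L)) <= 1
    structural[blob & tissue == s[["wm"]]] <- sc$code[i]
  }

  wmsa <- array(FALSE, d)
  if (spec$wmsa_n > 0L) {
    # lesions hug the superior/inferior ventricle borders, alternating sides
    vy <- spec$ventricle_axes[2L] + spec$wmsa_radius_mm * 0.6
    for (i in seq_len(spec$wmsa_n)) {
      vc <- spec$ventricle_centers[[(i - 1L) %% length(spec$ventricle_centers) + 1L]]
      side <- if (i %% 2L == 1L) 1 else -1
      les <- ellipsoid_r2(co, c(vc[1L], vc[2L] + side * vy, vc[3L]),
                          rep(spec$wmsa_radius_mm, 3L)) <= 1
      wmsa <- wmsa | (les & tissue == s[["wm"]] & structural == 0L)
    }
  }

  # ideal class-mean image per channel
  mean_img <- list(pd = array(spec$means$background[1L], d),
                   t2 = array(spec$means$background[2L], d))
  for (ci in 1:2) {
    m <- mean_img[[ci]]
    m[skull] <- spec$means$skull[ci]
    m[tissue == s[["csf"]]] <- spec$means$csf[ci]
    m[tissue == s[["gm"]]] <- spec$means$gm[ci]
    m[tissue == s[["wm"]]] <- spec$means$wm[ci]
    m[wmsa] <- spec$means$wmsa[ci]
    if (spec$pv_sigma_mm > 0) {
      sig_px <- spec$pv_sigma_mm / spec$spacing[1L]
      size <- 2L * as.integer(ceiling(3 * sig_px)) + 1L
      if (size >= 3L) {
        brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sig_px)
        for (z in seq_len(d[3L])) {
          m[, , z] <- EBImage::filter2(m[, , z], brush, boundary = "replicate")
        }
      }
    }
    mean_img[[ci]] <- m
  }

  bias <- array(1, d)
  if (spec$bias_amplitude > 0) {
    ramp <- spec$bias_amplitude * (2 * (seq_len(d[1L]) - 1) / (d[1L] - 1) - 1)
    bias <- array(rep(1 + ramp, times = d[2L] * d[3L]), d)
  }

  total_sd <- sqrt(spec$class_sd^2 + spec$noise_sd^2)
  nvox <- prod(d)
  intensities <- lapply(1:2, function(ci) {
    v <- mean_img[[ci]]
    if (total_sd > 0) v <- v + array(stats::rnorm(nvox, 0, total_sd), d)
    pmax(v * bias, 0.5)
  })

  volume <- neo_volume(intensities[[1L]], intensities[[2L]],
                       spacing = spec$spacing)
  truth <- list(
    tissue = neo_labelmap(tissue, spacing = spec$spacing),
    structural = neo_labelmap(structural, spacing = spec$spacing),
    wmsa = wmsa,
    brain_mask = brain,
    bias = list(pd = bias, t2 = bias)
  )
  check_truth(truth, s)
  structure(list(volume = volume, truth = truth, spec = spec),
            class = "neo_phantom")
}

# Ground-truth invariants, asserted on every generation.
check_truth <- function(truth, s = neoseg_scheme()) {
  stopifnot(
    !any(truth$wmsa & truth$tissue$labels != s[["wm"]]),
    !any(truth$structural$labels > 0L & !truth$brain_mask),
    !any(truth$tissue$labels > 0L & !truth$brain_mask),
    all(truth$bias$pd > 0), all(truth$bias$t2 > 0)
  )
  invisible(TRUE)
}

#' Analytic expected class volumes of a phantom spec
#'
#' Closed-form ellipsoid volumes of the tissue layers (mm^3), used to check
#' voxelized class proportions against their geometric expectation.
#'
#' @param spec A [phantom_spec()].
#' @return Named vector of expected volumes (mm^3) for csf, gm, wm.
#' @export
expected_class_volumes <- function(spec) {
  vol_ell <- function(axes) 4 / 3 * pi * prod(axes)
  v_brain <- vol_ell(spec$brain_axes)
  v_vent <- length(spec$ventricle_centers) * vol_ell(spec$ventricle_axes)
  c(csf = v_brain * (1 - spec$csf_frac^3) + v_vent,
    gm = v_brain * (spec$csf_frac^3 - spec$gm_frac^3),
    wm = v_brain * spec$gm_frac^3 - v_vent)
}

#' Draw a balanced labeled training set from phantoms
#'
#' Samples `(pd, t2, label)` triples from the true-class voxels of one or
#' more generated phantoms, balanced per tissue class. WMSA voxels are
#' excluded (the automated stage classifies three classes only).
#'
#' @param specs A [phantom_spec()] or list of them (the training scans).
#' @param n_per_class Samples per class (>= 2).
#' @param seed Seed for the sampling (independent of the phantom seeds).
#' @return A tibble with columns `pd`, `t2`, `label`.
#' @export
sample_training_set <- function(specs, n_per_class = 100L, seed = 1L) {
  if (inherits(specs, "phantom_spec")) specs <- list(specs)
  if (n_per_class < 2L) neo_stop("n_per_class must be >= 2", "neoseg_value_error")
  pools <- list()
  for (spec in specs) {
    ph <- generate_phantom(spec)
    lab <- ph$truth$tissue$labels
    lab[ph$truth$wmsa] <- 0L
    keep <- lab > 0L
    pools[[length(pools) + 1L]] <-
      data.frame(pd = ph$volume$pd[keep], t2 = ph$volume$t2[keep],
                 label = lab[keep])
  }
  pool <- do.call(rbind, pools)
  set.seed(seed)
  out <- lapply(1:3, function(k) {
    sub <- pool[pool$label == k, ]
    if (!nrow(sub)) {
      neo_stop(sprintf("class %d absent from the training phantoms", k),
               "neoseg_sampling_error")
    }
    sub[sample.int(nrow(sub), n_per_class, replace = nrow(sub) < n_per_class), ]
  })
  tibble::as_tibble(do.call(rbind, out))
}
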