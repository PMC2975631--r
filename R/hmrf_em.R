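#' Configuration for the hidden Markov random field EM
#'
#' @param beta Potts coupling strength (>= 0); `beta = 0` removes all spatial
#'   coupling. Default 1.
#' @param neighborhood `"8-2d"` (8 neighbours within each axial slice, the
#'   default, matching the in-plane processing convention and the strong
#'   slice-thickness anisotropy) or `"6-3d"`.
#' @param max_em Maximum EM iterations (default 20).
#' @param max_icm Maximum ICM sweeps per EM iteration (default 5).
#' @param tol Stop when the fraction of voxels changing label in one EM
#'   iteration falls below this (default 1e-4).
#' @param cov_model `"tied"` (default) shares one pooled covariance across
#'   the three classes; `"full"` fits a separate covariance per class.
#'   Under partial-volume mixing, per-class covariances let the
#'   intermediate-intensity class inflate along the mixing axis and swallow
#'   boundary shells, so the tied model is the safer default; the full model
#'   remains available for well-separated data.
#' @param bias Estimate and correct a multiplicative bias field (default
#'   TRUE).
#' @param bias_scale_mm Gaussian smoothing scale of the bias field in mm
#'   (default 25).
#' @param verbose Print per-iteration progress.
#' @return A list of class `neo_mrf_config`.
#' @export
mrf_config <- function(beta = 1, neighborhood = c("8-2d", "6-3d"),
                       cov_model = c("tied", "full"),
                       max_em = 20L, max_icm = 5L, tol = 1e-4,
                       bias = TRUE, bias_scale_mm = 25, verbose = FALSE) {
  neighborhood <- match.arg(neighborhood)
  cov_model <- match.arg(cov_model)
  if (beta < 0) neo_stop("beta must be >= 0", "neoseg_value_error")
  if (max_em < 1L || max_icm < 1L || tol <= 0 || bias_scale_mm <= 0) {
    neo_stop("iteration caps, tolerance and bias scale must be positive",
             "neoseg_value_error")
  }
  structure(list(beta = beta, neighborhood = neighborhood,
                 cov_model = cov_model,
                 max_em = as.integer(max_em), max_icm = as.integer(max_icm),
                 tol = tol, bias = bias, bias_scale_mm = bias_scale_mm,
                 verbose = verbose),
            class = "neo_mrf_config")
}

# Per-class negative log density of a 2-D Gaussian, analytic 2x2 inverse.
gauss_nll2 <- function(y, mean, cov) {
  a <- cov[1L, 1L]; b <- cov[1L, 2L]; d <- cov[2L, 2L]
  det <- a * d - b * b
  dx <- y[, 1L] - mean[1L]; dy <- y[, 2L] - mean[2L]
  q <- (d * dx * dx - 2 * b * dx * dy + a * dy * dy) / det
  0.5 * (q + log(det)) + log(2 * pi)
}

regularize_cov <- function(cov) {
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > 1e8) {
    warning("near-singular class covariance regularized")
    cov <- cov + diag(1e-6 * sum(diag(cov)) + 1e-12, 2L)
  }
  cov
}

m_step <- function(y, w, cov_model = "tied") {
  K <- ncol(w)
  nk <- colSums(w)
  if (any(nk < 2)) {
    neo_stop("a tissue class emptied during EM (class collapse)",
             "neoseg_class_collapse_error")
  }
  params <- lapply(seq_len(K), function(k) {
    mu <- colSums(y * w[, k]) / nk[k]
    dx <- sweep(y, 2L, mu)
    cov <- crossprod(dx * w[, k], dx) / nk[k]
    list(mean = mu, cov = (cov + t(cov)) / 2, prop = nk[k] / nrow(y))
  })
  if (cov_model == "tied") {
    pool <- Reduce(`+`, lapply(seq_len(K), function(k) {
      params[[k]]$cov * nk[k]
    })) / sum(nk)
    pool <- regularize_cov(pool)
    for (k in seq_len(K)) params[[k]]$cov <- pool
  } else {
    for (k in seq_len(K)) params[[k]]$cov <- regularize_cov(params[[k]]$cov)
  }
  params
}

emission_nll <- function(y, params) {
  vapply(params, function(p) gauss_nll2(y, p$mean, p$cov),
         numeric(nrow(y)))
}

#' One raster-order ICM sweep
#'
#' Sequentially visits every in-mask voxel (x fastest, then y, then z) and
#' assigns the class minimizing the local energy
#' `emission NLL + beta * (number of in-mask neighbours with a different
#' label)`. A configuration where no single-voxel change lowers the energy is
#' a fixed point. Ties break toward the smaller class code.
#'
#' @param labels [neo_labelmap()] or integer array of current labels
#'   (0 outside the mask).
#' @param volume A [neo_volume()] (bias-corrected intensities).
#' @param params List of per-class parameters (`mean`, `cov`), in class-code
#'   order.
#' @param beta Potts coupling.
#' @param neighborhood `"8-2d"` or `"6-3d"`.
#' @return Integer label array after one sweep.
#' @export
icm_sweep <- function(labels, volume, params, beta, neighborhood = "8-2d") {
  lab <- if (inherits(labels, "neo_labelmap")) labels$labels else labels
  d <- dim(lab)
  inmask <- lab > 0L
  K <- length(params)
  nll <- matrix(0, prod(d), K)
  y <- cbind(volume$pd[inmask], volume$t2[inmask])
  for (k in seq_len(K)) {
    col <- rep(0, prod(d))
    col[inmask] <- gauss_nll2(y, params[[k]]$mean, params[[k]]$cov)
    nll[, k] <- col
  }
  out <- icm_sweep_cpp(as.integer(lab), nll, as.integer(d), beta,
                       as.integer(neighborhood == "6-3d"))
  array(out, d)
}

#' Multiplicative bias-field estimation
#'
#' The gain per channel is `exp(smooth(log intensity - log fitted class
#' mean))`, smoothed in-plane with a Gaussian at the configured scale, and
#' gauge-fixed so the mean gain over the mask is exactly 1. Outside the mask
#' the gain is 1.
#'
#' @param volume A [neo_volume()]; intensities must be strictly positive
#'   inside the mask.
#' @param mask Logical brain mask.
#' @param labels Current crisp labels covering the mask.
#' @param params Per-class parameters (class-code order).
#' @param smoothing_scale_mm Gaussian smoothing scale in mm (default 25).
#' @param weights Optional posterior-probability matrix (in-mask voxels x
#'   classes). When supplied, the fitted mean at each voxel is the
#'   posterior-weighted mixture of class means instead of the crisp label's
#'   mean; at tissue boundaries the mixture interpolates, so partial-volume
#'   voxels do not masquerade as bias. [em_fit()] uses this form.
#' @return List with elements `pd` and `t2`, each a strictly positive gain
#'   array.
#' @export
estimate_bias <- function(volume, mask, labels, params,
                          smoothing_scale_mm = 25, weights = NULL) {
  mask <- as_array3d(mask, "mask") > 0
  lab <- if (inherits(labels, "neo_labelmap")) labels$labels else labels
  sigma_px <- smoothing_scale_mm / volume$spacing[1L]
  out <- list()
  for (ci in c(1L, 2L)) {
    ch <- c("pd", "t2")[ci]
    v <- volume[[ch]]
    if (any(v[mask] <= 0)) {
      neo_stop("nonpositive intensities inside the mask", "neoseg_bias_error")
    }
    mu <- vapply(params, function(p) p$mean[ci], numeric(1))
    resid <- array(0, dim(v))
    fitted <- if (is.null(weights)) mu[lab[mask]] else as.vector(weights %*% mu)
    resid[mask] <- log(v[mask]) - log(fitted)
    sm <- array(0, dim(v))
    for (z in seq_len(dim(v)[3L])) {
      if (any(mask[, , z])) {
        sm[, , z] <- smooth_slice_masked(resid[, , z], mask[, , z], sigma_px)
      }
    }
    gain <- exp(sm)
    gain[!mask] <- 1
    gain[mask] <- gain[mask] / mean(gain[mask])
    out[[ch]] <- gain
  }
  out
}

#' Hidden Markov random field EM segmentation
#'
#' Refines an initial tissue classification by alternating (E) posterior
#' computation under per-class 2-D Gaussian emissions with a Potts MRF prior
#' taken from the current neighbour labels, (M) closed-form mean, covariance
#' and mixing-proportion updates from the posteriors, an optional bias-field
#' update (smoothed log-residuals, see [estimate_bias()]), and raster-order
#' ICM label updates. Iteration stops when the fraction of voxels changing
#' label drops below `config$tol` or after `config$max_em` iterations.
#'
#' With `beta = 0` and bias correction off, the procedure reduces to
#' standard Gaussian-mixture EM (uniform prior) initialized from the supplied
#' labels, and the final labels equal the voxelwise maximum-likelihood
#' classification under the fitted parameters.
#'
#' @param volume A [neo_volume()] (normalized intensities).
#' @param mask Logical brain mask.
#' @param initial_labels Initial [neo_labelmap()] (e.g. from
#'   [classify_initial()]); all three tissue classes must be present.
#' @param config A [mrf_config()].
#' @return An object of class `neo_hmrf_fit`: `labels` (final
#'   [neo_labelmap()]), `params` (per-class mean/cov/proportion),
#'   `bias` (per-channel gain arrays), `iterations`, `changed` (final label
#'   change fraction).
#' @export
em_fit <- function(volume, mask, initial_labels, config = mrf_config()) {
  stopifnot(inherits(volume, "neo_volume"), inherits(config, "neo_mrf_config"))
  mask <- as_array3d(mask, "mask") > 0
  if (!any(mask)) neo_stop("empty mask", "neoseg_value_error")
  lab <- if (inherits(initial_labels, "neo_labelmap")) initial_labels$labels else initial_labels
  lab <- as_array3d(lab, "labels")
  lab[!mask] <- 0L
  classes <- 1:3
  if (!all(classes %in% lab)) {
    neo_stop("initialization must contain all three tissue classes",
             "neoseg_value_error")
  }
  K <- length(classes)
  d <- dim(lab)
  gain <- list(pd = array(1, d), t2 = array(1, d))
  corrected <- volume
  y <- cbind(corrected$pd[mask], corrected$t2[mask])

  # initial parameters from the crisp initialization
  w0 <- matrix(0, nrow(y), K)
  w0[cbind(seq_len(nrow(y)), lab[mask])] <- 1
  params <- m_step(y, w0, config$cov_model)

  iterations <- 0L
  changed <- NA_real_
  for (it in seq_len(config$max_em)) {
    iterations <- it
    lab_prev <- lab
    # E-step: Gaussian emission x Potts prior from current neighbour labels
    nllm <- emission_nll(y, params)
    agree <- neighbor_class_counts(lab, K, config$neighborhood)[as.vector(mask), , drop = FALSE]
    logw <- -nllm + config$beta * agree
    logw <- logw - apply(logw, 1L, max)
    w <- exp(logw)
    w <- w / rowSums(w)
    # M-step
    params <- m_step(y, w, config$cov_model)
    # bias update on the running corrected volume
    if (config$bias) {
      g <- estimate_bias(corrected, mask, lab, params, config$bias_scale_mm,
                         weights = w)
      gain$pd <- gain$pd * g$pd
      gain$t2 <- gain$t2 * g$t2
      corrected$pd <- volume$pd / gain$pd
      corrected$t2 <- volume$t2 / gain$t2
      y <- cbind(corrected$pd[mask], corrected$t2[mask])
    }
    # ICM label updates
    for (sw in seq_len(config$max_icm)) {
      lab_new <- icm_sweep(lab, corrected, params, config$beta,
                           config$neighborhood)
      if (identical(lab_new, lab)) break
      lab <- lab_new
    }
    if (!all(classes %in% lab)) {
      neo_stop("a tissue class emptied during EM (class collapse)",
               "neoseg_class_collapse_error")
    }
    changed <- mean(lab[mask] != lab_prev[mask])
    if (config$verbose) {
      message(sprintf("EM iter %d: %.5f voxels changed label", it, changed))
    }
    if (changed < config$tol) break
  }
  structure(list(labels = neo_labelmap(lab, spacing = volume$spacing),
                 params = stats::setNames(params, classes),
                 bias = gain,
                 iterations = iterations, changed = changed,
                 config = config),
            class = "neo_hmrf_fit")
}

#' @export
print.neo_hmrf_fit <- function(x, ...) {
  cat(sprintf("<neo_hmrf_fit> %d EM iterations, final label-change fraction %.2g\n",
              x$iterations, x$changed))
  for (k in names(x$params)) {
    p <- x$params[[k]]
    cat(sprintf("  class %s: mean (%.2f, %.2f), prop %.3f\n",
                k, p$mean[1], p$mean[2], p$prop))
  }
  invisible(x)
}

# Total Potts energy: sum of emission NLL plus beta x disagreeing neighbour
# pairs (each unordered pair counted once). Used by the monotonicity tests.
total_energy <- function(labels, volume, params, beta, neighborhood = "8-2d") {
  lab <- if (inherits(labels, "neo_labelmap")) labels$labels else labels
  inmask <- lab > 0L
  y <- cbind(volume$pd[inmask], volume$t2[inmask])
  nll <- emission_nll(y, params)
  e_em <- sum(nll[cbind(seq_len(nrow(nll)), lab[inmask])])
  K <- length(params)
  counts <- neighbor_class_counts(lab, K, neighborhood)
  nbr_in <- rowSums(counts)
  agree <- counts[cbind(seq_len(nrow(counts)), pmax(as.vector(lab), 1L))]
  disagree <- sum((nbr_in - agree)[as.vector(inmask)]) / 2
  e_em + beta * disagree
}
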