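# Brute-force local-energy minimization for one voxel, the ICM oracle.
icm_oracle_sweep <- function(lab, pd, t2, params, beta) {
  d <- dim(lab)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (lab[x, y, z] == 0L) next
    e <- vapply(seq_along(params), function(k) {
      p <- params[[k]]
      nll <- neoseg:::gauss_nll2(cbind(pd[x, y, z], t2[x, y, z]), p$mean, p$cov)
      dis <- 0
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        xx <- x + dx; yy <- y + dy
        if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2]) next
        l <- lab[xx, yy, z]
        if (l > 0L && l != k) dis <- dis + 1
      }
      nll + beta * dis
    }, numeric(1))
    lab[x, y, z] <- which.min(e)  # which.min ties to the first (smallest code)
  }
  lab
}

toy_params <- function() {
  list(list(mean = c(210, 220), cov = diag(2) * 25, prop = 1 / 3),
       list(mean = c(150, 130), cov = diag(2) * 25, prop = 1 / 3),
       list(mean = c(120, 90), cov = diag(2) * 25, prop = 1 / 3))
}

test_that("icm_sweep equals exhaustive per-voxel energy minimization", {
  set.seed(12)
  d <- c(5, 5, 2)
  truth <- array(sample(1:3, prod(d), TRUE), d)
  mu <- list(c(210, 220), c(150, 130), c(120, 90))
  pd <- array(rnorm(prod(d), vapply(mu, `[`, numeric(1), 1)[truth], 20), d)
  t2 <- array(rnorm(prod(d), vapply(mu, `[`, numeric(1), 2)[truth], 20), d)
  vol <- neo_volume(pd, t2)
  init <- array(sample(1:3, prod(d), TRUE), d)
  for (beta in c(0, 1, 3)) {
    got <- icm_sweep(init, vol, toy_params(), beta)
    want <- icm_oracle_sweep(init, pd, t2, toy_params(), beta)
    expect_identical(got, want, info = paste("beta =", beta))
  }
})

test_that("icm_sweep with beta 0 is the pure emission argmin", {
  set.seed(13)
  d <- c(6, 6, 1)
  pd <- array(runif(prod(d), 100, 230), d)
  t2 <- array(runif(prod(d), 70, 240), d)
  vol <- neo_volume(pd, t2)
  init <- array(sample(1:3, prod(d), TRUE), d)
  got <- icm_sweep(init, vol, toy_params(), 0)
  y <- cbind(as.vector(pd), as.vector(t2))
  nll <- vapply(toy_params(), function(p) neoseg:::gauss_nll2(y, p$mean, p$cov),
                numeric(prod(d)))
  expect_identical(as.vector(got), max.col(-nll, ties.method = "first"))
})

test_that("a local energy minimum is a fixed point of icm_sweep", {
  set.seed(14)
  d <- c(7, 7, 1)
  pd <- array(rnorm(prod(d), 150, 30), d)
  t2 <- array(rnorm(prod(d), 130, 30), d)
  vol <- neo_volume(pd, t2)
  lab <- array(sample(1:3, prod(d), TRUE), d)
  for (i in 1:20) {
    nxt <- icm_sweep(lab, vol, toy_params(), 1)
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  expect_identical(icm_sweep(lab, vol, toy_params(), 1), lab)
})

test_that("a salt voxel in a homogeneous plate is removed in one sweep", {
  # identical emissions for all classes: the Potts term alone decides
  d <- c(9, 9, 1)
  pd <- array(150, d); t2 <- array(130, d)
  vol <- neo_volume(pd, t2)
  lab <- array(2L, d)
  lab[5, 5, 1] <- 3L
  same <- list(list(mean = c(150, 130), cov = diag(2) * 25),
               list(mean = c(150, 130), cov = diag(2) * 25),
               list(mean = c(150, 130), cov = diag(2) * 25))
  out <- icm_sweep(lab, vol, same, beta = 2)
  expect_identical(unique(as.vector(out)), 2L)
})

test_that("total Potts energy is non-increasing across ICM sweeps", {
  set.seed(15)
  d <- c(10, 10, 2)
  truth <- array(sample(1:3, prod(d), TRUE), d)
  mu <- list(c(210, 220), c(150, 130), c(120, 90))
  pd <- array(rnorm(prod(d), vapply(mu, `[`, numeric(1), 1)[truth], 25), d)
  t2 <- array(rnorm(prod(d), vapply(mu, `[`, numeric(1), 2)[truth], 25), d)
  vol <- neo_volume(pd, t2)
  lab <- array(sample(1:3, prod(d), TRUE), d)
  e_prev <- neoseg:::total_energy(lab, vol, toy_params(), 1)
  for (i in 1:5) {
    lab <- icm_sweep(lab, vol, toy_params(), 1)
    e <- neoseg:::total_energy(lab, vol, toy_params(), 1)
    expect_lte(e, e_prev + 1e-9)
    e_prev <- e
  }
})

test_that("beta 0 with bias off gives the Gaussian ML classification", {
  ph <- generate_phantom(clean_spec(seed = 21L))
  mask <- ph$truth$brain_mask
  init <- classify_initial(ph$volume, mask, clean_training_fm())
  fit <- em_fit(ph$volume, mask, init,
                mrf_config(beta = 0, bias = FALSE, cov_model = "full"))
  y <- cbind(ph$volume$pd[mask], ph$volume$t2[mask])
  nll <- vapply(fit$params, function(p) neoseg:::gauss_nll2(y, p$mean, p$cov),
                numeric(nrow(y)))
  ml <- max.col(-nll, ties.method = "first")
  expect_identical(as.vector(fit$labels$labels[mask]), ml)
})

test_that("beta 0, bias off matches an independent Gaussian-mixture EM", {
  ph <- generate_phantom(clean_spec(seed = 22L))
  mask <- ph$truth$brain_mask
  init <- classify_initial(ph$volume, mask, clean_training_fm())
  fit <- em_fit(ph$volume, mask, init,
                mrf_config(beta = 0, bias = FALSE, cov_model = "full"))
  y <- cbind(ph$volume$pd[mask], ph$volume$t2[mask])
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  mc <- mclust::Mclust(y, G = 3, modelNames = "VVV", verbose = FALSE)
  # match components by nearest means
  ours <- t(vapply(fit$params, function(p) p$mean, numeric(2)))
  theirs <- t(mc$parameters$mean)
  perm <- apply(ours, 1, function(m) {
    which.min(colSums((t(theirs) - m)^2))
  })
  expect_identical(sort(unname(perm)), 1:3)
  for (k in 1:3) {
    expect_equal(ours[k, ], theirs[perm[k], ], tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
})

test_that("EM recovers generating class means and labels on a clean phantom", {
  ph <- generate_phantom(clean_spec(seed = 23L))
  spec <- ph$spec
  mask <- ph$truth$brain_mask
  init <- classify_initial(ph$volume, mask, clean_training_fm())
  fit <- em_fit(ph$volume, mask, init, mrf_config(bias = FALSE))
  gen <- list(spec$means$csf, spec$means$gm, spec$means$wm)
  for (k in 1:3) {
    expect_lt(max(abs(fit$params[[k]]$mean - gen[[k]]) / gen[[k]]), 0.02)
  }
  truth <- ph$truth$tissue$labels
  expect_gte(mean(fit$labels$labels[mask] == truth[mask]), 0.99)
})

test_that("class collapse is reported, not silently reseeded", {
  # initialization whose third class is a single absurd voxel collapses
  ph <- generate_phantom(clean_spec(seed = 24L))
  mask <- ph$truth$brain_mask
  lab <- ph$truth$tissue$labels
  lab[lab == 1L] <- 2L             # remove CSF entirely...
  idx <- which(mask & lab == 2L)
  lab[idx[1:2]] <- 1L              # ...except two arbitrary GM voxels
  expect_error(
    em_fit(ph$volume, mask, neo_labelmap(lab, spacing = ph$spec$spacing),
           mrf_config(beta = 2, bias = FALSE)),
    class = "neoseg_class_collapse_error")
})

test_that("bias gain is about 1 for unbiased input and gauge-fixed", {
  ph <- generate_phantom(phantom_spec(seed = 25L, pv_sigma_mm = 0,
                                      bias_amplitude = 0, noise_sd = 3,
                                      class_sd = 4, wmsa_n = 0L))
  mask <- ph$truth$brain_mask
  spec <- ph$spec
  params <- lapply(c("csf", "gm", "wm"), function(nm) {
    list(mean = spec$means[[nm]], cov = diag(2) * 25)
  })
  g <- estimate_bias(ph$volume, mask, ph$truth$tissue, params)
  expect_lt(max(abs(g$pd[mask] - 1)), 0.01)
  expect_lt(max(abs(g$t2[mask] - 1)), 0.01)
  expect_equal(mean(g$pd[mask]), 1, tolerance = 1e-6)
  expect_equal(mean(g$t2[mask]), 1, tolerance = 1e-6)
})

test_that("an imposed gain ramp is recovered up to smoothing attenuation", {
  spec <- phantom_spec(seed = 26L, pv_sigma_mm = 0, bias_amplitude = 0.2,
                       noise_sd = 2, class_sd = 2, wmsa_n = 0L)
  ph <- generate_phantom(spec)
  mask <- ph$truth$brain_mask
  params <- lapply(c("csf", "gm", "wm"), function(nm) {
    list(mean = spec$means[[nm]], cov = diag(2) * 25)
  })
  g <- estimate_bias(ph$volume, mask, ph$truth$tissue, params)
  expect_gte(cor(g$pd[mask], ph$truth$bias$pd[mask]), 0.95)
  expect_gte(cor(g$t2[mask], ph$truth$bias$t2[mask]), 0.95)
})

test_that("nonpositive in-mask intensities are a bias error", {
  ph <- generate_phantom(clean_spec(seed = 27L))
  mask <- ph$truth$brain_mask
  bad <- ph$volume
  bad$pd[which(mask)[1]] <- -1
  bad$pd <- array(bad$pd, dim(mask))
  params <- toy_params()
  expect_error(estimate_bias(neo_volume(bad$pd, ph$volume$t2), mask,
                             ph$truth$tissue, params),
               class = "neoseg_bias_error")
})
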