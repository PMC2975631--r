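# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# Compact phantom for unit tests: same layer structure as the default at a
# quarter of the voxel count.
small_spec <- function(...) {
  args <- list(dim = c(48L, 48L, 10L), brain_axes = c(7.4, 7, 8.5),
               ventricle_centers = list(c(-1.6, 0, 0), c(1.6, 0, 0)),
               ventricle_axes = c(1.2, 2.4, 2.6),
               wmsa_n = 1L, wmsa_radius_mm = 1.2, seed = 11L)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, args)
}

# A well-separated, artifact-free phantom for parameter-recovery checks:
# no partial volume, no bias, total per-voxel SD 5 against a minimum
# class-mean separation of 50 (10 SD).
clean_spec <- function(seed = 11L, ...) {
  small_spec(pv_sigma_mm = 0, bias_amplitude = 0, noise_sd = 3, class_sd = 4,
             wmsa_n = 0L, seed = seed, ...)
}

default_training_fm <- function() {
  memo("default_fm", {
    train <- sample_training_set(list(phantom_spec(seed = 101L),
                                      phantom_spec(seed = 102L)),
                                 n_per_class = 200L, seed = 5L)
    build_feature_map(train)
  })
}

small_training_fm <- function() {
  memo("small_fm", {
    train <- sample_training_set(list(small_spec(seed = 201L)),
                                 n_per_class = 150L, seed = 6L)
    build_feature_map(train)
  })
}

clean_training_fm <- function() {
  memo("clean_fm", {
    train <- sample_training_set(list(clean_spec(seed = 202L)),
                                 n_per_class = 150L, seed = 7L)
    build_feature_map(train)
  })
}

# Direct (ungridded) kernel-sum classification: the brute-force oracle for
# the Parzen feature map.
parzen_bruteforce <- function(pd, t2, samples, bandwidths) {
  classes <- sort(unique(samples$label))
  dens <- vapply(classes, function(k) {
    s <- samples[samples$label == k, ]
    h <- bandwidths[[as.character(k)]]
    vapply(seq_along(pd), function(i) {
      sum(exp(-((pd[i] - s$pd)^2 + (t2[i] - s$t2)^2) / (2 * h^2)))
    }, numeric(1)) / (nrow(s) * 2 * pi * h^2)
  }, numeric(length(pd)))
  dens <- matrix(dens, ncol = length(classes))
  classes[max.col(dens, ties.method = "first")]
}

# Truth tissue map with the WMSA lesions carrying their own code, the form
# the final merged map is compared against.
truth_with_wmsa <- function(ph) {
  tw <- ph$truth$tissue$labels
  tw[ph$truth$wmsa] <- 4L
  tw
}
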