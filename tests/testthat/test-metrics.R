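# Brute-force voxel enumeration oracle for the overlap indices.
confusion_oracle <- function(ref, auto, code) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(ref)) {
    r <- ref[i] == code; a <- auto[i] == code
    if (r && a) tp <- tp + 1L
    else if (!r && a) fp <- fp + 1L
    else if (r && !a) fn <- fn + 1L
  }
  list(TP = tp, FP = fp, FN = fn)
}

test_that("confusion counts match direct enumeration on crafted maps", {
  ref <- array(0L, c(4, 4, 1)); auto <- array(0L, c(4, 4, 1))
  ref[1:4] <- 2L                   # Ref has 4 class voxels
  auto[3:5] <- 2L                  # Auto has 3, overlap 2
  cc <- confusion(ref, auto, 2L)
  expect_equal(cc[c("TP", "FP", "FN")], list(TP = 2, FP = 1, FN = 2))
  expect_equal(similarity_index(cc), 4 / 7)
  expect_equal(estimation_indices(cc),
               c(cei = 0.5, oei = 0.25, uei = 0.5))

  same <- confusion(ref, ref, 2L)
  expect_equal(same$FP, 0); expect_equal(same$FN, 0)
  expect_equal(similarity_index(same), 1)
  expect_equal(estimation_indices(same), c(cei = 1, oei = 0, uei = 0))

  none <- confusion(ref, auto, 3L)  # class absent from both
  expect_equal(unlist(none), c(TP = 0, FP = 0, FN = 0, ref_size = 0, auto_size = 0))
  expect_true(is.na(similarity_index(none)))
  expect_true(all(is.na(estimation_indices(none))))

  disj <- confusion(array(c(1L, 0L), c(2, 1, 1)), array(c(0L, 1L), c(2, 1, 1)), 1L)
  expect_equal(similarity_index(disj), 0)

  expect_error(confusion(ref, array(0L, c(3, 3, 1)), 1L),
               class = "neoseg_geometry_error")
})

test_that("indices match the enumeration oracle on random label maps", {
  set.seed(41)
  for (i in 1:25) {
    ref <- array(sample(0:3, 16 * 16 * 4, TRUE), c(16, 16, 4))
    auto <- array(sample(0:3, 16 * 16 * 4, TRUE), c(16, 16, 4))
    for (code in 1:3) {
      cc <- confusion(ref, auto, code)
      oc <- confusion_oracle(as.vector(ref), as.vector(auto), code)
      expect_equal(cc$TP, oc$TP); expect_equal(cc$FP, oc$FP); expect_equal(cc$FN, oc$FN)
      si <- similarity_index(cc)
      expect_equal(si, 2 * oc$TP / (2 * oc$TP + oc$FP + oc$FN), tolerance = 1e-12)
      ei <- estimation_indices(cc)
      expect_equal(unname(ei["cei"] + ei["uei"]), 1, tolerance = 1e-12)
      # SI = 2 CEI / (2 CEI + OEI + UEI) algebraically
      expect_equal(si, 2 * ei[["cei"]] / (2 * ei[["cei"]] + ei[["oei"]] + ei[["uei"]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("SI is symmetric in reference and automated; CEI/OEI/UEI are not", {
  ref <- array(0L, c(5, 5, 1)); auto <- array(0L, c(5, 5, 1))
  ref[1:6] <- 1L; auto[4:8] <- 1L
  a <- confusion(ref, auto, 1L); b <- confusion(auto, ref, 1L)
  expect_equal(similarity_index(a), similarity_index(b))
  expect_false(isTRUE(all.equal(estimation_indices(a), estimation_indices(b))))
})

test_that("within-subject SD is the root residual mean square", {
  m <- data.frame(subject = c(1, 1, 2, 2), volume = c(100, 104, 200, 202))
  expect_equal(within_subject_sd(m), sqrt((16 + 4) / 4))
  expect_equal(within_subject_sd(m), sqrt(5))
  # identical repeats give zero
  expect_equal(within_subject_sd(data.frame(subject = c(1, 1, 2, 2),
                                            volume = c(5, 5, 9, 9))), 0)
  # location invariance
  m2 <- m; m2$volume <- m2$volume + 1000
  expect_equal(within_subject_sd(m2), within_subject_sd(m))
  # independent oracle: residual mean square from aov
  set.seed(42)
  m3 <- data.frame(subject = rep(1:8, each = 2), volume = rnorm(16, 100, 10))
  ms <- summary(aov(volume ~ factor(subject), data = m3))[[1]]
  expect_equal(within_subject_sd(m3), sqrt(ms["Residuals", "Mean Sq"]),
               tolerance = 1e-12)
  expect_error(within_subject_sd(data.frame(subject = c(1, 1, 2),
                                            volume = 1:3)),
               class = "neoseg_design_error")
})

test_that("repeatability is 2.77 times the within-subject SD", {
  expect_equal(repeatability(0), 0)
  expect_equal(repeatability(10), 27.7)
  expect_error(repeatability(-1), class = "neoseg_value_error")
})

test_that("one-way ICC matches hand arithmetic and the aov oracle", {
  m <- data.frame(subject = rep(1:3, each = 2),
                  volume = c(10, 12, 20, 19, 30, 31))
  got <- icc(m, "oneway")
  expect_equal(got$estimate, 0.990, tolerance = 1e-3)
  # oracle from aov mean squares
  ms <- summary(aov(volume ~ factor(subject), data = m))[[1]]
  msb <- ms["factor(subject)", "Mean Sq"]; msw <- ms["Residuals", "Mean Sq"]
  expect_equal(got$estimate, (msb - msw) / (msb + msw), tolerance = 1e-10)

  # exact duplicates across distinct subjects give ICC 1
  dup <- data.frame(subject = rep(1:4, each = 2), volume = rep(c(1, 5, 9, 13), each = 2))
  expect_equal(icc(dup, "oneway")$estimate, 1)

  set.seed(43)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    tab <- data.frame(subject = rep(1:10, each = k),
                      volume = rnorm(10 * k, rep(rnorm(10, 0, 50), each = k), 5))
    got <- icc(tab, "oneway")
    ms <- summary(aov(volume ~ factor(subject), data = tab))[[1]]
    msb <- ms["factor(subject)", "Mean Sq"]; msw <- ms["Residuals", "Mean Sq"]
    expect_equal(got$estimate, (msb - msw) / (msb + (k - 1) * msw),
                 tolerance = 1e-10)
  }
})

test_that("one-way ICC ignores which column an observation sits in", {
  set.seed(44)
  tab <- data.frame(subject = rep(1:10, each = 2),
                    rater = rep(1:2, 10),
                    volume = rnorm(20, rep(rnorm(10, 0, 50), each = 2), 5))
  base <- icc(tab, "oneway")$estimate
  swapped <- tab
  flip <- swapped$subject %in% c(2, 5, 7)
  swapped$rater[flip] <- 3 - swapped$rater[flip]
  expect_equal(icc(swapped, "oneway")$estimate, base, tolerance = 1e-12)
})

test_that("two-way absolute-agreement ICC matches the aov mean-square oracle", {
  set.seed(45)
  for (i in 1:5) {
    n <- 10; k <- 2
    tab <- data.frame(subject = rep(1:n, each = k), rater = rep(1:k, n),
                      volume = rnorm(n * k, rep(rnorm(n, 0, 50), each = k) +
                                       rep(c(0, 15), n), 5))
    got <- icc(tab, "twoway")
    ms <- summary(aov(volume ~ factor(subject) + factor(rater),
                      data = tab))[[1]]
    msr <- ms["factor(subject)", "Mean Sq"]
    msc <- ms["factor(rater)", "Mean Sq"]
    mse <- ms["Residuals", "Mean Sq"]
    want <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    expect_equal(got$estimate, want, tolerance = 1e-10)
    expect_true(got$ci_low <= got$estimate && got$estimate <= got$ci_high)
  }
})

test_that("unbalanced designs and degenerate tables are rejected", {
  bad <- data.frame(subject = c(1, 1, 1, 2, 2), rater = c(1, 2, 2, 1, 2),
                    volume = 1:5)
  expect_error(icc(bad), class = "neoseg_design_error")
  flat <- data.frame(subject = rep(1:3, each = 2), volume = rep(7, 6))
  expect_error(icc(flat, "oneway"), class = "neoseg_value_error")
})

test_that("accuracy and reliability reports assemble consistent columns", {
  ph <- generate_phantom(small_spec(seed = 45L))
  rep1 <- accuracy_report(ph$truth$tissue, ph$truth$tissue)
  expect_equal(nrow(rep1), 3)
  expect_true(all(rep1$si == 1))
  expect_true(all(rep1$cei == 1) && all(rep1$oei == 0))

  m <- data.frame(subject = rep(1:3, each = 2), rater = rep(1:2, 3),
                  volume = c(100, 104, 200, 202, 154, 150))
  rel <- reliability_report(m)
  expect_equal(rel$repeatability, 2.77 * rel$within_subject_sd)
  expect_equal(rel$within_subject_sd, within_subject_sd(m))
  expect_equal(rel$icc, icc(m, "oneway")$estimate)

  m$region <- "amygdalae"
  m2 <- m; m2$region <- "caudate"; m2$volume <- m2$volume * 3
  rel2 <- reliability_report(rbind(m, m2))
  expect_equal(nrow(rel2), 2)
  expect_equal(rel2$repeatability, 2.77 * rel2$within_subject_sd)
})
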