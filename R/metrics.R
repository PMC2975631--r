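#' Voxelwise confusion counts for one class
#'
#' True positives, false positives and false negatives of an automated
#' segmentation against a reference, for a single label code.
#'
#' @param ref_labels,auto_labels [neo_labelmap()]s (or integer arrays)
#'   sharing one geometry.
#' @param class_code Label code to evaluate.
#' @return A list with `TP`, `FP`, `FN`, `ref_size`, `auto_size`.
#' @export
confusion <- function(ref_labels, auto_labels, class_code) {
  ref <- if (inherits(ref_labels, "neo_labelmap")) ref_labels$labels else ref_labels
  auto <- if (inherits(auto_labels, "neo_labelmap")) auto_labels$labels else auto_labels
  if (!same_geometry(dim(ref), dim(auto))) {
    neo_stop("reference and automated maps differ in geometry",
             "neoseg_geometry_error")
  }
  r <- ref == class_code
  a <- auto == class_code
  tp <- sum(r & a)
  list(TP = tp, FP = sum(a) - tp, FN = sum(r) - tp,
       ref_size = sum(r), auto_size = sum(a))
}

#' Dice similarity index
#'
#' `SI = 2 TP / (2 TP + FP + FN)`: 1 for perfectly matched segmentations, 0
#' for disjoint nonempty ones. Undefined (NA) when both reference and
#' automated regions are empty — never reported as 0.
#'
#' @param counts A [confusion()] result.
#' @return SI in `[0, 1]`, or `NA` when undefined.
#' @export
similarity_index <- function(counts) {
  denom <- 2 * counts$TP + counts$FP + counts$FN
  if (denom == 0) return(NA_real_)
  2 * counts$TP / denom
}

#' Correct, over- and under-estimation indices
#'
#' All three are relative to the reference region size:
#' `CEI = TP / ref`, `OEI = FP / ref`, `UEI = FN / ref`, so `CEI + UEI = 1`
#' whenever the reference is nonempty. Undefined (all NA) for an empty
#' reference.
#'
#' @param counts A [confusion()] result.
#' @return Named numeric vector `c(cei, oei, uei)`.
#' @export
estimation_indices <- function(counts) {
  if (counts$ref_size == 0) {
    return(c(cei = NA_real_, oei = NA_real_, uei = NA_real_))
  }
  c(cei = counts$TP / counts$ref_size,
    oei = counts$FP / counts$ref_size,
    uei = counts$FN / counts$ref_size)
}

check_measures <- function(measures) {
  measures <- as.data.frame(measures)
  if (!all(c("subject", "volume") %in% names(measures))) {
    neo_stop("measures need columns subject and volume", "neoseg_value_error")
  }
  counts <- table(measures$subject)
  if (any(counts < 2L)) {
    neo_stop("every subject needs >= 2 observations", "neoseg_design_error")
  }
  measures
}

# Wide subject x occasion matrix; errors unless the design is balanced.
measures_matrix <- function(measures) {
  measures <- check_measures(measures)
  col <- if ("rater" %in% names(measures)) measures$rater
         else if ("repeat" %in% names(measures)) measures[["repeat"]]
         else stats::ave(seq_len(nrow(measures)), measures$subject, FUN = seq_along)
  tab <- table(measures$subject, col)
  if (any(tab != 1L)) {
    neo_stop("balanced design required: one observation per subject x occasion",
             "neoseg_design_error")
  }
  stats::xtabs(volume ~ subject + col,
               data = data.frame(subject = measures$subject, col = col,
                                 volume = measures$volume))
}

#' Within-subject standard deviation
#'
#' Square root of the one-way ANOVA residual (within-subject) mean square
#' over repeated volume measurements; for a duplicate design this equals
#' `sqrt(sum(d_i^2) / (2 n))` over the per-subject differences `d_i`.
#'
#' @param measures Data frame with columns `subject` and `volume` (extra
#'   columns such as `rater` or `repeat` are ignored here; filter or pool
#'   before calling, depending on the report being built).
#' @return Within-subject SD, in the units of `volume`.
#' @export
within_subject_sd <- function(measures) {
  measures <- check_measures(measures)
  mu <- stats::ave(measures$volume, measures$subject)
  ssw <- sum((measures$volume - mu)^2)
  dfw <- nrow(measures) - length(unique(measures$subject))
  sqrt(ssw / dfw)
}

#' Repeatability
#'
#' `2.77 x within-subject SD`: for the same subject, the difference between
#' two measurements is expected to be below this for 95% of pairs.
#'
#' @param within_subject_sd Nonnegative within-subject SD.
#' @return Repeatability in the same units.
#' @export
repeatability <- function(within_subject_sd) {
  if (any(within_subject_sd < 0)) {
    neo_stop("within-subject SD must be >= 0", "neoseg_value_error")
  }
  2.77 * within_subject_sd
}

#' Intraclass correlation coefficient from ANOVA mean squares
#'
#' One-way random-effects single-measure ICC(1,1)
#' `(MSB - MSW) / (MSB + (k-1) MSW)` for intra-rater designs (the column
#' factor is an interchangeable repeat), or two-way random-effects
#' single-measure absolute-agreement ICC(2,1) for inter-rater designs.
#' 95% confidence limits use the standard F-based formulas.
#'
#' @param measures Balanced data frame (`subject`, `volume`, plus a `rater`
#'   or `repeat` column defining the occasions).
#' @param model `"oneway"` (default) or `"twoway"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `estimate`, `ci_low`, `ci_high`, `model`.
#' @export
icc <- function(measures, model = c("oneway", "twoway"), conf_level = 0.95) {
  model <- match.arg(model)
  m <- measures_matrix(measures)
  n <- nrow(m); k <- ncol(m)
  alpha <- 1 - conf_level
  grand <- mean(m)
  msb <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msw <- sum((m - rowMeans(m))^2) / (n * (k - 1))
  if (model == "oneway") {
    if (msb == 0 && msw == 0) {
      neo_stop("zero between- and within-subject variance: ICC undefined",
               "neoseg_value_error")
    }
    est <- (msb - msw) / (msb + (k - 1) * msw)
    if (msw == 0) return(list(estimate = 1, ci_low = 1, ci_high = 1, model = model))
    fobs <- msb / msw
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- fobs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    return(list(estimate = est,
                ci_low = (fl - 1) / (fl + k - 1),
                ci_high = (fu - 1) / (fu + k - 1),
                model = model))
  }
  # two-way random, absolute agreement, single measure
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  mse <- (sum((m - outer(rowMeans(m), colMeans(m), "+") + grand)^2)) /
    ((n - 1) * (k - 1))
  denom <- msb + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) {
    neo_stop("zero variance in all directions: ICC undefined",
             "neoseg_value_error")
  }
  est <- (msb - mse) / denom
  if (mse == 0 && msc == 0) {
    return(list(estimate = est, ci_low = est, ci_high = est, model = model))
  }
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f1 <- stats::qf(1 - alpha / 2, n - 1, v)
  f2 <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msb - f1 * mse) /
    (f1 * (k * msc + (k * n - k - n) * mse) + n * msb)
  hi <- n * (f2 * msb - mse) /
    (k * msc + (k * n - k - n) * mse + n * f2 * msb)
  list(estimate = est, ci_low = lo, ci_high = hi, model = model)
}

#' Per-class segmentation accuracy report
#'
#' Assembles SI, CEI, OEI and UEI (plus raw confusion counts) for each
#' requested class, automated against reference.
#'
#' @param ref_map,auto_map [neo_labelmap()]s sharing one geometry.
#' @param classes Label codes to evaluate (default the three tissue
#'   classes).
#' @return A tibble with one row per class.
#' @export
accuracy_report <- function(ref_map, auto_map, classes = 1:3) {
  rows <- lapply(classes, function(k) {
    cc <- confusion(ref_map, auto_map, k)
    ei <- estimation_indices(cc)
    tibble::tibble(class = code_names(k,
                     if (inherits(ref_map, "neo_labelmap")) ref_map$scheme
                     else neoseg_scheme()),
                   code = as.integer(k),
                   TP = cc$TP, FP = cc$FP, FN = cc$FN,
                   si = similarity_index(cc),
                   cei = ei[["cei"]], oei = ei[["oei"]], uei = ei[["uei"]])
  })
  do.call(rbind, rows)
}

#' Reliability report (within-subject SD, repeatability, ICC)
#'
#' Columns follow the reporting convention: within-subject SD, repeatability
#' (always exactly 2.77 x the SD column) and the ICC with its 95% CI. When a
#' `region` column is present, one row per region is produced.
#'
#' @param measures Data frame with `subject`, `volume`, an occasion column
#'   (`rater` or `repeat`), and optionally `region`.
#' @param model ICC model, `"oneway"` (intra-rater) or `"twoway"`
#'   (inter-rater).
#' @return A tibble.
#' @export
reliability_report <- function(measures, model = c("oneway", "twoway")) {
  model <- match.arg(model)
  measures <- as.data.frame(measures)
  if ("region" %in% names(measures)) {
    parts <- split(measures, measures$region)
    out <- lapply(names(parts), function(r) {
      rep1 <- reliability_report(parts[[r]][setdiff(names(measures), "region")],
                                 model)
      tibble::tibble(region = r, rep1)
    })
    return(do.call(rbind, out))
  }
  sd <- within_subject_sd(measures)
  ic <- icc(measures, model)
  tibble::tibble(n_subjects = length(unique(measures$subject)),
                 within_subject_sd = sd,
                 repeatability = repeatability(sd),
                 icc = ic$estimate, icc_low = ic$ci_low,
                 icc_high = ic$ci_high, icc_model = ic$model)
}
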