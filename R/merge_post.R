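#' Relabel misclassified surface white matter as CSF
#'
#' Partial-volume averaging at the brain surface makes subarachnoid CSF look
#' like WM; this step erodes the brain mask `depth` times per axial slice
#' with a 3x3 structuring element and relabels WM voxels in the peeled rim as
#' CSF. No other label is ever changed.
#'
#' @param labels A [neo_labelmap()].
#' @param mask Logical brain mask sharing the geometry.
#' @param depth Rim depth in voxels, 2 or 3 (default 2).
#' @return A [neo_labelmap()] with surface WM relabeled to CSF.
#' @export
relabel_surface_wm <- function(labels, mask, depth = 2L) {
  stopifnot(inherits(labels, "neo_labelmap"))
  depth <- as.integer(depth)
  if (!depth %in% c(2L, 3L)) neo_stop("depth must be 2 or 3", "neoseg_value_error")
  mask <- as_array3d(mask, "mask") > 0
  if (!same_geometry(dim(labels$labels), dim(mask))) {
    neo_stop("labels and mask differ in geometry", "neoseg_geometry_error")
  }
  lab <- labels$labels
  s <- labels$scheme
  empty <- integer(0)
  for (z in seq_len(dim(lab)[3L])) {
    mz <- mask[, , z]
    if (!any(mz)) { empty <- c(empty, z); next }
    rim <- mz & !erode_slice(mz, depth)
    lz <- lab[, , z]
    lz[rim & lz == s[["wm"]]] <- s[["csf"]]
    lab[, , z] <- lz
  }
  if (length(empty)) {
    warning(sprintf("skipped %d empty mask slice(s): %s", length(empty),
                    paste(empty, collapse = ", ")))
  }
  neo_labelmap(lab, spacing = labels$spacing, scheme = s)
}

#' Paste a structural label map onto the tissue map
#'
#' Voxels carrying a structural code (10--18) take it; every other voxel
#' keeps its tissue code. Structural codes always win ("pasted onto"), and
#' the total voxel count is conserved.
#'
#' @param tissue_labels,structural_labels [neo_labelmap()]s sharing one
#'   geometry; the structural map is 0 outside the nine structures.
#' @return The merged [neo_labelmap()].
#' @export
merge_structural <- function(tissue_labels, structural_labels) {
  stopifnot(inherits(tissue_labels, "neo_labelmap"),
            inherits(structural_labels, "neo_labelmap"))
  if (!same_geometry(dim(tissue_labels$labels), dim(structural_labels$labels),
                     tissue_labels$spacing, structural_labels$spacing)) {
    neo_stop("tissue and structural maps differ in geometry",
             "neoseg_geometry_error")
  }
  str_codes <- structural_codes()
  bad <- setdiff(unique(as.vector(structural_labels$labels)), c(0L, str_codes))
  if (length(bad)) {
    neo_stop("structural map may only contain codes 10-18 and 0",
             "neoseg_scheme_error")
  }
  lab <- tissue_labels$labels
  idx <- structural_labels$labels > 0L
  lab[idx] <- structural_labels$labels[idx]
  neo_labelmap(lab, spacing = tissue_labels$spacing,
               scheme = tissue_labels$scheme)
}

#' Relabel rater-approved CSF misclassifications as WMSA
#'
#' Periventricular white matter signal abnormalities overlap CSF in
#' intensity and are systematically mislabeled CSF by the automated stage.
#' Given a rater-approved correction mask, CSF voxels inside it become WMSA;
#' nothing else changes. Mask voxels that are not labeled CSF are counted
#' and reported in the `n_not_csf` attribute, never relabeled — the
#' human-in-the-loop semantics of the correction step.
#'
#' @param labels A [neo_labelmap()].
#' @param correction_mask Logical array marking approved regions.
#' @return A [neo_labelmap()] with attribute `n_not_csf`.
#' @export
relabel_wmsa <- function(labels, correction_mask) {
  stopifnot(inherits(labels, "neo_labelmap"))
  correction_mask <- as_array3d(correction_mask, "correction_mask") > 0
  if (!same_geometry(dim(labels$labels), dim(correction_mask))) {
    neo_stop("labels and correction mask differ in geometry",
             "neoseg_geometry_error")
  }
  s <- labels$scheme
  lab <- labels$labels
  hit <- correction_mask & lab == s[["csf"]]
  lab[hit] <- s[["wmsa"]]
  out <- neo_labelmap(lab, spacing = labels$spacing, scheme = s)
  attr(out, "n_not_csf") <- sum(correction_mask & !hit)
  out
}

#' Suggest periventricular WMSA candidate regions for review
#'
#' Returns CSF-labeled connected components (per axial slice, 4-connected)
#' that are not connected to the subarachnoid surface and lie within
#' `max_distance_mm` of a ventricular/periventricular reference region —
#' the places where WM signal abnormality is typically mislabeled CSF.
#' The output is a proposal for human review, never applied automatically.
#'
#' @param labels A [neo_labelmap()].
#' @param reference Logical array (e.g. ventricle mask) or a
#'   [neo_labelmap()] whose nonzero voxels form the reference region.
#' @param mask Logical brain mask (defines the subarachnoid surface).
#' @param max_distance_mm In-plane distance limit from the reference region
#'   (default 10).
#' @return Logical candidate mask (possibly empty).
#' @export
suggest_wmsa_candidates <- function(labels, reference, mask,
                                    max_distance_mm = 10) {
  stopifnot(inherits(labels, "neo_labelmap"))
  ref <- if (inherits(reference, "neo_labelmap")) reference$labels > 0L else
    as_array3d(reference, "reference") > 0
  mask <- as_array3d(mask, "mask") > 0
  s <- labels$scheme
  lab <- labels$labels
  d <- dim(lab)
  out <- array(FALSE, d)
  radius_px <- max_distance_mm / labels$spacing[1L]
  for (z in seq_len(d[3L])) {
    csf <- lab[, , z] == s[["csf"]]
    if (!any(csf)) next
    mz <- mask[, , z]
    surface <- mz & !erode_slice(mz, 1L)
    near <- dilate_slice(ref[, , z], radius_px)
    comp <- label_components_slice(csf)
    surf_ids <- setdiff(unique(comp[surface]), 0)
    near_ids <- setdiff(unique(comp[near]), 0)
    keep <- setdiff(near_ids, surf_ids)
    if (length(keep)) out[, , z] <- matrix(comp %in% keep, d[1L], d[2L])
  }
  out
}

#' Run the full semi-automated segmentation pipeline
#'
#' Executes brain extraction, anisotropic diffusion, optional histogram
#' normalization, Parzen-window initial classification, HMRF-EM refinement,
#' morphological surface relabeling, optional structural-map merging and
#' optional rater-mask-driven WMSA relabeling, and emits a per-stage log and
#' a volume report. The pipeline is deterministic: identical inputs and
#' configuration give bit-identical labels.
#'
#' @param volume A [neo_volume()].
#' @param feature_map A [build_feature_map()] result on the pipeline's
#'   working intensity scale.
#' @param mask Optional precomputed brain mask; if `NULL`, `seed_voxel`,
#'   `low` and `high` drive [extract_brain_mask()].
#' @param seed_voxel,low,high Region-growing inputs (used when `mask` is
#'   `NULL`).
#' @param norm_model Optional [fit_normalization()] model; if `NULL` the
#'   intensities are assumed to be on the feature map's scale already.
#' @param structural Optional structural [neo_labelmap()] to merge.
#' @param wmsa_mask Optional rater-approved correction mask for
#'   [relabel_wmsa()].
#' @param config An [mrf_config()].
#' @param surface_depth Rim depth for [relabel_surface_wm()] (default 2).
#' @param diffusion_iter Anisotropic diffusion iterations (default 10).
#' @return A list of class `neo_pipeline_result`: `labels` (final
#'   [neo_labelmap()]), `bias`, `report` (volume tibble), `mask`, `fit`
#'   (the `neo_hmrf_fit`), and `stages` (per-stage timing log).
#' @export
run_pipeline <- function(volume, feature_map, mask = NULL,
                         seed_voxel = NULL, low = NULL, high = NULL,
                         norm_model = NULL, structural = NULL,
                         wmsa_mask = NULL, config = mrf_config(),
                         surface_depth = 2L, diffusion_iter = 10L) {
  stopifnot(inherits(volume, "neo_volume"))
  stages <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      neo_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "neoseg_pipeline_error")
    })
    stages[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  mask <- tick("brain_mask", {
    if (is.null(mask)) {
      if (is.null(seed_voxel) || is.null(low) || is.null(high)) {
        neo_stop("either a mask or seed_voxel/low/high must be supplied",
                 "neoseg_value_error")
      }
      extract_brain_mask(volume, seed_voxel, low, high)
    } else {
      as_array3d(mask, "mask") > 0
    }
  })
  volume <- tick("diffusion", {
    v <- volume
    v$pd <- anisotropic_diffusion(v$pd, n_iter = diffusion_iter)
    v$t2 <- anisotropic_diffusion(v$t2, n_iter = diffusion_iter)
    v
  })
  if (!is.null(norm_model)) {
    volume <- tick("normalization", apply_normalization(volume, mask, norm_model))
  }
  initial <- tick("parzen", classify_initial(volume, mask, feature_map))
  fit <- tick("hmrf_em", em_fit(volume, mask, initial, config))
  labels <- tick("surface_relabel",
                 relabel_surface_wm(fit$labels, mask, surface_depth))
  if (!is.null(structural)) {
    labels <- tick("merge_structural", merge_structural(labels, structural))
  }
  if (!is.null(wmsa_mask)) {
    labels <- tick("wmsa_relabel", relabel_wmsa(labels, wmsa_mask))
  }
  report <- tick("report", volume_report(labels))
  structure(list(labels = labels, bias = fit$bias, report = report,
                 mask = mask, fit = fit, initial = initial, stages = stages),
            class = "neo_pipeline_result")
}

#' @export
print.neo_pipeline_result <- function(x, ...) {
  cat("<neo_pipeline_result>\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-18s %6.2f s\n", nm, x$stages[[nm]]))
  }
  print(x$report)
  invisible(x)
}
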