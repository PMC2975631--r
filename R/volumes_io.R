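#' Two-channel (PD, T2) intensity volume
#'
#' Container for co-registered dual-echo scans: a proton-density-weighted and
#' a T2-weighted 3-D intensity grid sharing one voxel geometry. Both channels
#' must have identical dimensions and strictly positive voxel spacing, and all
#' intensities must be finite.
#'
#' @param pd,t2 3-D numeric arrays of identical dimensions.
#' @param spacing Voxel size in mm per axis (length 3, strictly positive).
#' @return An object of class `neo_volume` with elements `pd`, `t2`, `spacing`.
#' @export
neo_volume <- function(pd, t2, spacing = c(1, 1, 1)) {
  pd <- as_array3d(pd, "pd"); t2 <- as_array3d(t2, "t2")
  if (!same_geometry(dim(pd), dim(t2))) {
    neo_stop("pd and t2 channels differ in dimensions", "neoseg_geometry_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    neo_stop("spacing must be 3 strictly positive numbers", "neoseg_geometry_error")
  }
  if (any(!is.finite(pd)) || any(!is.finite(t2))) {
    neo_stop("intensities must be finite", "neoseg_value_error")
  }
  structure(list(pd = pd, t2 = t2, spacing = spacing), class = "neo_volume")
}

#' @export
print.neo_volume <- function(x, ...) {
  d <- dim(x$pd)
  cat(sprintf("<neo_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Integer label map sharing a volume's geometry
#'
#' @param labels 3-D integer array of label codes.
#' @param spacing Voxel size in mm per axis.
#' @param scheme Named integer vector of registered codes
#'   (default [neoseg_scheme()]). Every voxel value must be registered.
#' @return An object of class `neo_labelmap` with elements `labels`,
#'   `spacing`, `scheme`.
#' @export
neo_labelmap <- function(labels, spacing = c(1, 1, 1), scheme = neoseg_scheme()) {
  scheme <- validate_scheme(scheme)
  labels <- as_array3d(labels, "labels")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), scheme)
  if (length(bad)) {
    neo_stop(sprintf("unregistered label code(s): %s",
                     paste(bad, collapse = ", ")), "neoseg_scheme_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    neo_stop("spacing must be 3 strictly positive numbers", "neoseg_geometry_error")
  }
  structure(list(labels = labels, spacing = spacing, scheme = scheme),
            class = "neo_labelmap")
}

#' @export
print.neo_labelmap <- function(x, ...) {
  d <- dim(x$labels)
  present <- sort(unique(as.vector(x$labels)))
  cat(sprintf("<neo_labelmap> %d x %d x %d voxels, codes: %s\n",
              d[1], d[2], d[3], paste(present, collapse = " ")))
  invisible(x)
}

#' Read a co-registered dual-echo volume pair from NIfTI files
#'
#' @param path_pd,path_t2 Paths to the PD- and T2-weighted NIfTI volumes.
#' @return A [neo_volume()].
#' @export
read_volume <- function(path_pd, path_t2) {
  pd <- RNifti::readNifti(path_pd)
  t2 <- RNifti::readNifti(path_t2)
  sp_pd <- RNifti::pixdim(pd); sp_t2 <- RNifti::pixdim(t2)
  if (!same_geometry(dim(pd), dim(t2), sp_pd, sp_t2)) {
    neo_stop("PD and T2 channels disagree in dimensions or voxel spacing",
             "neoseg_geometry_error")
  }
  neo_volume(as.array(pd), as.array(t2), spacing = sp_pd[seq_len(3L)])
}

#' Write a dual-echo volume pair to NIfTI files
#'
#' Intensities are stored at double precision so a write/read roundtrip is
#' exact.
#'
#' @param volume A [neo_volume()].
#' @param path_pd,path_t2 Output paths (`.nii` or `.nii.gz`).
#' @return Invisibly, the two paths.
#' @export
write_volume <- function(volume, path_pd, path_t2) {
  stopifnot(inherits(volume, "neo_volume"))
  for (ch in c("pd", "t2")) {
    img <- RNifti::asNifti(volume[[ch]])
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, if (ch == "pd") path_pd else path_t2,
                       datatype = "double")
  }
  invisible(c(path_pd, path_t2))
}

#' Write and read label maps as NIfTI with a JSON scheme sidecar
#'
#' Label codes are written as 16-bit integers (lossless for the package's
#' scheme) and the code-to-name mapping is serialized next to the image as
#' `<path>.json`.
#'
#' @param map A [neo_labelmap()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_labelmap` invisibly returns `path`; `read_labelmap` returns
#'   a [neo_labelmap()].
#' @export
write_labelmap <- function(map, path) {
  stopifnot(inherits(map, "neo_labelmap"))
  img <- RNifti::asNifti(map$labels)
  RNifti::pixdim(img) <- map$spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  jsonlite::write_json(as.list(map$scheme), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_labelmap
#' @param scheme Scheme to validate codes against; if `NULL`, the JSON sidecar
#'   is used when present, else [neoseg_scheme()].
#' @export
read_labelmap <- function(path, scheme = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(scheme)) {
    sidecar <- paste0(path, ".json")
    scheme <- if (file.exists(sidecar)) {
      unlist(jsonlite::read_json(sidecar))
    } else {
      neoseg_scheme()
    }
  }
  neo_labelmap(as.array(img), spacing = RNifti::pixdim(img)[seq_len(3L)],
               scheme = scheme)
}

#' Volume of one labelled region in cubic millimetres
#'
#' Voxel count of the code multiplied by the voxel volume; zero when the code
#' is absent.
#'
#' @param map A [neo_labelmap()].
#' @param code A registered label code.
#' @return Volume in mm^3.
#' @export
volume_mm3 <- function(map, code) {
  stopifnot(inherits(map, "neo_labelmap"))
  if (!code %in% map$scheme) {
    neo_stop(sprintf("code %s is not registered in the scheme", code),
             "neoseg_scheme_error")
  }
  sum(map$labels == code) * prod(map$spacing)
}

#' Per-region volume report
#'
#' One row per code present in the map (background excluded), with voxel
#' counts and volumes in mm^3.
#'
#' @param map A [neo_labelmap()].
#' @return A tibble with columns `structure`, `code`, `voxels`, `mm3`.
#' @export
volume_report <- function(map) {
  stopifnot(inherits(map, "neo_labelmap"))
  codes <- sort(setdiff(unique(as.vector(map$labels)), 0L))
  vox <- vapply(codes, function(k) sum(map$labels == k), numeric(1))
  tibble::tibble(structure = code_names(codes, map$scheme),
                 code = codes,
                 voxels = as.integer(vox),
                 mm3 = vox * prod(map$spacing))
}
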