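#' Read a 4D perfusion series from NIfTI
#'
#' Reads a 4D NIfTI file into the canonical w x h x s x f order. TR/TE are
#' taken from the explicit arguments first, then from a YAML sidecar
#' (`<stem>.yaml` with fields `tr_s`, `te_s`), and TR alone can fall back
#' to the NIfTI time-dimension pixdim. Frame times default to `k * TR`.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param tr_s,te_s optional metadata overrides in seconds.
#' @param voxel_mm optional length-3 override of voxel size in mm.
#' @return A [perfusion_series].
#' @export
read_series <- function(path, tr_s = NULL, te_s = NULL, voxel_mm = NULL) {
  img <- RNifti::readNifti(path)
  x <- unclass(img)
  if (length(dim(x)) != 4L)
    stop(sprintf("expected a 4D NIfTI, got %dD: %s",
                 length(dim(x)), path), call. = FALSE)
  pix <- attr(img, "pixdim")
  side <- sidecar_path(path)
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  if (is.null(tr_s)) tr_s <- meta$tr_s
  if (is.null(te_s)) te_s <- meta$te_s
  if (is.null(tr_s) && length(pix) >= 4 && is.finite(pix[4]) && pix[4] > 0)
    tr_s <- pix[4]
  if (is.null(tr_s) || is.null(te_s))
    stop("TR/TE unavailable: pass `tr_s`/`te_s` or provide a YAML sidecar",
         call. = FALSE)
  if (is.null(voxel_mm)) {
    voxel_mm <- if (length(pix) >= 3 && all(is.finite(pix[1:3])) &&
                    all(pix[1:3] > 0)) abs(pix[1:3]) else c(1, 1, 1)
  }
  perfusion_series(x, tr_s = tr_s, te_s = te_s, voxel_mm = voxel_mm)
}

#' Write a perfusion series to NIfTI (plus YAML metadata sidecar)
#'
#' @param series a [perfusion_series].
#' @param path output `.nii` / `.nii.gz` path.
#' @param sidecar write a `<stem>.yaml` with `tr_s`/`te_s`? Default TRUE.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, sidecar = TRUE) {
  stopifnot(inherits(series, "perfusion_series"))
  img <- RNifti::asNifti(series$signal)
  RNifti::pixdim(img) <- c(series$voxel_mm, series$tr_s)
  RNifti::writeNifti(img, path)
  if (sidecar)
    yaml::write_yaml(list(tr_s = series$tr_s, te_s = series$te_s),
                     sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(stem, ".yaml")
}

#' Read / write a 3D volume (mask or parameter map)
#'
#' `read_volume` returns a bare 3D array with a `voxel_mm` attribute;
#' `write_volume` accepts a 3D array or a [volume_mask].
#'
#' @param path NIfTI file path.
#' @return `read_volume`: 3D array; `write_volume`: `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  x <- unclass(img)
  if (length(dim(x)) == 4L && dim(x)[4] == 1L) dim(x) <- dim(x)[1:3]
  if (length(dim(x)) != 3L)
    stop(sprintf("expected a 3D NIfTI: %s", path), call. = FALSE)
  pix <- attr(img, "pixdim")
  attr(x, "voxel_mm") <- if (length(pix) >= 3) abs(pix[1:3]) else c(1, 1, 1)
  x
}

#' @param vol 3D array or [volume_mask].
#' @param voxel_mm voxel size used when `vol` is a bare array.
#' @rdname read_volume
#' @export
write_volume <- function(vol, path, voxel_mm = c(1, 1, 1)) {
  if (inherits(vol, "volume_mask")) {
    voxel_mm <- vol$voxel_mm
    vol <- vol$mask
  }
  stopifnot(is.array(vol), length(dim(vol)) == 3L)
  img <- RNifti::asNifti(vol + 0)  # force numeric storage
  RNifti::pixdim(img) <- voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an AIF curve as a two-column CSV
#'
#' Columns `time_s, concentration`, the interchange format used by the
#' command-line tools.
#'
#' @param curve numeric concentration vector.
#' @param times_s acquisition times, same length.
#' @param path output CSV path.
#' @export
write_aif_csv <- function(curve, times_s, path) {
  stopifnot(length(curve) == length(times_s))
  utils::write.csv(data.frame(time_s = times_s, concentration = curve),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aif_csv
#' @return `read_aif_csv`: data.frame with `time_s`, `concentration`.
#' @export
read_aif_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "concentration") %in% names(df)))
  df
}
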