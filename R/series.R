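#' Construct a 4D perfusion series
#'
#' The canonical in-memory container for bolus-tracking perfusion data: a
#' 4D signal array ordered width x height x slices x frames, plus the
#' acquisition metadata every downstream step needs (frame interval,
#' echo time, voxel size, per-frame acquisition times).
#'
#' @param signal 4D numeric array, dims `w x h x s x f`, non-negative.
#' @param tr_s frame interval in seconds (time between dynamic volumes).
#' @param te_s echo time in seconds.
#' @param voxel_mm length-3 numeric, voxel edge lengths in mm.
#' @param frame_times_s optional length-`f` vector of acquisition times in
#'   seconds; defaults to `(0:(f-1)) * tr_s`.
#' @return A `perfusion_series` object (list with fields `signal`, `tr_s`,
#'   `te_s`, `voxel_mm`, `frame_times_s`).
#' @export
#' @examples
#' x <- array(100, dim = c(4, 4, 2, 6))
#' ser <- perfusion_series(x, tr_s = 1.5, te_s = 0.0026)
#' dim(ser$signal)
perfusion_series <- function(signal, tr_s, te_s, voxel_mm = c(1, 1, 1),
                             frame_times_s = NULL) {
  if (!is.array(signal) || length(dim(signal)) != 4L)
    stop("`signal` must be a 4D array (w x h x s x f)", call. = FALSE)
  d <- dim(signal)
  if (any(d < 1L) || d[4] < 2L)
    stop("all dims must be >= 1 and the series needs >= 2 frames",
         call. = FALSE)
  if (any(signal < 0)) stop("signal values must be >= 0", call. = FALSE)
  stopifnot(is.numeric(tr_s), tr_s > 0, is.numeric(te_s), te_s > 0,
            length(voxel_mm) == 3L, all(voxel_mm > 0))
  if (is.null(frame_times_s)) frame_times_s <- (seq_len(d[4]) - 1) * tr_s
  if (length(frame_times_s) != d[4] || any(diff(frame_times_s) <= 0))
    stop("`frame_times_s` must have length f and be strictly increasing",
         call. = FALSE)
  structure(
    list(signal = signal, tr_s = tr_s, te_s = te_s,
         voxel_mm = as.numeric(voxel_mm),
         frame_times_s = as.numeric(frame_times_s)),
    class = "perfusion_series")
}

#' @export
print.perfusion_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf(
    "<perfusion_series> %d x %d x %d voxels, %d frames | TR %.3g s, TE %.4g s, voxel %s mm\n",
    d[1], d[2], d[3], d[4], x$tr_s, x$te_s,
    paste(signif(x$voxel_mm, 3), collapse = " x ")))
  invisible(x)
}

#' Construct a 3D binary volume mask
#'
#' @param mask 3D array coercible to 0/1 (logical or numeric).
#' @param voxel_mm length-3 voxel edge lengths in mm.
#' @return A `volume_mask` object; `$mask` is an integer 0/1 array.
#' @export
volume_mask <- function(mask, voxel_mm = c(1, 1, 1)) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array", call. = FALSE)
  m <- mask
  if (is.logical(m)) m <- m * 1L
  if (!all(m %in% c(0, 1)))
    stop("mask values must be 0/1", call. = FALSE)
  storage.mode(m) <- "integer"
  structure(list(mask = m, voxel_mm = as.numeric(voxel_mm)),
            class = "volume_mask")
}

#' @export
print.volume_mask <- function(x, ...) {
  cat(sprintf("<volume_mask> %s | %d voxels set\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask)))
  invisible(x)
}

#' Rearrange a 4D series into a network stream tensor
#'
#' The two CNN streams consume the same 4D data in different axis orders:
#' the spatial stream frame by frame then slice by slice (`f x s x w x h`),
#' the temporal stream slice by slice then frame by frame
#' (`s x f x w x h`). The operation is a pure axis permutation.
#'
#' @param series a [perfusion_series], or a bare 4D array in w x h x s x f
#'   order.
#' @param layout `"spatial"` or `"temporal"`.
#' @return A `stream_tensor` object with fields `data` and `layout`.
#' @export
to_stream <- function(series, layout = c("spatial", "temporal")) {
  layout <- match.arg(layout)
  x <- if (inherits(series, "perfusion_series")) series$signal else series
  if (!is.array(x) || length(dim(x)) != 4L)
    stop("need a 4D array or perfusion_series", call. = FALSE)
  perm <- if (layout == "spatial") c(4, 3, 1, 2) else c(3, 4, 1, 2)
  structure(list(data = aperm(x, perm), layout = layout),
            class = "stream_tensor")
}

#' Invert a stream tensor back to canonical w x h x s x f order
#'
#' @param stream a `stream_tensor` from [to_stream()].
#' @return 4D array in w x h x s x f order.
#' @export
from_stream <- function(stream) {
  stopifnot(inherits(stream, "stream_tensor"))
  perm <- if (stream$layout == "spatial") c(4, 3, 1, 2) else c(3, 4, 1, 2)
  aperm(stream$data, order(perm))
}
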