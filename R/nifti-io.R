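#' Read / write volumes as NIfTI-1
#'
#' Spacing is stored in `pixdim` and the origin in the qform/sform
#' translation (axis-aligned grids only; oblique acquisitions are out of
#' scope).  Masks and labels are written as uint8, scalar volumes as
#' float64 so round-trips are exact.
#'
#' @param vol A `wb_volume`.
#' @param path Path ending in `.nii` or `.nii.gz`.
#' @param type Volume type to assign on read.
#' @return `read_volume` returns a `wb_volume`.
#' @export
write_volume <- function(vol, path) {
  im <- RNifti::asNifti(vol$values)
  RNifti::pixdim(im) <- vol$spacing
  m <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  m <- structure(m, code = 2L)
  RNifti::qform(im) <- m
  RNifti::sform(im) <- m
  dtype <- if (vol$type %in% c("mask", "label")) "uint8" else "double"
  RNifti::writeNifti(im, path, datatype = dtype)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, type = c("scalar", "mask", "label")) {
  type <- match.arg(type)
  im <- RNifti::readNifti(path)
  x <- RNifti::xform(im)
  spacing <- RNifti::pixdim(im)[1:3]
  if (max(abs(x[1:3, 1:3] - diag(spacing))) > 1e-3 * max(spacing))
    stop("only axis-aligned NIfTI volumes are supported: ", path)
  origin <- x[1:3, 4]
  volume(array(as.double(im), dim(im)[1:3]), spacing, origin, type = type)
}

#' Write a displacement field as a 4D (x,y,z,3) NIfTI
#' @param field A `wb_field`.
#' @param path Output path.
#' @export
write_field <- function(field, path) {
  g <- field$geometry
  im <- RNifti::asNifti(field$u)
  RNifti::pixdim(im) <- c(g$spacing, 1)
  m <- rbind(cbind(diag(g$spacing), g$origin), c(0, 0, 0, 1))
  m <- structure(m, code = 2L)
  RNifti::qform(im) <- m
  RNifti::sform(im) <- m
  RNifti::writeNifti(im, path, datatype = "double")
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 4L || d[4] != 3L) stop("not a displacement field: ", path)
  x <- RNifti::xform(im)
  g <- grid_geometry(d[1:3], RNifti::pixdim(im)[1:3], x[1:3, 4])
  structure(list(geometry = g, u = array(as.double(im), d)),
            class = "wb_field")
}
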