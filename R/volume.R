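#' 3-D intensity volume
#'
#' A `volume3d` wraps a 3-D numeric array of quantized gray levels in
#' `[0, Q-1]` together with its voxel spacing in millimetres. All pipeline
#' stages consume and return this container.
#'
#' @param data numeric 3-D array of intensities.
#' @param spacing numeric length-3, voxel spacing in mm per axis.
#' @param Q number of gray levels; intensities live on `0..Q-1`.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), Q = 256L) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            length(spacing) == 3, all(spacing > 0), Q >= 16)
  structure(list(data = data, spacing = as.numeric(spacing), Q = as.integer(Q)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm, Q=%d\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              x$Q))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Binary vessel mask
#'
#' Foreground mask of the delineated vasculature on the same grid as its
#' source volume, with 26-connected component labels.
#'
#' @param mask logical 3-D array.
#' @param spacing voxel spacing, mm.
#' @param labels optional integer array of component labels (0 = background);
#'   computed by 26-connected labeling when omitted.
#' @return An object of class `vessel_mask`.
#' @export
vessel_mask <- function(mask, spacing = c(1, 1, 1), labels = NULL) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  mask <- array(as.logical(mask), dim(mask))
  if (is.null(labels)) {
    labels <- array(cpp_label3d(as.vector(mask), dim(mask), 26L), dim(mask))
  }
  structure(list(mask = mask, labels = labels, spacing = as.numeric(spacing)),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %s voxels, %d foreground, %d component(s)\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask),
              max(x$labels)))
  invisible(x)
}

quantize <- function(x, Q) {
  pmin(pmax(round(x), 0), Q - 1)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over \pkg{RNifti} that carry the voxel spacing in the
#' header. Masks are stored as 0/1 volumes.
#'
#' @param x a `volume3d` or `vessel_mask`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param Q gray levels assumed when reading a volume.
#' @return `read_volume` returns a `volume3d`; `read_mask` a `vessel_mask`.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "vessel_mask")) {
    img <- RNifti::asNifti(array(as.numeric(x$mask), dim(x$mask)))
  } else {
    stopifnot(inherits(x, "volume3d"))
    img <- RNifti::asNifti(x$data)
  }
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, Q = 256L) {
  img <- RNifti::readNifti(path)
  volume3d(array(as.numeric(img), dim(img)[1:3]),
           spacing = RNifti::pixdim(img)[1:3], Q = Q)
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  vessel_mask(array(as.numeric(img) > 0.5, dim(img)[1:3]),
              spacing = RNifti::pixdim(img)[1:3])
}
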