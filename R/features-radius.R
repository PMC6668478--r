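#' Euclidean distance map of a vessel mask
#'
#' Exact anisotropy-aware Euclidean distance (mm) from every foreground
#' voxel center to the nearest background voxel center (so a one-voxel-wide
#' vessel maps to one spacing unit); background voxels are 0.
#'
#' @param mask a [vessel_mask()] or logical array.
#' @param spacing voxel spacing, mm (taken from the mask when available).
#' @return numeric 3-D array of distances in mm.
#' @export
distance_transform <- function(mask, spacing = NULL) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask
  if (is.null(spacing))
    spacing <- if (inherits(mask, "vessel_mask")) mask$spacing else c(1, 1, 1)
  if (all(m)) stop("all-foreground volume has no background boundary")
  array(sqrt(cpp_edt_sq(as.vector(m), dim(m), as.numeric(spacing))), dim(m))
}

# medial-axis voxels as the 26-neighborhood ridge of the distance map:
# foreground voxels whose distance value is >= all neighbours' (plateaus
# retained, so a tube keeps its full centerline)
skeletonize <- function(mask, dmap) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask
  nmax <- neighborhood_max(dmap)
  m & dmap >= nmax - 1e-9
}

#' Local vessel radii at the medial axis
#'
#' Samples the distance map at skeleton voxels (distance-ridge medial axis),
#' the standard local-radius estimator for tubular structures. Set
#' `all_voxels = TRUE` to sample every foreground voxel instead (sensitivity
#' analysis).
#'
#' @param mask a [vessel_mask()].
#' @param dmap precomputed [distance_transform()]; computed when `NULL`.
#' @param all_voxels sample all foreground voxels instead of the skeleton.
#' @return numeric vector of radii in mm (empty, with a warning, for an
#'   empty mask).
#' @export
vessel_radii <- function(mask, dmap = NULL, all_voxels = FALSE) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask
  if (!any(m)) {
    warning("empty vessel mask: no radii")
    return(numeric(0))
  }
  if (is.null(dmap)) dmap <- distance_transform(mask)
  if (all_voxels) return(dmap[m])
  dmap[skeletonize(m, dmap)]
}

#' Empirical CDF of vascular radii
#'
#' `F(x) = P(X <= x)` of the radius sample, with the median radius (midpoint
#' of the two central order statistics for even sample sizes). The CDF value
#' at which the curve saturates summarizes the caliber of the whole
#' vascular tree, enabling within-subject temporal comparisons.
#'
#' @param X numeric radius sample, mm (non-empty).
#' @return An object of class `radius_cdf`: sorted support `x`, `F` values
#'   at the support, `median_radius_mm`, the sample `X` and the
#'   interpolating function `cdf_fun`.
#' @export
radius_cdf <- function(X) {
  if (length(X) == 0) stop("empty radius sample")
  fn <- stats::ecdf(X)
  x <- sort(unique(X))
  structure(list(x = x, F = fn(x), median_radius_mm = median(X),
                 X = X, cdf_fun = fn),
            class = "radius_cdf")
}

#' @export
print.radius_cdf <- function(x, ...) {
  cat(sprintf("<radius_cdf> n=%d, median radius %.3f mm, range [%.3f, %.3f]\n",
              length(x$X), x$median_radius_mm, min(x$x), max(x$x)))
  invisible(x)
}

#' Write a radius CDF as two-column CSV
#' @param cdf a `radius_cdf`.
#' @param path output file.
#' @export
write_radius_cdf <- function(cdf, path) {
  write.csv(data.frame(radius_mm = cdf$x, F = cdf$F), path, row.names = FALSE)
  invisible(path)
}

#' Split a mask into lower and upper axial sections
#'
#' Axial split at `z = z_fraction` of the mask's axial extent (a stand-in
#' for the circle-of-Willis plane, which is not computable without
#' anatomy): the lower section is at-and-below the cut, the upper above;
#' the two sections partition the mask exactly.
#'
#' @param mask a [vessel_mask()] or logical array.
#' @param z_fraction split position in (0, 1) along the mask's z extent.
#' @return list with `lower` and `upper` logical arrays and the cut slice
#'   index `z_cut` (lower includes `z_cut`).
#' @export
split_sections <- function(mask, z_fraction = 0.5) {
  stopifnot(z_fraction > 0, z_fraction < 1)
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask
  zs <- which(apply(m, 3, any))
  if (length(zs) == 0) stop("empty mask")
  zmin <- min(zs); zmax <- max(zs)
  z_cut <- zmin - 1L + ceiling(z_fraction * (zmax - zmin + 1L))
  lower <- m
  lower[, , seq_len(dim(m)[3]) > z_cut] <- FALSE
  upper <- m & !lower
  list(lower = lower, upper = upper, z_cut = z_cut)
}
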