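#' Local adaptive refinement configuration
#'
#' Controls the second-stage segmentation: per-slice components, adaptive
#' search windows, local separation thresholds, seed generation and
#' 26-connected region growing.
#'
#' @param min_margin minimum window dilation margin, voxels.
#' @param margin_scale window margin as a fraction of the component's
#'   largest bounding-box side (the margin is the larger of the two rules).
#' @param seed_margin_frac seed contrast margin as a fraction of the
#'   window's class separation `mu_b - mu_o`.
#' @param max_rounds refinement iteration cap.
#' @return An object of class `refine_config`.
#' @export
refine_config <- function(min_margin = 5L, margin_scale = 0.5,
                          seed_margin_frac = 0.25, max_rounds = 5L) {
  structure(list(min_margin = as.integer(min_margin),
                 margin_scale = margin_scale,
                 seed_margin_frac = seed_margin_frac,
                 max_rounds = as.integer(max_rounds)),
            class = "refine_config")
}

#' Per-slice connected components
#'
#' Decomposes each axial slice of a binary mask into 8-connected 2-D
#' components.
#'
#' @param mask a [vessel_mask()] or logical array.
#' @return list of components; each holds `id`, the slice index `z`, the
#'   voxel index matrix `voxels` (columns x, y, z) and the 2-D bounding box
#'   `bbox` (xmin, xmax, ymin, ymax).
#' @export
slice_components <- function(mask) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask
  d <- dim(m)
  out <- list()
  for (z in seq_len(d[3])) {
    sl <- m[, , z]
    if (!any(sl)) next
    lab <- array(cpp_label2d(as.vector(sl), d[1:2], 8L), d[1:2])
    for (id in seq_len(max(lab))) {
      idx <- which(lab == id, arr.ind = TRUE)
      out[[length(out) + 1]] <- list(
        id = length(out) + 1L, z = z,
        voxels = cbind(x = idx[, 1], y = idx[, 2], z = z),
        bbox = c(xmin = min(idx[, 1]), xmax = max(idx[, 1]),
                 ymin = min(idx[, 2]), ymax = max(idx[, 2])))
    }
  }
  out
}

#' Adaptive search window around a component
#'
#' The component's bounding box dilated in-plane by
#' `max(min_margin, round(margin_scale * max side))` and extended to the
#' preceding and succeeding slices, clipped to the grid.
#'
#' @param component one element of [slice_components()].
#' @param cfg a [refine_config()].
#' @param grid_dim integer length-3 grid size.
#' @return A `component_window`: the window bounds plus the component.
#' @export
adaptive_window <- function(component, cfg, grid_dim) {
  bb <- component$bbox
  side <- max(bb["xmax"] - bb["xmin"] + 1, bb["ymax"] - bb["ymin"] + 1)
  margin <- max(cfg$min_margin, round(cfg$margin_scale * side))
  win <- c(xmin = max(1, bb[["xmin"]] - margin),
           xmax = min(grid_dim[1], bb[["xmax"]] + margin),
           ymin = max(1, bb[["ymin"]] - margin),
           ymax = min(grid_dim[2], bb[["ymax"]] + margin),
           zmin = max(1, component$z - 1L),
           zmax = min(grid_dim[3], component$z + 1L))
  structure(list(component = component, bounds = win), class = "component_window")
}

win_index <- function(bounds) {
  list(x = bounds[["xmin"]]:bounds[["xmax"]],
       y = bounds[["ymin"]]:bounds[["ymax"]],
       z = bounds[["zmin"]]:bounds[["zmax"]])
}

#' Local separation threshold of a window
#'
#' `T = (mu_b + mu_o) / 2`, the midpoint of the mean intensity of
#' vessel-labeled voxels and of the remaining voxels inside the window. A
#' window with an empty class, or with `mu_b <= mu_o`, is flagged unusable
#' (skipped, not fatal).
#'
#' @param volume a [volume3d()].
#' @param window a `component_window` from [adaptive_window()].
#' @param labels current logical vessel labeling (array).
#' @return list with `mu_b`, `mu_o`, `T` and `usable`; `NULL` when a class
#'   is empty in the window.
#' @export
local_threshold <- function(volume, window, labels) {
  ix <- win_index(window$bounds)
  v <- volume$data[ix$x, ix$y, ix$z]
  l <- labels[ix$x, ix$y, ix$z]
  nb <- sum(l)
  no <- sum(!l)
  if (nb == 0 || no == 0) return(NULL)
  mu_b <- mean(v[l])
  mu_o <- mean(v[!l])
  list(mu_b = mu_b, mu_o = mu_o, T = (mu_b + mu_o) / 2,
       sd_o = if (no > 1) sd(v[!l]) else 0, usable = mu_b > mu_o)
}

#' Seed generation for missed small vessels
#'
#' Seeds are voxels inside the window with intensity at or above the local
#' threshold `T`, not yet labeled, whose 26-neighborhood maximum intensity
#' exceeds the window's `mu_o` by more than
#' `seed_margin_frac * (mu_b - mu_o)`.
#'
#' @param volume a [volume3d()].
#' @param window a `component_window`.
#' @param thr output of [local_threshold()] for that window.
#' @param initial_mask current logical labeling.
#' @param cfg a [refine_config()].
#' @return integer vector of linear voxel indices (possibly empty).
#' @export
generate_seeds <- function(volume, window, thr, initial_mask, cfg = refine_config()) {
  d <- dim(volume$data)
  b <- window$bounds
  # pad by one voxel for the neighborhood maximum, clipped at the grid
  px <- max(1, b[["xmin"]] - 1):min(d[1], b[["xmax"]] + 1)
  py <- max(1, b[["ymin"]] - 1):min(d[2], b[["ymax"]] + 1)
  pz <- max(1, b[["zmin"]] - 1):min(d[3], b[["zmax"]] + 1)
  sub <- volume$data[px, py, pz]
  nmax <- neighborhood_max(sub)
  # positions of the window proper inside the padded block
  ox <- match(b[["xmin"]]:b[["xmax"]], px)
  oy <- match(b[["ymin"]]:b[["ymax"]], py)
  oz <- match(b[["zmin"]]:b[["zmax"]], pz)
  v <- sub[ox, oy, oz, drop = FALSE]
  nm <- nmax[ox, oy, oz, drop = FALSE]
  lab <- initial_mask[b[["xmin"]]:b[["xmax"]], b[["ymin"]]:b[["ymax"]],
                      b[["zmin"]]:b[["zmax"]], drop = FALSE]
  hit <- v >= thr$T & !lab &
    (nm - thr$mu_o) > cfg$seed_margin_frac * (thr$mu_b - thr$mu_o)
  if (!any(hit)) return(integer(0))
  idx <- which(hit, arr.ind = TRUE)
  gx <- b[["xmin"]] - 1L + idx[, 1]
  gy <- b[["ymin"]] - 1L + idx[, 2]
  gz <- b[["zmin"]] - 1L + idx[, 3]
  as.integer(gx + d[1] * (gy - 1 + d[2] * (gz - 1)))
}

# maximum over the 26-neighborhood (excluding self) of a 3-D array
neighborhood_max <- function(a) {
  d <- dim(a)
  out <- array(-Inf, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    tx <- sx - dx; ty <- sy - dy; tz <- sz - dz
    out[tx, ty, tz] <- pmax(out[tx, ty, tz], a[sx, sy, sz])
  }
  out
}

#' Threshold-gated 3-D region growing
#'
#' Grows 26-connected from the union of the initial mask and the seeds,
#' accepting a voxel when its intensity reaches the applicable per-voxel
#' threshold (the minimum local `T` over covering windows; elsewhere the
#' global fallback). The initial mask is always retained, so the output is
#' a superset of it, and re-running on its own output is a no-op.
#'
#' @param volume a [volume3d()].
#' @param seeds integer linear voxel indices.
#' @param tmap numeric array of per-voxel acceptance thresholds (`Inf`
#'   blocks growth).
#' @param initial_mask logical array.
#' @return A [vessel_mask()].
#' @export
region_grow <- function(volume, seeds, tmap, initial_mask) {
  region <- initial_mask
  region[seeds] <- TRUE
  grown <- cpp_region_grow(as.vector(volume$data), as.vector(region),
                           as.vector(tmap), dim(volume$data))
  vessel_mask(array(grown, dim(volume$data)), spacing = volume$spacing)
}

#' Local adaptive segmentation refinement
#'
#' Orchestrates the second stage: per-slice connected components of the
#' current vasculature, an adaptive window around each, the local threshold
#' `T = (mu_b + mu_o)/2`, seed generation in regions likely to hold missed
#' small vessels, and 26-connected region growing — iterated until no voxel
#' is added or `max_rounds` is reached. Voxels covered by several windows
#' use the most permissive (minimum) `T`.
#'
#' @param volume a [volume3d()].
#' @param initial a [vessel_mask()] from [classify_initial()].
#' @param cfg a [refine_config()].
#' @param global_threshold acceptance threshold where no window applies;
#'   defaults to the lowest gray level of the initial vasculature (pass the
#'   model's Bayesian decision boundary when available).
#' @param mask optional logical array (e.g. the stripped brain) outside of
#'   which no voxel is ever added — skull stripping precedes segmentation,
#'   so bright extracerebral structures must stay out of reach.
#' @return The final [vessel_mask()] (always a superset of `initial`).
#' @export
refine_segmentation <- function(volume, initial, cfg = refine_config(),
                                global_threshold = NULL, mask = NULL) {
  d <- dim(volume$data)
  current <- if (inherits(initial, "vessel_mask")) initial$mask else initial
  if (is.null(global_threshold)) {
    global_threshold <- if (any(current)) min(volume$data[current]) else Inf
  }
  for (round in seq_len(cfg$max_rounds)) {
    comps <- slice_components(current)
    if (length(comps) == 0) break
    tmap <- array(global_threshold, d)
    all_seeds <- integer(0)
    for (cm in comps) {
      win <- adaptive_window(cm, cfg, d)
      thr <- local_threshold(volume, win, current)
      if (is.null(thr) || !thr$usable) next
      # effective acceptance level: never below mu_o + 2 sd_o, so a window
      # whose "vessel" voxels barely clear the local tissue cannot erode
      # into it round after round
      thr$T <- max(thr$T, thr$mu_o + 2 * thr$sd_o)
      ix <- win_index(win$bounds)
      tmap[ix$x, ix$y, ix$z] <- pmin(tmap[ix$x, ix$y, ix$z], thr$T)
      all_seeds <- c(all_seeds, generate_seeds(volume, win, thr, current, cfg))
    }
    if (!is.null(mask)) tmap[!mask] <- Inf
    all_seeds <- unique(all_seeds)
    if (!is.null(mask)) all_seeds <- all_seeds[mask[all_seeds]]
    grown <- region_grow(volume, all_seeds, tmap, current)
    if (sum(grown$mask) == sum(current)) {
      current <- grown$mask
      break
    }
    current <- grown$mask
  }
  vessel_mask(current, spacing = volume$spacing)
}
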