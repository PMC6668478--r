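#' Synthetic vascular phantom specification
#'
#' Describes a seeded synthetic 3-D angiography-like phantom: a set of
#' smooth tubular vessels with known radii embedded in an ellipsoidal
#' "brain" of darker tissue on a dark background, optionally surrounded by a
#' bright marginal shell mimicking skull/fat, degraded by a smooth
#' multiplicative bias field and additive noise. Every stage of the phantom
#' is deterministic for a fixed `seed`, and the rasterized vessel mask is the
#' exact ground truth used to score segmentations.
#'
#' Intensity classes follow the time-of-flight contrast ordering
#' vessel > tissue > background. Defaults emulate an 8-bit MRA volume:
#' class means 200/90/30 gray levels with standard deviations 12/10/8,
#' additive noise sigma 5, and a mild low-order polynomial bias field.
#'
#' @param shape integer length-3 grid size in voxels.
#' @param spacing voxel spacing in mm per axis.
#' @param n_vessels number of vessels.
#' @param radius_range length-2, min/max vessel radius in mm.
#' @param tortuosity_amplitude dimensionless perturbation scale of the
#'   random-walk centerlines; 0 gives straight segments.
#' @param class_means named numeric: mean gray level of `background`,
#'   `tissue`, `vessel` (and `shell` when present).
#' @param class_sds matching standard deviations (>= 0).
#' @param bias_coefs named numeric of low-order polynomial coefficients in
#'   normalized coordinates; names among `x, y, z, xx, yy, zz, xy, xz, yz`.
#'   The field is `1 + sum(coef * term)` and must stay strictly positive.
#' @param noise_sd additive noise standard deviation, gray levels.
#' @param noise_type `"gaussian"` (default) or `"rician"`.
#' @param skull_shell logical; add a bright marginal shell.
#' @param Q number of gray levels (>= 16).
#' @param smooth_window centerline moving-average smoothing window, points.
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         spacing = c(1, 1, 1),
                         n_vessels = 8,
                         radius_range = c(0.75, 3),
                         tortuosity_amplitude = 1.5,
                         class_means = c(background = 30, tissue = 90,
                                         vessel = 200, shell = 190),
                         class_sds = c(background = 8, tissue = 10,
                                       vessel = 12, shell = 12),
                         bias_coefs = c(x = 0.15, y = -0.10, z = 0.10),
                         noise_sd = 5,
                         noise_type = c("gaussian", "rician"),
                         skull_shell = TRUE,
                         Q = 256L,
                         smooth_window = 5L,
                         seed = 1L) {
  noise_type <- match.arg(noise_type)
  stopifnot(length(shape) == 3, all(shape >= 8),
            length(radius_range) == 2, all(radius_range > 0),
            radius_range[1] <= radius_range[2],
            Q >= 16, noise_sd >= 0, tortuosity_amplitude >= 0)
  if (!(class_means[["vessel"]] > class_means[["tissue"]] &&
        class_means[["tissue"]] > class_means[["background"]]))
    stop("TOF-like contrast requires vessel mean > tissue mean > background mean")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_vessels = as.integer(n_vessels),
                 radius_range = as.numeric(radius_range),
                 tortuosity_amplitude = tortuosity_amplitude,
                 class_means = class_means, class_sds = class_sds,
                 bias_coefs = bias_coefs, noise_sd = noise_sd,
                 noise_type = noise_type, skull_shell = skull_shell,
                 Q = as.integer(Q), smooth_window = as.integer(smooth_window),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# evaluate code with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483646L) + 1L)
  force(code)
}

stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 131 + stage * 7919) %% 2147483647)
}

# normalized elliptical radius of mm coordinates (1 at the grid faces)
norm_radius <- function(pts, spec) {
  ext <- (spec$shape - 1) * spec$spacing
  ctr <- ext / 2
  sqrt(((pts[, 1] - ctr[1]) / (ext[1] / 2))^2 +
       ((pts[, 2] - ctr[2]) / (ext[2] / 2))^2 +
       ((pts[, 3] - ctr[3]) / (ext[3] / 2))^2)
}

# interior ("brain tissue") region bound, as a fraction of the half-extent
BRAIN_RHO <- 0.80
SHELL_RHO <- c(0.88, 0.95)
VESSEL_RHO <- 0.72

#' Generate seeded vessel centerlines
#'
#' Centerlines are smoothed random 3-D walks: a unit step direction is
#' perturbed at every step by isotropic Gaussian noise scaled by the
#' tortuosity amplitude, steered back toward the grid center near the brain
#' boundary, and the resulting polyline is smoothed with a moving-average
#' window. With zero amplitude the walk is a straight segment truncated at
#' the brain boundary. Per-point radii are a smooth wobble (+/-10%) around a
#' per-vessel base radius drawn uniformly from `radius_range`, clipped to
#' the range.
#'
#' @param spec a [phantom_spec()].
#' @return A `centerline_set`: list of curves, each with `points`
#'   (n x 3 matrix, mm), `radius` (mm per point) and integer `label`.
#' @export
generate_centerlines <- function(spec) {
  ext <- (spec$shape - 1) * spec$spacing
  ctr <- ext / 2
  # centerlines stay far enough inside the tissue that the full tube (max
  # radius plus a safety voxel) never leaves the brain and cannot touch the
  # marginal shell
  margin_mm <- spec$radius_range[2] + 1.5 * min(spec$spacing)
  rho_cap <- min(VESSEL_RHO, BRAIN_RHO - margin_mm / (min(ext) / 2))
  if (rho_cap <= 0.05 || rho_cap * min(ext) / 2 <= spec$radius_range[1])
    stop("grid too small to contain a vessel of the minimum radius")
  step <- min(spec$spacing)
  n_steps <- max(8L, round(1.2 * max(ext) / step))
  curves <- with_seed(stage_seed(spec$seed, 1L), {
    lapply(seq_len(spec$n_vessels), function(i) {
      # start inside rho <= 0.5
      repeat {
        p <- ctr + (runif(3) - 0.5) * ext * 0.5
        if (norm_radius(matrix(p, 1), spec) <= min(0.5, 0.8 * rho_cap)) break
      }
      d <- rnorm(3); d <- d / sqrt(sum(d^2))
      pts <- matrix(NA_real_, n_steps + 1, 3)
      pts[1, ] <- p
      k <- 1L
      for (s in seq_len(n_steps)) {
        if (spec$tortuosity_amplitude > 0) {
          d <- d + spec$tortuosity_amplitude * 0.15 * rnorm(3)
          rho_next <- norm_radius(matrix(p + step * d, 1), spec)
          if (rho_next > 0.9 * rho_cap) {
            back <- (ctr - p); back <- back / sqrt(sum(back^2))
            d <- d + 2 * back
          }
          d <- d / sqrt(sum(d^2))
          p <- p + step * d
          if (norm_radius(matrix(p, 1), spec) > rho_cap) break
        } else {
          p2 <- p + step * d
          if (norm_radius(matrix(p2, 1), spec) > rho_cap) break
          p <- p2
        }
        k <- k + 1L
        pts[k, ] <- p
      }
      pts <- pts[seq_len(k), , drop = FALSE]
      if (nrow(pts) >= 3 && spec$tortuosity_amplitude > 0) {
        w <- min(spec$smooth_window, nrow(pts))
        pts <- apply(pts, 2, function(col) {
          as.numeric(stats::filter(col, rep(1 / w, w), sides = 2)) -> sm
          sm[is.na(sm)] <- col[is.na(sm)]
          sm
        })
      }
      if (nrow(pts) < 2) { # fall back to a short straight stub
        pts <- rbind(pts[1, ], pts[1, ] + step * d)
      }
      base_r <- runif(1, spec$radius_range[1], spec$radius_range[2])
      t <- seq(0, 1, length.out = nrow(pts))
      wob <- 0.1 * base_r * sin(2 * pi * runif(1, 1, 3) * t + runif(1, 0, 2 * pi))
      r <- pmin(pmax(base_r + wob, spec$radius_range[1]), spec$radius_range[2])
      list(points = pts, radius = r, label = i)
    })
  })
  structure(list(curves = curves), class = "centerline_set")
}

#' @export
print.centerline_set <- function(x, ...) {
  cat(sprintf("<centerline_set> %d curve(s), %d points total\n",
              length(x$curves), sum(vapply(x$curves, function(c)
                nrow(c$points), 1L))))
  invisible(x)
}

#' Rasterize centerlines into a ground-truth vessel mask
#'
#' A voxel is foreground iff its center lies within the locally interpolated
#' tube radius of any centerline segment (exact point-to-segment distance;
#' no skeleton dilation), so rasterized radii match the requested radii.
#' Voxel centers sit at `(index - 1) * spacing` mm.
#'
#' @param centerlines a `centerline_set`.
#' @param spec the matching [phantom_spec()].
#' @return A [vessel_mask()] whose `labels` carry the per-vessel id (first
#'   vessel wins on overlap).
#' @export
rasterize_vessels <- function(centerlines, spec) {
  dims <- spec$shape
  sp <- spec$spacing
  mask <- array(FALSE, dims)
  labels <- array(0L, dims)
  for (cv in centerlines$curves) {
    pts <- cv$points
    r <- cv$radius
    np <- nrow(pts)
    if (np < 2) next
    for (s in seq_len(np - 1)) {
      p0 <- pts[s, ]; p1 <- pts[s + 1, ]
      r0 <- r[s]; r1 <- r[s + 1]
      rmax <- max(r0, r1)
      lo <- pmax(1L, floor(pmin(p0, p1) / sp - rmax / sp) + 1L)
      hi <- pmin(dims, ceiling(pmax(p0, p1) / sp + rmax / sp) + 1L)
      if (any(lo > hi)) next
      ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
      g <- expand.grid(x = (ix - 1) * sp[1], y = (iy - 1) * sp[2],
                       z = (iz - 1) * sp[3])
      d <- p1 - p0
      dd <- sum(d^2)
      vx <- g$x - p0[1]; vy <- g$y - p0[2]; vz <- g$z - p0[3]
      t <- if (dd > 0) pmin(pmax((vx * d[1] + vy * d[2] + vz * d[3]) / dd, 0), 1)
           else rep(0, length(vx))
      qx <- vx - t * d[1]; qy <- vy - t * d[2]; qz <- vz - t * d[3]
      dist <- sqrt(qx^2 + qy^2 + qz^2)
      rloc <- r0 + t * (r1 - r0)
      inside <- dist <= rloc
      if (!any(inside)) next
      idx <- as.matrix(expand.grid(ix, iy, iz))[inside, , drop = FALSE]
      lin <- idx[, 1] + dims[1] * (idx[, 2] - 1 + dims[2] * (idx[, 3] - 1))
      newly <- lin[!mask[lin]]
      mask[lin] <- TRUE
      labels[newly] <- cv$label
    }
  }
  vessel_mask(mask, spacing = sp, labels = labels)
}

# class index map: 0 background, 1 tissue, 2 vessel, 3 shell
phantom_classes <- function(mask, spec) {
  dims <- spec$shape
  idx <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                               seq_len(dims[3])))
  pts <- sweep(idx - 1, 2, spec$spacing, `*`)
  rho <- norm_radius(pts, spec)
  cls <- array(0L, dims)
  cls[array(rho <= BRAIN_RHO, dims)] <- 1L
  if (isTRUE(spec$skull_shell))
    cls[array(rho >= SHELL_RHO[1] & rho <= SHELL_RHO[2], dims)] <- 3L
  cls[mask$mask] <- 2L
  cls
}

#' Synthesize class-conditional intensities
#'
#' Each voxel's gray level is drawn from a Gaussian for its class
#' (background / tissue / vessel / optional shell) and quantized to
#' `[0, Q-1]`. Deterministic per spec seed.
#'
#' @param mask ground-truth [vessel_mask()].
#' @param spec the [phantom_spec()].
#' @return list with `volume` (a [volume3d()]) and `classes` (integer array,
#'   0 = background, 1 = tissue, 2 = vessel, 3 = shell).
#' @export
synthesize_volume <- function(mask, spec) {
  if (any(spec$class_sds < 0)) stop("class standard deviations must be >= 0")
  cls <- phantom_classes(mask, spec)
  names_by_code <- c("background", "tissue", "vessel", "shell")
  vol <- with_seed(stage_seed(spec$seed, 2L), {
    out <- array(0, spec$shape)
    for (code in 0:3) {
      sel <- cls == code
      n <- sum(sel)
      if (n == 0) next
      nm <- names_by_code[code + 1]
      out[sel] <- rnorm(n, spec$class_means[[nm]], spec$class_sds[[nm]])
    }
    out
  })
  list(volume = volume3d(quantize(vol, spec$Q), spec$spacing, spec$Q),
       classes = cls)
}

# evaluate the polynomial bias field (in normalized [-1,1] coordinates)
eval_bias_field <- function(spec) {
  dims <- spec$shape
  xs <- if (dims[1] > 1) seq(-1, 1, length.out = dims[1]) else 0
  ys <- if (dims[2] > 1) seq(-1, 1, length.out = dims[2]) else 0
  zs <- if (dims[3] > 1) seq(-1, 1, length.out = dims[3]) else 0
  cf <- function(nm) if (nm %in% names(spec$bias_coefs)) spec$bias_coefs[[nm]] else 0
  X <- array(rep(xs, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dims)
  1 + cf("x") * X + cf("y") * Y + cf("z") * Z +
    cf("xx") * X^2 + cf("yy") * Y^2 + cf("zz") * Z^2 +
    cf("xy") * X * Y + cf("xz") * X * Z + cf("yz") * Y * Z
}

#' Apply a smooth multiplicative bias field
#'
#' Multiplies the volume by the spec's low-order polynomial field, rescales
#' back into `[0, Q-1]` when the product overflows, and returns the
#' *effective* field (including any rescaling) so recovery can be tested
#' against the truth.
#'
#' @param volume a [volume3d()].
#' @param spec the [phantom_spec()].
#' @return list with `volume` (biased, quantized) and `field` (the effective
#'   multiplicative field actually applied).
#' @export
apply_bias_field <- function(volume, spec) {
  stopifnot(all(is.finite(spec$bias_coefs)))
  field <- eval_bias_field(spec)
  if (min(field) <= 0) stop("bias field must be strictly positive on the grid")
  biased <- volume$data * field
  scale <- 1
  if (max(biased) > volume$Q - 1) {
    scale <- (volume$Q - 1) / max(biased)
    biased <- biased * scale
  }
  list(volume = volume3d(quantize(biased, volume$Q), volume$spacing, volume$Q),
       field = field * scale)
}

#' Add seeded noise
#'
#' Additive zero-mean Gaussian noise by default; Rician
#' (`sqrt((v + n1)^2 + n2^2)`) behind `noise_type = "rician"` in the spec.
#' Output is clipped/quantized to `[0, Q-1]`.
#'
#' @param volume a [volume3d()].
#' @param spec the [phantom_spec()].
#' @return A [volume3d()].
#' @export
add_noise <- function(volume, spec) {
  stopifnot(spec$noise_sd >= 0)
  if (spec$noise_sd == 0) return(volume)
  out <- with_seed(stage_seed(spec$seed, 3L), {
    n <- length(volume$data)
    if (spec$noise_type == "rician") {
      n1 <- rnorm(n, 0, spec$noise_sd)
      n2 <- rnorm(n, 0, spec$noise_sd)
      array(sqrt((as.vector(volume$data) + n1)^2 + n2^2), dim(volume$data))
    } else {
      volume$data + array(rnorm(n, 0, spec$noise_sd), dim(volume$data))
    }
  })
  volume3d(quantize(out, volume$Q), volume$spacing, volume$Q)
}

#' Generate a complete phantom
#'
#' Runs centerline generation, rasterization, intensity synthesis, bias and
#' noise in order and keeps every intermediate ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (degraded volume as seen by the pipeline),
#'   `clean` (pre-bias, pre-noise volume), `truth` (ground-truth
#'   [vessel_mask()]), `centerlines`, `classes`, `bias_field`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  cl <- generate_centerlines(spec)
  truth <- rasterize_vessels(cl, spec)
  syn <- synthesize_volume(truth, spec)
  b <- apply_bias_field(syn$volume, spec)
  noisy <- add_noise(b$volume, spec)
  list(volume = noisy, clean = syn$volume, truth = truth, centerlines = cl,
       classes = syn$classes, bias_field = b$field, spec = spec)
}

#' Write centerlines as CSV
#'
#' Columns: `vessel_id, point_index, x_mm, y_mm, z_mm, radius_mm`.
#' @param centerlines a `centerline_set`.
#' @param path output file.
#' @export
write_centerlines <- function(centerlines, path) {
  rows <- do.call(rbind, lapply(centerlines$curves, function(cv) {
    data.frame(vessel_id = cv$label, point_index = seq_len(nrow(cv$points)),
               x_mm = cv$points[, 1], y_mm = cv$points[, 2],
               z_mm = cv$points[, 3], radius_mm = cv$radius)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
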