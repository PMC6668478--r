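#' GGMRF smoothing parameters
#'
#' Parameters of the edge-preserving generalized Gauss-Markov random field
#' smoother. Each ICM sweep replaces every voxel's gray level by the argmin
#' over candidate levels of
#' \deqn{|q_s - \tilde q_s|^\alpha + \rho^\alpha \lambda^\beta
#'   \sum_{r \in v_s} \eta_{s,r} |\tilde q_s - q_r|^\beta}
#' over the 26-neighborhood \eqn{v_s}, with
#' \eqn{\eta_{s,r} = 1/\sqrt{d}} for squared voxel distance d to the
#' neighbor. `alpha = 2` gives a Gaussian data prior, `alpha = 1` Laplace;
#' `beta` near 2 smooths aggressively while `beta = 1.01` (the default)
#' preserves relatively abrupt edges such as vessel boundaries.
#'
#' The candidate search is exhaustive over gray levels: the local argmin
#' provably lies between the minimum and maximum of the datum and its
#' neighbors, so the restricted scan is exact. `search_radius` can clamp the
#' scan further around the current value (at the cost of exactness) and
#' defaults to the full gray range.
#'
#' @param lambda,rho positive scaling factors.
#' @param alpha data-term exponent, 1 or 2.
#' @param beta smoothing-level control in `[1.01, 2]`.
#' @param n_iterations number of ICM sweeps.
#' @param search_radius max candidate distance from the current level.
#' @return An object of class `ggmrf_params`.
#' @export
ggmrf_params <- function(lambda = 1, rho = 1, alpha = 2, beta = 1.01,
                         n_iterations = 5L, search_radius = Inf) {
  if (!alpha %in% c(1, 2)) stop("alpha must be 1 (Laplace) or 2 (Gaussian)")
  if (beta < 1.01 || beta > 2) stop("beta must lie in [1.01, 2]")
  if (lambda <= 0 || rho <= 0) stop("lambda and rho must be positive")
  structure(list(lambda = lambda, rho = rho, alpha = alpha, beta = beta,
                 n_iterations = as.integer(n_iterations),
                 search_radius = search_radius),
            class = "ggmrf_params")
}

#' Edge-preserving GGMRF smoothing
#'
#' Runs `n_iterations` iterated-conditional-modes sweeps of the GGMRF
#' energy (see [ggmrf_params()]). The global energy — data term plus the
#' pairwise term counted once per unordered neighbor pair — never increases
#' between sweeps.
#'
#' @param volume a [volume3d()].
#' @param params a [ggmrf_params()].
#' @return The smoothed [volume3d()].
#' @seealso [ggmrf_energy()]
#' @export
ggmrf_smooth <- function(volume, params = ggmrf_params()) {
  stopifnot(inherits(volume, "volume3d"), inherits(params, "ggmrf_params"))
  q0 <- as.vector(volume$data)
  cur <- q0
  sr <- if (is.finite(params$search_radius)) as.integer(params$search_radius)
        else volume$Q
  for (i in seq_len(params$n_iterations)) {
    cur <- cpp_ggmrf_sweep(cur, q0, dim(volume$data), params$alpha,
                           params$beta, params$lambda, params$rho,
                           volume$Q, sr)
  }
  volume3d(array(cur, dim(volume$data)), volume$spacing, volume$Q)
}

#' Global GGMRF energy of an estimate
#'
#' @param estimate a [volume3d()] holding the candidate gray levels.
#' @param volume the original [volume3d()] (data term anchor).
#' @param params a [ggmrf_params()].
#' @return The scalar energy.
#' @export
ggmrf_energy <- function(estimate, volume, params = ggmrf_params()) {
  cpp_ggmrf_energy(as.vector(estimate$data), as.vector(volume$data),
                   dim(volume$data), params$alpha, params$beta,
                   params$lambda, params$rho)
}

# face-connected (6-neighborhood) binary erosion / dilation by one voxel
shift6 <- function(m, f) {
  d <- dim(m)
  out <- m
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    sh <- array(if (identical(f, `&`)) TRUE else FALSE, d)
    src <- dst <- list(1:d[1], 1:d[2], 1:d[3])
    keep <- 1:(d[ax] - 1)
    if (s > 0) {
      dst[[ax]] <- keep + 1L; src[[ax]] <- keep
    } else {
      dst[[ax]] <- keep; src[[ax]] <- keep + 1L
    }
    sh[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out <- f(out, sh)
  }
  out
}
erode6 <- function(m) shift6(m, `&`)
dilate6 <- function(m) shift6(m, `|`)

gauss_blur <- function(arr, sigma_vox) {
  array(cpp_gauss_blur3d(as.vector(arr), dim(arr),
                         as.numeric(rep(sigma_vox, length.out = 3))),
        dim(arr))
}

# Otsu threshold on a gray-level histogram (between-class variance maximum).
otsu_threshold <- function(h) {
  h <- h / sum(h)
  q <- seq_along(h) - 1
  w0 <- cumsum(h)
  m <- cumsum(h * q)
  mt <- m[length(m)]
  w1 <- 1 - w0
  between <- (mt * w0 - m)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  q[which.max(between)]
}

# two-threshold (three-class) Otsu: returns c(t_low, t_high) maximizing
# between-class variance; classes are q <= t_low, t_low < q <= t_high,
# q > t_high. Exhaustive over threshold pairs.
otsu_thresholds3 <- function(h) {
  h <- h / sum(h)
  q <- seq_along(h) - 1
  W <- cumsum(h)
  M <- cumsum(h * q)
  n <- length(h)
  best <- -Inf
  bt <- c(0, 1)
  for (t1 in 0:(n - 3)) {
    w1 <- W[t1 + 1]
    if (w1 <= 0) next
    m1 <- M[t1 + 1] / w1
    t2s <- (t1 + 1):(n - 2)
    w2 <- W[t2s + 1] - W[t1 + 1]
    w3 <- 1 - W[t2s + 1]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    m2 <- (M[t2s + 1] - M[t1 + 1]) / w2
    m3 <- (M[n] - M[t2s + 1]) / w3
    mt <- M[n]
    bcv <- w1 * (m1 - mt)^2 + w2 * (m2 - mt)^2 + w3 * (m3 - mt)^2
    bcv[!ok] <- -Inf
    i <- which.max(bcv)
    if (bcv[i] > best) {
      best <- bcv[i]
      bt <- c(t1, t2s[i])
    }
  }
  bt
}

#' Multiplicative bias-field correction
#'
#' Estimates a smooth, strictly positive multiplicative inhomogeneity field
#' by iterative wide-kernel smoothing in the log-intensity domain over
#' foreground voxels (normalized convolution, so the estimate is driven by
#' head voxels and extrapolated elsewhere), then divides it out. The field
#' is mean-normalized to 1 over the foreground, preserving overall scale.
#'
#' @param volume a non-constant, non-negative [volume3d()].
#' @param fwhm_frac Gaussian kernel FWHM as a fraction of the grid extent
#'   per axis (default 0.4 — wide enough that anatomy is not absorbed and
#'   the estimate is reproducible under re-correction).
#' @param n_iterations number of estimate-and-remove passes.
#' @param fg_threshold gray level above which a voxel counts as foreground;
#'   `NULL` picks the tissue band of a three-class Otsu split.
#' @return list with `volume` (corrected, quantized) and `field` (the
#'   estimated strictly positive multiplicative field).
#' @export
correct_bias <- function(volume, fwhm_frac = 0.4, n_iterations = 3L,
                         fg_threshold = NULL) {
  v <- volume$data
  if (all(v == 0)) stop("cannot bias-correct an all-zero volume")
  if (min(v) < 0) stop("volume must be non-negative")
  if (is.null(fg_threshold)) {
    # tissue band: above the background/head split, below the bright
    # vessel/fat split, so the field estimate tracks inhomogeneity of the
    # (nominally homogeneous) tissue rather than anatomy; lightly eroded so
    # partial-volume band-edge voxels cannot destabilize the estimate
    h <- tabulate(as.vector(v) + 1L, nbins = volume$Q)
    t3 <- otsu_thresholds3(h)
    W <- array(as.numeric(v > t3[1] & v <= t3[2]), dim(v))
    W <- W * as.numeric(gauss_blur(W, c(1, 1, 1)) > 0.6)
  } else {
    W <- array(as.numeric(v > fg_threshold), dim(v))
  }
  if (sum(W) == 0) W <- array(1, dim(v))
  sigma_vox <- fwhm_frac * dim(v) / 2.3548
  l <- log(v + 1)
  resid <- l
  f_acc <- array(0, dim(v))
  for (i in seq_len(n_iterations)) {
    num <- gauss_blur(resid * W, sigma_vox)
    den <- gauss_blur(W, sigma_vox)
    fl <- num / pmax(den, 1e-8)
    fl <- fl - sum(fl * W) / sum(W) # zero-mean over foreground
    f_acc <- f_acc + fl
    resid <- resid - fl
  }
  field <- exp(f_acc)
  corrected <- v / field
  structure(list(volume = volume3d(quantize(corrected, volume$Q),
                                   volume$spacing, volume$Q),
                 field = field),
            class = "bias_correction")
}

#' Simplified skull stripping
#'
#' Extracts a single connected brain mask and discards the bright marginal
#' shell (skull/fat, which shares the vessels' appearance). The head is
#' first thresholded from the background (Otsu by default); the deepest
#' interior voxel of the head — the maximum of its Euclidean distance map —
#' seeds the brain, which is taken as the seed's 26-connected component;
#' interior holes (voxel pockets unreachable from the grid border through
#' non-brain voxels) are filled so the cerebral topology is a single solid
#' component. A marginal shell, being separated from the brain surface, is
#' never reached from the interior seed.
#'
#' @param volume a preprocessed [volume3d()].
#' @param threshold background/head gray-level split; `NULL` for Otsu.
#' @return logical 3-D array, the brain mask (one 26-connected component).
#' @export
strip_skull <- function(volume, threshold = NULL) {
  v <- volume$data
  if (is.null(threshold)) {
    # lower split of the three-class (background / tissue / bright) Otsu:
    # the head is everything above background
    h <- tabulate(as.vector(v) + 1L, nbins = volume$Q)
    threshold <- otsu_thresholds3(h)[1]
  }
  head_mask <- v > threshold
  if (!any(head_mask)) stop("no interior region found above the threshold")
  # open the head mask: one-voxel erosion removes thin noise/halo chains
  # that could bridge the brain to the marginal shell, then a constrained
  # geodesic dilation reclaims the true boundary fringe
  eroded <- erode6(head_mask)
  if (!any(eroded)) eroded <- head_mask
  dsq <- cpp_edt_sq(as.vector(eroded), dim(v), volume$spacing)
  seed <- which.max(dsq)
  # 6-connectivity for the head objects: diagonal single-voxel bridges must
  # not merge the brain with the marginal shell
  lab <- array(cpp_label3d(as.vector(eroded), dim(v), 6L), dim(v))
  brain <- lab == lab[seed]
  for (k in 1:2) brain <- (dilate6(brain) & head_mask) | brain
  # fill interior holes: 6-connected background components not touching the
  # grid border belong to the brain
  bg_lab <- array(cpp_label3d(as.vector(!brain), dim(v), 6L), dim(v))
  d <- dim(v)
  border_labs <- unique(c(bg_lab[c(1, d[1]), , ], bg_lab[, c(1, d[2]), ],
                          bg_lab[, , c(1, d[3])]))
  hole <- !brain & !(bg_lab %in% border_labs)
  brain | array(hole, d)
}
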