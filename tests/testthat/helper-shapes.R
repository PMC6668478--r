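# shared fixtures, all built in code

# voxel ball of radius R (voxel units) centered in a padded cube
ball_mask <- function(R, pad = 4) {
  n <- 2 * (R + pad) + 1
  c0 <- R + pad + 1
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  array(sqrt(rowSums(sweep(idx, 2, c0)^2)) <= R, c(n, n, n))
}

# axis-aligned cylinder of radius r along z, length L, in an n x n x L grid
cyl_mask <- function(r, n = 2 * r + 13, L = 40) {
  c0 <- (n + 1) / 2
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:L))
  array(sqrt((idx[, 1] - c0)^2 + (idx[, 2] - c0)^2) <= r, c(n, n, L))
}

# hand-rolled centerline set (points in mm)
make_centerlines <- function(...) {
  structure(list(curves = list(...)), class = "centerline_set")
}

straight_curve <- function(p0, p1, r, label = 1L, n = 2) {
  t <- seq(0, 1, length.out = n)
  list(points = cbind(p0[1] + t * (p1[1] - p0[1]),
                      p0[2] + t * (p1[2] - p0[2]),
                      p0[3] + t * (p1[3] - p0[3])),
       radius = rep(r, n), label = label)
}

# brute-force flood fill (26- or 8-connectivity), independent of the C++ path
brute_flood_labels <- function(mask) {
  d <- dim(mask)
  is3d <- length(d) == 3
  if (!is3d) d <- c(d, 1L)
  lab <- array(0L, d)
  m <- array(mask, d)
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, if (is3d) -1:1 else 0))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (s in which(m)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      for (k in seq_len(nrow(offs))) {
        p <- ci + offs[k, ]
        if (any(p < 1) || any(p > d)) next
        li <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
        if (m[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  array(lab, dim(mask))
}

# brute-force nearest-background distance (mm), all-pairs
brute_edt <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  idx <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  pts <- sweep(idx, 2, spacing, `*`)
  bg <- pts[!mask, , drop = FALSE]
  out <- numeric(nrow(pts))
  fg <- which(mask)
  for (i in fg) {
    dd <- sweep(bg, 2, pts[i, ])
    out[i] <- sqrt(min(rowSums(dd^2)))
  }
  array(out, d)
}

# GGMRF local energy of one candidate gray level at voxel s (oracle form)
ggmrf_local_energy <- function(q0_s, cand, neigh_vals, neigh_eta, params) {
  abs(q0_s - cand)^params$alpha +
    params$rho^params$alpha * params$lambda^params$beta *
      sum(neigh_eta * abs(cand - neigh_vals)^params$beta)
}

# 26-neighbour values and eta weights of voxel (x, y, z) in array a
neigh_of <- function(a, x, y, z) {
  d <- dim(a)
  vals <- c(); eta <- c()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xx <- x + dx; yy <- y + dy; zz <- z + dz
    if (xx < 1 || yy < 1 || zz < 1 || xx > d[1] || yy > d[2] || zz > d[3]) next
    vals <- c(vals, a[xx, yy, zz])
    eta <- c(eta, 1 / sqrt(dx^2 + dy^2 + dz^2))
  }
  list(vals = vals, eta = eta)
}
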