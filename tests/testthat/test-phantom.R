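test_that("phantom generation is deterministic per seed and seed-sensitive", {
  sp <- phantom_spec(shape = c(32, 32, 32), n_vessels = 3, seed = 7)
  a <- generate_phantom(sp)
  b <- generate_phantom(phantom_spec(shape = c(32, 32, 32), n_vessels = 3,
                                     seed = 7))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$mask, b$truth$mask)
  c2 <- generate_centerlines(phantom_spec(shape = c(32, 32, 32),
                                          n_vessels = 3, seed = 8))
  expect_false(identical(a$centerlines$curves[[1]]$points,
                         c2$curves[[1]]$points))
})

test_that("degenerate radius range gives exactly constant radii", {
  sp <- phantom_spec(shape = c(32, 32, 32), n_vessels = 2,
                     radius_range = c(2, 2), seed = 1)
  cl <- generate_centerlines(sp)
  for (cv in cl$curves) expect_true(all(cv$radius == 2))
})

test_that("zero tortuosity amplitude yields straight centerlines", {
  sp <- phantom_spec(shape = c(48, 48, 48), n_vessels = 1,
                     tortuosity_amplitude = 0, seed = 5)
  cl <- generate_centerlines(sp)
  p <- cl$curves[[1]]$points
  expect_gte(nrow(p), 2)
  d0 <- p[nrow(p), ] - p[1, ]
  d0 <- d0 / sqrt(sum(d0^2))
  dev <- apply(p, 1, function(q) {
    v <- q - p[1, ]
    sqrt(sum((v - sum(v * d0) * d0)^2))
  })
  expect_lt(max(dev), 1e-8)
})

test_that("grid too small for the minimum radius errors", {
  expect_error(generate_centerlines(
    phantom_spec(shape = c(8, 8, 8), radius_range = c(5, 6), seed = 1)),
    "too small")
})

test_that("rasterized straight tube volume matches the analytic cylinder", {
  sp <- phantom_spec(shape = c(32, 32, 32), seed = 1)
  # full-grid tube: no end caps inside the volume
  cl <- make_centerlines(straight_curve(c(15, 15, -2), c(15, 15, 33), r = 3))
  m <- rasterize_vessels(cl, sp)
  expect_lt(abs(sum(m$mask) - pi * 9 * 32) / (pi * 9 * 32), 0.05)
})

test_that("empty centerline set rasterizes to background", {
  sp <- phantom_spec(shape = c(16, 16, 16), seed = 1)
  m <- rasterize_vessels(make_centerlines(), sp)
  expect_false(any(m$mask))
})

test_that("two disjoint tubes give two 26-connected components (flood-fill oracle)", {
  sp <- phantom_spec(shape = c(24, 24, 24), seed = 1)
  cl <- make_centerlines(
    straight_curve(c(5, 5, 2), c(5, 5, 21), r = 1.5, label = 1L),
    straight_curve(c(17, 17, 2), c(17, 17, 21), r = 1.5, label = 2L))
  m <- rasterize_vessels(cl, sp)
  expect_equal(max(m$labels), 2L)
  mk <- vessel_mask(m$mask) # recompute connectivity labels
  expect_equal(max(mk$labels), 2L)
  expect_equal(max(brute_flood_labels(m$mask)), 2L)
})

test_that("rasterization agrees with brute-force point-in-tube membership", {
  sp <- phantom_spec(shape = c(20, 20, 20), seed = 2)
  cl <- make_centerlines(straight_curve(c(4, 5, 3), c(15, 14, 17), r = 2.2,
                                        n = 7))
  m <- rasterize_vessels(cl, sp)
  pts <- cl$curves[[1]]$points
  idx <- as.matrix(expand.grid(1:20, 1:20, 1:20))
  ctr <- idx - 1
  inside <- rep(FALSE, nrow(ctr))
  for (s in seq_len(nrow(pts) - 1)) {
    p0 <- pts[s, ]; p1 <- pts[s + 1, ]
    dseg <- p1 - p0
    tt <- pmin(pmax(as.vector(sweep(ctr, 2, p0) %*% dseg) / sum(dseg^2), 0), 1)
    proj <- cbind(p0[1] + tt * dseg[1], p0[2] + tt * dseg[2],
                  p0[3] + tt * dseg[3])
    inside <- inside | sqrt(rowSums((ctr - proj)^2)) <= 2.2
  }
  expect_identical(as.vector(m$mask), inside)
})

test_that("noise-free zero-variance synthesis is piecewise constant at class means", {
  sp <- phantom_spec(shape = c(24, 24, 24), n_vessels = 2, noise_sd = 0,
                     class_sds = c(background = 0, tissue = 0, vessel = 0,
                                   shell = 0),
                     seed = 4)
  ph <- generate_phantom(phantom_spec(shape = c(24, 24, 24), n_vessels = 2,
                                      noise_sd = 0, bias_coefs = c(x = 0),
                                      class_sds = c(background = 0, tissue = 0,
                                                    vessel = 0, shell = 0),
                                      seed = 4))
  v <- ph$volume$data
  expect_true(all(v[ph$classes == 0] == 30))
  expect_true(all(v[ph$classes == 1] == 90))
  expect_true(all(v[ph$classes == 2] == 200))
  expect_setequal(unique(as.vector(v)), c(30, 90, 200, 190)[
    c(30, 90, 200, 190) %in% unique(as.vector(v))])
})

test_that("synthesized class means match the requested means within 2 percent", {
  sp <- phantom_spec(shape = c(64, 64, 64), n_vessels = 12,
                     radius_range = c(2, 3), seed = 9, bias_coefs = c(x = 0),
                     noise_sd = 0)
  ph <- generate_phantom(sp)
  v <- ph$volume$data
  for (k in 0:2) {
    expect_gt(sum(ph$classes == k), 1e4)
    target <- c(30, 90, 200)[k + 1]
    expect_lt(abs(mean(v[ph$classes == k]) - target) / target, 0.02)
  }
})

test_that("bias field application: identity, ratio recovery, analytic extrema", {
  sp0 <- phantom_spec(shape = c(24, 24, 24), bias_coefs = c(x = 0), seed = 2,
                      noise_sd = 0)
  ph <- synthesize_volume(rasterize_vessels(generate_centerlines(sp0), sp0),
                          sp0)
  b0 <- apply_bias_field(ph$volume, sp0)
  expect_identical(b0$volume$data, ph$volume$data)
  expect_true(all(b0$field == 1))

  spl <- phantom_spec(shape = c(24, 24, 24),
                      bias_coefs = c(x = 1 / 3), # 2:1 extent ratio
                      seed = 2, noise_sd = 0)
  bl <- apply_bias_field(ph$volume, spl)
  sel <- ph$volume$data > 50 # quantization-tolerant on bright voxels
  ratio <- bl$volume$data[sel] / ph$volume$data[sel]
  expect_lt(max(abs(ratio - bl$field[sel])), 0.02)
  fr <- range(bl$field) / min(bl$field)
  expect_equal(max(bl$field) / min(bl$field), (1 + 1 / 3) / (1 - 1 / 3),
               tolerance = 1e-6)
  spbad <- phantom_spec(shape = c(24, 24, 24), bias_coefs = c(x = 2), seed = 2)
  expect_error(apply_bias_field(ph$volume, spbad), "positive")
})

test_that("noise stage: identity at zero, calibrated sigma, Rician floor", {
  spc <- phantom_spec(shape = c(32, 32, 32), noise_sd = 0, seed = 3)
  vol <- volume3d(array(128, c(32, 32, 32)))
  expect_identical(add_noise(vol, spc)$data, vol$data)
  sp5 <- phantom_spec(shape = c(32, 32, 32), noise_sd = 5, seed = 3)
  noisy <- add_noise(vol, sp5)
  expect_lt(abs(sd(noisy$data) - 5) / 5, 0.05)
  spr <- phantom_spec(shape = c(32, 32, 32), noise_sd = 5,
                      noise_type = "rician", seed = 3)
  zero <- volume3d(array(0, c(32, 32, 32)))
  ric <- add_noise(zero, spr)
  expect_gt(mean(ric$data), 3) # Rician floor: E|n| = sigma*sqrt(pi/2)
})

test_that("class-mean contrast ordering survives default bias and noise", {
  ph <- generate_phantom(phantom_spec(shape = c(48, 48, 48), seed = 6))
  v <- ph$volume$data
  expect_gt(mean(v[ph$classes == 2]), mean(v[ph$classes == 1]))
  expect_gt(mean(v[ph$classes == 1]), mean(v[ph$classes == 0]))
})
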