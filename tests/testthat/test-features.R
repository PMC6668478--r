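test_that("distance transform: degenerate voxel, ball maximum, brute-force oracle", {
  a <- array(FALSE, c(5, 5, 5))
  a[3, 3, 3] <- TRUE
  expect_equal(distance_transform(a)[3, 3, 3], 1)

  ball <- ball_mask(5, pad = 3)
  dm <- distance_transform(ball)
  expect_lt(abs(max(dm) - 5), 1)

  set.seed(3)
  m <- array(runif(16 * 12 * 10) > 0.6, c(16, 12, 10))
  sp <- c(0.7, 1, 1.3) # anisotropic
  expect_equal(distance_transform(m, sp), brute_edt(m, sp), tolerance = 1e-9)
  expect_error(distance_transform(array(TRUE, c(4, 4, 4))), "background")
})

test_that("medial-axis radii recover tube calibers", {
  sp <- phantom_spec(shape = c(24, 24, 40), seed = 1)
  tube3 <- rasterize_vessels(
    make_centerlines(straight_curve(c(11, 11, 0), c(11, 11, 39), r = 3)), sp)
  X <- vessel_radii(tube3)
  expect_true(all(X > 0))
  expect_lt(abs(median(X) - 3), 0.5)

  sp2 <- phantom_spec(shape = c(32, 32, 40), seed = 1)
  two <- rasterize_vessels(make_centerlines(
    straight_curve(c(8, 8, 0), c(8, 8, 39), r = 2, label = 1L),
    straight_curve(c(22, 22, 0), c(22, 22, 39), r = 4, label = 2L)), sp2)
  X2 <- vessel_radii(two)
  expect_lt(abs(median(X2[X2 < 3]) - 2), 0.5)
  expect_lt(abs(median(X2[X2 >= 3]) - 4), 0.5)
  expect_warning(X0 <- vessel_radii(vessel_mask(array(FALSE, c(4, 4, 4)))),
                 "empty")
  expect_length(X0, 0)
})

test_that("radius CDF counting, medians and stochastic ordering", {
  cdf <- radius_cdf(c(1, 1, 2, 3))
  expect_equal(cdf$cdf_fun(2), 0.75)
  expect_equal(cdf$median_radius_mm, 1.5) # midpoint convention for even n
  cdf2 <- radius_cdf(rep(2.5, 10))
  expect_equal(cdf2$cdf_fun(2.5), 1)
  expect_equal(cdf2$median_radius_mm, 2.5)
  expect_error(radius_cdf(numeric(0)), "empty")
  expect_true(all(diff(cdf$F) >= 0))
  expect_equal(cdf$F[length(cdf$F)], 1)

  # thicker phantom saturates at a larger radius: F_thick(x) <= F_thin(x)
  mk <- function(r, seed) {
    sp <- phantom_spec(shape = c(40, 40, 40), n_vessels = 3,
                       radius_range = c(r, r), tortuosity_amplitude = 1,
                       seed = seed)
    radius_cdf(vessel_radii(rasterize_vessels(generate_centerlines(sp), sp)))
  }
  thin <- mk(2, 5)
  thick <- mk(2.5, 5)
  grid <- seq(0.5, 4, by = 0.1)
  expect_true(all(thick$cdf_fun(grid) <= thin$cdf_fun(grid) + 1e-12))
  expect_lt(max(thin$x), max(thick$x) + 1e-9)
})

test_that("axial sections partition the mask at the requested fraction", {
  ball <- ball_mask(10, pad = 3)
  sec <- split_sections(ball, 0.5)
  expect_true(all((sec$lower | sec$upper) == ball))
  expect_false(any(sec$lower & sec$upper))
  # z-symmetric object with an even slice count splits evenly
  cyl <- cyl_mask(4, L = 30)
  sc <- split_sections(cyl, 0.5)
  expect_lt(abs(sum(sc$lower) - sum(sc$upper)) / sum(cyl), 0.05)
  # a vessel crossing the plane contributes to both sections
  sp <- phantom_spec(shape = c(16, 16, 32), seed = 1)
  tube <- rasterize_vessels(
    make_centerlines(straight_curve(c(7, 7, 2), c(7, 7, 29), r = 1.5)), sp)
  s2 <- split_sections(tube, 0.5)
  expect_gt(sum(s2$lower), 0)
  expect_gt(sum(s2$upper), 0)
  expect_error(split_sections(ball, 1.2))
})

test_that("iso-surface extraction gives closed, oriented, accurate meshes", {
  mesh <- extract_mesh(ball_mask(8))
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 64) / (4 * pi * 64), 0.1)
  expect_gt(mesh_volume(mesh), 0) # outward orientation
  expect_equal(euler_characteristic(mesh), 2)
  # capped tube is a topological sphere too
  tube <- cyl_mask(3, L = 20)
  mt <- extract_mesh(tube)
  expect_equal(euler_characteristic(mt), 2)
  expect_error(extract_mesh(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("vertex normals: tetrahedron hand computation and sphere accuracy", {
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                 c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  faces <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)) # outward
  tet <- structure(list(vertices = verts, faces = faces), class = "trimesh")
  expect_gt(mesh_volume(tet), 0)
  nrm <- vertex_normals(tet, smooth_iters = 0)
  expect_equal(rowSums(nrm^2), rep(1, 4), tolerance = 1e-12)
  # oracle: unnormalized sum of the 3 incident (area-weighted) face normals
  fc <- lapply(1:4, function(f) {
    e1 <- verts[faces[f, 2], ] - verts[faces[f, 1], ]
    e2 <- verts[faces[f, 3], ] - verts[faces[f, 1], ]
    c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
      e1[1] * e2[2] - e1[2] * e2[1])
  })
  v1 <- fc[[1]] + fc[[2]] + fc[[4]] # faces incident on vertex 1
  expect_equal(nrm[1, ], v1 / sqrt(sum(v1^2)), tolerance = 1e-12)

  mesh <- extract_mesh(ball_mask(8))
  nrm <- vertex_normals(mesh)
  ctr <- colMeans(mesh$vertices)
  radial <- sweep(mesh$vertices, 2, ctr)
  radial <- radial / sqrt(rowSums(radial^2))
  ang <- acos(pmin(1, rowSums(nrm * radial))) * 180 / pi
  expect_lt(max(ang), 5)
})

test_that("principal curvatures match analytic sphere, cylinder and plate", {
  mesh <- extract_mesh(ball_mask(8))
  cv <- estimate_principal_curvatures(mesh)
  expect_true(all(cv$values$k1 >= cv$values$k2, na.rm = TRUE))
  expect_true(all(cv$values$H^2 >= cv$values$K - 1e-12, na.rm = TRUE))
  expect_lt(abs(median(cv$values$H, na.rm = TRUE) - 1 / 8) / (1 / 8), 0.1)
  expect_lt(abs(median(cv$values$K, na.rm = TRUE) - 1 / 64) / (1 / 64), 0.1)

  mc <- extract_mesh(cyl_mask(4, L = 40))
  cvc <- estimate_principal_curvatures(mc)
  zc <- mc$vertices[, 3]
  interior <- zc > quantile(zc, 0.2) & zc < quantile(zc, 0.8)
  expect_lt(abs(median(cvc$values$H[interior]) - 1 / 8) / (1 / 8), 0.1)
  expect_lt(abs(median(cvc$values$K[interior])), 0.1 / 16)

  # flat plate: interior is planar
  plate <- array(FALSE, c(30, 30, 12))
  plate[4:27, 4:27, 5:8] <- TRUE
  mp <- extract_mesh(plate)
  cvp <- estimate_principal_curvatures(mp)
  vin <- mp$vertices[, 1] > 8 & mp$vertices[, 1] < 22 &
    mp$vertices[, 2] > 8 & mp$vertices[, 2] < 22
  expect_lt(abs(median(cvp$values$H[vin], na.rm = TRUE)), 0.02)
  expect_lt(abs(median(cvp$values$K[vin], na.rm = TRUE)), 0.002)
})

test_that("curvature summaries: sphere values, scale law, tortuosity ordering", {
  s8 <- curvature_summaries(estimate_principal_curvatures(extract_mesh(ball_mask(8))))
  expect_lt(abs(s8$median_H - 1 / 8) / (1 / 8), 0.1)
  expect_lt(abs(s8$median_K - 1 / 64) / (1 / 64), 0.1)
  # integral |K| over a closed convex surface is ~ 4 pi (Gauss-Bonnet)
  expect_lt(abs(s8$integral_absK - 4 * pi) / (4 * pi), 0.15)
  # scale law: doubling the radius halves H and quarters K
  s16 <- curvature_summaries(estimate_principal_curvatures(extract_mesh(ball_mask(16))))
  expect_equal(s8$median_H / s16$median_H, 2, tolerance = 0.1)
  expect_equal(s8$median_K / s16$median_K, 4, tolerance = 0.2)

  # a helix beats a straight tube of the same caliber and axial extent:
  # the bends must be strong enough (kappa * r > 0.5) to flip |H| locally
  spb <- phantom_spec(shape = c(64, 64, 64), seed = 1)
  zs <- seq(2, 61, by = 0.5)
  straight <- rasterize_vessels(make_centerlines(
    list(points = cbind(31, 31, zs), radius = rep(3, length(zs)),
         label = 1L)), spb)
  helix <- rasterize_vessels(make_centerlines(
    list(points = cbind(31 + 10 * sin(2 * pi * zs / 40),
                        31 + 10 * cos(2 * pi * zs / 40), zs),
         radius = rep(3, length(zs)), label = 1L)), spb)
  cs <- estimate_principal_curvatures(extract_mesh(straight))
  ct <- estimate_principal_curvatures(extract_mesh(helix))
  expect_gt(mean(abs(ct$values$H), na.rm = TRUE),
            mean(abs(cs$values$H), na.rm = TRUE))
  expect_gt(curvature_summaries(ct)$integral_absK,
            curvature_summaries(cs)$integral_absK)
})

test_that("curvature summaries are invariant under lattice rotation", {
  sp <- phantom_spec(shape = c(40, 40, 40), n_vessels = 2,
                     radius_range = c(1.5, 2.5), seed = 8)
  m <- rasterize_vessels(generate_centerlines(sp), sp)$mask
  rot <- aperm(m, c(2, 3, 1)) # exact 90-degree lattice rotation
  s1 <- curvature_summaries(estimate_principal_curvatures(extract_mesh(m)))
  s2 <- curvature_summaries(estimate_principal_curvatures(extract_mesh(rot)))
  for (f in c("median_H", "mean_H", "integral_absK"))
    expect_equal(s1[[f]], s2[[f]], tolerance = 0.02)
})
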